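#' Convert a pair set to dot-bracket notation
#'
#' @param pairs Tibble (or data frame) with 0-based columns `i`, `j`
#'   (`i < j`), describing a pseudoknot-free pairing.
#' @param length Transcript length.
#' @return A dot-bracket string.
#' @export
#' @examples
#' pairs_to_dotbracket(data.frame(i = 0, j = 8), 9)
pairs_to_dotbracket <- function(pairs, length) {
  db <- rep(".", length)
  if (nrow(pairs) > 0) {
    if (any(pairs$i >= pairs$j) || any(pairs$i < 0) ||
        any(pairs$j >= length)) {
      abort("invalid pair coordinates")
    }
    db[pairs$i + 1L] <- "("
    db[pairs$j + 1L] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation into a pair set
#'
#' @param dotbracket A string over `(`, `)`, `.`.
#' @return Tibble with 0-based columns `i`, `j`.
#' @export
dotbracket_to_pairs <- function(dotbracket) {
  ch <- seq_chars(dotbracket)
  if (!all(ch %in% c("(", ")", "."))) abort("invalid dot-bracket character")
  open <- integer(0)
  i <- integer(0)
  j <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      open <- c(open, k)
    } else if (ch[k] == ")") {
      if (length(open) == 0) abort("unbalanced parentheses in dot-bracket")
      i <- c(i, open[length(open)] - 1L)
      j <- c(j, k - 1L)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0) abort("unbalanced parentheses in dot-bracket")
  tibble::tibble(i = as.integer(i), j = as.integer(j)) |>
    dplyr::arrange(.data$i)
}

#' Write structures in dot-bracket format
#'
#' One FASTA-like block per transcript: header, sequence, dot-bracket.
#'
#' @param structures Tibble with columns `transcript_id`, `sequence`,
#'   `dotbracket`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structures, path) {
  bad <- purrr::map_lgl(structures$dotbracket, function(db) {
    tryCatch({ dotbracket_to_pairs(db); FALSE }, error = function(e) TRUE)
  })
  if (any(bad)) {
    abort(sprintf("unbalanced dot-bracket for: %s",
                  paste(structures$transcript_id[bad], collapse = ", ")))
  }
  out <- purrr::pmap(structures[c("transcript_id", "sequence", "dotbracket")],
                     function(transcript_id, sequence, dotbracket)
                       c(paste0(">", transcript_id), sequence, dotbracket))
  writeLines(unlist(out), path)
  invisible(path)
}

#' Read structures from a dot-bracket file
#'
#' @param path Path written by [write_dotbracket()].
#' @return Tibble with columns `transcript_id`, `sequence`, `dotbracket`.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0) abort(sprintf("%s: malformed dot-bracket file",
                                             path))
  hdr <- lines[seq(1, length(lines), by = 3)]
  if (!all(startsWith(hdr, ">"))) abort(sprintf("%s: malformed header", path))
  tibble::tibble(transcript_id = sub("^>", "", hdr),
                 sequence = lines[seq(2, length(lines), by = 3)],
                 dotbracket = lines[seq(3, length(lines), by = 3)])
}

#' Write a structure in CT format
#'
#' Standard 6-column connectivity table, 1-based.
#'
#' @param sequence RNA sequence string.
#' @param pairs Tibble with 0-based columns `i`, `j`.
#' @param path Output path.
#' @param title Structure title for the header line.
#' @return `path`, invisibly.
#' @export
write_ct <- function(sequence, pairs, path, title = "structure") {
  n <- nchar(sequence)
  partner <- rep(0L, n)
  if (nrow(pairs) > 0) {
    partner[pairs$i + 1L] <- pairs$j + 1L
    partner[pairs$j + 1L] <- pairs$i + 1L
  }
  bases <- seq_chars(sequence)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases, seq_len(n) - 1L,
                  c(seq_len(n - 1L) + 1L, 0L), partner, seq_len(n))
  writeLines(c(sprintf("%d %s", n, title), rows), path)
  invisible(path)
}

#' Read a CT file into a pair set
#'
#' @param path Path to a 6-column CT file.
#' @return Tibble with 0-based columns `i`, `j` (each pair listed once).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n)) abort(sprintf("%s: malformed CT header (field 1)", path))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    abort(sprintf("%s: CT row count %d != declared length %d", path,
                  length(body), n))
  }
  fields <- strsplit(trimws(body), "\\s+")
  pos <- as.integer(purrr::map_chr(fields, 1))
  partner <- as.integer(purrr::map_chr(fields, 5))
  if (anyNA(pos) || anyNA(partner)) abort(sprintf("%s: malformed CT row",
                                                  path))
  keep <- partner > pos  # each pair once
  tibble::tibble(i = pos[keep] - 1L, j = partner[keep] - 1L)
}
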