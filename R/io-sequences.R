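#' Read transcript sequences from FASTA
#'
#' Reads a (possibly DNA) FASTA file and returns one row per transcript with
#' the sequence converted to RNA (`T` becomes `U`). Record ids are taken
#' verbatim from the header up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `transcript_id`, `sequence`, `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "ACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("%s: duplicate transcript id(s): %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as_rna(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("%s: empty sequence for id(s): %s", path,
                  paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  purrr::walk2(seqs, ids, check_rna_alphabet)
  tibble::tibble(transcript_id = ids, sequence = unname(seqs),
                 length = nchar(seqs))
}

#' Write transcript sequences to FASTA
#'
#' @param transcripts A tibble with columns `transcript_id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(transcripts))) {
    writeLines(paste0(">", transcripts$transcript_id[k]), con)
    s <- transcripts$sequence[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read region annotation (5'UTR / CDS / 3'UTR boundaries)
#'
#' Accepts either a three-column TSV (`transcript_id`, `cds_start`,
#' `cds_end`; 0-based half-open, i.e. the CDS occupies
#' `[cds_start, cds_end)`) or a transcript-space GFF3 whose `CDS` features
#' are 1-based closed intervals on the transcript (converted on read).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gff3"`.
#' @return A tibble with columns `transcript_id`, `cds_start`, `cds_end`
#'   (0-based half-open).
#' @export
read_annotation <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ann <- readr::read_tsv(path, comment = "#", progress = FALSE,
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             transcript_id = readr::col_character(),
                             cds_start = readr::col_integer(),
                             cds_end = readr::col_integer()))
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    ann <- tibble::tibble(
      transcript_id = as.character(GenomicRanges::seqnames(gr)),
      cds_start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based
      cds_end = GenomicRanges::end(gr))
  }
  if (anyDuplicated(ann$transcript_id)) {
    dup <- unique(ann$transcript_id[duplicated(ann$transcript_id)])
    abort(sprintf("%s: overlapping/multiple region definitions for: %s",
                  path, paste(dup, collapse = ", ")))
  }
  bad <- ann$cds_start < 0 | ann$cds_end < ann$cds_start
  if (any(bad)) {
    abort(sprintf("%s: invalid CDS interval for: %s", path,
                  paste(ann$transcript_id[bad], collapse = ", ")))
  }
  ann
}

#' Assemble the transcript table used throughout the pipeline
#'
#' Joins sequences, region annotation, and (optionally) a homoeolog pair
#' list assigning subgenome labels (`a_id` rows become subgenome `A`,
#' `b_id` rows subgenome `B`, everything else `other`).
#'
#' @param seqs Tibble from [read_fasta()].
#' @param annotation Optional tibble from [read_annotation()]. Every
#'   annotated id must be present in `seqs` and CDS bounds must fit inside
#'   the transcript.
#' @param pairs Optional tibble with columns `a_id`, `b_id`.
#' @return A tibble with columns `transcript_id`, `subgenome`, `sequence`,
#'   `length`, `cds_start`, `cds_end` (`NA` bounds where unannotated).
#' @export
make_transcripts <- function(seqs, annotation = NULL, pairs = NULL) {
  tr <- seqs
  if (!is.null(annotation)) {
    missing_ids <- setdiff(annotation$transcript_id, tr$transcript_id)
    if (length(missing_ids) > 0) {
      abort(sprintf("annotation refers to transcript(s) absent from FASTA: %s",
                    paste(missing_ids, collapse = ", ")))
    }
    tr <- dplyr::left_join(tr, annotation, by = "transcript_id")
    bad <- !is.na(tr$cds_end) & tr$cds_end > tr$length
    if (any(bad)) {
      abort(sprintf("cds_end exceeds transcript length for: %s",
                    paste(tr$transcript_id[bad], collapse = ", ")))
    }
  } else {
    tr$cds_start <- NA_integer_
    tr$cds_end <- NA_integer_
  }
  tr$subgenome <- "other"
  if (!is.null(pairs)) {
    tr$subgenome[tr$transcript_id %in% pairs$a_id] <- "A"
    tr$subgenome[tr$transcript_id %in% pairs$b_id] <- "B"
  }
  dplyr::select(tr, "transcript_id", "subgenome", "sequence", "length",
                "cds_start", "cds_end")
}

#' Write region annotation as transcript-space GFF3
#'
#' One `CDS` feature per annotated transcript, 1-based closed coordinates
#' on the transcript itself; the exact inverse of
#' [read_annotation()]`(format = "gff3")`.
#'
#' @param annotation Tibble with `transcript_id`, `cds_start`, `cds_end`
#'   (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  ann <- annotation[!is.na(annotation$cds_start), ]
  writeLines(c("##gff-version 3",
               sprintf("%s\tribostruct\tCDS\t%d\t%d\t.\t+\t0\tID=cds_%s",
                       ann$transcript_id, ann$cds_start + 1L, ann$cds_end,
                       ann$transcript_id)), path)
  invisible(path)
}
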