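#' Global alignment of a homoeolog pair
#'
#' Needleman-Wunsch with affine gap costs (Gotoh). A gap run of length L
#' costs `gap_open + gap_ext * L`. Traceback is deterministic: on ties the
#' diagonal move wins over a gap in B ("up"), which wins over a gap in A
#' ("left").
#'
#' @param seq_a,seq_b RNA sequences (non-empty).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return An object of class `ribo_alignment`: list with gapped strings
#'   `aligned_a`, `aligned_b`, the `score`, and `map`, a tibble with one
#'   row per alignment column (`column`, 0-based `pos_a`, `pos_b`; `NA`
#'   at gaps).
#' @export
align_pair <- function(seq_a, seq_b, match = 1, mismatch = -1,
                       gap_open = -4, gap_ext = -1) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    abort("align_pair: sequences must be non-empty")
  }
  seq_a <- as_rna(seq_a)
  seq_b <- as_rna(seq_b)
  res <- .nw_align_cpp(encode_rna(seq_a), encode_rna(seq_b), match,
                       mismatch, gap_open, gap_ext)
  ca <- seq_chars(seq_a)
  cb <- seq_chars(seq_b)
  ia <- res$a_idx + 1L
  ib <- res$b_idx + 1L
  ia[ia == 0L] <- NA_integer_
  ib[ib == 0L] <- NA_integer_
  ga <- ifelse(is.na(ia), "-", ca[ia])
  gb <- ifelse(is.na(ib), "-", cb[ib])
  map <- tibble::tibble(
    column = seq_along(res$a_idx) - 1L,
    pos_a = ifelse(res$a_idx < 0, NA_integer_, res$a_idx),
    pos_b = ifelse(res$b_idx < 0, NA_integer_, res$b_idx))
  structure(list(aligned_a = paste(ga, collapse = ""),
                 aligned_b = paste(gb, collapse = ""),
                 score = res$score, map = map),
            class = "ribo_alignment")
}

#' @export
#' @method print ribo_alignment
#' @keywords internal
print.ribo_alignment <- function(x, ...) {
  cat(sprintf("<ribo_alignment> score=%.1f length=%d\n", x$score,
              nrow(x$map)))
  invisible(x)
}

#' Extract SNVs and indels from a pair alignment
#'
#' An SNV is an aligned mismatch column with both bases in ACGU (columns
#' containing `N` are dropped and counted); an indel is a maximal gap run.
#' Substitutions are classified as transition (A<->G, C<->U) or
#' transversion. The per-pair SNV ratio is SNVs / aligned non-gap columns.
#' Region labels use the A transcript's annotation; when the B annotation
#' disagrees the SNV is flagged `discordant_region`.
#'
#' @param alignment A [align_pair()] result.
#' @param annotation_a,annotation_b Optional lists/rows with `cds_start`,
#'   `cds_end` (0-based half-open) for region assignment.
#' @return A list with `snvs` (tibble: `column`, `pos_a`, `pos_b`,
#'   `allele_a`, `allele_b`, `mutation_class`, `region`,
#'   `discordant_region`), `indels` (tibble: `start_column`, `length`,
#'   `which_sequence`), and `counts` (matched, snv, n_dropped, gap
#'   columns, aligned_columns, snv_ratio).
#' @export
extract_variants <- function(alignment, annotation_a = NULL,
                             annotation_b = NULL) {
  ca <- seq_chars(alignment$aligned_a)
  cb <- seq_chars(alignment$aligned_b)
  map <- alignment$map
  gap <- ca == "-" | cb == "-"
  has_n <- !gap & (ca == "N" | cb == "N")
  mism <- !gap & !has_n & ca != cb
  matched <- !gap & !has_n & ca == cb
  transitions <- c(AG = TRUE, GA = TRUE, CU = TRUE, UC = TRUE)
  reg <- function(pos, ann) {
    if (is.null(ann) || is.na(ann$cds_start)) return(NA_character_)
    region_of(pos, ann$cds_start, ann$cds_end)
  }
  snvs <- tibble::tibble(
    column = map$column[mism],
    pos_a = map$pos_a[mism],
    pos_b = map$pos_b[mism],
    allele_a = ca[mism],
    allele_b = cb[mism]) |>
    dplyr::mutate(
      mutation_class = dplyr::if_else(
        paste0(.data$allele_a, .data$allele_b) %in% names(transitions),
        "transition", "transversion"),
      region = purrr::map_chr(.data$pos_a, reg, ann = annotation_a),
      region_b = purrr::map_chr(.data$pos_b, reg, ann = annotation_b),
      discordant_region = !is.na(.data$region) & !is.na(.data$region_b) &
        .data$region != .data$region_b)
  # maximal gap runs
  indels <- purrr::map_dfr(list(c("a", "-"), c("b", "-")), function(spec) {
    v <- if (spec[1] == "a") ca else cb
    r <- rle(v == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    tibble::tibble(start_column = starts[keep] - 1L,
                   length = r$lengths[keep],
                   which_sequence = spec[1])
  })
  n_aligned <- sum(!gap)
  counts <- tibble::tibble(
    matched = sum(matched), snv = sum(mism), n_dropped = sum(has_n),
    gap = sum(gap), aligned_columns = n_aligned,
    snv_ratio = if (n_aligned > 0) sum(mism) / n_aligned else NA_real_)
  list(snvs = snvs, indels = indels, counts = counts)
}

#' Experimental structure disruption coefficient
#'
#' Reactivity profiles of the two homoeologs are projected onto alignment
#' columns; columns with a gap or a missing value in either profile are
#' dropped pairwise. Over the L shared columns,
#' `eSDC = (1 - PearsonR) * L^exponent` (default square root).
#'
#' @param react_a,react_b Per-nucleotide reactivity vectors in transcript
#'   coordinates (`NA` = missing).
#' @param alignment A [align_pair()] result.
#' @param min_shared Minimum shared columns (below: `NA`).
#' @param exponent Exponent on L.
#' @return eSDC (a non-negative number), with attribute `L`.
#' @export
esdc <- function(react_a, react_b, alignment, min_shared = 20,
                 exponent = 0.5) {
  map <- alignment$map
  ra <- ifelse(is.na(map$pos_a), NA_real_, react_a[map$pos_a + 1L])
  rb <- ifelse(is.na(map$pos_b), NA_real_, react_b[map$pos_b + 1L])
  ok <- !is.na(ra) & !is.na(rb)
  L <- sum(ok)
  if (L < min_shared) {
    return(structure(NA_real_, L = L))
  }
  if (sd(ra[ok]) == 0 || sd(rb[ok]) == 0) {
    return(structure(NA_real_, L = L))
  }
  r <- cor(ra[ok], rb[ok])
  structure((1 - r) * L^exponent, L = L)
}

#' Correlation of eSDC with SNV counts and indel lengths
#'
#' Pearson correlation between per-pair eSDC and SNV count, and between
#' eSDC and total inserted/deleted length per subgenome.
#'
#' @param pair_stats Tibble with columns `esdc`, `n_snv`, and optionally
#'   `indel_len_a`, `indel_len_b`.
#' @return Tibble `covariate`, `r`, `p`, `n`.
#' @export
esdc_snv_correlation <- function(pair_stats) {
  one <- function(x, name) {
    ok <- is.finite(pair_stats$esdc) & is.finite(x)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(pair_stats$esdc[ok]) == 0) {
      return(tibble::tibble(covariate = name, r = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    ct <- cor.test(pair_stats$esdc[ok], x[ok])
    tibble::tibble(covariate = name, r = unname(ct$estimate),
                   p = ct$p.value, n = sum(ok))
  }
  out <- one(pair_stats$n_snv, "n_snv")
  if ("indel_len_a" %in% names(pair_stats)) {
    out <- dplyr::bind_rows(out, one(pair_stats$indel_len_a, "indel_len_a"),
                            one(pair_stats$indel_len_b, "indel_len_b"))
  }
  out
}
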