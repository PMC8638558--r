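#' Positive predictive value between two pair sets
#'
#' Fraction of predicted base pairs present in the reference structure.
#' `NA` when the predicted set is empty.
#'
#' @param pred_pairs,ref_pairs Tibbles with 0-based columns `i`, `j`.
#' @return A number in `[0, 1]`, or `NA`.
#' @export
ppv <- function(pred_pairs, ref_pairs) {
  if (nrow(pred_pairs) == 0) return(NA_real_)
  key <- function(p) paste(p$i, p$j)
  mean(key(pred_pairs) %in% key(ref_pairs))
}

#' Agreement of SHAPE reactivity with a reference structure
#'
#' True-positive rate: fraction of nucleotides with reactivity above `high`
#' that are single-stranded in the reference. True-negative rate: fraction
#' with reactivity below `low` that are paired. Reactivities in the
#' `[low, high]` band are excluded.
#'
#' @param reactivity Numeric vector (`NA` = missing).
#' @param ref_paired Logical vector: is each nucleotide paired in the
#'   reference?
#' @param low,high Reactivity cutoffs.
#' @return Tibble with `tp_rate`, `tn_rate`, `n_high`, `n_low` (`NA` rate
#'   when a class is empty).
#' @export
reference_agreement <- function(reactivity, ref_paired, low = 0.3,
                                high = 0.6) {
  ok <- !is.na(reactivity) & !is.na(ref_paired)
  hi <- ok & reactivity > high
  lo <- ok & reactivity < low
  tibble::tibble(
    tp_rate = if (any(hi)) mean(!ref_paired[hi]) else NA_real_,
    tn_rate = if (any(lo)) mean(ref_paired[lo]) else NA_real_,
    n_high = sum(hi), n_low = sum(lo))
}

#' Mean base-pairing probability by genic region
#'
#' @param bpp Per-nucleotide BPP vector for one transcript.
#' @param cds_start,cds_end 0-based half-open CDS bounds.
#' @return Tibble with `utr5`, `cds`, `utr3`, `full` means (`NA` for empty
#'   regions).
#' @export
mean_bpp_by_region <- function(bpp, cds_start, cds_end) {
  pos <- seq_along(bpp) - 1L
  reg <- region_of(pos, cds_start, cds_end)
  m <- function(sel) if (any(sel, na.rm = TRUE))
    mean(bpp[sel], na.rm = TRUE) else NA_real_
  tibble::tibble(utr5 = m(reg == "utr5"), cds = m(reg == "cds"),
                 utr3 = m(reg == "utr3"), full = m(rep(TRUE, length(bpp))))
}
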