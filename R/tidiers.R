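#' Tidiers for ribostruct result objects
#'
#' Broom-style methods: `tidy()` returns one row per elementary unit (per
#' nucleotide for folds, per pair for differential-TE results);
#' `glance()` returns a one-row summary.
#'
#' @param x A `ribo_fold` or `ribo_dte` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-ribostruct
NULL
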