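#' Wilcoxon comparison of homoeolog base-pairing probabilities
#'
#' Two-sample Wilcoxon rank-sum test on the per-nucleotide BPP values of
#' the two homoeologs; direction by difference of means, `NSD` when
#' `p >= alpha`.
#'
#' @param bpp_a,bpp_b Per-nucleotide BPP vectors (`NA` allowed).
#' @param alpha Significance level.
#' @param min_positions Minimum defined positions per transcript; below it
#'   the pair is excluded (`NA` result).
#' @return Tibble with `p`, `mean_a`, `mean_b`, `direction`.
#' @export
pair_bpp_test <- function(bpp_a, bpp_b, alpha = 0.05, min_positions = 20) {
  a <- bpp_a[!is.na(bpp_a)]
  b <- bpp_b[!is.na(bpp_b)]
  if (length(a) < min_positions || length(b) < min_positions) {
    return(tibble::tibble(p = NA_real_, mean_a = NA_real_, mean_b = NA_real_,
                          direction = NA_character_))
  }
  p <- if (length(unique(c(a, b))) == 1) 1.0 else
    suppressWarnings(wilcox.test(a, b)$p.value)
  tibble::tibble(
    p = p, mean_a = mean(a), mean_b = mean(b),
    direction = dplyr::case_when(p >= alpha ~ "NSD",
                                 mean(a) > mean(b) ~ "A_higher",
                                 TRUE ~ "B_higher"))
}

#' Pairwise BPP tests over a homoeolog pair list
#'
#' @param pairs Tibble with columns `a_id`, `b_id`.
#' @param folds Named list of `ribo_fold` objects (or a BPP tibble from
#'   [bpp_table()]).
#' @inheritParams pair_bpp_test
#' @return Tibble: `a_id`, `b_id`, `p`, `mean_a`, `mean_b`, `direction`.
#' @export
pairs_bpp_tests <- function(pairs, folds, alpha = 0.05, min_positions = 20) {
  get_bpp <- if (is.data.frame(folds)) {
    by_id <- split(folds$bpp, folds$transcript_id)
    function(id) by_id[[id]]
  } else {
    function(id) folds[[id]]$bpp
  }
  purrr::pmap_dfr(pairs[c("a_id", "b_id")], function(a_id, b_id) {
    dplyr::bind_cols(
      tibble::tibble(a_id = a_id, b_id = b_id),
      pair_bpp_test(get_bpp(a_id) %||% NA_real_,
                    get_bpp(b_id) %||% NA_real_, alpha, min_positions))
  })
}

#' Summarize structural asymmetry directions
#'
#' Fractions of tested pairs with significantly higher BPP in the A
#' subgenome, in the B subgenome, or with no significant difference; the
#' three fractions partition unity.
#'
#' @param tests Output of [pairs_bpp_tests()] (or any tibble with a
#'   `direction` column).
#' @return One-row tibble with `n_tested`, `frac_A_higher`,
#'   `frac_B_higher`, `frac_NSD`, `frac_divergent`.
#' @export
asymmetry_summary <- function(tests) {
  d <- tests$direction[!is.na(tests$direction)]
  n <- length(d)
  tibble::tibble(
    n_tested = n,
    frac_A_higher = if (n > 0) mean(d == "A_higher") else NA_real_,
    frac_B_higher = if (n > 0) mean(d == "B_higher") else NA_real_,
    frac_NSD = if (n > 0) mean(d == "NSD") else NA_real_,
    frac_divergent = if (n > 0) mean(d != "NSD") else NA_real_)
}

#' Correlation between structural and translational asymmetry
#'
#' Pearson correlation between `|delta BPP|` (absolute difference of mean
#' BPP, optionally restricted to one region) and `|delta TE|` (absolute
#' log2 TE ratio) across homoeolog pairs.
#'
#' @param deltas Tibble with columns `dbpp` and `dte` (signed or absolute;
#'   absolute values are taken).
#' @return Tibble with `r`, `p`, `n`.
#' @export
delta_correlation <- function(deltas) {
  x <- abs(deltas$dbpp)
  y <- abs(deltas$dte)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(tibble::tibble(r = NA_real_, p = NA_real_,
                                         n = sum(ok)))
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Build the per-pair delta table
#'
#' Joins per-pair mean-BPP differences (per region and overall) with log2
#' TE ratios.
#'
#' @param pairs Tibble with `a_id`, `b_id`.
#' @param folds Named list of `ribo_fold` objects.
#' @param transcripts Transcript table (for region bounds).
#' @param dte A [differential_te()] result (for `log2_te_ratio`).
#' @param region `"full"`, `"utr5"`, `"cds"`, or `"utr3"`.
#' @return Tibble `a_id`, `b_id`, `dbpp` (signed A - B), `dte` (signed
#'   log2 TE ratio).
#' @export
pair_deltas <- function(pairs, folds, transcripts, dte, region = "full") {
  ann <- setNames(
    purrr::map(seq_len(nrow(transcripts)),
               ~ transcripts[.x, c("cds_start", "cds_end")]),
    transcripts$transcript_id)
  mb <- function(id) {
    f <- folds[[id]]
    if (is.null(f)) return(NA_real_)
    a <- ann[[id]]
    if (region == "full" || is.null(a) || is.na(a$cds_start)) {
      return(mean(f$bpp))
    }
    mean_bpp_by_region(f$bpp, a$cds_start, a$cds_end)[[region]]
  }
  dte_tbl <- tibble::as_tibble(unclass(dte))[c("a_id", "b_id",
                                               "log2_te_ratio")]
  pairs |>
    dplyr::mutate(dbpp = purrr::map2_dbl(.data$a_id, .data$b_id,
                                         ~ mb(.x) - mb(.y))) |>
    dplyr::left_join(dte_tbl, by = c("a_id", "b_id")) |>
    dplyr::rename(dte = "log2_te_ratio") |>
    dplyr::select("a_id", "b_id", "dbpp", "dte")
}

#' Per-group delta correlations
#'
#' [delta_correlation()] within user-supplied functional groups, with BH
#' correction across groups; groups with fewer than `min_pairs` pairs are
#' excluded.
#'
#' @param deltas Output of [pair_deltas()].
#' @param group_map Tibble with columns `a_id`, `group` (a pair belongs to
#'   the group of its A-subgenome transcript).
#' @param min_pairs Minimum pairs per group.
#' @param alpha Significance level for the flag.
#' @return Tibble `group`, `r`, `p`, `n`, `p_adj`, `significant`.
#' @export
grouped_delta_correlation <- function(deltas, group_map, min_pairs = 10,
                                      alpha = 0.05) {
  df <- dplyr::inner_join(deltas, group_map, by = "a_id",
                          relationship = "many-to-many")
  parts <- split(df, df$group)
  parts <- parts[purrr::map_int(parts, nrow) >= min_pairs]
  out <- purrr::imap_dfr(parts, function(part, g)
    dplyr::mutate(delta_correlation(part), group = g, .before = 1))
  if (nrow(out) == 0) {
    return(tibble::tibble(group = character(), r = numeric(),
                          p = numeric(), n = integer(), p_adj = numeric(),
                          significant = logical()))
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Per-group mean TE difference
#'
#' Mean and standard error of the per-pair TE difference within each
#' group; groups with fewer than `min_pairs` pairs are excluded.
#'
#' @param deltas Tibble with columns `a_id` and `dte` (signed TE
#'   difference, log2 scale).
#' @param group_map Tibble with columns `a_id`, `group`.
#' @param min_pairs Minimum pairs per group.
#' @return Tibble `group`, `mean_dte`, `se`, `n`.
#' @export
grouped_te_difference <- function(deltas, group_map, min_pairs = 10) {
  dplyr::inner_join(deltas, group_map, by = "a_id",
                    relationship = "many-to-many") |>
    dplyr::filter(is.finite(.data$dte)) |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(dplyr::n() >= min_pairs) |>
    dplyr::summarise(mean_dte = mean(.data$dte),
                     se = sd(.data$dte) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}
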