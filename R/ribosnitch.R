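# riboSNitch calling: paired tests on local BPP and reactivity differences

# project a per-nucleotide vector onto alignment columns
project_on_alignment <- function(x, pos) {
  ifelse(is.na(pos), NA_real_, x[pos + 1L])
}

# monotone quantile mapping of y onto x's empirical distribution, over
# jointly defined entries; undefined entries stay NA
quantile_match <- function(y, x) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(y)
  xs <- sort(x[ok])
  r <- rank(y[ok], ties.method = "average")
  y[ok] <- stats::approx(seq_along(xs), xs, xout = r, rule = 2)$y
  y
}

#' Per-SNV structural-difference tests for one homoeolog pair
#'
#' For each SNV (or cluster of SNVs closer than `window / 2`, which is
#' tested jointly and flagged non-isolated), the per-nucleotide BPP and
#' reactivity differences between the two homoeologs are collected over
#' the alignment columns within `window` of the SNV and submitted to
#' paired Wilcoxon signed-rank tests. Because 2-8% normalization is
#' per-transcript, the two reactivity profiles can differ by a global
#' scale; with `scale_match = TRUE` (default) the B profile is quantile-
#' mapped onto the A profile over all shared aligned columns before
#' differences are taken, so the window test responds to local structural
#' change rather than to normalization offsets. Effect sizes are mean
#' absolute paired differences within the window.
#'
#' @param snvs SNV tibble from [extract_variants()] (needs `column`).
#' @param alignment The pair's [align_pair()] result.
#' @param bpp_a,bpp_b Per-nucleotide BPP vectors (transcript coordinates).
#' @param react_a,react_b Per-nucleotide reactivity vectors.
#' @param window Half-width of the test window, in alignment columns.
#' @param min_positions Minimum defined aligned positions in the window;
#'   below it the SNV is untested (`NA` p-values).
#' @param scale_match Quantile-match the reactivity profiles before
#'   differencing?
#' @return `snvs` with added columns `cluster`, `isolated`, `n_window`,
#'   `p_bpp`, `p_react`, `effect_bpp`, `effect_react`.
#' @export
ribosnitch_tests <- function(snvs, alignment, bpp_a, bpp_b, react_a,
                             react_b, window = 50, min_positions = 20,
                             scale_match = TRUE) {
  map <- alignment$map
  ra <- project_on_alignment(react_a, map$pos_a)
  rb <- project_on_alignment(react_b, map$pos_b)
  if (scale_match) rb <- quantile_match(rb, ra)
  dbpp <- project_on_alignment(bpp_a, map$pos_a) -
    project_on_alignment(bpp_b, map$pos_b)
  dreact <- ra - rb
  if (nrow(snvs) == 0) {
    return(dplyr::mutate(snvs, cluster = integer(), isolated = logical(),
                         n_window = integer(), p_bpp = numeric(),
                         p_react = numeric(), effect_bpp = numeric(),
                         effect_react = numeric()))
  }
  cols <- sort(snvs$column)
  cluster_of <- cumsum(c(1L, as.integer(diff(cols) >= window / 2)))
  cluster <- cluster_of[match(snvs$column, cols)]
  one_test <- function(d, sel) {
    dd <- d[sel]
    dd <- dd[!is.na(dd)]
    if (length(dd) < min_positions) {
      return(c(p = NA_real_, effect = NA_real_, n = length(dd)))
    }
    p <- if (all(dd == 0)) 1.0 else
      suppressWarnings(wilcox.test(dd, mu = 0)$p.value)
    c(p = p, effect = mean(abs(dd)), n = length(dd))
  }
  stats <- purrr::map_dfr(unique(cluster), function(cl) {
    ccols <- snvs$column[cluster == cl]
    sel <- map$column >= min(ccols) - window & map$column <=
      max(ccols) + window
    tb <- one_test(dbpp, sel)
    tr <- one_test(dreact, sel)
    tibble::tibble(cluster = cl, isolated = length(ccols) == 1,
                   n_window = as.integer(min(tb["n"], tr["n"])),
                   p_bpp = tb[["p"]], p_react = tr[["p"]],
                   effect_bpp = tb[["effect"]],
                   effect_react = tr[["effect"]])
  })
  dplyr::left_join(dplyr::mutate(snvs, cluster = cluster), stats,
                   by = "cluster")
}

#' Final riboSNitch calls across all tested SNVs
#'
#' Applies Benjamini-Hochberg correction per statistic across all tested
#' SNVs, then calls a riboSNitch when both tests are significant and both
#' window mean-absolute-difference effect sizes reach `min_effect`. By default significance uses the raw
#' p-values (the BH-adjusted call is available with
#' `use_adjusted = TRUE`). Untested SNVs keep `is_ribosnitch = NA`.
#'
#' @param tested Row-bound output of [ribosnitch_tests()] over all pairs.
#' @param alpha Significance level.
#' @param min_effect Minimum absolute median difference for both signals.
#' @param use_adjusted Call on BH-adjusted p-values instead of raw.
#' @return `tested` with added `p_bpp_adj`, `p_react_adj`,
#'   `is_ribosnitch`.
#' @export
ribosnitch_calls <- function(tested, alpha = 0.05, min_effect = 0.1,
                             use_adjusted = FALSE) {
  out <- tested
  out$p_bpp_adj <- NA_real_
  out$p_react_adj <- NA_real_
  ok_b <- !is.na(out$p_bpp)
  ok_r <- !is.na(out$p_react)
  out$p_bpp_adj[ok_b] <- p.adjust(out$p_bpp[ok_b], method = "BH")
  out$p_react_adj[ok_r] <- p.adjust(out$p_react[ok_r], method = "BH")
  pb <- if (use_adjusted) out$p_bpp_adj else out$p_bpp
  pr <- if (use_adjusted) out$p_react_adj else out$p_react
  out$is_ribosnitch <- ifelse(
    is.na(pb) | is.na(pr), NA,
    pb < alpha & pr < alpha & out$effect_bpp >= min_effect &
      out$effect_react >= min_effect)
  out
}

#' riboSNitch / SNV ratios per genic region
#'
#' RiboSNitch count over tested-SNV count, per region and overall.
#' Untested SNVs (`is_ribosnitch` `NA`) are excluded from both numerator
#' and denominator by default; `strict = TRUE` keeps them in the
#' denominator.
#'
#' @param calls Output of [ribosnitch_calls()] (needs `region`,
#'   `is_ribosnitch`).
#' @param strict Count untested SNVs in the denominator?
#' @return Tibble `region`, `n_ribosnitch`, `n_snv`, `ratio` (regions
#'   `utr5`, `cds`, `utr3`, and `all`).
#' @export
ribosnitch_region_ratios <- function(calls, strict = FALSE) {
  base <- if (strict) calls else calls[!is.na(calls$is_ribosnitch), ]
  one <- function(df, label) {
    n <- nrow(df)
    tibble::tibble(region = label,
                   n_ribosnitch = sum(df$is_ribosnitch, na.rm = TRUE),
                   n_snv = n,
                   ratio = if (n > 0)
                     sum(df$is_ribosnitch, na.rm = TRUE) / n else NA_real_)
  }
  dplyr::bind_rows(
    purrr::map_dfr(c("utr5", "cds", "utr3"),
                   ~ one(base[!is.na(base$region) & base$region == .x, ],
                         .x)),
    one(base, "all"))
}
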