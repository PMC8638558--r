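#' Per-subpopulation allele frequencies and major alleles
#'
#' `f_i = c(i) / sum(c(i))` within each subpopulation; the allele with the
#' maximum frequency is the major allele, ties broken alphabetically
#' (A < C < G < U).
#'
#' @param pop_table Allele-count tibble from [read_vcf_population()]
#'   (columns `snv_id`, `subpop`, `allele`, `count`).
#' @return Tibble `snv_id`, `subpop`, `allele`, `count`, `freq`, `major`
#'   (logical). Subpopulations with zero total count are dropped.
#' @export
allele_frequencies <- function(pop_table) {
  pop_table |>
    dplyr::filter(sum(.data$count) > 0, .by = c("snv_id", "subpop")) |>
    dplyr::mutate(freq = .data$count / sum(.data$count),
                  .by = c("snv_id", "subpop")) |>
    dplyr::arrange(.data$snv_id, .data$subpop, .data$allele) |>
    dplyr::mutate(major = seq_along(.data$freq) ==
                    which.max(.data$freq),  # first max = alphabetical tie-break
                  .by = c("snv_id", "subpop"))
}

#' Fixation index from per-subpopulation allele frequencies
#'
#' `F_ST = sigma_pi^2 / (pi_bar * (1 - pi_bar))`, where `pi_bar` is the
#' mean and `sigma_pi^2` the variance of the tracked allele's frequency
#' across subpopulations. The population variance (divide by the number of
#' subpopulations) is used by default. `F_ST` is clipped to `[0, 1]` and
#' missing when `pi_bar` is 0 or 1.
#'
#' @param freqs Numeric vector of the allele's frequency in each
#'   subpopulation (length >= 2).
#' @param sample_variance Use the n-1 denominator instead.
#' @return One-row tibble `pi_bar`, `sigma2_pi`, `fst`.
#' @export
#' @examples
#' fst(c(0.8, 0.4))  # F_ST = 0.04 / 0.24 = 0.1667
fst <- function(freqs, sample_variance = FALSE) {
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) < 2) {
    return(tibble::tibble(pi_bar = NA_real_, sigma2_pi = NA_real_,
                          fst = NA_real_))
  }
  pi_bar <- mean(freqs)
  sigma2 <- if (sample_variance) stats::var(freqs) else
    mean((freqs - pi_bar)^2)
  f <- if (pi_bar <= 0 || pi_bar >= 1) NA_real_ else
    min(1, max(0, sigma2 / (pi_bar * (1 - pi_bar))))
  tibble::tibble(pi_bar = pi_bar, sigma2_pi = sigma2, fst = f)
}

#' F_ST for every SNV in a population table
#'
#' Tracks, per SNV, the frequency of the globally (count-summed) major
#' allele in each subpopulation; for biallelic sites F_ST is the same for
#' either allele.
#'
#' @inheritParams allele_frequencies
#' @param sample_variance Passed to [fst()].
#' @return Tibble `snv_id`, `allele` (tracked), `pi_bar`, `sigma2_pi`,
#'   `fst`.
#' @export
fst_table <- function(pop_table, sample_variance = FALSE) {
  af <- allele_frequencies(pop_table)
  global_major <- af |>
    dplyr::summarise(total = sum(.data$count),
                     .by = c("snv_id", "allele")) |>
    dplyr::arrange(.data$snv_id, dplyr::desc(.data$total), .data$allele) |>
    dplyr::slice_head(n = 1, by = "snv_id")
  af |>
    dplyr::inner_join(dplyr::select(global_major, "snv_id", "allele"),
                      by = c("snv_id", "allele")) |>
    dplyr::summarise(
      allele = .data$allele[1],
      res = list(fst(.data$freq)), .by = "snv_id") |>
    tidyr::unnest("res")
}

#' Conservation ratios for riboSNitch vs non-riboSNitch SNVs
#'
#' Per transcript and SNV class, the fraction of SNV sites at which the
#' allele observed in the reference homoeolog equals the major allele of
#' the reference subpopulation (`c(major) / c(total)`).
#'
#' @param snvs Tibble with columns `transcript_id`, `snv_id`, `allele`
#'   (the reference-pair allele, RNA spelling), `is_ribosnitch`, and
#'   optionally `region`.
#' @param pop_table Allele-count tibble (see [read_vcf_population()]).
#' @param reference_pop Subpopulation whose major allele defines
#'   conservation.
#' @param by_region Also stratify by `region`?
#' @return Tibble `transcript_id`, (`region`,) `class`, `c_major`,
#'   `c_total`, `ratio`.
#' @export
conservation_ratios <- function(snvs, pop_table, reference_pop,
                                by_region = FALSE) {
  majors <- allele_frequencies(pop_table) |>
    dplyr::filter(.data$subpop == reference_pop, .data$major) |>
    dplyr::select("snv_id", major_allele = "allele")
  df <- snvs |>
    dplyr::filter(!is.na(.data$is_ribosnitch)) |>
    dplyr::inner_join(majors, by = "snv_id") |>
    dplyr::mutate(
      class = dplyr::if_else(.data$is_ribosnitch, "ribosnitch",
                             "non_ribosnitch"),
      is_major = .data$allele == .data$major_allele)
  keys <- if (by_region) c("transcript_id", "region", "class") else
    c("transcript_id", "class")
  df |>
    dplyr::summarise(c_major = sum(.data$is_major),
                     c_total = dplyr::n(),
                     ratio = sum(.data$is_major) / dplyr::n(),
                     .by = dplyr::all_of(keys))
}

#' Two-class contrast of a statistic
#'
#' Compares a statistic (e.g. F_ST or conservation ratio) between
#' riboSNitch and non-riboSNitch SNV classes with a Student t test or
#' Wilcoxon rank-sum test.
#'
#' @param values_ribosnitch,values_non Numeric vectors (>= 3 values each).
#' @param test `"t"` or `"wilcoxon"`.
#' @return Tibble `test`, `p`, `mean_ribosnitch`, `mean_non`,
#'   `median_ribosnitch`, `median_non`, `se_ribosnitch`, `se_non`.
#' @export
class_contrast <- function(values_ribosnitch, values_non,
                           test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  x <- values_ribosnitch[!is.na(values_ribosnitch)]
  y <- values_non[!is.na(values_non)]
  if (length(x) < 3 || length(y) < 3) {
    abort("class_contrast: need at least 3 values per class")
  }
  p <- if (test == "t") t.test(x, y)$p.value else
    suppressWarnings(wilcox.test(x, y)$p.value)
  tibble::tibble(test = test, p = p,
                 mean_ribosnitch = mean(x), mean_non = mean(y),
                 median_ribosnitch = median(x), median_non = median(y),
                 se_ribosnitch = sd(x) / sqrt(length(x)),
                 se_non = sd(y) / sqrt(length(y)))
}
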