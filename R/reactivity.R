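#' Per-nucleotide RT-stop rates
#'
#' Adds a `rate = stops / coverage` column; positions below the coverage
#' floor become `NA` rather than being dropped, so profiles keep their full
#' length.
#'
#' @param stops Long-format stop-count tibble (see [read_stop_counts()]).
#' @param min_coverage Minimum coverage for a position to be scored.
#' @return The input tibble with an added `rate` column.
#' @export
stop_rate <- function(stops, min_coverage = 50) {
  dplyr::mutate(stops,
                rate = dplyr::if_else(.data$coverage >= min_coverage,
                                      .data$stops / .data$coverage,
                                      NA_real_))
}

#' Raw SHAPE reactivity from plus/minus channel stop rates
#'
#' Per replicate and position, `max(0, rate_plus - rate_minus)`; missing
#' wherever either channel is missing.
#'
#' @param rates Output of [stop_rate()] (both channels present).
#' @return Tibble with columns `transcript_id`, `replicate`, `position`,
#'   `raw`.
#' @export
raw_reactivity <- function(rates) {
  wide <- rates |>
    dplyr::select("transcript_id", "replicate", "position", "channel",
                  "rate") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "rate",
                       names_prefix = "rate_")
  if (!all(c("rate_plus", "rate_minus") %in% names(wide))) {
    abort("raw_reactivity: both 'plus' and 'minus' channels are required")
  }
  wide |>
    dplyr::mutate(raw = pmax(0, .data$rate_plus - .data$rate_minus)) |>
    dplyr::select("transcript_id", "replicate", "position", "raw") |>
    dplyr::arrange(.data$transcript_id, .data$replicate, .data$position)
}

#' 2-8% normalization of a raw reactivity vector
#'
#' The top 2% of defined values (count = `ceiling(0.02 * n)`) are set aside
#' as outliers; all values are divided by the mean of the next 8% (count =
#' `floor(0.08 * n + 0.5)`, i.e. round-half-up). Ties are broken by value
#' then by position, so the result is bit-reproducible.
#'
#' @param raw Numeric vector of raw reactivities (`NA` = missing).
#' @param min_positions Minimum number of defined positions; below it the
#'   vector is returned all-`NA` with a warning.
#' @return The normalized vector, with the divisor attached as attribute
#'   `divisor`.
#' @export
#' @examples
#' x <- normalize_2_8(as.numeric(0:99))
#' attr(x, "divisor")  # 93.5
normalize_2_8 <- function(raw, min_positions = 20) {
  defined <- which(!is.na(raw))
  out <- rep(NA_real_, length(raw))
  if (length(defined) < min_positions) {
    warn(sprintf("normalize_2_8: only %d defined position(s) (< %d); dropped",
                 length(defined), min_positions))
    attr(out, "divisor") <- NA_real_
    return(out)
  }
  v <- raw[defined]
  ord <- order(v, defined, decreasing = TRUE)  # value desc, then position
  n <- length(v)
  n_out <- ceiling(0.02 * n)
  n_div <- floor(0.08 * n + 0.5)
  idx <- ord[(n_out + 1):min(n, n_out + n_div)]
  divisor <- mean(v[idx])
  if (!is.finite(divisor) || divisor <= 0) {
    warn("normalize_2_8: normalization divisor is zero; transcript dropped")
    attr(out, "divisor") <- NA_real_
    return(out)
  }
  out[defined] <- v / divisor
  attr(out, "divisor") <- divisor
  out
}

#' Merge replicate reactivity profiles
#'
#' Position-wise mean of defined values (a position missing in one
#' replicate takes the other's value). Per-transcript Pearson correlation
#' between replicate profiles is attached as attribute `replicate_r`.
#'
#' @param profiles Tibble with columns `transcript_id`, `replicate`,
#'   `position`, `reactivity`.
#' @return Tibble `transcript_id`, `position`, `reactivity` with attribute
#'   `replicate_r` (tibble `transcript_id`, `r`, `n`).
#' @export
merge_replicates <- function(profiles) {
  lens <- profiles |>
    dplyr::summarise(n = dplyr::n_distinct(.data$position),
                     .by = c("transcript_id", "replicate")) |>
    dplyr::distinct(.data$transcript_id, .data$n)
  if (anyDuplicated(lens$transcript_id)) {
    abort("merge_replicates: replicate length mismatch")
  }
  merged <- profiles |>
    dplyr::summarise(
      reactivity = if (all(is.na(.data$reactivity))) NA_real_ else
        mean(.data$reactivity, na.rm = TRUE),
      .by = c("transcript_id", "position")) |>
    dplyr::arrange(.data$transcript_id, .data$position)
  reps <- sort(unique(profiles$replicate))
  rep_r <- if (length(reps) >= 2) {
    profiles |>
      tidyr::pivot_wider(names_from = "replicate",
                         values_from = "reactivity", names_prefix = "rep") |>
      dplyr::summarise(
        r = {
          m <- as.matrix(dplyr::pick(dplyr::starts_with("rep")))
          cc <- complete.cases(m)
          if (sum(cc) >= 3) mean(cor(m[cc, , drop = FALSE])[
            lower.tri(diag(ncol(m)))]) else NA_real_
        },
        n = sum(complete.cases(
          as.matrix(dplyr::pick(dplyr::starts_with("rep"))))),
        .by = "transcript_id")
  } else {
    tibble::tibble(transcript_id = unique(profiles$transcript_id),
                   r = NA_real_, n = NA_integer_)
  }
  attr(merged, "replicate_r") <- rep_r
  merged
}

#' RT-stop counts to normalized SHAPE reactivities
#'
#' The full reactivity chain: coverage-filtered stop rates, plus-minus
#' subtraction (clipped at zero), per-replicate 2-8% normalization, then
#' replicate merging.
#'
#' @inheritParams stop_rate
#' @inheritParams normalize_2_8
#' @return Tibble `transcript_id`, `position`, `reactivity` (`NA` =
#'   missing), with attribute `replicate_r`.
#' @export
shape_reactivity <- function(stops, min_coverage = 50, min_positions = 20) {
  raw <- raw_reactivity(stop_rate(stops, min_coverage))
  normed <- raw |>
    dplyr::mutate(reactivity = as.numeric(
      normalize_2_8(.data$raw, min_positions)),
      .by = c("transcript_id", "replicate")) |>
    dplyr::select("transcript_id", "replicate", "position", "reactivity")
  merge_replicates(normed)
}

#' Write a reactivity table
#' @param reactivity Tibble `transcript_id`, `position`, `reactivity`.
#' @param path Output path.
#' @param params Optional named list for the commented header.
#' @return `path`, invisibly.
#' @export
write_reactivity <- function(reactivity, path, params = NULL) {
  write_tsv_commented(reactivity, path, params)
}

#' Read a reactivity table written by [write_reactivity()]
#' @param path Path to the TSV.
#' @return Tibble `transcript_id`, `position`, `reactivity`.
#' @export
read_reactivity <- function(path) {
  read_tsv_commented(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    position = readr::col_integer(),
    reactivity = readr::col_double()))
}
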