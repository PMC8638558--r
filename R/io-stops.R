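#' Read per-nucleotide RT-stop counts
#'
#' Reads the long-format TSV with columns `transcript_id`, `position`
#' (0-based), `channel` (`plus`/`minus`), `replicate`, `stops`, `coverage`.
#' When `transcripts` is supplied, positions absent from the file are filled
#' with `stops = 0, coverage = 0` for every transcript/channel/replicate
#' combination present, so profiles always span the full transcript.
#'
#' @param path Path to the TSV.
#' @param transcripts Optional transcript table (for length completion).
#' @return A tibble in the same long format.
#' @export
read_stop_counts <- function(path, transcripts = NULL) {
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        show_col_types = FALSE,
                        col_types = readr::cols(
                          transcript_id = readr::col_character(),
                          position = readr::col_integer(),
                          channel = readr::col_character(),
                          replicate = readr::col_integer(),
                          stops = readr::col_integer(),
                          coverage = readr::col_integer()))
  bad <- which(df$stops > df$coverage)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: stops > coverage at transcript %s position %d (field 'stops')",
      path, df$transcript_id[bad[1]], df$position[bad[1]]))
  }
  if (any(df$stops < 0 | df$coverage < 0)) {
    abort(sprintf("%s: negative stops/coverage", path))
  }
  if (!all(df$channel %in% c("plus", "minus"))) {
    abort(sprintf("%s: channel must be 'plus' or 'minus'", path))
  }
  if (!is.null(transcripts)) {
    df <- complete_stop_counts(df, transcripts)
  }
  df
}

# fill unobserved positions with zeros over each transcript's full length
complete_stop_counts <- function(stops, transcripts) {
  lens <- dplyr::select(transcripts, "transcript_id", "length")
  grid <- stops |>
    dplyr::distinct(.data$transcript_id, .data$channel, .data$replicate) |>
    dplyr::inner_join(lens, by = "transcript_id") |>
    dplyr::reframe(position = seq_len(.data$length) - 1L,
                   .by = c("transcript_id", "channel", "replicate"))
  grid |>
    dplyr::left_join(stops,
                     by = c("transcript_id", "channel", "replicate",
                            "position")) |>
    dplyr::mutate(stops = dplyr::coalesce(.data$stops, 0L),
                  coverage = dplyr::coalesce(.data$coverage, 0L))
}

#' Write per-nucleotide RT-stop counts
#'
#' @param stops Long-format stop-count tibble.
#' @param path Output path.
#' @param params Optional named list recorded on the commented header line.
#' @return `path`, invisibly.
#' @export
write_stop_counts <- function(stops, path, params = NULL) {
  write_tsv_commented(
    dplyr::select(stops, "transcript_id", "position", "channel",
                  "replicate", "stops", "coverage"),
    path, params)
}
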