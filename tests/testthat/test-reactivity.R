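make_stops <- function(stops_plus, cov_plus, stops_minus = NULL,
                       cov_minus = NULL, id = "t1", replicate = 1L) {
  n <- length(stops_plus)
  if (is.null(stops_minus)) stops_minus <- rep(0L, n)
  if (is.null(cov_minus)) cov_minus <- cov_plus
  tibble::tibble(
    transcript_id = id, position = rep(0:(n - 1), 2),
    channel = rep(c("plus", "minus"), each = n), replicate = replicate,
    stops = c(stops_plus, stops_minus),
    coverage = c(cov_plus, cov_minus))
}

test_that("stop rates apply the coverage floor as missingness", {
  st <- make_stops(c(10L, 0L, 3L), c(100L, 100L, 10L))
  r <- stop_rate(st, min_coverage = 50)
  plus <- r[r$channel == "plus", ]
  expect_equal(plus$rate, c(0.10, 0, NA))
})

test_that("raw reactivity is the clipped plus-minus rate difference", {
  st <- make_stops(c(10L, 1L, 5L), c(100L, 100L, 100L),
                   c(2L, 5L, 5L), c(100L, 100L, 10L))
  raw <- raw_reactivity(stop_rate(st, min_coverage = 50))
  expect_equal(raw$raw, c(0.08, 0, NA))  # clipped at 0; missing propagates
})

test_that("2-8% normalization reproduces the 0..99 worked example", {
  x <- normalize_2_8(as.numeric(0:99))
  # outliers {99, 98}; divisor = mean(90..97) = 93.5
  expect_equal(attr(x, "divisor"), 93.5)
  expect_equal(x[94], 93 / 93.5)
  expect_equal(unclass(x), as.numeric(0:99) / 93.5, ignore_attr = TRUE)
})

test_that("normalization is scale-invariant and handles degenerate input", {
  v <- c(runif(80), rep(NA, 20))
  a <- normalize_2_8(v)
  b <- normalize_2_8(v * 37.5)
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)

  const <- rep(2.5, 50)
  expect_equal(as.numeric(normalize_2_8(const)), rep(1, 50))

  expect_warning(z <- normalize_2_8(rep(0, 50)), "divisor")
  expect_true(all(is.na(z)))
  expect_warning(normalize_2_8(c(1, 2, 3)), "dropped")
})

test_that("replicate merging averages defined values and reports r", {
  prof <- tibble::tibble(
    transcript_id = "t1",
    replicate = rep(1:2, each = 3),
    position = rep(0:2, 2),
    reactivity = c(0.2, 0.5, NA, 0.4, 0.5, 0.8))
  m <- merge_replicates(prof)
  expect_equal(m$reactivity, c(0.3, 0.5, 0.8))

  ident <- dplyr::mutate(prof, reactivity = rep(c(0.1, 0.4, 0.9), 2))
  expect_equal(attr(merge_replicates(ident), "replicate_r")$r, 1.0)

  bad <- prof[-1, ]  # replicate 1 shorter than replicate 2
  expect_error(merge_replicates(bad), "length mismatch")
})

test_that("reactivity separates paired from unpaired positions", {
  cfg <- sim_config(seed = 21, n_pairs = 4L, mean_len = 700L)
  sim <- simulate_homoeolog_pairs(cfg)
  tr <- sim$transcripts[sim$transcripts$subgenome == "A", ]
  folds <- fold_transcripts(tr)
  stops <- simulate_probing(tr, folds, cfg)
  react <- suppressWarnings(shape_reactivity(stops))
  paired <- unlist(purrr::map(folds,
                              ~ ribostruct:::seq_chars(.x$dotbracket) != "."))
  expect_gt(nrow(react), 2500)
  expect_gt(mean(react$reactivity[!paired], na.rm = TRUE),
            mean(react$reactivity[paired], na.rm = TRUE))
  # never negative; mask respected
  expect_true(all(react$reactivity >= 0, na.rm = TRUE))
})

test_that("zero coverage yields an all-missing profile", {
  cfg <- sim_config(seed = 3, coverage_mean = 0)
  tr <- tibble::tibble(transcript_id = "t1", subgenome = "A",
                       sequence = strrep("A", 60), length = 60L,
                       cds_start = NA_integer_, cds_end = NA_integer_)
  stops <- simulate_probing(tr, list(t1 = rep(FALSE, 60)), cfg)
  react <- suppressWarnings(shape_reactivity(stops))
  expect_true(all(is.na(react$reactivity)))
})

test_that("the internal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  score <- c(rnorm(60, 1), rnorm(60, 0))
  pos <- rep(c(TRUE, FALSE), each = 60)
  ours <- ribostruct:::rank_auc(score, pos)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
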