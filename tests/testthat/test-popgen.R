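pop_tbl <- function(...) {
  # build an allele-count table from per-subpop named count vectors
  rows <- list(...)
  purrr::imap_dfr(rows, function(cnt, sp)
    tibble::tibble(snv_id = "s1", chrom = "c", pos = 1L, subpop = sp,
                   allele = names(cnt), count = unname(cnt)))
}

test_that("allele frequencies normalize per subpopulation with tie-break", {
  af <- allele_frequencies(pop_tbl(p1 = c(A = 3, C = 1)))
  expect_equal(af$freq, c(0.75, 0.25))
  expect_equal(af$allele[af$major], "A")
  # tie broken alphabetically
  af2 <- allele_frequencies(pop_tbl(p1 = c(C = 2, A = 2)))
  expect_equal(af2$allele[af2$major], "A")
  # empty counts dropped
  af3 <- allele_frequencies(pop_tbl(p1 = c(A = 0, G = 0),
                                    p2 = c(A = 1, G = 1)))
  expect_equal(unique(af3$subpop), "p2")
})

test_that("F_ST matches its closed forms", {
  expect_equal(fst(c(0.5, 0.5))$fst, 0)
  expect_equal(fst(c(1, 0))$fst, 1)
  r <- fst(c(0.8, 0.4))
  expect_equal(r$pi_bar, 0.6)
  expect_equal(r$sigma2_pi, 0.04)
  expect_equal(r$fst, 0.04 / 0.24)
  # fixed allele: undefined
  expect_true(is.na(fst(c(1, 1))$fst))
  # sample-variance mode doubles the two-population variance
  expect_equal(fst(c(0.8, 0.4), sample_variance = TRUE)$sigma2_pi, 0.08)
})

test_that("F_ST is allele-symmetric for biallelic sites and in [0, 1]", {
  set.seed(91)
  for (k in 1:20) {
    f <- runif(3)
    expect_equal(fst(f)$fst, fst(1 - f)$fst, tolerance = 1e-12)
    expect_true(fst(f)$fst >= 0 && fst(f)$fst <= 1)
  }
  # fst_table tracks the global major allele; check against direct fst()
  tbl <- dplyr::bind_rows(
    pop_tbl(p1 = c(A = 8, G = 2), p2 = c(A = 4, G = 6)))
  ft <- fst_table(tbl)
  expect_equal(ft$fst, fst(c(0.8, 0.4))$fst)
  expect_equal(ft$allele, "A")
})

test_that("conservation ratios count major-allele SNVs per class", {
  pop <- dplyr::bind_rows(purrr::map(1:3, function(k)
    tibble::tibble(snv_id = paste0("s", k), chrom = "c", pos = k,
                   subpop = "DW", allele = c("A", "G"),
                   count = if (k < 3) c(9, 1) else c(1, 9))))
  snvs <- tibble::tibble(
    transcript_id = "t1", snv_id = paste0("s", 1:3), allele = "A",
    is_ribosnitch = c(TRUE, TRUE, TRUE), region = "utr5")
  # alleles at s1, s2 are major (A), s3 is minor -> 2/3
  cr <- conservation_ratios(snvs, pop, "DW")
  expect_equal(cr$ratio, 2 / 3)
  # every allele major -> 1; ordering invariance
  snvs2 <- snvs[c(2, 1), ]
  snvs2$snv_id <- c("s2", "s1")
  expect_equal(conservation_ratios(snvs2, pop, "DW")$ratio, 1.0)
  # untested class absent -> no row
  expect_equal(unique(cr$class), "ribosnitch")
})

test_that("class contrasts run both tests and enforce the minimum n", {
  set.seed(92)
  x <- rnorm(30, 1, 0.2)
  y <- rnorm(30, 0.4, 0.2)  # 3 pooled-sd shift
  for (tst in c("t", "wilcoxon")) {
    res <- class_contrast(x, y, test = tst)
    expect_lt(res$p, 1e-6)
    expect_gt(res$mean_ribosnitch, res$mean_non)
  }
  same <- rnorm(30)
  expect_gt(class_contrast(same, same, test = "wilcoxon")$p, 0.9)
  expect_error(class_contrast(1, c(1, 2, 3)), "at least 3")
})

test_that("estimated frequencies converge to the generating values", {
  cfg <- sim_config(seed = 95, pop_sizes = c(DW = 50L, DEW = 50L,
                                             WEW = 50L))
  snvs <- tibble::tibble(snv_id = sprintf("s%02d", 1:30),
                         chrom = sprintf("s%02d", 1:30), pos = 1L,
                         allele_a = "A", allele_b = "G",
                         is_ribosnitch = rep(c(TRUE, FALSE), 15))
  pop <- simulate_population(snvs, cfg)
  af <- allele_frequencies(pop$pop_table)
  m <- dplyr::inner_join(af[af$allele == "A", ], pop$freqs,
                         by = c("snv_id", "subpop"))
  expect_equal(nrow(m), 90L)
  err <- abs(m$freq - m$freq_a)
  # per-subpopulation mean absolute error at 50 accessions (100 alleles)
  by_pop <- tapply(err, m$subpop, mean)
  expect_lt(max(by_pop), 0.05)
  # divergent riboSNitch sites give high F_ST, shared sites low
  ft <- fst_table(pop$pop_table)
  ft <- dplyr::inner_join(ft, snvs, by = "snv_id")
  expect_gt(median(ft$fst[ft$is_ribosnitch], na.rm = TRUE),
            median(ft$fst[!ft$is_ribosnitch], na.rm = TRUE))
})
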