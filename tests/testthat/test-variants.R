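test_that("alignment scores match the exhaustive matching oracle", {
  set.seed(55)
  # identical sequences align gaplessly with score = length
  al <- align_pair("ACGUACGU", "ACGUACGU")
  expect_equal(al$score, 8)
  expect_equal(al$aligned_a, al$aligned_b)
  # single mismatch column
  al2 <- align_pair("ACGU", "AGGU")
  expect_equal(al2$aligned_a, "ACGU")
  expect_equal(al2$aligned_b, "AGGU")
  for (k in 1:20) {
    a <- random_rna(sample(2:7, 1))
    b <- random_rna(sample(2:7, 1))
    expect_equal(align_pair(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
  expect_error(align_pair("", "ACG"), "non-empty")
})

test_that("alignment rows always ungap to the input sequences", {
  set.seed(56)
  for (k in 1:10) {
    a <- random_rna(sample(20:60, 1))
    b <- random_rna(sample(20:60, 1))
    al <- align_pair(a, b)
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
  }
})

test_that("variant extraction classifies columns exhaustively", {
  al <- align_pair("ACGUACGUACGUNA", "AGGUACUACGUNA")
  v <- extract_variants(al)
  cnt <- v$counts
  expect_equal(cnt$matched + cnt$snv + cnt$n_dropped + cnt$gap,
               nrow(al$map))
  # transitions and transversions by definition
  v2 <- extract_variants(align_pair("AAAACCCC", "AAAGCCCU"))
  expect_equal(v2$snvs$mutation_class, c("transition", "transition"))
  v3 <- extract_variants(align_pair("AAAAACCCC", "AAACACCCC"))
  expect_equal(v3$snvs$mutation_class, "transversion")
  # no mismatches -> zero SNVs
  expect_equal(nrow(extract_variants(align_pair("ACGU", "ACGU"))$snvs), 0L)
})

test_that("column accounting holds on simulated homoeolog pairs", {
  cfg <- sim_config(seed = 61, n_pairs = 3L, mean_len = 400L)
  sim <- simulate_homoeolog_pairs(cfg)
  for (k in 1:3) {
    a <- sim$transcripts$sequence[2 * k - 1]
    b <- sim$transcripts$sequence[2 * k]
    al <- align_pair(a, b)
    v <- extract_variants(al)
    expect_equal(v$counts$matched + v$counts$snv + v$counts$n_dropped +
                   v$counts$gap, nrow(al$map))
    # realized SNVs match the truth records for this pair
    truth_k <- sim$truth[sim$truth$pair_id == sprintf("pair%03d", k) &
                           sim$truth$type == "snv", ]
    expect_equal(v$counts$snv, nrow(truth_k))
    expect_equal(v$snvs$pos_a, truth_k$pos_a)
    expect_equal(v$snvs$allele_b, truth_k$allele_b)
  }
})

test_that("eSDC follows its closed form and Pearson invariances", {
  al <- align_pair(strrep("A", 99), strrep("A", 99))
  # exact r = 0.5 by construction: b = a/2 + sqrt(3)/2 * orthogonal
  a <- rep(c(1, 0, -1, 0), length.out = 96)
  co <- rep(c(0, 1, 0, -1), length.out = 96)
  b <- 0.5 * a + sqrt(0.75) * co
  al96 <- align_pair(strrep("A", 96), strrep("A", 96))
  e <- esdc(a + 2, b + 2, al96)
  expect_equal(as.numeric(e), 0.5 * sqrt(96), tolerance = 1e-9)
  # identical profiles -> 0
  x <- runif(99)
  expect_equal(as.numeric(esdc(x, x, al)), 0)
  # anticorrelated profiles -> 2 * sqrt(L)
  expect_equal(as.numeric(esdc(x, -x, al)), 2 * sqrt(99))
  # invariant to shift and positive rescale of either profile
  y <- runif(99)
  expect_equal(as.numeric(esdc(x, y, al)),
               as.numeric(esdc(3 * x + 1, 10 * y - 2, al)))
  # too few shared columns -> missing
  short <- align_pair(strrep("A", 10), strrep("A", 10))
  expect_true(is.na(esdc(runif(10), runif(10), short)))
})

test_that("eSDC correlates with SNV count when SNVs drive divergence", {
  set.seed(71)
  n <- 60
  n_snv <- rpois(n, 10)
  # reactivity decorrelation increasing with SNV count
  stats <- purrr::map_dfr(seq_len(n), function(k) {
    L <- 200
    al <- align_pair(strrep("A", L), strrep("A", L))
    x <- runif(L)
    noise_sd <- 0.05 + 0.03 * n_snv[k]
    y <- x + rnorm(L, 0, noise_sd)
    tibble::tibble(esdc = as.numeric(esdc(x, y, al)), n_snv = n_snv[k])
  })
  res <- esdc_snv_correlation(stats)
  expect_gt(res$r[res$covariate == "n_snv"], 0.5)
  # independent eSDC and SNV count decorrelate at large n
  set.seed(72)
  perm <- tibble::tibble(esdc = runif(500, 0, 10), n_snv = rpois(500, 10))
  expect_lt(abs(esdc_snv_correlation(perm)$r[1]), 0.15)
  # zero variance -> missing
  const <- tibble::tibble(esdc = rep(1, 10), n_snv = 1:10)
  expect_true(is.na(esdc_snv_correlation(const)$r[1]))
})
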