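counts_for <- function(rna, poly, ids = paste0("t", seq_along(rna)),
                       reps = 1L) {
  purrr::map_dfr(seq_len(reps), function(r)
    tibble::tibble(transcript_id = ids, replicate = r, rna_count = rna,
                   polysome_count = poly))
}

test_that("TE is the polysome/RNA abundance ratio", {
  cnt <- counts_for(c(10, 10), c(20, 10))
  te <- translation_efficiency(cnt, method = "cpm")
  # per-million scaling cancels in the ratio of ratios
  expect_equal(te$te[1] / te$te[2], 2.0)
  # poly == rna for all transcripts -> all TE 1
  te1 <- translation_efficiency(counts_for(c(5, 7), c(5, 7)),
                                method = "cpm")
  expect_equal(te1$te, c(1, 1))
  # zero RNA abundance -> missing
  te0 <- translation_efficiency(counts_for(c(0, 10), c(5, 5)),
                                method = "cpm")
  expect_true(is.na(te0$te[1]))
})

test_that("TPM abundances are length-normalized", {
  tr <- tibble::tibble(transcript_id = c("t1", "t2"),
                       length = c(100L, 200L))
  cnt <- counts_for(c(10, 20), c(10, 20))
  te <- translation_efficiency(cnt, tr, method = "tpm")
  expect_equal(te$te, c(1, 1))  # equal rates cancel
})

test_that("GC content counts G+C over ACGU", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("AUAU"), 0.0)
  expect_equal(gc_content(c("GCAU", "GCGCAT")), c(0.5, 2 / 3))
})

test_that("CAI and tAI are geometric means of adaptiveness weights", {
  # every codon the most frequent of its family -> 1
  usage <- tibble::tibble(codon = c("AAA", "AAG"), count = c(10, 5))
  expect_equal(cai("AAAAAA", usage), 1.0)
  # weights (1, 0.25) -> sqrt(0.25) = 0.5
  expect_equal(cai("AAAAAG", tibble::tibble(codon = c("AAA", "AAG"),
                                            count = c(4, 1))), 0.5)
  w <- tibble::tibble(codon = c("AAA", "GAA"), w = c(1, 0.25))
  expect_equal(tai("AAAGAA", w), 0.5)
  expect_equal(tai("AAAAAA", w), 1.0)
  # log-space equals the direct product on a longer CDS
  set.seed(2)
  fam <- codon_adaptiveness(tibble::tibble(
    codon = names(ribostruct:::rna_genetic_code()),
    count = runif(64, 1, 100)))
  cds <- paste(sample(fam$codon, 40, replace = TRUE), collapse = "")
  direct <- prod(fam$r[match(ribostruct:::split_codons(cds), fam$codon)])^
    (1 / 40)
  expect_equal(cai(cds, fam), direct, tolerance = 1e-12)
  # contract errors
  expect_error(cai("AAAA", usage), "divisible")
  expect_error(cai("CCC", usage), "absent")
  # codons with N are skipped with n decremented
  expect_equal(cai("AAAANA", tibble::tibble(codon = "AAA", count = 1)), 1.0)
})

test_that("differential TE matches a hand-computed Welch test", {
  te <- tibble::tibble(
    transcript_id = c("a1", "b1"),
    te = c(2.0, 1.0), n_reps = 3L,
    te_reps = list(c(2.0, 2.1, 1.9), c(1.0, 1.05, 0.95)))
  pairs <- tibble::tibble(a_id = "a1", b_id = "b1")
  res <- differential_te(pairs, te)
  # Welch t statistic computed from first principles
  la <- log2(c(2.0, 2.1, 1.9))
  lb <- log2(c(1.0, 1.05, 0.95))
  tstat <- (mean(la) - mean(lb)) / sqrt(var(la) / 3 + var(lb) / 3)
  df <- (var(la) / 3 + var(lb) / 3)^2 /
    ((var(la) / 3)^2 / 2 + (var(lb) / 3)^2 / 2)
  expect_equal(res$p, 2 * pt(-abs(tstat), df))
  expect_equal(res$direction, "A_higher")
  expect_lt(res$p_adj, 0.05)

  # identical replicates -> p = 1, NSD
  te2 <- dplyr::mutate(te, te_reps = list(c(1, 1.1, 0.9), c(1, 1.1, 0.9)),
                       te = 1)
  expect_equal(differential_te(pairs, te2)$direction, "NSD")

  # pairs lacking replicates are excluded and counted
  te3 <- te[1, ]
  res3 <- differential_te(pairs, te3)
  expect_true(is.na(res3$p))
  expect_equal(attr(res3, "excluded"), 1L)
})

test_that("BH-adjusted p-values are monotone in raw p and within [0, 1]", {
  set.seed(9)
  te_reps <- purrr::map(1:40, ~ 2^rnorm(3, 0, 0.3))
  te <- tibble::tibble(
    transcript_id = c(sprintf("a%02d", 1:20), sprintf("b%02d", 1:20)),
    te = purrr::map_dbl(te_reps, mean), n_reps = 3L, te_reps = te_reps)
  pairs <- tibble::tibble(a_id = sprintf("a%02d", 1:20),
                          b_id = sprintf("b%02d", 1:20))
  res <- differential_te(pairs, te)
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
})

test_that("TE covariate correlations behave at the extremes", {
  set.seed(4)
  df <- tibble::tibble(te = 2^rnorm(400))
  df$self <- log2(df$te)
  df$affine <- 2 * log2(df$te)
  df$noise <- rnorm(400)
  res <- te_covariate_correlations(df, c("self", "affine", "noise"))
  expect_equal(res$r[1], 1.0)
  expect_equal(res$r[2], 1.0)  # affine invariance of Pearson r
  expect_lt(abs(res$r[3]), 0.12)
})

test_that("metagene profiles recover a constructed TE-linked offset", {
  set.seed(6)
  n_tr <- 20
  len <- 120L
  tr <- tibble::tibble(
    transcript_id = sprintf("t%02d", 1:n_tr), subgenome = "other",
    sequence = strrep("A", len), length = len,
    cds_start = 30L, cds_end = 90L)
  te_vals <- seq(0.1, 4, length.out = n_tr)
  te <- tibble::tibble(transcript_id = tr$transcript_id, te = te_vals,
                       n_reps = 1L, te_reps = as.list(te_vals))
  react <- purrr::map_dfr(seq_len(n_tr), function(k)
    tibble::tibble(transcript_id = tr$transcript_id[k],
                   position = 0:(len - 1),
                   reactivity = 0.5 + ifelse(te_vals[k] > 2, 0.2, 0)))
  prof <- metagene_profile(react, tr, te, decile = 0.10)
  hi <- prof$reactivity[prof$group == "high_te"]
  lo <- prof$reactivity[prof$group == "low_te"]
  expect_equal(unique(hi), 0.7)
  expect_equal(unique(lo), 0.5)
  # decile = 0.5 with n transcripts puts half in each group
  prof50 <- metagene_profile(react, tr, te, decile = 0.5)
  expect_equal(unique(prof50$n_transcripts), n_tr / 2)
})

test_that("period-3 score matches its closed forms", {
  expect_equal(periodicity_3nt(rep(c(1, 0, 0), 20)), 1.0)
  expect_equal(periodicity_3nt(rep(0.7, 60)), 0)
  # adding a constant strictly dilutes the periodic component
  s1 <- periodicity_3nt(rep(c(1, 0, 0), 20) + 0.2)
  s2 <- periodicity_3nt(rep(c(1, 0, 0), 20) + 0.8)
  expect_true(s2 < s1 && s1 < 1)
  # closed form: component n/3 over total n/3 + n*c
  cc <- 0.2
  expect_equal(s1, (20) / (20 + 60 * cc))
  expect_error(periodicity_3nt(rep(1, 10)), "shorter")
})
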