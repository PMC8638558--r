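test_that("the canonical hairpin folds as expected", {
  f <- fold_rna("GGGAAACCC", want_pmat = TRUE)
  expect_equal(f$dotbracket, "(((...)))")
  expect_equal(f$pairs, tibble::tibble(i = 0:2, j = c(8L, 7L, 6L)))
  o <- oracle_fold("GGGAAACCC")
  expect_equal(f$mfe, o$mfe)
  expect_equal(f$bpp, o$bpp, tolerance = 1e-9)
  # pair-probability matrix is symmetric and rows sum to bpp
  expect_equal(f$pmat, t(f$pmat))
  expect_equal(rowSums(f$pmat), f$bpp)
})

test_that("DP partition function matches exhaustive enumeration", {
  set.seed(101)
  for (k in 1:40) {
    n <- sample(5:16, 1)
    s <- random_rna(n)
    react <- if (k %% 2 == 0) runif(n, 0, 2) else NULL
    if (!is.null(react)) react[sample(n, 2)] <- NA
    o <- oracle_fold(s, reactivity = react)
    f <- fold_rna(s, reactivity = react)
    expect_equal(f$bpp, o$bpp, tolerance = 1e-9)
    expect_equal(f$logZ, o$logZ, tolerance = 1e-9)
    expect_equal(f$mfe, o$mfe, tolerance = 1e-9)
  }
})

test_that("SHAPE pseudo-energy follows the Deigan form", {
  m <- energy_model()
  expect_equal(shape_pseudo_energy(0, m), -0.6)
  expect_equal(shape_pseudo_energy(exp(1) - 1, m), 1.2)
  expect_equal(shape_pseudo_energy(NA, m), 0)
})

test_that("uniform high reactivity abolishes pairing", {
  s <- "GGGGAAAACCCC"
  # pseudo-energy penalty per paired nucleotide exceeding half the best
  # pair gain forces the open chain
  f <- fold_rna(s, reactivity = rep(20, nchar(s)))
  expect_equal(f$dotbracket, strrep(".", nchar(s)))
  expect_true(all(f$bpp < 0.05))
  # min_hairpin blocks all pairs on very short sequences
  expect_equal(fold_rna("ACGU")$dotbracket, "....")
  # no legal pair at all
  f2 <- fold_rna("AAAAA")
  expect_equal(f2$bpp, rep(0, 5))
  expect_equal(f2$logZ, 0)
})

test_that("raising a nucleotide's reactivity never raises its bpp", {
  set.seed(77)
  for (k in 1:8) {
    s <- random_rna(14)
    react <- runif(14, 0, 1)
    f0 <- fold_rna(s, reactivity = react)
    i <- sample(14, 1)
    react2 <- react
    react2[i] <- react[i] + 1.5
    f1 <- fold_rna(s, reactivity = react2)
    expect_lte(f1$bpp[i], f0$bpp[i] + 1e-12)
  }
})

test_that("windowed folding covers long transcripts", {
  set.seed(5)
  s <- random_rna(700)
  f <- fold_transcript(s, window = 300, step = 150)
  expect_equal(f$n, 700L)
  expect_true(all(f$bpp >= 0 & f$bpp <= 1))
  expect_equal(nchar(f$dotbracket), 700L)
  # short sequences fold in one window, identical to fold_rna
  s2 <- random_rna(80)
  expect_equal(fold_transcript(s2)$bpp, fold_rna(s2)$bpp)
})

test_that("PPV matches its definition, including the undefined case", {
  p1 <- tibble::tibble(i = c(0L, 1L), j = c(8L, 7L))
  ref <- tibble::tibble(i = 0L, j = 8L)
  expect_equal(ppv(p1, p1), 1.0)
  expect_equal(ppv(p1, tibble::tibble(i = 3L, j = 9L)), 0.0)
  expect_equal(ppv(p1, ref), 0.5)
  expect_true(is.na(ppv(p1[0, ], ref)))
  # in-silico vs itself
  f <- fold_rna("GGGAAACCC")
  expect_equal(ppv(f$pairs, f$pairs), 1.0)
})

test_that("reference agreement classifies by the 0.3/0.6 reactivity bands", {
  r <- reference_agreement(c(0.7, 0.1), ref_paired = c(FALSE, TRUE))
  expect_equal(r$tp_rate, 1.0)
  expect_equal(r$tn_rate, 1.0)
  r2 <- reference_agreement(c(0.7, 0.1), ref_paired = c(TRUE, FALSE))
  expect_equal(r2$tp_rate, 0.0)
  expect_equal(r2$tn_rate, 0.0)
  r3 <- reference_agreement(c(0.45, 0.45), ref_paired = c(TRUE, FALSE))
  expect_true(is.na(r3$tp_rate) && is.na(r3$tn_rate))
})

test_that("regional mean bpp follows the annotation", {
  bpp <- (0:9) / 10
  m <- mean_bpp_by_region(bpp, cds_start = 4, cds_end = 10)
  expect_equal(m$cds, mean(seq(0.4, 0.9, by = 0.1)))  # 0.65
  expect_equal(m$utr5, mean((0:3) / 10))
  expect_true(is.na(m$utr3))
  flat <- mean_bpp_by_region(rep(0.5, 10), 3, 7)
  expect_equal(unlist(flat), c(utr5 = 0.5, cds = 0.5, utr3 = 0.5,
                               full = 0.5))
})

test_that("fold tidiers expose per-nucleotide and summary views", {
  f <- fold_rna("GGGAAACCC")
  f$transcript_id <- "t1"
  td <- tidy(f)
  expect_equal(nrow(td), 9L)
  expect_equal(td$mfe_paired, c(rep(TRUE, 3), rep(FALSE, 3), rep(TRUE, 3)))
  g <- glance(f)
  expect_equal(g$n_pairs, 3L)
  expect_equal(g$mfe, f$mfe)
})

test_that("engine and external folder agree on unambiguous hairpins", {
  # sanity check against an independently developed thermodynamic folder,
  # on constructs whose structure is unambiguous under any sane model
  skip_if(Sys.which("RNAfold") == "", "no external folding backend")
  set.seed(3)
  agree <- purrr::map_dbl(1:8, function(k) {
    stem <- sample(6:9, 1)
    loop <- sample(4:6, 1)
    s <- paste0(strrep("A", 5), strrep("G", stem), strrep("A", loop),
                strrep("C", stem), strrep("A", 5))
    ours <- strsplit(fold_rna(s)$dotbracket, "")[[1]] != "."
    out <- system2("RNAfold", "--noPS", input = c(">x", s), stdout = TRUE)
    theirs <- strsplit(sub(" .*$", "", out[3]), "")[[1]] != "."
    mean(ours == theirs)
  })
  expect_gte(mean(agree), 0.9)
})
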