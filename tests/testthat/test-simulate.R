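test_that("config validation enforces rate and dispersion contracts", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, snv_rate = 1.2), "outside")
  expect_error(sim_config(seed = 1, nb_dispersion = 0), "dispersion")
  expect_error(sim_config(seed = 1, mod_rate_unpaired = 0.01,
                          mod_rate_paired = 0.05), "exceed")
})

test_that("zero divergence yields identical homoeologs", {
  cfg <- sim_config(seed = 2, n_pairs = 3L, mean_len = 200L,
                    snv_rate = 0, indel_rate = 0)
  sim <- simulate_homoeolog_pairs(cfg)
  for (k in 1:3) {
    expect_equal(sim$transcripts$sequence[2 * k - 1],
                 sim$transcripts$sequence[2 * k])
  }
  expect_equal(nrow(sim$truth), 0L)
})

test_that("realized substitution fraction tracks the configured rate", {
  cfg <- sim_config(seed = 13, n_pairs = 50L, mean_len = 1000L,
                    snv_rate = 0.05, indel_rate = 0)
  sim <- simulate_homoeolog_pairs(cfg)
  total_len <- sum(sim$transcripts$length[sim$transcripts$subgenome == "A"])
  frac <- sum(sim$truth$type == "snv") / total_len
  expect_lt(abs(frac - 0.05), 0.01)
  # transitions outnumber transversions roughly 2:1
  cls <- ifelse(paste0(sim$truth$allele_a, sim$truth$allele_b) %in%
                  c("AG", "GA", "CU", "UC"), "ts", "tv")
  expect_gt(mean(cls == "ts"), 0.55)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 17, n_pairs = 3L, mean_len = 200L)
  s1 <- simulate_homoeolog_pairs(cfg)
  s2 <- simulate_homoeolog_pairs(cfg)
  expect_identical(s1, s2)
  e1 <- simulate_expression(s1$pairs, cfg)
  e2 <- simulate_expression(s1$pairs, cfg)
  expect_identical(e1$counts, e2$counts)
  # byte-identical FASTA output
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(s1$transcripts, f1)
  write_fasta(s2$transcripts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("CDS stays in frame and indels avoid boundaries", {
  cfg <- sim_config(seed = 19, n_pairs = 10L, mean_len = 400L,
                    indel_rate = 0.01)
  sim <- simulate_homoeolog_pairs(cfg)
  cds_len <- sim$transcripts$cds_end - sim$transcripts$cds_start
  expect_true(all(cds_len %% 3 == 0))
  expect_true(all(sim$transcripts$cds_end <= sim$transcripts$length))
  idl <- sim$truth[sim$truth$type %in% c("ins", "del"), ]
  expect_true(all(idl$length %in% 1:3))
  expect_true(all(idl$length[idl$region == "cds"] == 3))
})

test_that("null probing produces vanishing reactivity", {
  cfg <- sim_config(seed = 23, mod_rate_unpaired = 0.0501,
                    mod_rate_paired = 0.05, coverage_mean = 2000)
  tr <- tibble::tibble(transcript_id = "t1", subgenome = "A",
                       sequence = random_rna(300), length = 300L,
                       cds_start = NA_integer_, cds_end = NA_integer_)
  paired <- rep(c(TRUE, FALSE), 150)
  stops <- simulate_probing(tr, list(t1 = paired), cfg)
  raw <- raw_reactivity(stop_rate(stops, min_coverage = 50))
  # plus and minus channels nearly equal in expectation -> raw ~ 0 with
  # the 0.05 shared modification excess
  expect_lt(mean(raw$raw, na.rm = TRUE), 0.06)
  expect_gt(mean(raw$raw, na.rm = TRUE), 0.03)
})

test_that("population simulation rejects invalid frequencies", {
  cfg <- sim_config(seed = 29)
  snvs <- tibble::tibble(snv_id = "s1", chrom = "c", pos = 1L,
                         allele_a = "A", allele_b = "G",
                         is_ribosnitch = FALSE)
  bad <- tibble::tibble(snv_id = "s1", subpop = c("DW", "DEW", "WEW"),
                        freq_a = c(1.2, 0.5, 0.5))
  expect_error(simulate_population(snvs, cfg, freqs = bad), "outside")
  # fixed allele in all pops -> F_ST undefined (pi_bar = 1)
  fixed <- dplyr::mutate(bad, freq_a = 1)
  pop <- simulate_population(snvs, cfg, freqs = fixed)
  expect_true(is.na(fst_table(pop$pop_table)$fst))
  # full fixation difference -> F_ST = 1
  polar <- tibble::tibble(snv_id = "s1", subpop = c("DW", "DEW"),
                          freq_a = c(1, 0))
  cfg2 <- sim_config(seed = 29, pop_sizes = c(DW = 10L, DEW = 10L))
  pop2 <- simulate_population(snvs, cfg2, freqs = polar)
  expect_equal(fst_table(pop2$pop_table)$fst, 1)
})

test_that("simulated studies re-parse through the package readers", {
  cfg <- sim_config(seed = 31, n_pairs = 2L, mean_len = 200L)
  study <- simulate_study(cfg, fold_window = 150L, fold_step = 75L)
  outdir <- withr::local_tempdir()
  write_simulation(study, outdir)
  expect_no_warning({
    seqs <- read_fasta(file.path(outdir, "transcripts.fa"))
    ann <- read_annotation(file.path(outdir, "annotation.tsv"))
    tr <- make_transcripts(seqs, ann)
    stops <- read_stop_counts(file.path(outdir, "stops.tsv"), tr)
  })
  expect_equal(sort(seqs$transcript_id),
               sort(study$transcripts$transcript_id))
  expect_equal(nrow(stops),
               sum(study$transcripts$length) * 2 * cfg$n_probe_reps)
})
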