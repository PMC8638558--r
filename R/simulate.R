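#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: homoeolog
#' pairs diverged by point substitutions at ~4.58% with a 2:1
#' transition:transversion weight plus sparse short indels; SHAPE probing
#' that modifies single-stranded nucleotides about ten times more often
#' than paired ones over a 2% background; negative-binomial expression
#' counts with per-pair log2 TE differences; and three subpopulations
#' (durum, domesticated emmer, wild emmer) of 13/29/28 accessions.
#'
#' @param seed Integer seed (required; no silent default).
#' @param n_pairs Number of homoeolog pairs.
#' @param mean_len Mean transcript length (nt).
#' @param snv_rate Per-nucleotide substitution rate between subgenomes.
#' @param indel_rate Per-nucleotide indel initiation rate.
#' @param ts_tv_weight Transition:transversion weight.
#' @param te_logfc_sd SD of true per-pair log2 TE differences.
#' @param null_te_fraction Fraction of pairs forced to a zero TE
#'   difference.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param base_abundance Mean RNA-seq count per transcript.
#' @param mod_rate_unpaired,mod_rate_paired SHAPE modification rates for
#'   single-stranded / paired nucleotides (unpaired must exceed paired).
#' @param mod_rate_hyper Modification rate for hyper-exposed nucleotides
#'   (e.g. a helix fully melted in vivo); at least `mod_rate_unpaired`.
#' @param background_stop_rate RT-stop background rate (both channels).
#' @param coverage_mean Mean per-position coverage (Poisson).
#' @param n_probe_reps,n_expr_reps Replicates for probing / expression.
#' @param pop_sizes Named integer vector of accessions per subpopulation.
#' @param ribosnitch_fraction Fraction of SNV sites given divergent
#'   subpopulation allele frequencies.
#' @return A validated list of class `ribo_sim_config`.
#' @export
sim_config <- function(seed, n_pairs = 50L, mean_len = 500L,
                       snv_rate = 0.0458, indel_rate = 0.002,
                       ts_tv_weight = 2, te_logfc_sd = 0.8,
                       null_te_fraction = 0.3, nb_dispersion = 0.01,
                       base_abundance = 500, mod_rate_unpaired = 0.10,
                       mod_rate_paired = 0.01, mod_rate_hyper = 0.25,
                       background_stop_rate = 0.02, coverage_mean = 200,
                       n_probe_reps = 2L, n_expr_reps = 3L,
                       pop_sizes = c(DW = 13L, DEW = 29L, WEW = 28L),
                       ribosnitch_fraction = 0.2) {
  if (missing(seed) || !is_scalar_number(seed)) {
    abort("sim_config: an integer 'seed' is required")
  }
  rates <- c(snv_rate = snv_rate, indel_rate = indel_rate,
             mod_rate_unpaired = mod_rate_unpaired,
             mod_rate_paired = mod_rate_paired,
             background_stop_rate = background_stop_rate,
             null_te_fraction = null_te_fraction,
             ribosnitch_fraction = ribosnitch_fraction)
  if (any(rates < 0 | rates > 1)) {
    abort(sprintf("sim_config: rate(s) outside [0, 1]: %s",
                  paste(names(rates)[rates < 0 | rates > 1],
                        collapse = ", ")))
  }
  if (snv_rate >= 1) abort("sim_config: snv_rate must be < 1")
  if (mod_rate_unpaired <= mod_rate_paired) {
    abort("sim_config: mod_rate_unpaired must exceed mod_rate_paired")
  }
  if (mod_rate_hyper < mod_rate_unpaired || mod_rate_hyper > 1) {
    abort("sim_config: mod_rate_hyper must be in [mod_rate_unpaired, 1]")
  }
  if (nb_dispersion <= 0) abort("sim_config: nb_dispersion must be > 0")
  structure(list(
    seed = as.integer(seed), n_pairs = as.integer(n_pairs),
    mean_len = as.integer(mean_len), snv_rate = snv_rate,
    indel_rate = indel_rate, ts_tv_weight = ts_tv_weight,
    te_logfc_sd = te_logfc_sd, null_te_fraction = null_te_fraction,
    nb_dispersion = nb_dispersion, base_abundance = base_abundance,
    mod_rate_unpaired = mod_rate_unpaired,
    mod_rate_paired = mod_rate_paired, mod_rate_hyper = mod_rate_hyper,
    background_stop_rate = background_stop_rate,
    coverage_mean = coverage_mean,
    n_probe_reps = as.integer(n_probe_reps),
    n_expr_reps = as.integer(n_expr_reps), pop_sizes = pop_sizes,
    ribosnitch_fraction = ribosnitch_fraction),
    class = "ribo_sim_config")
}

# transition partner; everything else is a transversion
TRANSITION <- c(A = "G", G = "A", C = "U", U = "C")

draw_substitution <- function(base, ts_tv_weight) {
  others <- setdiff(RNA_BASES, base)
  w <- ifelse(others == TRANSITION[[base]], ts_tv_weight, 0.5)
  sample(others, 1, prob = w)
}

# seed offsets: each generator consumes an independent, documented stream
SEED_OFFSETS <- c(pairs = 0L, probing = 1L, expression = 2L,
                  population = 3L, switch = 4L)

#' Simulate diverged homoeolog pairs
#'
#' The A transcript is drawn uniformly over ACGU with region boundaries
#' (~15% 5'UTR, 60% CDS rounded to a codon multiple, remainder 3'UTR);
#' the B homoeolog is derived by iid substitutions at `snv_rate`
#' (transition-weighted) and indels at `indel_rate` (1-3 nt in UTRs,
#' 3 nt in the CDS so the reading frame is preserved; never within 10 nt
#' of a region boundary). Every introduced variant is recorded in the
#' truth table.
#'
#' @param config A [sim_config()].
#' @return List with `transcripts` (tibble, both homoeologs annotated),
#'   `pairs` (`pair_id`, `a_id`, `b_id`), and `truth` (one row per
#'   variant: `pair_id`, `type`, `pos_a`, `pos_b`, `allele_a`,
#'   `allele_b`, `length`, `region`).
#' @export
simulate_homoeolog_pairs <- function(config) {
  set.seed(config$seed + SEED_OFFSETS[["pairs"]])
  res <- purrr::map(seq_len(config$n_pairs), function(k) {
    len <- max(150L, round(rnorm(1, config$mean_len,
                                 0.1 * config$mean_len)))
    cds_start <- max(30L, round(0.15 * len))
    cds_len <- (floor(0.60 * len) %/% 3L) * 3L
    cds_end <- cds_start + cds_len
    a <- sample(RNA_BASES, len, replace = TRUE)
    region <- region_of(seq_len(len) - 1L, cds_start, cds_end)

    # substitutions
    sub_pos <- which(runif(len) < config$snv_rate)
    sub_new <- vapply(a[sub_pos], draw_substitution, character(1),
                      ts_tv_weight = config$ts_tv_weight,
                      USE.NAMES = FALSE)
    # indels: away from boundaries, non-adjacent
    bnd <- c(0L, cds_start, cds_end, len)
    eligible <- which(purrr::map_lgl(seq_len(len) - 1L,
                                     ~ all(abs(.x - bnd) > 10)))
    idl_pos <- eligible[runif(length(eligible)) < config$indel_rate]
    if (length(idl_pos) > 1) {  # keep indels >= 5 nt apart
      idl_pos <- idl_pos[c(TRUE, diff(idl_pos) >= 5)]
    }
    indels <- tibble::tibble(
      pos = idl_pos,
      type = sample(c("ins", "del"), length(idl_pos), replace = TRUE),
      len = purrr::map_int(idl_pos, function(p) {
        if (region[p] == "cds") 3L else sample(1:3, 1)
      }))

    # walk A left to right building B
    b <- character(0)
    truth <- list()
    pos_b <- 0L
    skip_until <- -1L
    for (p in seq_len(len)) {
      p0 <- p - 1L
      idl <- which(indels$pos == p0)
      if (length(idl) == 1 && indels$type[idl] == "del") {
        truth[[length(truth) + 1]] <- tibble::tibble(
          type = "del", pos_a = p0, pos_b = pos_b, allele_a = NA_character_,
          allele_b = NA_character_, length = indels$len[idl],
          region = region[p])
        skip_until <- p0 + indels$len[idl] - 1L
      }
      if (p0 <= skip_until) next
      base <- a[p]
      si <- which(sub_pos == p)
      if (length(si) == 1) {
        base <- sub_new[si]
        truth[[length(truth) + 1]] <- tibble::tibble(
          type = "snv", pos_a = p0, pos_b = pos_b, allele_a = a[p],
          allele_b = base, length = 1L, region = region[p])
      }
      b <- c(b, base)
      pos_b <- pos_b + 1L
      if (length(idl) == 1 && indels$type[idl] == "ins") {
        ins <- sample(RNA_BASES, indels$len[idl], replace = TRUE)
        truth[[length(truth) + 1]] <- tibble::tibble(
          type = "ins", pos_a = p0, pos_b = pos_b, allele_a = NA_character_,
          allele_b = NA_character_, length = indels$len[idl],
          region = region[p])
        b <- c(b, ins)
        pos_b <- pos_b + length(ins)
      }
    }
    truth <- dplyr::bind_rows(truth)
    shift_at <- function(x) {
      if (nrow(truth) == 0) return(x)
      ins <- sum(truth$length[truth$type == "ins" & truth$pos_a < x])
      del <- sum(truth$length[truth$type == "del" & truth$pos_a < x])
      x + ins - del
    }
    a_id <- sprintf("pair%03d_A", k)
    b_id <- sprintf("pair%03d_B", k)
    list(
      transcripts = tibble::tibble(
        transcript_id = c(a_id, b_id), subgenome = c("A", "B"),
        sequence = c(paste(a, collapse = ""), paste(b, collapse = "")),
        length = c(len, length(b)),
        cds_start = c(cds_start, shift_at(cds_start)),
        cds_end = c(cds_end, shift_at(cds_end))),
      pairs = tibble::tibble(pair_id = sprintf("pair%03d", k),
                             a_id = a_id, b_id = b_id),
      truth = dplyr::mutate(truth, pair_id = sprintf("pair%03d", k),
                            a_id = a_id, b_id = b_id))
  })
  list(transcripts = purrr::map_dfr(res, "transcripts"),
       pairs = purrr::map_dfr(res, "pairs"),
       truth = purrr::map_dfr(res, "truth"))
}

#' Simulate SHAPE probing stop counts
#'
#' Coverage is Poisson per position; plus-channel stops are binomial with
#' probability `background + mod_rate` (the mod rate chosen by the
#' nucleotide's structural class in the supplied true structure), minus-
#' channel stops use the background alone. RT stops are independent per
#' position (no drop-off cascade).
#'
#' @param transcripts Transcript tibble.
#' @param structures Named list (by transcript id) of either `ribo_fold`
#'   objects, logical paired-status vectors, or integer class vectors
#'   (0 = single-stranded, 1 = paired, 2 = hyper-exposed).
#' @param config A [sim_config()].
#' @return Long-format stop-count tibble (see [read_stop_counts()]).
#' @export
simulate_probing <- function(transcripts, structures, config) {
  set.seed(config$seed + SEED_OFFSETS[["probing"]])
  purrr::map_dfr(seq_len(nrow(transcripts)), function(k) {
    id <- transcripts$transcript_id[k]
    n <- transcripts$length[k]
    st <- structures[[id]]
    class_vec <- if (inherits(st, "ribo_fold")) {
      as.integer(seq_chars(st$dotbracket) != ".")
    } else if (is.logical(st)) {
      as.integer(st)
    } else {
      as.integer(st)
    }
    stopifnot(length(class_vec) == n, all(class_vec %in% 0:2))
    mod <- c(config$mod_rate_unpaired, config$mod_rate_paired,
             config$mod_rate_hyper)[class_vec + 1L]
    p_plus <- pmin(1, config$background_stop_rate + mod)
    p_minus <- min(1, config$background_stop_rate)
    purrr::map_dfr(seq_len(config$n_probe_reps), function(r) {
      cov_p <- rpois(n, config$coverage_mean)
      cov_m <- rpois(n, config$coverage_mean)
      tibble::tibble(
        transcript_id = id,
        position = rep(seq_len(n) - 1L, 2),
        channel = rep(c("plus", "minus"), each = n),
        replicate = r,
        stops = c(rbinom(n, cov_p, p_plus), rbinom(n, cov_m, p_minus)),
        coverage = c(cov_p, cov_m))
    })
  })
}

#' Simulate RNA-seq and polysome-seq counts
#'
#' Each pair draws a true log2 TE difference from
#' `N(0, te_logfc_sd)` (a `null_te_fraction` of pairs is forced to zero)
#' and a base abundance; counts are negative-binomial around
#' abundance (RNA) and abundance x TE (polysome).
#'
#' @param pairs Pair tibble from [simulate_homoeolog_pairs()].
#' @param config A [sim_config()].
#' @return List with `counts` (long tibble: `transcript_id`, `replicate`,
#'   `rna_count`, `polysome_count`) and `truth` (`pair_id`,
#'   `true_log2_te_ratio`).
#' @export
simulate_expression <- function(pairs, config) {
  set.seed(config$seed + SEED_OFFSETS[["expression"]])
  n <- nrow(pairs)
  delta <- rnorm(n, 0, config$te_logfc_sd)
  delta[runif(n) < config$null_te_fraction] <- 0
  base <- config$base_abundance * exp(rnorm(n, 0, 0.5))
  size <- 1 / config$nb_dispersion
  counts <- purrr::map_dfr(seq_len(n), function(k) {
    te_a <- 2^(delta[k] / 2)
    te_b <- 2^(-delta[k] / 2)
    purrr::map_dfr(seq_len(config$n_expr_reps), function(r) {
      tibble::tibble(
        transcript_id = c(pairs$a_id[k], pairs$b_id[k]),
        replicate = r,
        rna_count = rnbinom(2, mu = base[k], size = size),
        polysome_count = rnbinom(2, mu = base[k] * c(te_a, te_b),
                                 size = size))
    })
  })
  list(counts = counts,
       truth = tibble::tibble(pair_id = pairs$pair_id,
                              a_id = pairs$a_id, b_id = pairs$b_id,
                              true_log2_te_ratio = delta))
}

#' Simulate population genotypes for SNV sites
#'
#' Per SNV and subpopulation, an allele frequency for the A-subgenome
#' allele is chosen (divergent across subpopulations at riboSNitch sites,
#' shared at the rest, unless `freqs` supplies them explicitly); each
#' accession's diploid genotype is drawn binomially.
#'
#' @param snvs Tibble with `snv_id`, `chrom`, `pos` (1-based),
#'   `allele_a`, `allele_b`, `is_ribosnitch`.
#' @param config A [sim_config()].
#' @param freqs Optional explicit frequencies: tibble `snv_id`, `subpop`,
#'   `freq_a` in `[0, 1]`.
#' @return List with `pop_table` (allele counts, as from
#'   [read_vcf_population()]), `sites`, `genotypes` (alt dosage matrix),
#'   `popmap`, and `freqs` (the generating frequencies).
#' @export
simulate_population <- function(snvs, config, freqs = NULL) {
  set.seed(config$seed + SEED_OFFSETS[["population"]])
  subpops <- names(config$pop_sizes)
  if (is.null(freqs)) {
    freqs <- purrr::map_dfr(seq_len(nrow(snvs)), function(k) {
      f <- if (isTRUE(snvs$is_ribosnitch[k])) {
        # divergent: near-fixed in the reference population, spread in the
        # others
        c(runif(1, 0.90, 1.0), runif(1, 0.10, 0.50),
          runif(1, 0.30, 0.80))[seq_along(subpops)]
      } else {
        rep(runif(1, 0.10, 0.90), length(subpops))
      }
      tibble::tibble(snv_id = snvs$snv_id[k], subpop = subpops, freq_a = f)
    })
  }
  if (any(freqs$freq_a < 0 | freqs$freq_a > 1)) {
    abort("simulate_population: frequency outside [0, 1]")
  }
  popmap <- tibble::tibble(
    sample = unlist(purrr::imap(as.list(config$pop_sizes),
                                ~ sprintf("%s_%02d", .y, seq_len(.x)))),
    subpop = rep(subpops, times = config$pop_sizes))
  fmat <- freqs |>
    tidyr::pivot_wider(names_from = "subpop", values_from = "freq_a") |>
    dplyr::arrange(match(.data$snv_id, snvs$snv_id))
  genotypes <- matrix(NA_integer_, nrow = nrow(snvs),
                      ncol = nrow(popmap),
                      dimnames = list(snvs$snv_id, popmap$sample))
  for (k in seq_len(nrow(snvs))) {
    for (s in seq_len(nrow(popmap))) {
      fa <- fmat[[popmap$subpop[s]]][k]
      genotypes[k, s] <- rbinom(1, 2, 1 - fa)  # alt (= B allele) dosage
    }
  }
  sites <- tibble::tibble(chrom = snvs$chrom, pos = snvs$pos,
                          ref = snvs$allele_a, alt = snvs$allele_b)
  # allele counts directly from the genotype matrix
  pop_table <- purrr::map_dfr(seq_len(nrow(snvs)), function(k) {
    purrr::map_dfr(subpops, function(sp) {
      g <- genotypes[k, popmap$subpop == sp]
      tibble::tibble(
        snv_id = snvs$snv_id[k],
        chrom = snvs$chrom[k], pos = snvs$pos[k], subpop = sp,
        allele = c(snvs$allele_a[k], snvs$allele_b[k]),
        count = c(sum(2 - g, na.rm = TRUE), sum(g, na.rm = TRUE)))
    })
  })
  list(pop_table = pop_table, sites = sites, genotypes = genotypes,
       popmap = popmap, freqs = freqs)
}

#' Construct homoeolog pairs whose SNV melts a hairpin in vivo
#'
#' Builds riboSNitch test fixtures: each transcript carries a single
#' GU-wobble hairpin (a G-run arm, an N loop, a U-run arm) embedded in
#' unpairable N flanks. The ground-truth in vivo structure is the paired
#' stem for the A allele and a fully melted stem for the B allele, whose
#' mid-stem G-to-A substitution destabilizes the helix in vivo. Probing
#' simulated from these truths yields low-reactivity stems in A and
#' high-reactivity stems in B, so SHAPE-directed folds -- and hence
#' per-nucleotide base-pairing probabilities -- diverge across the whole
#' stem. With `effect = "null"` both alleles keep the paired truth and
#' the SNV sits in a distal unstructured poly-A segment.
#'
#' @param n_pairs Number of constructs.
#' @param seed Integer seed.
#' @param stem_len Stem arm length (nt).
#' @param effect `"switch"` or `"null"`.
#' @return List with `transcripts`, `pairs`, `snvs` (one row per
#'   construct: `pair_id`, `pos_a`, `pos_b`, `allele_a`, `allele_b`),
#'   and `structures`, a named list of logical ground-truth paired-status
#'   vectors for [simulate_probing()].
#' @export
simulate_ribosnitch_pairs <- function(n_pairs, seed, stem_len = 13L,
                                      effect = c("switch", "null")) {
  effect <- match.arg(effect)
  set.seed(seed + SEED_OFFSETS[["switch"]])
  h <- stem_len
  res <- purrr::map(seq_len(n_pairs), function(k) {
    # for switch constructs, long unpaired flanks keep the hyper-exposed
    # stem in the outlier tail of the 2-8% normalization, so its melted
    # reactivity normalizes near 2; null constructs stay short
    flank5 <- if (effect == "switch") sample(260:300, 1) else
      sample(15:25, 1)
    loop <- sample(4:6, 1)
    flank3 <- if (effect == "switch") sample(260:300, 1) else
      sample(15:25, 1)
    core <- paste0(strrep("N", flank5), strrep("G", h), strrep("N", loop),
                   strrep("U", h), strrep("N", flank3))
    stem_pos <- c(flank5 + seq_len(h), flank5 + h + loop + seq_len(h)) - 1L
    tail_len <- 0L
    if (effect == "null") {
      core <- paste0(core, strrep("N", 5), strrep("A", 30))
      tail_len <- 35L
    }
    n <- nchar(core)
    paired <- rep(0L, n)
    paired[stem_pos + 1L] <- 1L
    snv_g <- flank5 + sample(3:(h - 2), 1) - 1L  # mid-stem G position
    ca <- seq_chars(core)
    cb <- ca
    if (effect == "switch") {
      cb[snv_g + 1L] <- "A"
      snv_pos <- snv_g
      allele_a <- "G"
      allele_b <- "A"
      paired_b <- rep(0L, n)      # melted in vivo: stem hyper-exposed
      paired_b[stem_pos + 1L] <- 2L
    } else {
      snv_pos <- n - tail_len + 5L + 15L  # mid poly-A tail
      cb[snv_pos + 1L] <- "C"
      allele_a <- "A"
      allele_b <- "C"
      paired_b <- paired
    }
    a_id <- sprintf("switch%03d_A", k)
    b_id <- sprintf("switch%03d_B", k)
    list(
      transcripts = tibble::tibble(
        transcript_id = c(a_id, b_id), subgenome = c("A", "B"),
        sequence = c(core, paste(cb, collapse = "")),
        length = c(n, n),
        cds_start = NA_integer_, cds_end = NA_integer_),
      pairs = tibble::tibble(pair_id = sprintf("switch%03d", k),
                             a_id = a_id, b_id = b_id),
      snvs = tibble::tibble(pair_id = sprintf("switch%03d", k),
                            a_id = a_id, b_id = b_id,
                            pos_a = snv_pos, pos_b = snv_pos,
                            allele_a = allele_a, allele_b = allele_b),
      structures = setNames(list(paired, paired_b), c(a_id, b_id)))
  })
  list(transcripts = purrr::map_dfr(res, "transcripts"),
       pairs = purrr::map_dfr(res, "pairs"),
       snvs = purrr::map_dfr(res, "snvs"),
       structures = purrr::flatten(purrr::map(res, "structures")))
}

#' Generate a complete synthetic study
#'
#' Runs every generator in a documented order: homoeolog pairs, in-silico
#' true structures (folded with the default energy model), SHAPE probing
#' counts, expression counts, and population genotypes over the
#' substitution truth (a `ribosnitch_fraction` of SNV sites receives
#' divergent subpopulation frequencies).
#'
#' @param config A [sim_config()].
#' @param fold_window,fold_step Windowing for the truth folds.
#' @return List with `config`, `transcripts`, `pairs`, `truth`, `folds`,
#'   `stops`, `expression` (counts + truth), and `population`.
#' @export
simulate_study <- function(config, fold_window = 300L, fold_step = 150L) {
  sim <- simulate_homoeolog_pairs(config)
  folds <- fold_transcripts(sim$transcripts, model = energy_model(),
                            window = fold_window, step = fold_step)
  stops <- simulate_probing(sim$transcripts, folds, config)
  expr <- simulate_expression(sim$pairs, config)
  snv_truth <- sim$truth[sim$truth$type == "snv", ]
  set.seed(config$seed + SEED_OFFSETS[["population"]])
  is_rs <- runif(nrow(snv_truth)) < config$ribosnitch_fraction
  snv_sites <- tibble::tibble(
    snv_id = paste0(snv_truth$a_id, ":", snv_truth$pos_a + 1L),
    chrom = snv_truth$a_id, pos = snv_truth$pos_a + 1L,
    allele_a = snv_truth$allele_a, allele_b = snv_truth$allele_b,
    is_ribosnitch = is_rs)
  population <- simulate_population(snv_sites, config)
  population$snv_sites <- snv_sites
  list(config = config, transcripts = sim$transcripts, pairs = sim$pairs,
       truth = sim$truth, folds = folds, stops = stops,
       expression = expr, population = population)
}

#' Write a simulated study to files
#'
#' Writes FASTA, annotation TSV, pair list, stop counts, expression
#' counts, VCF + popmap, and a truth JSON into `outdir`. Every file
#' re-parses through the package's readers.
#'
#' @param study Output of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_fasta(study$transcripts, fp("transcripts.fa"))
  write_tsv_commented(
    dplyr::select(study$transcripts, "transcript_id", "cds_start",
                  "cds_end"), fp("annotation.tsv"))
  write_tsv_commented(study$pairs, fp("pairs.tsv"))
  write_stop_counts(study$stops, fp("stops.tsv"))
  write_tsv_commented(study$expression$counts, fp("counts.tsv"))
  pop <- study$population
  write_population_vcf(pop$sites, pop$genotypes, fp("population.vcf"))
  readr::write_tsv(pop$popmap, fp("popmap.tsv"), progress = FALSE)
  truth <- list(variants = study$truth,
                te = study$expression$truth,
                freqs = pop$freqs,
                snv_sites = pop$snv_sites)
  jsonlite::write_json(truth, fp("truth.json"), digits = NA,
                       na = "null")
  invisible(outdir)
}
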