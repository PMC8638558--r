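PIPELINE_STAGES <- c("simulate", "reactivity", "fold", "te", "asymmetry",
                     "ribosnitch", "popgen", "report")

VALID_CONFIG_KEYS <- c("seed", "simulate", "thresholds")
VALID_THRESHOLD_KEYS <- c("alpha", "min_coverage", "min_positions",
                          "fold_window", "fold_step", "ribosnitch_window",
                          "min_effect", "decile", "reference_pop")

default_thresholds <- function() {
  list(alpha = 0.05, min_coverage = 50, min_positions = 20,
       fold_window = 300L, fold_step = 150L, ribosnitch_window = 50,
       min_effect = 0.1, decile = 0.1, reference_pop = "DW")
}

#' Validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent list) with keys
#' `seed` (required), `simulate` (arguments to [sim_config()] other than
#' the seed) and `thresholds`. Unknown keys raise an error listing the
#' valid ones; omitted thresholds take their documented defaults.
#'
#' @param config Path to a YAML file, or a list.
#' @return The validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), VALID_CONFIG_KEYS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s (valid keys: %s)",
                  paste(unknown, collapse = ", "),
                  paste(VALID_CONFIG_KEYS, collapse = ", ")))
  }
  if (is.null(config$seed)) abort("config: 'seed' is required")
  th <- config$thresholds %||% list()
  unknown <- setdiff(names(th), VALID_THRESHOLD_KEYS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown threshold key(s): %s (valid keys: %s)",
                  paste(unknown, collapse = ", "),
                  paste(VALID_THRESHOLD_KEYS, collapse = ", ")))
  }
  config$thresholds <- utils::modifyList(default_thresholds(), th)
  config$simulate <- config$simulate %||% list()
  config
}

stage_file <- function(outdir, name) file.path(outdir, name)

require_stage_input <- function(path, stage_needed) {
  if (!file.exists(path)) {
    abort(sprintf("missing upstream output '%s': run stage '%s' first",
                  basename(path), stage_needed))
  }
  path
}

#' Run the analysis pipeline end to end
#'
#' Stages run in dependency order on files under `outdir`:
#' `simulate` writes the synthetic inputs (FASTA, annotation, stop
#' counts, expression counts, VCF/popmap) under `outdir/inputs/`;
#' `reactivity`, `fold`, `te`, `asymmetry`, `ribosnitch` and `popgen`
#' each read their upstream TSVs and write their own; `report` collects
#' the summary JSON and a human-readable report. Partial reruns are
#' supported through `stages`; a missing upstream file raises an error
#' naming the stage that produces it. All outputs are deterministic under
#' a fixed config seed.
#'
#' @param config Path to a YAML config, or a list (see
#'   [validate_config()]).
#' @param outdir Output directory.
#' @param stages Subset of stages to run (dependency order enforced).
#' @return The summary list, invisibly (when `report` runs), otherwise
#'   `outdir`.
#' @export
run_pipeline <- function(config, outdir, stages = PIPELINE_STAGES) {
  config <- validate_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  hash <- rlang::hash(config)
  params <- list(config_hash = hash, seed = config$seed)
  indir <- file.path(outdir, "inputs")
  log_stage <- function(stage, ...) {
    inform(sprintf("[%s] %s", stage, sprintf(...)))
  }

  if ("simulate" %in% stages) {
    cfg <- do.call(sim_config, c(list(seed = config$seed),
                                 config$simulate))
    study <- simulate_study(cfg, fold_window = th$fold_window,
                            fold_step = th$fold_step)
    write_simulation(study, indir)
    log_stage("simulate", "%d pairs, %d variants, %d SNV sites",
              nrow(study$pairs), nrow(study$truth),
              nrow(study$population$snv_sites))
  }

  read_inputs <- function() {
    require_stage_input(file.path(indir, "transcripts.fa"), "simulate")
    seqs <- read_fasta(file.path(indir, "transcripts.fa"))
    ann <- read_annotation(file.path(indir, "annotation.tsv"))
    pairs <- read_tsv_commented(file.path(indir, "pairs.tsv"))
    list(transcripts = make_transcripts(seqs, ann, pairs), pairs = pairs)
  }

  if ("reactivity" %in% stages) {
    inp <- read_inputs()
    stops <- read_stop_counts(
      require_stage_input(file.path(indir, "stops.tsv"), "simulate"),
      inp$transcripts)
    react <- shape_reactivity(stops, min_coverage = th$min_coverage,
                              min_positions = th$min_positions)
    write_reactivity(react, stage_file(outdir, "reactivity.tsv"), params)
    log_stage("reactivity", "%d transcripts, %d/%d positions defined",
              dplyr::n_distinct(react$transcript_id),
              sum(!is.na(react$reactivity)), nrow(react))
  }

  if ("fold" %in% stages) {
    inp <- read_inputs()
    react <- read_reactivity(
      require_stage_input(stage_file(outdir, "reactivity.tsv"),
                          "reactivity"))
    folds <- fold_transcripts(inp$transcripts, react,
                              window = th$fold_window,
                              step = th$fold_step)
    write_tsv_commented(bpp_table(folds),
                        stage_file(outdir, "bpp.tsv"), params)
    write_dotbracket(
      tibble::tibble(
        transcript_id = names(folds),
        sequence = purrr::map_chr(folds, "sequence"),
        dotbracket = purrr::map_chr(folds, "dotbracket")),
      stage_file(outdir, "structures.db"))
    log_stage("fold", "%d transcripts folded", length(folds))
  }

  if ("te" %in% stages) {
    inp <- read_inputs()
    counts <- read_tsv_commented(
      require_stage_input(file.path(indir, "counts.tsv"), "simulate"))
    te <- translation_efficiency(counts, inp$transcripts)
    dte <- differential_te(inp$pairs, te, alpha = th$alpha)
    write_tsv_commented(
      dplyr::select(te, "transcript_id", "te", "n_reps"),
      stage_file(outdir, "te.tsv"), params)
    write_tsv_commented(tidy(dte), stage_file(outdir, "dte.tsv"), params)
    log_stage("te", "%d pairs tested, %d excluded", sum(!is.na(dte$p)),
              attr(dte, "excluded"))
  }

  if ("asymmetry" %in% stages) {
    inp <- read_inputs()
    bpp <- read_tsv_commented(
      require_stage_input(stage_file(outdir, "bpp.tsv"), "fold"))
    dte <- read_tsv_commented(
      require_stage_input(stage_file(outdir, "dte.tsv"), "te"))
    tests <- pairs_bpp_tests(inp$pairs, bpp, alpha = th$alpha,
                             min_positions = th$min_positions)
    mean_bpp <- bpp |>
      dplyr::summarise(mean_bpp = mean(.data$bpp, na.rm = TRUE),
                       .by = "transcript_id")
    deltas <- inp$pairs |>
      dplyr::left_join(dplyr::rename(mean_bpp, a_mb = "mean_bpp"),
                       by = c(a_id = "transcript_id")) |>
      dplyr::left_join(dplyr::rename(mean_bpp, b_mb = "mean_bpp"),
                       by = c(b_id = "transcript_id")) |>
      dplyr::left_join(dte[c("a_id", "b_id", "log2_te_ratio")],
                       by = c("a_id", "b_id")) |>
      dplyr::transmute(.data$a_id, .data$b_id,
                       dbpp = .data$a_mb - .data$b_mb,
                       dte = .data$log2_te_ratio)
    write_tsv_commented(
      dplyr::left_join(tests, deltas, by = c("a_id", "b_id")),
      stage_file(outdir, "asymmetry.tsv"), params)
    log_stage("asymmetry", "%d pairs tested", sum(!is.na(tests$p)))
  }

  if ("ribosnitch" %in% stages) {
    inp <- read_inputs()
    react <- read_reactivity(
      require_stage_input(stage_file(outdir, "reactivity.tsv"),
                          "reactivity"))
    bpp <- read_tsv_commented(
      require_stage_input(stage_file(outdir, "bpp.tsv"), "fold"))
    snv <- ribosnitch_pipeline(inp$pairs, inp$transcripts, react, bpp,
                               window = th$ribosnitch_window,
                               min_positions = th$min_positions,
                               alpha = th$alpha,
                               min_effect = th$min_effect)
    write_tsv_commented(snv$snvs, stage_file(outdir, "snv.tsv"), params)
    write_tsv_commented(snv$pair_stats,
                        stage_file(outdir, "pair_stats.tsv"), params)
    log_stage("ribosnitch", "%d SNVs, %d tested, %d riboSNitches",
              nrow(snv$snvs), sum(!is.na(snv$snvs$is_ribosnitch)),
              sum(snv$snvs$is_ribosnitch, na.rm = TRUE))
  }

  if ("popgen" %in% stages) {
    snv <- read_tsv_commented(
      require_stage_input(stage_file(outdir, "snv.tsv"), "ribosnitch"))
    pop <- read_vcf_population(
      require_stage_input(file.path(indir, "population.vcf"), "simulate"),
      require_stage_input(file.path(indir, "popmap.tsv"), "simulate"))
    fst_tbl <- fst_table(pop)
    snv$snv_id <- paste0(snv$a_id, ":", snv$pos_a + 1L)
    merged <- dplyr::inner_join(
      snv[!is.na(snv$is_ribosnitch),
          c("snv_id", "a_id", "allele_a", "region", "is_ribosnitch")],
      fst_tbl, by = "snv_id")
    cons <- conservation_ratios(
      dplyr::transmute(snv[!is.na(snv$is_ribosnitch), ],
                       transcript_id = .data$a_id,
                       snv_id = .data$snv_id, allele = .data$allele_a,
                       is_ribosnitch = .data$is_ribosnitch,
                       region = .data$region),
      pop, reference_pop = th$reference_pop)
    write_tsv_commented(merged, stage_file(outdir, "popgen.tsv"), params)
    write_tsv_commented(cons, stage_file(outdir, "conservation.tsv"),
                        params)
    log_stage("popgen", "%d SNVs with F_ST", nrow(merged))
  }

  if ("report" %in% stages) {
    summary <- pipeline_summary(outdir, config)
    jsonlite::write_json(summary, stage_file(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(make_report(summary), stage_file(outdir, "report.txt"))
    return(invisible(summary))
  }
  invisible(outdir)
}

# riboSNitch stage as a reusable function: align each pair, extract SNVs,
# run the paired window tests, and make calls across all pairs
#' Align pairs, extract variants, and call riboSNitches
#'
#' @param pairs Pair tibble (`a_id`, `b_id`).
#' @param transcripts Transcript table.
#' @param reactivity Reactivity tibble.
#' @param bpp BPP tibble (from [bpp_table()] or the pipeline TSV).
#' @param window,min_positions,alpha,min_effect,use_adjusted riboSNitch
#'   calling parameters (see [ribosnitch_tests()] and
#'   [ribosnitch_calls()]).
#' @return List with `snvs` (per-SNV calls incl. pair ids and regions)
#'   and `pair_stats` (per-pair `esdc`, `n_snv`, indel lengths,
#'   `snv_ratio`).
#' @export
ribosnitch_pipeline <- function(pairs, transcripts, reactivity, bpp,
                                window = 50, min_positions = 20,
                                alpha = 0.05, min_effect = 0.1,
                                use_adjusted = FALSE) {
  tr_by_id <- split(transcripts, transcripts$transcript_id)
  vec_by_id <- function(df, col) {
    out <- split(df, df$transcript_id)
    function(id, n) {
      v <- rep(NA_real_, n)
      d <- out[[id]]
      if (!is.null(d)) v[d$position + 1L] <- d[[col]]
      v
    }
  }
  get_react <- vec_by_id(reactivity, "reactivity")
  get_bpp <- vec_by_id(bpp, "bpp")
  res <- purrr::pmap(pairs[c("a_id", "b_id")], function(a_id, b_id) {
    ta <- tr_by_id[[a_id]]
    tb <- tr_by_id[[b_id]]
    aln <- align_pair(ta$sequence, tb$sequence)
    var <- extract_variants(aln, ta, tb)
    na <- ta$length
    nb <- tb$length
    ra <- get_react(a_id, na)
    rb <- get_react(b_id, nb)
    ba <- get_bpp(a_id, na)
    bb <- get_bpp(b_id, nb)
    tested <- ribosnitch_tests(var$snvs, aln, ba, bb, ra, rb,
                               window = window,
                               min_positions = min_positions)
    e <- esdc(ra, rb, aln)
    list(
      snvs = dplyr::mutate(tested, a_id = a_id, b_id = b_id,
                           .before = 1),
      pair_stats = tibble::tibble(
        a_id = a_id, b_id = b_id, esdc = as.numeric(e),
        esdc_L = attr(e, "L"), n_snv = var$counts$snv,
        snv_ratio = var$counts$snv_ratio,
        indel_len_a = sum(var$indels$length[
          var$indels$which_sequence == "a"]),
        indel_len_b = sum(var$indels$length[
          var$indels$which_sequence == "b"])))
  })
  snvs <- ribosnitch_calls(purrr::map_dfr(res, "snvs"), alpha = alpha,
                           min_effect = min_effect,
                           use_adjusted = use_adjusted)
  list(snvs = snvs, pair_stats = purrr::map_dfr(res, "pair_stats"))
}

# collect headline numbers from the stage outputs
pipeline_summary <- function(outdir, config) {
  g <- function(name) read_tsv_commented(
    require_stage_input(stage_file(outdir, name),
                        stage_for_output(name)))
  dte <- g("dte.tsv")
  asym <- g("asymmetry.tsv")
  snv <- g("snv.tsv")
  popg <- g("popgen.tsv")
  if (nrow(popg) > 0) popg$is_ribosnitch <- as.logical(popg$is_ribosnitch)
  tested <- dte[!is.na(dte$p_adj), ]
  asum <- asymmetry_summary(asym)
  ratios <- ribosnitch_region_ratios(snv)
  dc <- delta_correlation(asym[!is.na(asym$dbpp) & !is.na(asym$dte), ])
  fst_contrast <- if (nrow(popg) > 0 &&
                      sum(popg$is_ribosnitch, na.rm = TRUE) >= 3 &&
                      sum(!popg$is_ribosnitch, na.rm = TRUE) >= 3) {
    class_contrast(popg$fst[popg$is_ribosnitch],
                   popg$fst[!popg$is_ribosnitch], test = "wilcoxon")
  } else {
    tibble::tibble(test = "wilcoxon", p = NA_real_,
                   mean_ribosnitch = NA_real_, mean_non = NA_real_)
  }
  list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_pairs = nrow(dte),
    te = list(n_tested = nrow(tested),
              significant_fraction = mean(
                tested$direction %in% c("A_higher", "B_higher"))),
    bpp_asymmetry = as.list(asum),
    snv = list(n_snv = nrow(snv),
               n_tested = sum(!is.na(snv$is_ribosnitch)),
               n_ribosnitch = sum(snv$is_ribosnitch, na.rm = TRUE),
               ribosnitch_ratio =
                 ratios$ratio[ratios$region == "all"],
               region_ratios = as.list(setNames(ratios$ratio,
                                                ratios$region))),
    delta_correlation = as.list(dc),
    fst = list(mean_ribosnitch = fst_contrast$mean_ribosnitch,
               mean_non_ribosnitch = fst_contrast$mean_non,
               p = fst_contrast$p))
}

stage_for_output <- function(name) {
  switch(name, "dte.tsv" = "te", "asymmetry.tsv" = "asymmetry",
         "snv.tsv" = "ribosnitch", "popgen.tsv" = "popgen", "unknown")
}

#' Render a pipeline summary as human-readable text
#'
#' @param summary The list written to `summary.json` by [run_pipeline()].
#' @return A character vector of report lines.
#' @export
make_report <- function(summary) {
  pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f%%", 100 * x))
  b <- summary$bpp_asymmetry
  c(sprintf("ribostruct pipeline report (seed %s, config %s)",
            summary$seed, summary$config_hash),
    "",
    sprintf("Homoeolog pairs analyzed: %d", summary$n_pairs),
    sprintf("TE asymmetry: %s of %d tested pairs significant",
            pct(summary$te$significant_fraction), summary$te$n_tested),
    sprintf(paste0("BPP asymmetry: A higher %s, B higher %s, NSD %s ",
                   "(of %d tested; divergent %s)"),
            pct(b$frac_A_higher), pct(b$frac_B_higher), pct(b$frac_NSD),
            b$n_tested, pct(b$frac_divergent)),
    sprintf("SNVs: %d total, %d structure-tested, %d riboSNitches (%s)",
            summary$snv$n_snv, summary$snv$n_tested,
            summary$snv$n_ribosnitch, pct(summary$snv$ribosnitch_ratio)),
    sprintf("|dBPP| vs |dTE| correlation: r = %s (p = %s, n = %s)",
            fmt_num(summary$delta_correlation$r),
            fmt_num(summary$delta_correlation$p),
            summary$delta_correlation$n),
    sprintf("F_ST: riboSNitch mean %s vs non-riboSNitch %s (p = %s)",
            fmt_num(summary$fst$mean_ribosnitch),
            fmt_num(summary$fst$mean_non_ribosnitch),
            fmt_num(summary$fst$p)))
}

fmt_num <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "NA" else
    format(signif(x, 3))
}
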