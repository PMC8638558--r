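#' Translation efficiency from RNA-seq and polysome-seq counts
#'
#' Counts are scaled per replicate to a per-million abundance; with
#' `method = "tpm"` (default) they are first length-normalized. TE per
#' replicate is polysome abundance over RNA abundance; the point estimate
#' is the mean of replicate TEs and is missing whenever RNA abundance is
#' zero in any replicate.
#'
#' @param counts Tibble with columns `transcript_id`, `replicate`,
#'   `rna_count`, `polysome_count`.
#' @param transcripts Transcript table providing `length` (required for
#'   `method = "tpm"`).
#' @param method `"tpm"` (length-normalized per-million) or `"cpm"`.
#' @return Tibble with one row per transcript: `transcript_id`, `te`
#'   (`NA` when undefined), `n_reps`, and list-column `te_reps` of
#'   per-replicate TEs.
#' @export
translation_efficiency <- function(counts, transcripts = NULL,
                                   method = c("tpm", "cpm")) {
  method <- match.arg(method)
  df <- counts
  if (method == "tpm") {
    if (is.null(transcripts)) {
      abort("translation_efficiency: 'transcripts' required for method 'tpm'")
    }
    df <- dplyr::inner_join(
      df, dplyr::select(transcripts, "transcript_id", "length"),
      by = "transcript_id")
    df$rna_rate <- df$rna_count / df$length
    df$poly_rate <- df$polysome_count / df$length
  } else {
    df$rna_rate <- df$rna_count
    df$poly_rate <- df$polysome_count
  }
  df <- df |>
    dplyr::mutate(
      rna_abund = .data$rna_rate / sum(.data$rna_rate) * 1e6,
      poly_abund = .data$poly_rate / sum(.data$poly_rate) * 1e6,
      .by = "replicate") |>
    dplyr::mutate(te_rep = dplyr::if_else(.data$rna_abund > 0,
                                          .data$poly_abund /
                                            .data$rna_abund, NA_real_))
  df |>
    dplyr::summarise(
      te = if (anyNA(.data$te_rep)) NA_real_ else mean(.data$te_rep),
      n_reps = dplyr::n(),
      te_reps = list(.data$te_rep),
      .by = "transcript_id")
}

#' GC content of a sequence
#'
#' @param sequence RNA/DNA string(s); vectorized.
#' @return Fraction of G+C among A/C/G/U(T) bases.
#' @export
gc_content <- function(sequence) {
  s <- as_rna(sequence)
  gc <- stringr::str_count(s, "[GC]")
  acgu <- stringr::str_count(s, "[ACGU]")
  ifelse(acgu > 0, gc / acgu, NA_real_)
}

# codon -> amino acid for RNA codons, from the standard genetic code
rna_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc), gsub("T", "U", names(gc), fixed = TRUE))
}

split_codons <- function(cds) {
  cds <- as_rna(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) abort("CDS length must be divisible by 3")
  substring(cds, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Relative adaptiveness weights from codon usage counts
#'
#' For each codon, the adaptiveness is its count divided by the count of
#' the most frequent synonymous codon (stop codons excluded).
#'
#' @param usage Tibble with columns `codon` (RNA or DNA spelling) and
#'   `count` (or `f`).
#' @return Tibble `codon`, `aa`, `count`, `r`.
#' @export
codon_adaptiveness <- function(usage) {
  code <- rna_genetic_code()
  cnt_col <- if ("count" %in% names(usage)) "count" else "f"
  df <- tibble::tibble(codon = gsub("T", "U", toupper(usage$codon),
                                    fixed = TRUE),
                       count = as.numeric(usage[[cnt_col]]))
  unknown <- setdiff(df$codon, names(code))
  if (length(unknown) > 0) {
    abort(sprintf("unknown codon(s) in usage table: %s",
                  paste(unknown, collapse = ", ")))
  }
  df$aa <- code[df$codon]
  df <- df[df$aa != "*", ]
  dplyr::mutate(df, r = .data$count / max(.data$count), .by = "aa")
}

# geometric mean of per-codon weights, computed in log-space;
# codons containing N are skipped with n decremented; stop codons excluded
codon_geomean <- function(cds, weights, what = "weight") {
  code <- rna_genetic_code()
  codons <- split_codons(cds)
  # trailing stop codon and internal stops excluded
  codons <- codons[is.na(code[codons]) | code[codons] != "*"]
  has_n <- grepl("N", codons, fixed = TRUE)
  codons <- codons[!has_n]
  if (length(codons) == 0) abort("no scorable codons in CDS")
  w <- weights[codons]
  if (anyNA(w)) {
    abort(sprintf("codon(s) absent from %s table: %s", what,
                  paste(unique(codons[is.na(w)]), collapse = ", ")))
  }
  exp(mean(log(w)))
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `r` of each CDS codon
#' (stop codon excluded, computed in log-space).
#'
#' @param cds In-frame CDS sequence (length divisible by 3).
#' @param usage Codon usage table (see [codon_adaptiveness()]), or a
#'   precomputed tibble with columns `codon` and `r`.
#' @return CAI in `(0, 1]`.
#' @export
cai <- function(cds, usage) {
  adapt <- if ("r" %in% names(usage)) {
    tibble::tibble(codon = gsub("T", "U", toupper(usage$codon), fixed = TRUE),
                   r = usage$r)
  } else {
    codon_adaptiveness(usage)
  }
  codon_geomean(cds, setNames(adapt$r, adapt$codon), "codon-usage")
}

#' tRNA adaptation index
#'
#' Geometric mean of per-codon tRNA adaptiveness weights `w` (normalized so
#' `max(w) = 1`), stop codon excluded.
#'
#' @param cds In-frame CDS sequence.
#' @param weights Tibble with columns `codon`, `w`.
#' @return tAI in `(0, 1]`.
#' @export
tai <- function(cds, weights) {
  w <- weights$w / max(weights$w)
  codon_geomean(cds, setNames(w, gsub("T", "U", toupper(weights$codon),
                                      fixed = TRUE)), "tAI-weight")
}

#' Differential translation efficiency between homoeologs
#'
#' Per pair, a two-sample Student t test on log2 per-replicate TEs of the
#' A vs B transcript, Benjamini-Hochberg corrected across pairs. Pairs
#' with fewer than two defined replicate TEs on either side are excluded
#' (reported via attribute `excluded`).
#'
#' @param pairs Tibble with columns `a_id`, `b_id`.
#' @param te Output of [translation_efficiency()].
#' @param alpha Significance level after BH correction.
#' @return A tibble of class `ribo_dte` with columns `a_id`, `b_id`,
#'   `te_a`, `te_b`, `log2_te_ratio`, `p`, `p_adj`, `direction`
#'   (`A_higher` / `B_higher` / `NSD`).
#' @export
differential_te <- function(pairs, te, alpha = 0.05) {
  lookup <- setNames(te$te_reps, te$transcript_id)
  point <- setNames(te$te, te$transcript_id)
  res <- purrr::pmap_dfr(pairs[c("a_id", "b_id")], function(a_id, b_id) {
    ra <- lookup[[a_id]]
    rb <- lookup[[b_id]]
    ok <- !is.null(ra) && !is.null(rb) && sum(!is.na(ra) & ra > 0) >= 2 &&
      sum(!is.na(rb) & rb > 0) >= 2
    if (!ok) {
      return(tibble::tibble(a_id = a_id, b_id = b_id, te_a = NA_real_,
                            te_b = NA_real_, log2_te_ratio = NA_real_,
                            p = NA_real_))
    }
    la <- log2(ra[!is.na(ra) & ra > 0])
    lb <- log2(rb[!is.na(rb) & rb > 0])
    p <- if (sd(la) == 0 && sd(lb) == 0) {
      if (isTRUE(all.equal(mean(la), mean(lb)))) 1.0 else 0.0
    } else {
      t.test(la, lb)$p.value
    }
    tibble::tibble(a_id = a_id, b_id = b_id,
                   te_a = unname(point[a_id]), te_b = unname(point[b_id]),
                   log2_te_ratio = mean(la) - mean(lb), p = p)
  })
  tested <- !is.na(res$p)
  res$p_adj <- NA_real_
  res$p_adj[tested] <- p.adjust(res$p[tested], method = "BH")
  res$direction <- dplyr::case_when(
    is.na(res$p_adj) ~ NA_character_,
    res$p_adj >= alpha ~ "NSD",
    res$log2_te_ratio > 0 ~ "A_higher",
    TRUE ~ "B_higher")
  attr(res, "excluded") <- sum(!tested)
  attr(res, "alpha") <- alpha
  class(res) <- c("ribo_dte", class(res))
  res
}

#' @rdname tidy-ribostruct
#' @export
tidy.ribo_dte <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy-ribostruct
#' @export
glance.ribo_dte <- function(x, ...) {
  tested <- !is.na(x$p_adj)
  tibble::tibble(
    n_pairs = nrow(x), n_tested = sum(tested),
    n_significant = sum(x$direction %in% c("A_higher", "B_higher")),
    significant_fraction = mean(
      x$direction[tested] %in% c("A_higher", "B_higher")),
    alpha = attr(x, "alpha"))
}

#' Correlations between log2 TE and covariates
#'
#' Pearson correlation of `log2(te)` against each covariate column, on
#' pairwise-complete observations.
#'
#' @param df Tibble containing a `te` column and the covariates.
#' @param covariates Character vector of covariate column names.
#' @return Tibble `covariate`, `r`, `p`, `n`.
#' @export
te_covariate_correlations <- function(df, covariates) {
  lte <- log2(df$te)
  purrr::map_dfr(covariates, function(cv) {
    x <- df[[cv]]
    ok <- is.finite(lte) & is.finite(x)
    if (sum(ok) < 3) {
      return(tibble::tibble(covariate = cv, r = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    ct <- cor.test(lte[ok], x[ok], method = "pearson")
    tibble::tibble(covariate = cv, r = unname(ct$estimate), p = ct$p.value,
                   n = sum(ok))
  })
}

# rescale one region's values onto a fixed number of bins
rescale_region <- function(x, nbins) {
  if (length(x) == 0 || all(is.na(x))) return(rep(NA_real_, nbins))
  if (length(x) == 1) return(rep(x, nbins))
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = nbins), rule = 2)$y
}

#' Metagene reactivity profiles for TE deciles
#'
#' Transcripts are anchored at their start and stop codons; each region
#' (5'UTR / CDS / 3'UTR) is linearly rescaled to a fixed number of bins
#' and per-bin means are taken over the transcripts in the top and bottom
#' TE decile.
#'
#' @param reactivity Reactivity tibble (`transcript_id`, `position`,
#'   `reactivity`).
#' @param transcripts Transcript table with CDS bounds.
#' @param te Output of [translation_efficiency()].
#' @param decile Fraction of transcripts in each TE group.
#' @param bins Integer vector of bin counts for 5'UTR, CDS, 3'UTR.
#' @return Tibble `group` (`high_te` / `low_te`), `bin`, `region`,
#'   `reactivity`, `n_transcripts`.
#' @export
metagene_profile <- function(reactivity, transcripts, te, decile = 0.10,
                             bins = c(50L, 100L, 50L)) {
  te_ok <- te[!is.na(te$te), ]
  te_ok <- te_ok[order(te_ok$te), ]
  k <- max(1L, floor(nrow(te_ok) * decile))
  groups <- list(low_te = head(te_ok$transcript_id, k),
                 high_te = tail(te_ok$transcript_id, k))
  react_by_id <- split(reactivity, reactivity$transcript_id)
  region_names <- c("utr5", "cds", "utr3")
  purrr::imap_dfr(groups, function(ids, gname) {
    prof <- purrr::map(ids, function(id) {
      tr <- transcripts[transcripts$transcript_id == id, ]
      rdf <- react_by_id[[id]]
      if (nrow(tr) != 1 || is.null(rdf) || is.na(tr$cds_start)) return(NULL)
      rv <- rep(NA_real_, tr$length)
      rv[rdf$position + 1L] <- rdf$reactivity
      c(rescale_region(rv[seq_len(tr$cds_start)], bins[1]),
        rescale_region(rv[(tr$cds_start + 1L):tr$cds_end], bins[2]),
        rescale_region(rv[seq.int(tr$cds_end + 1L, length.out =
                                    tr$length - tr$cds_end)], bins[3]))
    })
    prof <- prof[!purrr::map_lgl(prof, is.null)]
    m <- colMeans(do.call(rbind, prof), na.rm = TRUE)
    tibble::tibble(group = gname, bin = seq_along(m),
                   region = rep(region_names, times = bins),
                   reactivity = m, n_transcripts = length(prof))
  })
}

#' Three-nucleotide periodicity score
#'
#' Magnitude of the discrete-Fourier component at period 3, normalized by
#' the total signal, on a CDS-restricted mean reactivity vector. The
#' vector is truncated to a multiple of 3; missing values are dropped in
#' frame-consistent triples. Returns a score in `[0, 1]`: 0 for a flat
#' profile, 1 for a pure `(x, 0, 0)` repeat.
#'
#' @param x Numeric vector (CDS reactivity profile), length >= 30.
#' @return Periodicity score.
#' @export
periodicity_3nt <- function(x) {
  n0 <- length(x) - length(x) %% 3
  if (n0 < 30) abort("periodicity_3nt: profile shorter than 30 positions")
  x <- x[seq_len(n0)]
  keep <- matrix(!is.na(x), nrow = 3)
  triple_ok <- rep(apply(keep, 2, all), each = 3)
  x <- x[triple_ok]
  n <- length(x)
  if (n < 30) abort("periodicity_3nt: fewer than 30 defined positions")
  total <- sum(x)
  if (total <= 0) return(0)
  comp <- sum(x * exp(-2i * pi * (seq_len(n) - 1) / 3))
  min(1, Mod(comp) / total)
}
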