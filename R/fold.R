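#' Folding energy model
#'
#' Parameters of the simplified pair-wise energy model used by the folding
#' engine: one stacking-free energy per pair type, a minimum hairpin loop,
#' the Boltzmann temperature factor `kT`, and the SHAPE pseudo-energy slope
#' and intercept (Deigan form, `m * ln(reactivity + 1) + b` per paired
#' nucleotide).
#'
#' @param eGC,eAU,eGU Pair energies (must be <= 0).
#' @param min_hairpin Minimum number of unpaired nucleotides in a hairpin
#'   loop (>= 3).
#' @param kT Boltzmann factor (> 0); a free scale parameter, not a physical
#'   temperature.
#' @param shape_m,shape_b Pseudo-energy slope/intercept.
#' @return A list of class `ribo_energy_model`.
#' @export
energy_model <- function(eGC = -3, eAU = -2, eGU = -1, min_hairpin = 3L,
                         kT = 0.6, shape_m = 1.8, shape_b = -0.6) {
  if (any(c(eGC, eAU, eGU) > 0)) abort("pair energies must be <= 0")
  if (min_hairpin < 3) abort("min_hairpin must be >= 3")
  if (kT <= 0) abort("kT must be > 0")
  structure(list(eGC = eGC, eAU = eAU, eGU = eGU,
                 min_hairpin = as.integer(min_hairpin), kT = kT,
                 shape_m = shape_m, shape_b = shape_b),
            class = "ribo_energy_model")
}

#' SHAPE pseudo-energy term
#'
#' `m * ln(reactivity + 1) + b` per paired nucleotide; missing reactivity
#' contributes zero (no constraint).
#'
#' @param reactivity Numeric vector (>= 0 or `NA`).
#' @param model An [energy_model()].
#' @return Numeric vector of per-nucleotide energies.
#' @export
shape_pseudo_energy <- function(reactivity, model = energy_model()) {
  out <- model$shape_m * log(reactivity + 1) + model$shape_b
  out[is.na(reactivity)] <- 0
  out
}

#' Fold one sequence (single window)
#'
#' Computes the partition function over all pseudoknot-free structures with
#' pairs in \{GC, AU, GU\} and hairpin loops of at least `min_hairpin`
#' unpaired nucleotides, giving the per-nucleotide base-pairing probability
#' (probability of being paired to any partner) by inside-outside dynamic
#' programming, plus the minimum-energy structure via a deterministic
#' traceback (ties prefer leaving a nucleotide unpaired, then the closer
#' partner).
#'
#' @param sequence RNA string over ACGUN (`N` never pairs). DNA `T` is
#'   accepted and converted.
#' @param model An [energy_model()].
#' @param reactivity Optional per-nucleotide SHAPE reactivities (same
#'   length); when supplied, pseudo-energies are added for each paired
#'   nucleotide. `NULL` gives the in-silico fold.
#' @param want_pmat Keep the full pair-probability matrix?
#' @return An object of class `ribo_fold`: a list with `transcript_id`,
#'   `sequence`, `n`, `mfe`, `dotbracket`, `pairs` (0-based tibble),
#'   `bpp`, `logZ`, and optionally `pmat`.
#' @export
#' @examples
#' f <- fold_rna("GGGAAACCC")
#' f$dotbracket  # "(((...)))"
fold_rna <- function(sequence, model = energy_model(), reactivity = NULL,
                     want_pmat = FALSE) {
  sequence <- as_rna(sequence)
  check_rna_alphabet(sequence)
  n <- nchar(sequence)
  pseudo <- if (is.null(reactivity)) rep(0, n) else {
    if (length(reactivity) != n) {
      abort("reactivity length must match sequence length")
    }
    shape_pseudo_energy(reactivity, model)
  }
  res <- .fold_engine_cpp(encode_rna(sequence), pseudo, model$eGC,
                          model$eAU, model$eGU, model$min_hairpin, model$kT,
                          TRUE, want_pmat)
  partner <- res$partner
  paired <- which(partner > seq_len(n))
  pairs <- tibble::tibble(i = paired - 1L, j = partner[paired] - 1L)
  structure(list(transcript_id = NA_character_, sequence = sequence, n = n,
                 mfe = res$mfe, dotbracket = pairs_to_dotbracket(pairs, n),
                 pairs = pairs, bpp = res$bpp, logZ = res$logZ,
                 pmat = res$pmat),
            class = "ribo_fold")
}

#' @export
#' @method print ribo_fold
#' @keywords internal
print.ribo_fold <- function(x, ...) {
  cat(sprintf("<ribo_fold> %s  n=%d  MFE=%.3f  mean BPP=%.3f\n",
              x$transcript_id %||% "", x$n, x$mfe, mean(x$bpp)))
  invisible(x)
}

#' Fold a transcript with sliding windows
#'
#' Sequences longer than `window` are folded in sliding windows of `window`
#' nucleotides advanced by `step`; per-nucleotide BPP is averaged over all
#' covering windows. The reported minimum-energy structure is assembled
#' from non-overlapping `window`-sized blocks (local structure only).
#'
#' @inheritParams fold_rna
#' @param window Window size in nucleotides.
#' @param step Step between window starts.
#' @return A `ribo_fold` object (no `pmat` for windowed folds).
#' @export
fold_transcript <- function(sequence, model = energy_model(),
                            reactivity = NULL, window = 300L, step = 150L) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  if (n <= window) {
    return(fold_rna(sequence, model, reactivity))
  }
  starts <- seq(1L, n - window + 1L, by = step)
  if (tail(starts, 1) + window - 1L < n) {
    starts <- c(starts, n - window + 1L)
  }
  bpp_sum <- rep(0, n)
  bpp_cnt <- rep(0L, n)
  for (s in starts) {
    span <- s:(s + window - 1L)
    f <- fold_rna(substr(sequence, s, s + window - 1L), model,
                  if (is.null(reactivity)) NULL else reactivity[span])
    bpp_sum[span] <- bpp_sum[span] + f$bpp
    bpp_cnt[span] <- bpp_cnt[span] + 1L
  }
  # MFE dot-bracket from non-overlapping blocks
  blocks <- seq(1L, n, by = window)
  pairs <- purrr::map_dfr(blocks, function(s) {
    e <- min(s + window - 1L, n)
    f <- fold_rna(substr(sequence, s, e), model,
                  if (is.null(reactivity)) NULL else reactivity[s:e])
    dplyr::mutate(f$pairs, i = .data$i + s - 1L, j = .data$j + s - 1L)
  })
  structure(list(transcript_id = NA_character_, sequence = sequence, n = n,
                 mfe = NA_real_, dotbracket = pairs_to_dotbracket(pairs, n),
                 pairs = pairs, bpp = bpp_sum / bpp_cnt, logZ = NA_real_,
                 pmat = NULL),
            class = "ribo_fold")
}

#' Fold every transcript in a table
#'
#' @param transcripts Transcript tibble (see [make_transcripts()]).
#' @param reactivity Optional reactivity tibble (`transcript_id`,
#'   `position`, `reactivity`).
#' @inheritParams fold_transcript
#' @return A named list of `ribo_fold` objects, one per transcript.
#' @export
fold_transcripts <- function(transcripts, reactivity = NULL,
                             model = energy_model(), window = 300L,
                             step = 150L) {
  react_by_id <- if (is.null(reactivity)) NULL else
    split(reactivity, reactivity$transcript_id)
  out <- purrr::map(seq_len(nrow(transcripts)), function(k) {
    id <- transcripts$transcript_id[k]
    rv <- NULL
    if (!is.null(react_by_id) && !is.null(react_by_id[[id]])) {
      rdf <- react_by_id[[id]]
      rv <- rep(NA_real_, transcripts$length[k])
      rv[rdf$position + 1L] <- rdf$reactivity
    }
    f <- fold_transcript(transcripts$sequence[k], model, rv, window, step)
    f$transcript_id <- id
    f
  })
  setNames(out, transcripts$transcript_id)
}

#' Per-nucleotide BPP table from folded transcripts
#'
#' @param folds A list of `ribo_fold` objects (see [fold_transcripts()]).
#' @return Tibble with columns `transcript_id`, `position` (0-based),
#'   `bpp`.
#' @export
bpp_table <- function(folds) {
  purrr::map_dfr(folds, function(f)
    tibble::tibble(transcript_id = f$transcript_id,
                   position = seq_len(f$n) - 1L, bpp = f$bpp))
}

#' @rdname tidy-ribostruct
#' @export
tidy.ribo_fold <- function(x, ...) {
  tibble::tibble(transcript_id = x$transcript_id,
                 position = seq_len(x$n) - 1L,
                 base = seq_chars(x$sequence),
                 bpp = x$bpp,
                 mfe_paired = seq_chars(x$dotbracket) != ".")
}

#' @rdname tidy-ribostruct
#' @export
glance.ribo_fold <- function(x, ...) {
  tibble::tibble(transcript_id = x$transcript_id, n = x$n, mfe = x$mfe,
                 n_pairs = nrow(x$pairs), mean_bpp = mean(x$bpp),
                 logZ = x$logZ)
}
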