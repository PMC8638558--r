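# Independent oracles used to validate the dynamic-programming engines.
# Both deliberately avoid the implementation's algorithms: folding is
# checked against explicit enumeration of every nested structure, and
# alignment against enumeration of every monotone matching.

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
}

# all nested pair sets over s[i..j] (1-based), as k x 2 matrices
oracle_enum_structures <- function(s, min_hairpin = 3) {
  memo <- new.env(parent = emptyenv())
  empty <- list(matrix(integer(0), ncol = 2))
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1) return(empty)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)  # i unpaired
    for (k in (i + min_hairpin + 1):j) {
      if (oracle_can_pair(s[i], s[k])) {
        inner <- rec(i + 1, k - 1)
        after <- rec(k + 1, j)
        for (x in inner) {
          for (y in after) {
            out <- c(out, list(rbind(c(i, k), x, y)))
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, length(s))
}

oracle_pair_energy <- function(a, b, model) {
  key <- paste0(sort(c(a, b)), collapse = "")
  switch(key, "CG" = model$eGC, "AU" = model$eAU, "GU" = model$eGU,
         stop("not pairable"))
}

# exhaustive partition function, per-nucleotide bpp, and MFE
oracle_fold <- function(sequence, model = energy_model(),
                        reactivity = NULL) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  pseudo <- if (is.null(reactivity)) rep(0, n) else {
    p <- model$shape_m * log(reactivity + 1) + model$shape_b
    p[is.na(reactivity)] <- 0
    p
  }
  structs <- oracle_enum_structures(s, model$min_hairpin)
  energies <- vapply(structs, function(ps) {
    if (nrow(ps) == 0) return(0)
    sum(vapply(seq_len(nrow(ps)), function(r)
      oracle_pair_energy(s[ps[r, 1]], s[ps[r, 2]], model), numeric(1))) +
      sum(pseudo[as.vector(ps)])
  }, numeric(1))
  w <- exp(-energies / model$kT)
  Z <- sum(w)
  bpp <- numeric(n)
  for (k in seq_along(structs)) {
    ps <- structs[[k]]
    if (nrow(ps) > 0) bpp[as.vector(ps)] <- bpp[as.vector(ps)] + w[k]
  }
  list(Z = Z, logZ = log(Z), bpp = bpp / Z, mfe = min(energies),
       n_structures = length(structs))
}

# best global affine-gap alignment score by enumerating monotone matchings;
# unmatched stretches between consecutive matches are grouped into at most
# one gap run per sequence (optimal since opening costs are negative)
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -4, gap_ext = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  gap_cost <- function(da, db) {
    gap_ext * (da + db) + gap_open * ((da > 0) + (db > 0))
  }
  seg_score <- function(ia, ib) {  # ia, ib: matched indices (equal length)
    k <- length(ia)
    sc <- if (k > 0) {
      sum(ifelse(ca[ia] == cb[ib], match, mismatch))
    } else 0
    bounds_a <- c(0, ia, n + 1)
    bounds_b <- c(0, ib, m + 1)
    for (t in seq_len(k + 1)) {
      sc <- sc + gap_cost(bounds_a[t + 1] - bounds_a[t] - 1,
                          bounds_b[t + 1] - bounds_b[t] - 1)
    }
    sc
  }
  best <- seg_score(integer(0), integer(0))
  for (k in seq_len(min(n, m))) {
    subs_a <- utils::combn(n, k, simplify = FALSE)
    subs_b <- utils::combn(m, k, simplify = FALSE)
    for (ia in subs_a) {
      for (ib in subs_b) {
        best <- max(best, seg_score(ia, ib))
      }
    }
  }
  best
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
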