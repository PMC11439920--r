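# Cross-validated intersubject correlation of MCCA components, with a
# circular-shift bootstrap null. The recording is split into k contiguous
# folds; the MCCA model is fitted on the training folds and applied to the
# held-out fold; pairwise Pearson correlations of each canonical component
# across subjects are Fisher-z pooled; the component with the strongest
# pooled test-set correlation is selected per fold; folds are combined by the
# mean of absolute values, for the observed statistic and for every null
# draw alike.

#' Contiguous cross-validation fold plan
#'
#' Partitions `[1, t]` into `k` contiguous non-overlapping ranges whose
#' lengths differ by at most one sample (the remainder goes to the earliest
#' folds).
#'
#' @param t_len number of time samples.
#' @param k fold count (default 3).
#' @return integer matrix with columns `start`, `end` (half-open, 1-based),
#'   one row per fold.
#' @export
make_folds <- function(t_len, k = 3L) {
  if (t_len < k) stop("make_folds: need at least k samples (t = ", t_len, ", k = ", k, ")")
  t_len <- as.integer(t_len); k <- as.integer(k)
  sizes <- rep(t_len %/% k, k)
  r <- t_len %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ends <- cumsum(sizes)
  cbind(start = c(1L, utils::head(ends, -1L) + 1L), end = ends + 1L)
}

# pooled Fisher-z of the off-diagonal of a correlation matrix; NA entries
# (constant variates) are excluded and counted
pool_offdiag <- function(R) {
  r <- R[upper.tri(R)]
  bad <- sum(is.na(r))
  if (bad == length(r)) return(list(z = NA_real_, dropped = bad))
  list(z = mean(atanh(clip_r(r[!is.na(r)]))), dropped = bad)
}

#' Cross-validated MCCA intersubject correlation for one design cell
#'
#' For each fold: fits the MAXVAR model on the training samples (after an
#' optional per-subject PCA fitted on the training portion only), projects
#' the held-out samples, computes pairwise Pearson correlations of every
#' canonical component across subjects, pools them with the Fisher
#' z-transform, and selects the component with the strongest pooled test-set
#' correlation (ties broken by lowest index). The per-fold values are
#' combined by the mean of absolute values.
#'
#' @param recordings named list of equal-length `channels x time` matrices,
#'   one per subject (>= 2).
#' @param k fold count (default 3).
#' @param pca_d optional per-subject PCA dimension fitted on training data.
#' @param n_components number of MCCA components (default: all available).
#' @param cell optional named list/vector of cell labels carried through to
#'   the result.
#' @return object of class `alignment_result`: per-fold selected component,
#'   `M x M` pairwise correlation matrix, pooled `zbar`, pooled z per
#'   component, held-out variates; plus `combined` (mean absolute fold
#'   value), `r_equivalent = tanh(combined)`, per-subject ISC, and the count
#'   of excluded (constant-variate) pairs.
#' @export
crossval_alignment <- function(recordings, k = 3L, pca_d = NULL,
                               n_components = NULL, cell = NULL) {
  M <- length(recordings)
  if (M < 2L) stop("crossval_alignment: need at least 2 subjects")
  t_len <- unique(vapply(recordings, ncol, integer(1)))
  if (length(t_len) != 1L) {
    stop("crossval_alignment: recordings must have equal length")
  }
  subj <- names(recordings)
  if (is.null(subj)) subj <- names(recordings) <- sprintf("s%02d", seq_len(M))
  folds <- make_folds(t_len, k)
  dropped_total <- 0L

  fold_out <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds[f, "start"]:(folds[f, "end"] - 1L)
    tr <- setdiff(seq_len(t_len), te)
    Ztr <- vector("list", M); Zte <- vector("list", M)
    for (m in seq_len(M)) {
      if (!is.null(pca_d)) {
        red <- fit_pca(recordings[[m]][, tr, drop = FALSE], pca_d)
        Ztr[[m]] <- apply_pca(red, recordings[[m]][, tr, drop = FALSE])
        Zte[[m]] <- apply_pca(red, recordings[[m]][, te, drop = FALSE])
      } else {
        Ztr[[m]] <- recordings[[m]][, tr, drop = FALSE]
        Zte[[m]] <- recordings[[m]][, te, drop = FALSE]
      }
    }
    names(Ztr) <- names(Zte) <- subj
    model <- fit_maxvar(Ztr, n_components)
    K <- model$n_components
    variates <- lapply(subj, function(s) project(model, Zte[[s]], s))
    names(variates) <- subj

    zbar_all <- numeric(K)
    Rs <- vector("list", K)
    for (d in seq_len(K)) {
      V <- t(vapply(variates, function(y) y[d, ], numeric(length(te))))
      R <- suppressWarnings(stats::cor(t(V)))
      pz <- pool_offdiag(R)
      dropped_total <- dropped_total + pz$dropped
      zbar_all[d] <- if (is.na(pz$z)) 0 else pz$z
      Rs[[d]] <- R
    }
    sel <- which.max(abs(zbar_all))
    fold_out[[f]] <- list(
      component = sel, zbar = zbar_all[sel], zbar_all = zbar_all,
      cor_matrix = Rs[[sel]], variates = variates,
      test_range = c(folds[f, "start"], folds[f, "end"]))
  }
  if (dropped_total > 0L) {
    message("crossval_alignment: excluded ", dropped_total,
            " constant-variate pair correlation(s)")
  }
  combined <- mean(abs(vapply(fold_out, `[[`, numeric(1), "zbar")))
  res <- structure(list(
    folds = fold_out, combined = combined,
    r_equivalent = tanh(combined),
    M = M, k = k, subjects = subj, cell = cell,
    dropped_pairs = dropped_total,
    null = NULL, p_value = NA_real_
  ), class = "alignment_result")
  res$subject_isc <- subject_isc(res)
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("alignment_result: M =", x$M, ", k =", x$k, "folds\n")
  cat("  combined |z-bar| =", signif(x$combined, 4),
      " (r =", signif(x$r_equivalent, 4), ")\n")
  if (!is.na(x$p_value)) cat("  p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Circular-shift bootstrap null for an alignment result
#'
#' Each draw circularly shifts every subject's held-out canonical variates by
#' an independent uniform random lag in `[1, t_test - 1]` (lag 0 excluded),
#' then recomputes the pooled statistic exactly as the observed one —
#' including the per-fold selection of the strongest component — and combines
#' folds by the mean of absolute values. Shifting preserves each series'
#' autocorrelation while destroying cross-subject temporal alignment.
#' Implemented via precomputed FFT circular cross-correlations, so the cost
#' is independent of the number of draws for the heavy part.
#'
#' @param result an `alignment_result` from [crossval_alignment()].
#' @param n_shuffles number of null draws (default 5000).
#' @param seed integer seed; draws are reproducible.
#' @return numeric vector of `n_shuffles` combined null values.
#' @export
circular_null <- function(result, n_shuffles = 5000L, seed = 1L) {
  stopifnot(inherits(result, "alignment_result"))
  if (n_shuffles < 1L) stop("circular_null: n_shuffles must be >= 1")
  M <- result$M
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # enumerate the upper triangle column-wise, matching R[upper.tri(R)]
  ut <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
  pair_i <- ut[, 1]; pair_j <- ut[, 2]
  npair <- nrow(ut)

  total <- numeric(n_shuffles)
  for (f in seq_along(result$folds)) {
    fo <- result$folds[[f]]
    t_te <- ncol(fo$variates[[1]])
    if (t_te < 2L) stop("circular_null: test segment shorter than 2 samples")
    K <- nrow(fo$variates[[1]])
    lags <- matrix(sample.int(t_te - 1L, n_shuffles * M, replace = TRUE),
                   n_shuffles, M)
    delta <- (lags[, pair_i, drop = FALSE] - lags[, pair_j, drop = FALSE]) %% t_te
    idx_off <- delta * 1L                                  # 0-based lag
    zmat <- matrix(NA_real_, n_shuffles, K)
    for (d in seq_len(K)) {
      V <- t(vapply(fo$variates, function(y) y[d, ], numeric(t_te)))
      Vc <- V - rowMeans(V)
      sdp <- sqrt(rowSums(Vc^2) / t_te)
      ok <- sdp > 0
      Vs <- Vc
      Vs[ok, ] <- Vc[ok, , drop = FALSE] / sdp[ok]
      Fm <- stats::mvfft(t(Vs))                            # t x M
      # circular cross-correlation table: ctab[delta + 1, p] =
      #   corr(x_i shifted rel. x_j by delta) for pair p = (i, j)
      cross <- Conj(Fm[, pair_i, drop = FALSE]) * Fm[, pair_j, drop = FALSE]
      ctab <- Re(stats::mvfft(cross, inverse = TRUE)) / (t_te^2)
      pair_ok <- ok[pair_i] & ok[pair_j]
      if (!any(pair_ok)) next
      rs <- matrix(NA_real_, n_shuffles, npair)
      for (p in which(pair_ok)) {
        rs[, p] <- ctab[idx_off[, p] + 1L, p]
      }
      zmat[, d] <- rowMeans(atanh(clip_r(rs[, pair_ok, drop = FALSE])))
    }
    fold_null <- apply(abs(zmat), 1L, max, na.rm = TRUE)
    total <- total + fold_null
  }
  total / length(result$folds)
}

#' One-sided exceedance p-value from null draws
#'
#' Add-one rule: `p = (1 + #\{null >= observed\}) / (1 + n)`. One-sided,
#' because the mean-absolute combined statistic has a folded null.
#'
#' @param observed observed combined statistic.
#' @param null numeric vector of null draws (>= 1).
#' @return p-value in `(0, 1]`.
#' @export
p_from_null <- function(observed, null) {
  if (length(null) < 1L) stop("p_from_null: need at least one null draw")
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return object of class `cell_pvalue_set`: list with `raw`, `adjusted`
#'   (BH step-up), `procedure`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("fdr_adjust: p-values must be in [0, 1]")
  structure(list(raw = p, adjusted = stats::p.adjust(p, method = "BH"),
                 procedure = "BH"),
            class = "cell_pvalue_set")
}

#' Per-subject intersubject correlation values
#'
#' Subject m's per-fold value is the Fisher-z mean of its `M - 1` pairwise
#' correlations with all other subjects (for the selected component); folds
#' are combined by the mean of absolute values. These scalars are what enter
#' the pre/post contrasts.
#'
#' @param result an `alignment_result`.
#' @return named numeric vector, one value per subject.
#' @export
subject_isc <- function(result) {
  stopifnot(inherits(result, "alignment_result"))
  M <- result$M
  if (M < 3L) warning("subject_isc: fewer than 3 subjects; per-subject values are degenerate")
  per_fold <- vapply(result$folds, function(fo) {
    vapply(seq_len(M), function(m) {
      r <- fo$cor_matrix[m, -m]
      r <- r[!is.na(r)]
      if (length(r) == 0L) return(NA_real_)
      mean(atanh(clip_r(r)))
    }, numeric(1))
  }, numeric(M))
  out <- rowMeans(abs(matrix(per_fold, nrow = M)))
  names(out) <- result$subjects
  out
}

#' Run the alignment analysis over every cell of a study
#'
#' Iterates the (group, session, version, condition) cells of a
#' `study_dataset`, runs [crossval_alignment()] in each, optionally attaches
#' the circular-shift null and its p-value, and FDR-adjusts the cell p-values
#' across the whole family analysed in the run.
#'
#' @param study a `study_dataset`.
#' @param k fold count.
#' @param pca_d optional per-subject PCA dimension (fitted on training data).
#' @param n_components MCCA components to compute (default: all).
#' @param n_shuffles null draws per cell; 0 skips the null (no p-values).
#' @param seed master seed for the null draws.
#' @return list with `cells` (one row per cell: labels, selected components,
#'   combined statistic, `r_equivalent`, `p`, `p_adj`) and `isc` (long-format
#'   per-subject ISC table with a `version` covariate column).
#' @export
align_study <- function(study, k = 3L, pca_d = NULL, n_components = NULL,
                        n_shuffles = 0L, seed = 1L) {
  stopifnot(inherits(study, "study_dataset"))
  idx <- study$index
  cells <- unique(idx[, c("group", "session", "version", "condition")])
  rownames(cells) <- NULL
  rows <- list(); isc_rows <- list()
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    sel <- idx$group == ce$group & idx$session == ce$session &
      idx$version == ce$version & idx$condition == ce$condition
    keys <- idx$key[sel]
    recs <- study$recordings[keys]
    names(recs) <- idx$subject[sel]
    res <- crossval_alignment(recs, k = k, pca_d = pca_d,
                              n_components = n_components, cell = as.list(ce))
    p <- NA_real_
    if (n_shuffles > 0L) {
      null <- circular_null(res, n_shuffles = n_shuffles,
                            seed = derive_seed(seed, 5000L + i))
      p <- p_from_null(res$combined, null)
    }
    rows[[i]] <- data.frame(
      ce, M = res$M, combined = res$combined,
      r_equivalent = res$r_equivalent, p = p)
    isc_rows[[i]] <- data.frame(
      ce, subject = names(res$subject_isc), isc = unname(res$subject_isc),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (n_shuffles > 0L) out$p_adj <- fdr_adjust(out$p)$adjusted
  list(cells = out, isc = do.call(rbind, isc_rows))
}
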