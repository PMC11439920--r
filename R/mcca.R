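# MAXVAR multiset canonical correlation. Each subject's sensor (or PCA)
# space is sphered with an eigenvalue whitening; the stage-wise MAXVAR
# solution is then the top eigenvector of the joint correlation matrix of the
# stacked whitened data, its per-subject blocks normalised to give the
# subject weight vectors. Deflating each subject's block before the next
# stage enforces exact within-subject decorrelation of the canonical
# variates, and the deflated eigenvalues order components by decreasing
# across-subject consistency.

# eigenvalue whitening with a relative floor; returns the r x D whitener K
# such that K %*% centred-data has identity sample covariance
whiten_transform <- function(Zc, floor_rel = 1e-10) {
  t_len <- ncol(Zc)
  S <- tcrossprod(Zc) / t_len
  eg <- eigen(S, symmetric = TRUE)
  keep <- eg$values >= floor_rel * eg$values[1] & eg$values > 0
  K <- sweep(t(eg$vectors[, keep, drop = FALSE]), 1,
             sqrt(eg$values[keep]), "/")
  list(K = K, rank = sum(keep))
}

#' Fit a MAXVAR multiset canonical correlation model
#'
#' Finds, for each of `M >= 2` datasets (subjects), a set of spatial-filter
#' weight vectors whose projections (canonical variates) are mutually
#' uncorrelated within a subject and maximally consistent across subjects
#' under the MAXVAR criterion. Components are ordered by decreasing
#' across-subject consistency; each component's sign per subject is fixed so
#' that its training variate correlates non-negatively with the across-subject
#' mean variate.
#'
#' @param datasets list of `D x time` numeric matrices, one per subject, all
#'   with the same number of time points (the zero-padding contract). Row
#'   counts may differ between subjects.
#' @param n_components number of canonical components; defaults to the
#'   smallest whitened rank across subjects.
#' @param floor_rel relative eigenvalue floor of the whitening (default 1e-10).
#' @return object of class `mcca_model` with per-subject `weights` (in
#'   whitened space), `filters` (n_components x D, applied to centred data),
#'   `means`, the `whiteners`, per-component MAXVAR eigenvalues `lambda`, and
#'   the training variates.
#' @export
fit_maxvar <- function(datasets, n_components = NULL, floor_rel = 1e-10) {
  M <- length(datasets)
  if (M < 2L) stop("fit_maxvar: need at least 2 datasets")
  t_len <- unique(vapply(datasets, ncol, integer(1)))
  if (length(t_len) != 1L) {
    stop("fit_maxvar: all datasets must have equal length; pad rejected ",
         "segments with zeros to restore equal length")
  }
  subj <- names(datasets)
  if (is.null(subj)) subj <- sprintf("s%02d", seq_len(M))

  means <- lapply(datasets, rowMeans)
  U <- vector("list", M)     # whitened centred data
  wh <- vector("list", M)
  for (m in seq_len(M)) {
    Zc <- datasets[[m]] - means[[m]]
    wh[[m]] <- whiten_transform(Zc, floor_rel)
    U[[m]] <- wh[[m]]$K %*% Zc
  }
  ranks <- vapply(wh, function(w) w$rank, integer(1))
  K <- if (is.null(n_components)) min(ranks) else n_components
  if (any(ranks < K)) {
    stop("fit_maxvar: dataset rank (", min(ranks),
         ") below requested n_components (", K, ")")
  }

  X <- do.call(rbind, U)                       # (sum ranks) x t
  C <- tcrossprod(X) / t_len                   # joint correlation matrix
  blk <- rep(seq_len(M), ranks)

  W <- lapply(seq_len(M), function(m) matrix(0, K, ranks[m]))
  lambda <- numeric(K)
  for (k in seq_len(K)) {
    eg <- eigen(C, symmetric = TRUE)
    v <- eg$vectors[, 1]
    v <- v * sign(v[which.max(abs(v))])        # deterministic global sign
    lambda[k] <- eg$values[1]
    for (m in seq_len(M)) {
      vm <- v[blk == m]
      nv <- sqrt(sum(vm^2))
      w <- if (nv > 1e-12) vm / nv else vm * 0
      W[[m]][k, ] <- w
      # deflate subject m's block of C (rows and columns)
      if (nv > 1e-12) {
        rows <- which(blk == m)
        C[rows, ] <- C[rows, ] - w %*% (t(w) %*% C[rows, , drop = FALSE])
        C[, rows] <- C[, rows] - (C[, rows, drop = FALSE] %*% w) %*% t(w)
      }
    }
  }

  # training variates + per-subject sign convention (non-negative correlation
  # with the across-subject mean variate)
  Y <- lapply(seq_len(M), function(m) W[[m]] %*% U[[m]])
  for (k in seq_len(K)) {
    vk <- vapply(Y, function(y) y[k, ], numeric(t_len))    # t x M
    ybar <- rowMeans(vk)
    if (stats::sd(ybar) > 0) {
      for (m in seq_len(M)) {
        if (stats::sd(vk[, m]) > 0 && stats::cor(vk[, m], ybar) < 0) {
          W[[m]][k, ] <- -W[[m]][k, ]
          Y[[m]][k, ] <- -Y[[m]][k, ]
        }
      }
    }
  }

  filters <- lapply(seq_len(M), function(m) W[[m]] %*% wh[[m]]$K)
  names(W) <- names(filters) <- names(means) <- names(Y) <- names(wh) <- subj
  structure(list(
    weights = W, filters = filters, means = means, whiteners = wh,
    lambda = lambda, n_components = K, subjects = subj,
    training_variates = Y
  ), class = "mcca_model")
}

#' @export
print.mcca_model <- function(x, ...) {
  cat("mcca_model:", length(x$subjects), "subjects,", x$n_components,
      "components (MAXVAR)\n")
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$lambda, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project a dataset through a subject's MCCA spatial filters
#'
#' Pure linear map: centres the data with the subject's training means and
#' applies the subject's filter matrix, yielding the canonical variates.
#'
#' @param model an `mcca_model`.
#' @param dataset `D x time` matrix in the space the model was fitted in.
#' @param subject subject name (or index) in the model.
#' @return `n_components x time` matrix of canonical variates.
#' @export
project <- function(model, dataset, subject) {
  stopifnot(inherits(model, "mcca_model"))
  if (is.character(subject) && !subject %in% model$subjects) {
    stop("project: unknown subject '", subject, "'")
  }
  f <- model$filters[[subject]]
  if (ncol(f) != nrow(dataset)) {
    stop("project: dataset dimension (", nrow(dataset),
         ") does not match model dimension (", ncol(f), ")")
  }
  f %*% (dataset - model$means[[subject]])
}

#' Forward-model activation pattern of a canonical component
#'
#' Converts a spatial filter to its activation pattern
#' `A = Sigma_z W' Sigma_y` for one component, using only that component's
#' variance (robust to singular variate covariance):
#' `a = Cov(z, y_k) * Var(y_k)`, with covariances computed on the supplied
#' data segment. Unlike the raw weights, the pattern is interpretable as the
#' component's projection into sensor space and is invariant (up to scale) to
#' invertible re-mixing of the subject's sensors.
#'
#' @param model an `mcca_model`.
#' @param dataset `D x time` matrix (the segment on which covariances are
#'   computed).
#' @param subject subject name or index.
#' @param component component index (default 1).
#' @param pca optional `pca_reduction`; when supplied the pattern is
#'   back-projected through the PCA loadings to the original channel space.
#' @return object of class `activation_pattern`: list with `pattern` (numeric
#'   vector, arbitrary units), `subject`, `component`.
#' @export
activation_pattern <- function(model, dataset, subject, component = 1L,
                               pca = NULL) {
  y <- project(model, dataset, subject)[component, ]
  yc <- y - mean(y)
  zc <- dataset - rowMeans(dataset)
  a <- as.numeric(zc %*% yc) / ncol(dataset) * stats::var(y)
  if (!is.null(pca)) {
    stopifnot(inherits(pca, "pca_reduction"))
    a <- as.numeric(t(pca$components) %*% a)
  }
  structure(list(pattern = a, subject = subject, component = component),
            class = "activation_pattern")
}
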