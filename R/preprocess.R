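# Deterministic preprocessing applied before MCCA: zero-phase band-pass
# filtering, anti-aliased resampling, zero-padding of rejected segments, and
# PCA dimensionality reduction.

# FIR band-pass design (windowed sinc, Hamming). The transition width sets the
# filter order: ~3.3 * fs / transition taps, rounded up to an odd length so the
# filter is type-I linear phase.
design_fir_bandpass <- function(fs, low, high, transition) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("bandpass: need 0 < low < high < fs/2 (got ", low, "-", high,
         " Hz at fs = ", fs, " Hz)")
  }
  if (transition <= 0) stop("bandpass: transition width must be > 0")
  ord <- ceiling(3.3 * fs / transition)
  if (ord %% 2 == 1L) ord <- ord + 1L       # even order -> odd tap count
  signal::fir1(ord, c(low, high) * 2 / fs, type = "pass")
}

# Zero-phase forward-backward application of a symmetric FIR filter to the
# rows of a matrix, via FFT convolution with the filter's autocorrelation and
# odd (antisymmetric) edge reflection to suppress boundary transients.
filtfilt_rows <- function(mat, h) {
  n <- ncol(mat)
  ntaps <- length(h)
  if (n <= ntaps) {
    stop("bandpass: signal length (", n, ") must exceed the filter warm-up (",
         ntaps, " taps)")
  }
  g <- stats::convolve(h, rev(h), type = "open")  # forward-backward kernel
  center <- ntaps                                 # zero-phase centre of g
  p <- min(ntaps - 1L, n - 1L)                    # reflection pad length
  left  <- 2 * mat[, 1] - mat[, (p + 1L):2L, drop = FALSE]
  right <- 2 * mat[, n] - mat[, (n - 1L):(n - p), drop = FALSE]
  z <- cbind(left, mat, right)                    # ch x (n + 2p)
  np <- ncol(z)
  lg <- length(g)
  nfft <- stats::nextn(np + lg - 1L, 2)
  zp <- rbind(t(z), matrix(0, nfft - np, nrow(z)))
  gf <- stats::fft(c(g, rep(0, nfft - lg)))
  y <- Re(stats::mvfft(stats::mvfft(zp) * gf, inverse = TRUE)) / nfft
  t(y[(center + p):(center + p + n - 1L), , drop = FALSE])
}

#' Zero-phase band-pass filter
#'
#' Filters each channel (row) with a linear-phase FIR band-pass applied
#' forward-backward, giving exactly zero phase shift. Defaults reproduce the
#' analysis band used before MCCA: 0.5--10 Hz with a 0.5 Hz transition.
#'
#' @param mat channels x time numeric matrix (a plain vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param low,high pass-band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param transition transition-band width in Hz; controls filter length.
#' @return filtered matrix of the same shape (vector in, vector out).
#' @export
bandpass <- function(mat, fs, low = 0.5, high = 10, transition = 0.5) {
  vec <- is.null(dim(mat))
  if (vec) mat <- matrix(mat, nrow = 1L)
  if (any(!is.finite(mat))) stop("bandpass: input must be finite")
  h <- design_fir_bandpass(fs, low, high, transition)
  out <- filtfilt_rows(mat, h)
  if (vec) drop(out) else out
}

#' Resample to a lower sampling rate
#'
#' Fourier-domain resampling: the spectrum is truncated to the new bandwidth
#' and inverse-transformed, so pass-band content is preserved without phase
#' distortion. Only downsampling (or the identity) is supported.
#'
#' @param mat channels x time matrix (or vector).
#' @param fs_in input sampling rate (Hz).
#' @param fs_out output sampling rate (Hz), `fs_out <= fs_in`. Default 400.
#' @return matrix with `round(ncol(mat) * fs_out / fs_in)` columns.
#' @export
resample_to <- function(mat, fs_in, fs_out = 400) {
  if (fs_out > fs_in) stop("resample_to: upsampling is not supported (fs_out > fs_in)")
  vec <- is.null(dim(mat))
  if (vec) mat <- matrix(mat, nrow = 1L)
  if (fs_out == fs_in) return(if (vec) drop(mat) else mat)
  n <- ncol(mat)
  m <- as.integer(round(n * fs_out / fs_in))
  X <- stats::mvfft(t(mat))                       # n x ch
  Y <- matrix(0 + 0i, m, ncol(X))
  kmax <- (m - 1L) %/% 2L                         # fully-kept positive bins
  Y[1L, ] <- X[1L, ]
  if (kmax >= 1L) {
    idx <- seq_len(kmax)
    Y[1L + idx, ] <- X[1L + idx, ]
    Y[m + 1L - idx, ] <- X[n + 1L - idx, ]
  }
  if (m %% 2L == 0L) {                            # folded Nyquist bin, kept real
    k <- m %/% 2L
    Y[k + 1L, ] <- X[k + 1L, ] + X[n + 1L - k, ]
  }
  out <- t(Re(stats::mvfft(Y, inverse = TRUE))) * (1 / n)
  if (vec) drop(out) else out
}

#' Zero out rejected time segments
#'
#' Replaces the samples inside each half-open interval `[start, end)` (1-based
#' sample indices, `end` exclusive) with zeros, leaving all other samples
#' untouched and the length unchanged. This is the equal-length contract MCCA
#' relies on when artifactual segments have been rejected.
#'
#' @param mat channels x time matrix (or vector).
#' @param intervals integer matrix with columns `start`, `end` (half-open,
#'   1-based), or `NULL`/zero-row for the identity.
#' @return matrix of identical shape with masked columns set to 0.
#' @export
zero_pad <- function(mat, intervals) {
  vec <- is.null(dim(mat))
  if (vec) mat <- matrix(mat, nrow = 1L)
  n <- ncol(mat)
  if (is.null(intervals) || NROW(intervals) == 0L) {
    return(if (vec) drop(mat) else mat)
  }
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L) stop("zero_pad: intervals must have two columns (start, end)")
  s <- intervals[, 1]; e <- intervals[, 2]
  if (any(s < 1 | e > n + 1 | s >= e)) {
    stop("zero_pad: intervals must satisfy 1 <= start < end <= length + 1")
  }
  o <- order(s)
  if (any(s[o][-1] < e[o][-length(e)])) stop("zero_pad: overlapping intervals")
  for (i in seq_along(s)) mat[, s[i]:(e[i] - 1L)] <- 0
  if (vec) drop(mat) else mat
}

#' Fit a PCA reduction of sensor data
#'
#' Channels are mean-centred and projected onto the top `D` principal axes of
#' the channel covariance. `D` defaults to 50, the reduction applied to the
#' 248-channel arrays before MCCA.
#'
#' @param mat channels x time matrix.
#' @param D number of retained dimensions; capped at `min(channels, time)`
#'   with a warning if larger.
#' @return an object of class `pca_reduction` with fields `mean` (channel
#'   vector), `components` (D x channels, orthonormal rows),
#'   `explained_variance_ratio` (length D, non-increasing) and `D`.
#' @export
fit_pca <- function(mat, D = 50) {
  nch <- nrow(mat); nt <- ncol(mat)
  rmax <- min(nch, nt)
  if (D > rmax) {
    warning("fit_pca: D = ", D, " exceeds min(channels, time) = ", rmax,
            "; truncated")
    D <- rmax
  }
  pr <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  evr_all <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(
    mean = pr$center,
    components = t(pr$rotation[, seq_len(D), drop = FALSE]),
    explained_variance_ratio = evr_all[seq_len(D)],
    D = D
  ), class = "pca_reduction")
}

#' Apply a fitted PCA reduction
#'
#' @param reduction a `pca_reduction` from [fit_pca()].
#' @param mat channels x time matrix with the same channel count the
#'   reduction was fitted on.
#' @return D x time matrix of component scores.
#' @export
apply_pca <- function(reduction, mat) {
  stopifnot(inherits(reduction, "pca_reduction"))
  if (nrow(mat) != length(reduction$mean)) {
    stop("apply_pca: channel count mismatch (", nrow(mat), " vs ",
         length(reduction$mean), ")")
  }
  reduction$components %*% (mat - reduction$mean)
}

#' Full preprocessing chain for one recording
#'
#' Convenience wrapper running the deterministic chain in its fixed order:
#' resample to `fs_out`, zero-pad rejected segments (interval indices given at
#' the output rate), then band-pass into the analysis band.
#'
#' @inheritParams bandpass
#' @inheritParams resample_to
#' @param intervals optional rejected-segment intervals at the output rate
#'   (see [zero_pad()]).
#' @return preprocessed channels x time matrix at `fs_out`.
#' @export
preprocess_recording <- function(mat, fs_in, fs_out = 400, intervals = NULL,
                                 low = 0.5, high = 10, transition = 0.5) {
  mat <- resample_to(mat, fs_in, fs_out)
  mat <- zero_pad(mat, intervals)
  bandpass(mat, fs_out, low = low, high = high, transition = transition)
}
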