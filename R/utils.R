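#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft mvfft prcomp pt qt rnorm runif sd uniroot var
#' @importFrom utils head tail
NULL

# Correlation guard before the Fisher transform: arctanh diverges at |r| = 1,
# so magnitudes are clipped just inside the open interval.
.CLIP <- 1 - 1e-12

clip_r <- function(r) pmin(pmax(r, -.CLIP), .CLIP)

#' Fisher z-transform pooling of correlation coefficients
#'
#' Applies `z = arctanh(r)` to each coefficient (with `|r|` clipped to
#' `1 - 1e-12`) and returns the mean z. Used to pool the M(M-1)/2 pairwise
#' intersubject correlations into a single alignment value.
#'
#' @param r numeric vector of correlations, all in `[-1, 1]`.
#' @return pooled mean z (scalar).
#' @seealso [inverse_fisher()]
#' @export
fisher_pool <- function(r) {
  if (length(r) == 0L) stop("fisher_pool: empty correlation set")
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-8)) {
    stop("fisher_pool: correlations must be finite and within [-1, 1]")
  }
  mean(atanh(clip_r(r)))
}

#' Inverse Fisher transform
#'
#' @param z pooled z value(s).
#' @return correlation scale value `tanh(z)`.
#' @export
inverse_fisher <- function(z) tanh(z)

# Deterministic derived seeds: one master seed, per-entity seeds obtained by a
# documented counter hash so that any subset of a study regenerates
# identically. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, counter) {
  m <- as.double(master) %% 2147483629
  as.integer((m * 7919 + as.double(counter) * 104729) %% 2147483629)
}

# consistent internal label sets for the study design
.GROUPS <- c("intervention", "control")
.SESSIONS <- c("pre", "post")
.VERSIONS <- c("v1", "v2")
.CONDITIONS <- c("political_congruent", "political_incongruent",
                 "nonpolitical_congruent", "nonpolitical_incongruent")

rec_key <- function(group, session, version, condition, subject) {
  paste(group, session, version, condition, subject, sep = "|")
}
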