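# Pre/post contrast layer: paired and Welch t-tests, Cohen's d conversions,
# sensitivity power analysis, and the per-cell contrast table over the
# per-subject ISC values.

#' Paired t-test on difference scores
#'
#' One-sample t on the post - pre differences, `df = n - 1`, two-sided p.
#'
#' @param diffs numeric vector of paired differences (n >= 2, finite).
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(diffs) {
  if (length(diffs) < 2L || any(!is.finite(diffs))) {
    stop("paired_t: need >= 2 finite differences")
  }
  if (stats::sd(diffs) == 0) stop("paired_t: zero variance in differences")
  ht <- stats::t.test(diffs)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Welch two-sample t-test from summary statistics
#'
#' Welch statistic and Welch-Satterthwaite degrees of freedom computed from
#' per-group means, standard deviations and sizes.
#'
#' @param mean_a,sd_a,n_a first group's mean, sd, size.
#' @param mean_b,sd_b,n_b second group's mean, sd, size.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2L || n_b < 2L) stop("welch_t: both groups need n >= 2")
  if (sd_a == 0 && sd_b == 0) stop("welch_t: zero variance in both groups")
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  tval <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = tval, df = df, p = two_tailed_p(tval, df))
}

#' Cohen's d from a paired t statistic
#'
#' Within-subject conversion `d = t / sqrt(n)`.
#'
#' @param t t statistic.
#' @param n number of pairs.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) {
  if (n < 2L) stop("cohens_d_from_t: n must be >= 2")
  t / sqrt(n)
}

#' Pooled-SD Cohen's d from summary statistics
#'
#' `d = (mean_a - mean_b) / s_p` with
#' `s_p^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)`.
#'
#' @inheritParams welch_t
#' @return Cohen's d.
#' @export
cohens_d_pooled <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2L || n_b < 2L) stop("cohens_d_pooled: both groups need n >= 2")
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (sp2 == 0) stop("cohens_d_pooled: pooled sd is zero")
  (mean_a - mean_b) / sqrt(sp2)
}

#' Two-sided p-value for a t statistic
#'
#' @param t t statistic.
#' @param df degrees of freedom (>= 1).
#' @return `p = 2 * P(T_df > |t|)`.
#' @export
two_tailed_p <- function(t, df) {
  if (df < 1) stop("two_tailed_p: df must be >= 1")
  2 * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Sensitivity power analysis for a paired t-test
#'
#' Solves for the minimal detectable Cohen's d: the effect size at which a
#' two-sided one-sample (paired) t-test with noncentrality `d * sqrt(n)`
#' attains the requested power at level `alpha`. Root-found on the exact
#' noncentral-t power function to 1e-6.
#'
#' @param n number of pairs (>= 2).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80); must exceed `alpha`.
#' @param two_sided logical; one- or two-sided test (default TRUE).
#' @return minimal detectable Cohen's d.
#' @export
sensitivity_power <- function(n, alpha = 0.05, power = 0.80, two_sided = TRUE) {
  if (n < 2L) stop("sensitivity_power: n must be >= 2")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("sensitivity_power: alpha and power must be in (0, 1)")
  }
  if (power <= alpha) stop("sensitivity_power: power must exceed alpha")
  df <- n - 1
  pw <- function(d) {
    ncp <- d * sqrt(n)
    if (two_sided) {
      tc <- stats::qt(1 - alpha / 2, df)
      stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
        stats::pt(-tc, df, ncp = ncp)
    } else {
      tc <- stats::qt(1 - alpha, df)
      stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
    }
  }
  stats::uniroot(function(d) pw(d) - power, c(1e-8, 10), tol = 1e-6)$root
}

#' Pre/post contrast table over per-subject ISC values
#'
#' Takes the long-format per-subject ISC table produced by [align_study()]
#' (columns `group`, `session`, `version`, `condition`, `subject`, `isc`),
#' averages each subject's value across stimulus versions, and runs, per
#' (group x condition), a paired t-test on the post - pre differences, with
#' `d = t / sqrt(n)` and a BH-adjusted p-value column across all rows.
#'
#' @param isc long-format per-subject ISC data.frame.
#' @param alpha significance level used for the `significant` flag on the
#'   adjusted p-values (default 0.05).
#' @return object of class `contrast_table`: data.frame with one row per
#'   (group, condition): `t`, `df`, `p`, `cohens_d`, `n`, `p_adj`,
#'   `significant`.
#' @export
build_contrast_table <- function(isc, alpha = 0.05) {
  need <- c("group", "session", "version", "condition", "subject", "isc")
  if (!all(need %in% names(isc))) {
    stop("build_contrast_table: isc table must have columns ",
         paste(need, collapse = ", "))
  }
  # average each subject's value over versions within group/session/condition
  agg <- stats::aggregate(isc ~ group + session + condition + subject,
                          data = isc, FUN = mean)
  rows <- list()
  for (g in unique(agg$group)) for (co in unique(agg$condition)) {
    pre <- agg[agg$group == g & agg$condition == co & agg$session == "pre", ]
    post <- agg[agg$group == g & agg$condition == co & agg$session == "post", ]
    if (!setequal(pre$subject, post$subject)) {
      bad <- c(setdiff(pre$subject, post$subject),
               setdiff(post$subject, pre$subject))
      stop("build_contrast_table: unmatched pre/post subjects in (", g, ", ",
           co, "): ", paste(bad, collapse = ", "))
    }
    ord <- match(pre$subject, post$subject)
    diffs <- post$isc[ord] - pre$isc
    tt <- paired_t(diffs)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, condition = co, contrast = "post - pre",
      t = tt$t, df = tt$df, p = tt$p,
      cohens_d = cohens_d_from_t(tt$t, length(diffs)),
      n = length(diffs), test = "paired")
  }
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_adjust(out$p)$adjusted
  out$significant <- out$p_adj < alpha
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' @export
print.contrast_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  for (cl in c("t", "p", "cohens_d", "p_adj")) y[[cl]] <- round(y[[cl]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}
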