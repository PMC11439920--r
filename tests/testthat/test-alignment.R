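test_that("fold plans partition the series into near-equal contiguous ranges", {
  f3 <- make_folds(36000, 3)
  expect_identical(f3[, "start"], c(1L, 12001L, 24001L))
  expect_identical(f3[, "end"], c(12001L, 24001L, 36001L))

  f10 <- make_folds(10, 3)
  expect_identical(f10[, "end"] - f10[, "start"], c(4L, 3L, 3L))

  covered <- unlist(lapply(seq_len(3), function(i) f10[i, 1]:(f10[i, 2] - 1L)))
  expect_identical(sort(covered), 1:10)
  expect_identical(anyDuplicated(covered), 0L)
  expect_error(make_folds(2, 3), "at least k")
})

test_that("Fisher pooling matches arctanh/tanh closed forms", {
  expect_identical(fisher_pool(c(0, 0, 0)), 0)
  expect_equal(fisher_pool(c(0.5, 0.5)), atanh(0.5), tolerance = 1e-12)
  expect_equal(inverse_fisher(fisher_pool(c(0.5, 0.5))), 0.5, tolerance = 1e-12)
  for (r in c(-0.9, -0.2, 0.3, 0.99)) {
    expect_equal(inverse_fisher(fisher_pool(r)), r, tolerance = 1e-9)
  }
  expect_error(fisher_pool(numeric(0)), "empty")
  expect_error(fisher_pool(c(0.2, 1.5)), "within")
})

test_that("shared structure lifts the combined statistic far above noise cells", {
  aligned <- crossval_alignment(
    make_cell(8, 2, n_channels = 16, duration_s = 30, fs = 100, seed = 31)$recs,
    k = 3)
  noise <- crossval_alignment(
    make_cell(8, 0, n_channels = 16, duration_s = 30, fs = 100, seed = 31)$recs,
    k = 3)
  expect_gt(aligned$combined / noise$combined, 3)
  # noise cell sits inside its own circular null
  null0 <- circular_null(noise, n_shuffles = 200, seed = 32)
  p0 <- p_from_null(noise$combined, null0)
  expect_gt(p0, 0.025)
})

test_that("perfectly correlated duplicate subjects hit the arctanh clip guard", {
  set.seed(33)
  Z <- matrix(rnorm(4 * 600), 4)
  suppressWarnings(res <- crossval_alignment(list(a = Z, b = Z), k = 3))
  expect_equal(res$combined, atanh(1 - 1e-12), tolerance = 1e-6)
})

test_that("null draws are reproducible, lag-0-free and shift-robust", {
  cell <- make_cell(4, 1, n_channels = 8, duration_s = 15, fs = 100, seed = 34)
  res <- crossval_alignment(cell$recs, k = 3)
  n1 <- circular_null(res, n_shuffles = 100, seed = 35)
  n2 <- circular_null(res, n_shuffles = 100, seed = 35)
  expect_identical(n1, n2)
  # lag 0 is excluded by construction, so no draw reproduces the observed
  # statistic exactly
  expect_false(any(n1 == res$combined))
  expect_error(circular_null(res, n_shuffles = 0), "n_shuffles")
})

test_that("shifting destroys alignment but preserves single-pair null structure", {
  # at M = 2 the pooled statistic has no cross-pair dependence, so the null
  # mean is insensitive to the alignment strength (matched marginal spectra)
  mk2 <- function(snr) {
    cell <- make_cell(2, snr, n_channels = 8, duration_s = 30, fs = 100,
                      seed = 36, bandpassed = TRUE)
    suppressWarnings(crossval_alignment(cell$recs, k = 3))
  }
  r0 <- mk2(0); r2 <- mk2(2)
  m0 <- mean(circular_null(r0, 800, seed = 37))
  m2 <- mean(circular_null(r2, 800, seed = 38))
  expect_lt(abs(m2 / m0 - 1), 0.10)
  # at M = 8 pooled pairs share lags; the folded null mean moves a little,
  # but the observed aligned statistic dwarfs both null means
  mk8 <- function(snr) {
    cell <- make_cell(8, snr, n_channels = 8, duration_s = 30, fs = 100,
                      seed = 39, bandpassed = TRUE)
    crossval_alignment(cell$recs, k = 3)
  }
  s0 <- mk8(0); s2 <- mk8(2)
  mm0 <- mean(circular_null(s0, 400, seed = 40))
  mm2 <- mean(circular_null(s2, 400, seed = 41))
  expect_lt(mm2 / mm0, 1.3)
  expect_gt(s2$combined / mm2, 10)
})

test_that("exceedance p-values follow the add-one rule and are monotone", {
  null <- seq(0.001, 0.5, length.out = 5000)
  expect_equal(p_from_null(0.6, null), 1 / 5001, tolerance = 1e-12)
  expect_equal(p_from_null(median(null), null), 0.5, tolerance = 0.001)
  obs <- seq(0, 0.6, by = 0.05)
  p <- vapply(obs, p_from_null, numeric(1), null = null)
  expect_true(all(diff(p) <= 0))
  expect_error(p_from_null(1, numeric(0)), "null draw")
})

test_that("BH adjustment reproduces the step-up hand computation", {
  adj <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adj$adjusted, rep(0.04, 4), tolerance = 1e-12)
  expect_identical(fdr_adjust(0.37)$adjusted, 0.37)
  expect_identical(fdr_adjust(rep(1, 5))$adjusted, rep(1, 5))
  expect_true(all(adj$adjusted >= adj$raw))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("per-subject ISC values aggregate pairwise correlations correctly", {
  fake_result <- function(Rs, subjects) {
    structure(list(
      folds = lapply(Rs, function(R) list(cor_matrix = R)),
      M = nrow(Rs[[1]]), k = length(Rs), subjects = subjects
    ), class = "alignment_result")
  }
  # symmetric case: all pairwise r = 0.5 -> every subject value atanh(0.5)
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  vals <- subject_isc(fake_result(list(R), c("a", "b", "c")))
  expect_equal(unname(vals), rep(atanh(0.5), 3), tolerance = 1e-12)

  # algebraic identity: mean of subject values equals the pooled z-bar when
  # all fold values share a sign
  set.seed(42)
  M <- 6
  r <- matrix(runif(M * M, 0.1, 0.6), M); R1 <- (r + t(r)) / 2; diag(R1) <- 1
  res1 <- fake_result(list(R1), sprintf("s%d", 1:M))
  zbar <- mean(atanh(R1[upper.tri(R1)]))
  expect_equal(mean(subject_isc(res1)), zbar, tolerance = 1e-12)

  # permutation equivariance
  perm <- c(3, 1, 2, 6, 5, 4)
  resp <- fake_result(list(R1[perm, perm]), sprintf("s%d", 1:M)[perm])
  expect_equal(subject_isc(resp), subject_isc(res1)[perm], tolerance = 1e-12)
})

test_that("noise-cell p-values are approximately uniform", {
  ps <- vapply(1:100, function(i) {
    recs <- make_noise_cell(4, 6, 600, seed = 4300 + i)
    res <- crossval_alignment(recs, k = 3)
    p_from_null(res$combined,
                circular_null(res, n_shuffles = 99, seed = 4400 + i))
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("alignment at scale detects a moderate shared signal reliably", {
  # regression guard: M = 20 subjects, 12,000 held-out samples per fold,
  # snr = 0.5 -> the circular null should essentially never cover the
  # observed statistic
  ps <- vapply(1:5, function(i) {
    lat <- make_latent_signal(90, 400, c(0.5, 10), seed = 4500 + i)
    recs <- lapply(1:20, function(j) {
      set.seed(i * 1000 + j)
      g <- rnorm(8); g <- g / sqrt(sum(g^2))
      synthesize_subject(lat, g, 0.5, noise_seed = i * 2000 + j)
    })
    res <- crossval_alignment(recs, k = 3)
    p_from_null(res$combined,
                circular_null(res, n_shuffles = 200, seed = 4600 + i))
  }, numeric(1))
  expect_true(all(ps < 0.05))
})
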