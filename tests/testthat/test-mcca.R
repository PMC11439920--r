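test_that("MAXVAR at M=2 reproduces classic canonical correlations", {
  set.seed(21)
  for (i in 1:5) {
    D <- sample(3:10, 1)
    t_len <- 2000
    s <- rnorm(t_len)
    Z1 <- matrix(rnorm(D * t_len), D) + outer(rnorm(D), s)
    Z2 <- matrix(rnorm(D * t_len), D) + outer(rnorm(D), s)
    m <- fit_maxvar(list(Z1, Z2))
    cc <- cancor(t(Z1), t(Z2))$cor
    for (k in seq_len(min(D, 3))) {
      r <- cor(m$training_variates[[1]][k, ], m$training_variates[[2]][k, ])
      expect_equal(abs(r), cc[k], tolerance = 1e-6)
    }
  }
})

test_that("identical datasets give perfect first-component correlations", {
  set.seed(22)
  Z <- matrix(rnorm(6 * 800), 6)
  m <- fit_maxvar(list(Z, Z, Z))
  v <- lapply(m$training_variates, function(y) y[1, ])
  expect_equal(cor(v[[1]], v[[2]]), 1, tolerance = 1e-10)
  expect_equal(cor(v[[2]], v[[3]]), 1, tolerance = 1e-10)
})

test_that("independent noise overfits in training but not on held-out data", {
  recs <- make_noise_cell(5, 10, 2000, seed = 23)
  tr <- 1:1400; te <- 1401:2000
  m <- fit_maxvar(lapply(recs, function(x) x[, tr]))
  pool_first <- function(vs) {
    V <- do.call(rbind, lapply(vs, function(y) y[1, ]))
    R <- cor(t(V))
    mean(atanh(R[upper.tri(R)]))
  }
  z_tr <- pool_first(m$training_variates)
  vs_te <- lapply(names(recs), function(s) project(m, recs[[s]][, te], s))
  z_te <- pool_first(vs_te)
  expect_gt(z_tr, 0.05)          # training overfit is real but modest
  expect_lt(abs(z_te), 0.05)     # and does not generalise
})

test_that("training variates are mutually uncorrelated and ordered by consistency", {
  set.seed(24)
  cell <- make_cell(5, 1, n_channels = 8, duration_s = 15, fs = 100, seed = 24)
  m <- fit_maxvar(cell$recs)
  for (y in m$training_variates) {
    R <- cor(t(y))
    expect_lt(max(abs(R[upper.tri(R)])), 1e-6)
  }
  expect_true(all(diff(m$lambda) <= 1e-8))
})

test_that("canonical correlations are invariant to invertible sensor re-mixing", {
  set.seed(25)
  Zs <- lapply(1:4, function(i) {
    matrix(rnorm(6 * 600), 6) + outer(rnorm(6), rnorm(600))
  })
  m1 <- fit_maxvar(Zs)
  A <- matrix(rnorm(36), 6)                    # invertible w.p. 1
  Zs2 <- Zs; Zs2[[2]] <- A %*% Zs[[2]]
  m2 <- fit_maxvar(Zs2)
  expect_equal(m1$lambda, m2$lambda, tolerance = 1e-8)
  r1 <- cor(m1$training_variates[[1]][1, ], m1$training_variates[[3]][1, ])
  r2 <- cor(m2$training_variates[[1]][1, ], m2$training_variates[[3]][1, ])
  expect_equal(abs(r1), abs(r2), tolerance = 1e-8)
})

test_that("projection is a pure linear map reproducing the training variates", {
  set.seed(26)
  cell <- make_cell(3, 1, n_channels = 6, duration_s = 10, fs = 100, seed = 26)
  m <- fit_maxvar(cell$recs)
  # train-data round trip
  for (s in names(cell$recs)) {
    expect_equal(project(m, cell$recs[[s]], s), m$training_variates[[s]],
                 tolerance = 1e-12)
  }
  # linearity around the stored training mean
  z0 <- project(m, matrix(0, 6, 50) + m$means[[1]], "s01")
  expect_equal(max(abs(z0)), 0, tolerance = 1e-12)
  X <- matrix(rnorm(6 * 50), 6)
  y1 <- project(m, X + m$means[[1]], "s01")
  y3 <- project(m, 3 * X + m$means[[1]], "s01")
  expect_equal(y3, 3 * y1, tolerance = 1e-10)
  expect_error(project(m, X, "nope"), "unknown subject")
  expect_error(project(m, X[1:3, ], "s01"), "dimension")
})

test_that("held-out first variate recovers the latent, monotonically in snr", {
  snrs <- c(0.25, 0.5, 1, 2)
  rec_cor <- vapply(snrs, function(s) {
    lat <- make_latent_signal(30, 100, c(0.5, 10), seed = 27)
    recs <- lapply(1:6, function(i) {
      set.seed(270 + i)
      synthesize_subject(lat, rnorm(8), s, noise_seed = 2700 + i)
    })
    tr <- 1:2000; te <- 2001:3000
    m <- fit_maxvar(lapply(recs, function(x) x[, tr]))
    y <- project(m, recs[[1]][, te], 1)[1, ]
    abs(cor(y, lat$samples[te]))
  }, numeric(1))
  expect_gt(rec_cor[3], 0.8)   # snr = 1
  expect_gt(rec_cor[4], 0.8)   # snr = 2
  expect_true(all(diff(rec_cor) > -0.02))   # non-decreasing within noise
})

test_that("activation patterns behave as forward models", {
  # identity-filter white noise: pattern proportional to a covariance column
  set.seed(28)
  Z <- matrix(rnorm(5 * 400), 5)
  m <- list(filters = list(a = diag(5)), means = list(a = rowMeans(Z)),
            subjects = "a", n_components = 5L)
  class(m) <- "mcca_model"
  ap <- activation_pattern(m, Z, "a", component = 2L)
  Zc <- Z - rowMeans(Z)
  Sz <- tcrossprod(Zc) / ncol(Z)
  expect_gt(abs(cosine(ap$pattern, Sz[, 2])), 1 - 1e-8)

  # single-source recovery of the true mixing vector
  cellA <- make_cell(4, 2, n_channels = 8, duration_s = 20, fs = 100, seed = 28)
  mf <- fit_maxvar(cellA$recs)
  apA <- activation_pattern(mf, cellA$recs[[1]], "s01")
  expect_gt(abs(cosine(apA$pattern, cellA$mixing[[1]])), 0.95)

  # equivariance: re-mixing one subject's sensors leaves the pattern direction
  A <- matrix(rnorm(64), 8); recs2 <- cellA$recs
  recs2[["s01"]] <- A %*% recs2[["s01"]]
  mf2 <- fit_maxvar(recs2)
  ap2 <- activation_pattern(mf2, recs2[["s01"]], "s01")
  expect_gt(abs(cosine(ap2$pattern, A %*% apA$pattern)), 0.99)
})

test_that("contract errors reference the zero-padding and rank requirements", {
  set.seed(29)
  Z1 <- matrix(rnorm(4 * 100), 4)
  Z2 <- matrix(rnorm(4 * 90), 4)
  expect_error(fit_maxvar(list(Z1, Z2)), "zeros")
  expect_error(fit_maxvar(list(Z1)), "at least 2")
  low <- outer(rnorm(4), rnorm(100))          # rank 1
  expect_error(fit_maxvar(list(low, Z1), n_components = 3), "rank")
})
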