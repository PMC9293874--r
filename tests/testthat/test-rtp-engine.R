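# Smoothing, drift basis, percent scaling, streaming regression.

test_that("masked Gaussian smoothing preserves constants and total intensity", {
  vol <- array(1, c(12, 12, 12))
  mask <- array(TRUE, c(12, 12, 12))
  expect_equal(gaussian_smooth(vol, 0, 2, mask), vol)      # fwhm 0 = identity
  sm <- gaussian_smooth(vol * 7, 6, 2, mask)
  expect_equal(sm, vol * 7, tolerance = 1e-12)             # constant in mask
  # delta image in the mask interior: total intensity conserved
  # (kernel-sum oracle = 1; kernel support must clear the border
  # renormalization zone, i.e. two kernel radii from every face)
  delta <- array(0, c(28, 28, 28))
  delta[14, 14, 14] <- 1
  smd <- gaussian_smooth(delta, 6, 2, array(TRUE, c(28, 28, 28)))
  expect_equal(sum(smd), 1, tolerance = 1e-9)
  expect_error(gaussian_smooth(vol, 6, 0), "positive")
})

test_that("smoothing restricted to a mask renormalizes at its border", {
  mask <- array(FALSE, c(10, 10, 10))
  mask[3:8, 3:8, 3:8] <- TRUE
  vol <- array(5, c(10, 10, 10))
  sm <- gaussian_smooth(vol, 6, 2, mask)
  expect_equal(sm[mask], rep(5, sum(mask)), tolerance = 1e-12)
  expect_true(all(sm[!mask] == 0))
})

test_that("Legendre basis follows the Bonnet recurrence on [-1, 1]", {
  b <- legendre_basis(101, 3)
  expect_equal(b[, "leg0"], rep(1, 101))
  expect_equal(unname(b[1, "leg1"]), -1)
  expect_equal(unname(b[101, "leg1"]), 1)
  x <- seq(-1, 1, length.out = 101)
  expect_equal(b[, "leg2"], (3 * x^2 - 1) / 2, tolerance = 1e-12)
  expect_equal(b[, "leg3"], (5 * x^3 - 3 * x) / 2, tolerance = 1e-12)
  # numeric Gram oracle: near-diagonal for n >= 100
  g <- crossprod(legendre_basis(200, 4)) / 200
  off <- g - diag(diag(g))
  expect_lt(max(abs(off)), 0.02)
})

test_that("percent scaling freezes the baseline window", {
  x <- matrix(200, 25, 2)
  x[21, 1] <- 202
  p <- scale_to_percent(x, 19)
  expect_equal(p[21, 1], 1)
  expect_equal(p[20, 1], 0)
  expect_true(all(is.na(p[1:19, ])))
  # the baseline ignores later data entirely
  x2 <- x
  x2[20:25, ] <- 1e6
  expect_equal(attr(scale_to_percent(x2, 19), "baseline"),
               attr(scale_to_percent(x, 19), "baseline"))
  # near-zero baseline voxels are excluded with a warning
  x3 <- cbind(x[, 1], 0)
  expect_warning(p3 <- scale_to_percent(x3, 19), "near-zero")
  expect_true(all(is.na(p3[, 2])))
})

test_that("intercept-only streaming regression removes the running mean", {
  set.seed(2)
  y <- rnorm(40)
  st <- rtp_init(1, gate_extra = 0)
  res <- rep(NA_real_, 40)
  for (v in 1:40) {
    out <- rtp_step(st, y[v], 1)
    st <- out$state
    res[v] <- out$residual
  }
  expect_equal(res[5:40], vapply(5:40, function(v) y[v] - mean(y[1:v]), 0),
               tolerance = 1e-12)
})

test_that("signals built from the nuisance basis are removed exactly", {
  set.seed(3)
  n <- 120
  X <- cbind(1, legendre_basis(n, 3)[, -1], matrix(rnorm(n * 4), n))
  beta <- rnorm(ncol(X))
  y <- drop(X %*% beta)
  st <- rtp_init(ncol(X))
  res <- c()
  for (v in 1:n) {
    out <- rtp_step(st, y[v], X[v, ])
    st <- out$state
    if (out$exported) res <- c(res, out$residual)
  }
  expect_lt(max(abs(res)), 1e-8)
})

test_that("streaming OLS equals naive per-TR refits from scratch", {
  set.seed(11)
  n <- 150
  k <- 12
  X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
  y <- drop(X %*% rnorm(k)) + rnorm(n)
  st <- rtp_init(k)
  res <- rep(NA_real_, n)
  for (v in 1:n) {
    out <- rtp_step(st, y[v], X[v, ])
    st <- out$state
    res[v] <- out$residual
  }
  naive <- rep(NA_real_, n)
  for (v in (k + 5):n) {
    b <- qr.coef(qr(X[1:v, , drop = FALSE]), y[1:v])
    naive[v] <- y[v] - sum(X[v, ] * b)
  }
  expect_equal(res, naive, tolerance = 1e-6)
  # warm-up gate: nothing exported before k + 5 samples
  expect_true(all(is.na(res[1:(k + 4)])))
})

test_that("protected columns keep their contribution in the residual", {
  set.seed(5)
  n <- 100
  task <- hrf_convolve(rep(c(0, 1), each = 25)[rep(1:50, 2)], tr = 2)
  nuis <- cbind(1, legendre_basis(n, 1)[, -1])
  y <- 2 * task + drop(nuis %*% c(0.5, -1)) + rnorm(n, sd = 0.01)
  st <- rtp_init(3, protect = 1L)
  res <- rep(NA_real_, n)
  # the task column is still all-zero at the warm-up gate, so the first
  # steps legitimately warn about rank deficiency
  suppressWarnings(for (v in 1:n) {
    out <- rtp_step(st, y[v], c(task[v], nuis[v, ]))
    st <- out$state
    res[v] <- out$residual
  })
  late <- 60:100
  expect_equal(res[late], (2 * task)[late], tolerance = 0.15)
})

test_that("duplicate design columns are dropped with a warning", {
  set.seed(6)
  n <- 60
  x1 <- rnorm(n)
  X <- cbind(1, x1, x1)                       # exact duplicate
  y <- rnorm(n)
  st <- rtp_init(3)
  expect_warning({
    for (v in 1:n) {
      out <- rtp_step(st, y[v], X[v, ])
      st <- out$state
    }
  }, "rank-deficient")
  expect_true(length(st$dropped) >= 1)
})

test_that("the real-time chain recovers the deactivation and is deterministic", {
  sub <- noise_free_subject()
  rt <- suppressWarnings(run_realtime(sub, "NF1"))
  expect_equal(nrow(rt), 213)
  lab <- rt$condition
  late_focus <- which(lab == "FOCUS" & rt$volume > 180)
  expect_lt(mean(rt$residual[late_focus]), -0.3)   # negative plateau
  rt2 <- suppressWarnings(run_realtime(sub, "NF1"))
  expect_identical(tibble::as_tibble(rt), tibble::as_tibble(rt2))
  # no exported value before the gate
  expect_true(all(is.na(rt$residual[!rt$exported])))
  expect_false(any(rt$exported[1:20]))
})

test_that("ROI-mean regression equals voxelwise-then-average residuals", {
  # shared regressors: regressing the mean equals averaging voxel residuals
  set.seed(9)
  n <- 80
  X <- cbind(1, legendre_basis(n, 2)[, -1], rnorm(n))
  Y <- matrix(rnorm(n * 6), n)
  b <- qr.coef(qr(X), Y)
  vox_res <- Y - X %*% b
  ym <- rowMeans(Y)
  mean_res <- ym - X %*% qr.coef(qr(X), ym)
  expect_equal(drop(mean_res), rowMeans(vox_res), tolerance = 1e-8)
})
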