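# Despiking, offline preprocessing, GLM, ROI extraction, t-maps, PPI.

test_that("despiking clips only outliers", {
  expect_equal(despike(rep(3, 20)), rep(3, 20))
  set.seed(1)
  x <- rnorm(100)
  xs <- x
  xs[50] <- x[50] + 100 * mad(x)
  d <- despike(xs)
  expect_lt(abs(d[50]), abs(xs[50]))
  med <- stats::runmed(xs, 11, endrule = "median")
  expect_equal(d[50], med[50] + 4 * mad(xs - med))   # clipped to the boundary
  # spike-free Gaussian series: fewer than 1% of points altered
  changed <- mean(despike(x) != x)
  expect_lt(changed, 0.01)
})

test_that("offline preprocessing drops 5 volumes and centers voxels", {
  sub <- noisy_subject()
  prep <- preprocess_offline(sub, "NF1")
  raw_len <- dim(sub$runs$NF1$volumes$data)[4]
  expect_equal(nrow(prep$series), raw_len - 5)
  expect_equal(prep$drop_lead, 2)
  # percent scaling against the voxel's own run mean: columns average zero
  expect_lt(max(abs(colMeans(prep$series))), 1e-9)
})

test_that("physiological variance is removed from pure-physio voxels", {
  sub <- noisy_subject()
  sched <- sub$runs$NF1$schedule
  n <- attr(sched, "n_volumes")
  vt <- (2 + seq_len(n - 2) - 1) * 2
  r8 <- retroicor_regressors(sub$runs$NF1$physio, vt)
  sig <- 500 * (1 + drop(r8 %*% c(0.8, 0.6, 0.4, 0.3, 0.5, 0.3, 0.2, 0.1)) / 100)
  # regression step of the offline chain, applied to a constructed voxel
  xp <- scale(cbind(r8, rvt_regressor(sub$runs$NF1$physio, vt)),
              center = TRUE, scale = FALSE)
  res <- sig - xp %*% qr.coef(qr(xp), sig)
  expect_lt(stats::var(drop(res)) / stats::var(sig), 0.01)
})

test_that("the offline design matrix has the documented 23 columns", {
  sub <- noisy_subject()
  prep <- preprocess_offline(sub, "NF1")
  comp <- as.integer(test_geom()$compartments)[prep$vox_keep]
  x <- build_design_matrix(prep$schedule, prep$motion,
                           prep$series[, comp == 3L, drop = FALSE],
                           rowMeans(prep$series[, comp == 2L, drop = FALSE]),
                           drop_lead = prep$drop_lead)
  expect_equal(ncol(x), 2 + 12 + 3 + 1 + 5)
  pcs <- x[, c("vent_pc1", "vent_pc2", "vent_pc3")]
  expect_equal(unname(crossprod(pcs)), diag(3), tolerance = 1e-8)
  expect_true(all(c("FOCUS", "DESCRIBE", "wm", "leg0", "leg4") %in%
                    colnames(x)))
})

test_that("zero motion loses its derivative columns with a warning", {
  sub <- noise_free_subject()
  prep <- preprocess_offline(sub, "NF1", despike_series = FALSE)
  comp <- as.integer(test_geom()$compartments)[prep$vox_keep]
  w <- capture_warnings(
    x <- build_design_matrix(prep$schedule, prep$motion,
                             prep$series[, comp == 3L, drop = FALSE],
                             rowMeans(prep$series[, comp == 2L,
                                                  drop = FALSE]),
                             drop_lead = prep$drop_lead))
  expect_true(any(grepl("zero", w)))
  expect_false(any(grepl("^d_", colnames(x))))
})

test_that("GLM contrasts are additive and degenerate fits behave", {
  sub <- noisy_subject()
  prep <- preprocess_offline(sub, "NF1")
  fit <- fit_offline_glm(prep)
  expect_equal(fit$contrasts["FOCUS_VS_DESCRIBE", ],
               fit$contrasts["FOCUS_VS_REST", ] -
                 fit$contrasts["DESCRIBE_VS_REST", ],
               tolerance = 1e-10)
  # intercept-only design with zero-mean data: all betas zero
  y <- scale(matrix(rnorm(200), 50), center = TRUE, scale = FALSE)
  d0 <- matrix(1, 50, 1, dimnames = list(NULL, "leg0"))
  f0 <- fit_run_glm(y, d0)
  expect_lt(max(abs(f0$betas)), 1e-12)
  expect_error(fit_run_glm(y[1:5, ], d0[1:5, , drop = FALSE]),
               "degrees of freedom")
})

test_that("censoring rows equals deleting them before the fit", {
  set.seed(3)
  n <- 80
  x <- cbind(FOCUS = hrf_convolve(rep(c(0, 1), each = 20)[rep(1:40, 2)],
                                  tr = 2),
             leg0 = 1, leg1 = seq(-1, 1, length.out = n))
  y <- drop(x %*% c(-0.5, 0.1, 0.4)) + rnorm(n, sd = 0.2)
  cen <- rep(FALSE, n)
  cen[c(10, 33, 57)] <- TRUE
  f1 <- fit_run_glm(y, x, censor = cen)
  f2 <- fit_run_glm(y[!cen], x[!cen, ])
  expect_equal(f1$betas, f2$betas, tolerance = 1e-10)
  expect_equal(f1$dof, f2$dof)
})

test_that("single-subject recovery lands near the simulated truth", {
  sub <- noisy_subject()
  psc <- roi_psc_offline(sub, "NF1")
  expect_equal(psc, -0.7, tolerance = 0.2)
  # and matches the full voxelwise route exactly on the ROI mean
  fit <- fit_offline_glm(preprocess_offline(sub, "NF1"))
  expect_equal(psc, extract_roi_psc(fit), tolerance = 1e-9)
})

test_that("ROI extraction averages in-sphere voxels (brute-force oracle)", {
  geom <- default_geometry(24)
  # 7-mm sphere on the 2-mm grid: brute-force voxel enumeration
  idx <- roi_voxels(geom$roi, geom$dim, geom$affine)
  expect_equal(length(idx), 179)
  map <- rep(0.37, prod(geom$dim))
  fake <- list(map = map, vox_keep = seq_along(map), geometry = geom)
  expect_equal(extract_roi_psc(fake, geom$roi), 0.37)
  far <- roi_spec(c(500, 500, 500), 7)
  expect_error(extract_roi_psc(fake, far), "intersect")
})

test_that("group t-maps mask degenerate voxels and control the null rate", {
  dims <- c(6, 6, 6)
  maps_const <- replicate(5, array(2, dims), simplify = FALSE)
  tt <- group_voxel_ttest(maps_const)
  expect_true(all(is.na(tt$t)))                       # zero variance masked
  set.seed(8)
  maps <- replicate(8, array(3 + rnorm(prod(dims), sd = 0.1), dims),
                    simplify = FALSE)
  tt2 <- group_voxel_ttest(maps)
  expect_true(all(tt2$t > 0))
  # null maps: voxelwise p < 0.001 at about the nominal rate
  nulls <- matrix(rnorm(12 * 4000), 12)
  tt3 <- group_voxel_ttest(nulls, dims = c(20, 20, 10))
  rate <- mean(tt3$p < 0.001)
  expect_lt(rate, 0.001 + 3 * sqrt(0.001 / 4000) + 0.001)
})

test_that("clusters are face-connected components with peak bookkeeping", {
  dims <- c(8, 8, 8)
  base <- array(0, dims)
  blob1 <- base; blob1[2:3, 2:3, 2] <- 1
  blob2 <- base; blob2[6:7, 6, 6] <- 1
  set.seed(2)
  maps <- replicate(10, base + 5 * (blob1 + blob2) +
                      array(rnorm(prod(dims), sd = 0.5), dims),
                    simplify = FALSE)
  tt <- group_voxel_ttest(maps, p_thresh = 1e-6)
  cl <- tt$clusters
  expect_gte(nrow(cl), 2)
  big <- cl[cl$sign == 1, ]
  expect_setequal(big$extent[1:2], c(4, 2))
})

test_that("PPI recovers the sign of task-modulated coupling", {
  s <- build_run_schedule("NF1")
  n <- attr(s, "n_volumes")
  hits <- 0
  for (seed in 1:20) {
    withr::with_seed(seed, {
      roi <- as.numeric(arima.sim(list(ar = 0.3), n))
      task01 <- boxcar(s, "FOCUS")
      y <- 0.5 * roi + 0.6 * task01 * roi + rnorm(n, sd = 0.5)
      fd <- runif(n, 0, 0.2)
      fd[sample(n, 5)] <- 0.5
      p <- run_ppi(y, roi, s, nuisance = cbind(leg0 = rep(1, n)), fd = fd)
      if (p$beta[1] > 0) hits <- hits + 1
    })
  }
  expect_gte(hits, 18)
})

test_that("PPI validates inputs and censors strictly above threshold", {
  s <- build_run_schedule("NF1")
  n <- attr(s, "n_volumes")
  expect_error(run_ppi(rnorm(n), rep(0, n), s), "identically zero")
  fd <- rep(0.1, n)
  fd[2] <- 0.4
  fd[10] <- 0.3                                # boundary: not censored
  p <- run_ppi(rnorm(n), rnorm(n), s, nuisance = cbind(leg0 = rep(1, n)),
               fd = fd)
  expect_equal(p$censored, 2L)
  expect_error(run_ppi(rnorm(n), rnorm(n), s, fd = rep(1, n)), "50%")
})
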