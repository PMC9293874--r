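# Real-time per-volume processing: smoothing, percent scaling over the first
# 19 TRs, streaming nuisance regression, ROI residual export.

#' Spherical region-of-interest specification
#'
#' @param center world coordinates in mm; default the PCC target (-5, -55, 23).
#' @param radius sphere radius in mm (default 7). A voxel belongs to the
#'   sphere when its center lies within `radius` of `center` (Euclidean).
#' @return list of class `roi_spec`.
#' @export
roi_spec <- function(center = c(-5, -55, 23), radius = 7) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "roi_spec")
}

#' Linear voxel indices of a spherical ROI
#'
#' @param roi an [roi_spec()].
#' @param dims 3-element grid dimensions.
#' @param affine 4x4 voxel-to-world affine (0-based voxel indices).
#' @return integer vector of linear voxel indices.
#' @export
roi_voxels <- function(roi, dims, affine) {
  ijk <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  world <- ijk %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
  d2 <- rowSums(sweep(world, 2, roi$center)^2)
  which(d2 <= roi$radius^2)
}

#' Masked separable Gaussian smoothing
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 log 2))` per axis in
#' voxel units. Smoothing is restricted to the mask by normalized
#' convolution: `smooth(x * m) / smooth(m)`, so a constant image inside the
#' mask is left unchanged. Out-of-mask voxels are set to zero.
#'
#' @param data 3D array (one volume) or 4D array (volumes along dim 4).
#' @param fwhm_mm full width at half maximum in mm; 0 is the identity.
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @param mask logical 3D array; default all `TRUE`.
#' @return smoothed array, same shape as `data`.
#' @export
gaussian_smooth <- function(data, fwhm_mm, voxel_size, mask = NULL) {
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  stopifnot(fwhm_mm >= 0)
  d <- dim(data)
  is3d <- length(d) == 3
  if (is3d) { dim(data) <- c(d, 1); d <- dim(data) }
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (fwhm_mm == 0) {
    out <- data * as.numeric(mask)
    if (is3d) dim(out) <- d[1:3]
    return(out)
  }
  voxel_size <- rep(voxel_size, length.out = 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  sm <- lapply(1:3, function(a) smooth_matrix_1d(d[a], sigma[a]))
  conv3 <- function(x) {
    # x: nx x ny x nz x nt; contract each spatial axis with its kernel matrix
    dd <- dim(x)
    x <- array(sm[[1]] %*% matrix(x, dd[1]), dd)
    x <- aperm(x, c(2, 1, 3, 4))
    x <- aperm(array(sm[[2]] %*% matrix(x, dd[2]), dd[c(2, 1, 3, 4)]),
               c(2, 1, 3, 4))
    x <- aperm(x, c(3, 2, 1, 4))
    aperm(array(sm[[3]] %*% matrix(x, dd[3]), dd[c(3, 2, 1, 4)]),
          c(3, 2, 1, 4))
  }
  m <- as.numeric(mask)
  num <- conv3(data * array(m, d))
  den <- conv3(array(m, c(d[1:3], 1)))[, , , 1]
  den[den <= 0] <- Inf
  out <- num / array(rep(den, d[4]), d)
  out <- out * array(m, d)
  if (is3d) dim(out) <- d[1:3]
  out
}

# dense n x n matrix applying a normalized 1D Gaussian kernel with
# zero-padding at the edges (rows renormalized by the mask term instead)
smooth_matrix_1d <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    m[i, j[ok]] <- k[ok]
  }
  m
}

#' Legendre polynomial drift basis
#'
#' Legendre polynomials of orders `0..order` evaluated on the volume index
#' mapped linearly onto `[-1, 1]`, via the Bonnet recurrence.
#'
#' @param n_volumes number of volumes (rows).
#' @param order highest polynomial order (>= 0).
#' @return matrix `n_volumes x (order + 1)`, columns named `leg0, leg1, ...`.
#' @export
legendre_basis <- function(n_volumes, order) {
  stopifnot(order >= 0, n_volumes >= 1)
  x <- if (n_volumes == 1) 0 else seq(-1, 1, length.out = n_volumes)
  p <- matrix(0, n_volumes, order + 1)
  p[, 1] <- 1
  if (order >= 1) p[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      p[, k + 1] <- ((2 * k - 1) * x * p[, k] - (k - 1) * p[, k - 1]) / k
    }
  }
  colnames(p) <- paste0("leg", 0:order)
  p
}

#' Scale a series to percent change over a frozen baseline window
#'
#' Per-voxel baseline is the mean of the first `n_baseline` volumes (the
#' real-time chain uses 19 TRs inside the initial rest block); volumes
#' before the window closes are withheld as warm-up (`NA`). Baseline voxels
#' with near-zero mean are excluded from the mask with a warning.
#'
#' @param x numeric matrix (time x voxel) or vector.
#' @param n_baseline baseline window length in volumes.
#' @param eps threshold below which a baseline mean counts as zero.
#' @return object like `x` in percent units, first `n_baseline` rows `NA`;
#'   attribute `baseline` holds the frozen means, attribute `excluded` any
#'   excluded voxel columns.
#' @export
scale_to_percent <- function(x, n_baseline = 19, eps = 1e-6) {
  v <- is.null(dim(x))
  m <- if (v) matrix(x, ncol = 1) else x
  stopifnot(nrow(m) > n_baseline)
  base <- colMeans(m[seq_len(n_baseline), , drop = FALSE])
  excluded <- which(abs(base) < eps)
  if (length(excluded))
    warning(length(excluded), " voxel(s) with near-zero baseline excluded")
  base[excluded] <- NA_real_
  out <- 100 * sweep(sweep(m, 2, base), 2, base, "/")
  out[seq_len(n_baseline), ] <- NA_real_
  if (v) out <- drop(out)
  structure(out, baseline = base, excluded = excluded)
}

#' Initialize streaming regression state
#'
#' The real-time engine maintains a QR factorization of the accumulated
#' design incrementally (recursive least squares with Givens rotations): one
#' O(k^2) update per volume, numerically equivalent to refitting the full
#' OLS from scratch at every TR.
#'
#' @param k number of design columns.
#' @param col_names optional regressor names.
#' @param gate_extra exported values start once samples >= `k + gate_extra`.
#' @param protect indices of *protected* columns (e.g. the task model): they
#'   take part in the fit so nuisance estimates are not contaminated by task
#'   variance, but their fitted contribution is retained in the exported
#'   residual.
#' @return list of class `rtp_state`.
#' @export
rtp_init <- function(k, col_names = NULL, gate_extra = 5,
                     protect = integer(0)) {
  structure(list(k = k, n = 0L,
                 r = matrix(0, k, k),          # upper-triangular QR factor
                 z = numeric(k),               # Q'y, first k components
                 col_scale = rep(NA_real_, k), # running column norms
                 col_names = col_names %||% paste0("x", seq_len(k)),
                 gate = k + gate_extra, dropped = integer(0),
                 protect = as.integer(protect)),
            class = "rtp_state")
}

# Givens-rotation row update of the triangular factor: after the call,
# (r, z) represent the QR factorization of the design with (x, y) appended.
givens_update <- function(r, z, x, y) {
  k <- length(x)
  for (i in seq_len(k)) {
    if (x[i] == 0) next
    h <- sqrt(r[i, i]^2 + x[i]^2)
    c_ <- r[i, i] / h
    s_ <- x[i] / h
    cols <- i:k
    ri <- r[i, cols]
    r[i, cols] <- c_ * ri + s_ * x[cols]
    x[cols] <- -s_ * ri + c_ * x[cols]
    zi <- z[i]
    z[i] <- c_ * zi + s_ * y
    y <- -s_ * zi + c_ * y
  }
  list(r = r, z = z)
}

#' One streaming-regression step
#'
#' Appends the new sample to the accumulated design, refits the OLS of all
#' samples so far via the updated normal equations, and exports the residual
#' of the *current* volume with the nuisance partition removed (protected
#' columns, if any, keep their fitted contribution). Before the warm-up gate
#' (samples >= regressors + 5) no value is exported. A rank-deficient design
#' drops dependent columns (recorded in `state$dropped`) and continues with a
#' warning.
#'
#' @param state an `rtp_state`.
#' @param y_new scaled ROI-mean value of the current volume (percent).
#' @param x_new design row for the current volume (length `k`).
#' @return list with `state` (updated), `residual` (numeric or `NA` during
#'   warm-up) and `exported` (logical).
#' @export
rtp_step <- function(state, y_new, x_new) {
  stopifnot(inherits(state, "rtp_state"), length(x_new) == state$k)
  x_new <- as.numeric(x_new)
  up <- givens_update(state$r, state$z, x_new, y_new)
  state$r <- up$r
  state$z <- up$z
  state$col_scale <- pmax(state$col_scale, abs(x_new), na.rm = TRUE)
  state$n <- state$n + 1L
  if (state$n < state$gate)
    return(list(state = state, residual = NA_real_, exported = FALSE))
  # rank check on the triangular diagonal, relative to the column scale
  diag_r <- abs(diag(state$r))
  tol <- 1e-7 * pmax(state$col_scale, 1) * sqrt(state$n)
  dropped <- which(diag_r < tol)
  if (length(dropped) && !identical(dropped, state$dropped)) {
    warning("rank-deficient design: dropping column(s) ",
            paste(state$col_names[dropped], collapse = ", "))
    state$dropped <- dropped
  }
  # back-substitution with dropped columns pinned to zero
  beta <- numeric(state$k)
  for (i in state$k:1) {
    if (i %in% dropped) next
    j <- if (i < state$k) (i + 1):state$k else integer(0)
    beta[i] <- (state$z[i] - sum(state$r[i, j] * beta[j])) / state$r[i, i]
  }
  nuis <- setdiff(seq_len(state$k), state$protect)
  res <- y_new - sum(x_new[nuis] * beta[nuis])
  list(state = state, residual = res, exported = TRUE)
}

#' Real-time processing configuration
#'
#' @param fwhm_mm spatial smoothing kernel FWHM in mm.
#' @param n_baseline percent-scaling baseline window, volumes.
#' @param legendre_order real-time Legendre drift order.
#' @param gate_extra extra samples required beyond the regressor count before
#'   residual export starts.
#' @return list of class `rtp_config`.
#' @export
rtp_config <- function(fwhm_mm = 6, n_baseline = 19, legendre_order = 3,
                       gate_extra = 5) {
  structure(list(fwhm_mm = fwhm_mm, n_baseline = n_baseline,
                 legendre_order = legendre_order, gate_extra = gate_extra),
            class = "rtp_config")
}

#' Run the real-time chain over one run
#'
#' Per volume: strip dummies, smooth within the brain mask, scale to percent
#' change against the frozen 19-TR baseline, assemble the design row
#' (protected HRF-convolved task model, six motion parameters, eight
#' RETROICOR regressors at the volume time computed from physiology observed
#' so far, white-matter mean, ventricle mean, Legendre drift terms), update
#' the streaming regression of the scaled ROI mean, and export the
#' current-volume noise-reduced value once past the warm-up gate. The task
#' model is fitted but not subtracted, so the feedback signal retains the
#' task response while nuisance estimates stay uncontaminated by it; tissue
#' nuisance means are taken from unsmoothed data (eroded-mask equivalent).
#'
#' @param subject an `nf_subject`.
#' @param run run name present in `subject$runs`.
#' @param roi an [roi_spec()].
#' @param config an [rtp_config()].
#' @return tibble of class `rtp_result` with one row per retained volume:
#'   `volume`, `time`, `condition`, `roi_scaled`, `residual`, `exported`.
#'   Attributes: `log` (gate, dropped columns, regressor names), `run`,
#'   `schedule`.
#' @export
run_realtime <- function(subject, run, roi = roi_spec(),
                         config = rtp_config()) {
  stopifnot(inherits(subject, "nf_subject"))
  if (!run %in% names(subject$runs)) stop("subject has no run ", run)
  rr <- subject$runs[[run]]
  geom <- subject$geometry
  sched <- rr$schedule
  tr <- attr(sched, "tr")
  n <- attr(sched, "n_volumes")
  roi_idx <- roi_voxels(roi, geom$dim, geom$affine)
  if (!length(roi_idx)) stop("ROI does not intersect the grid")
  wm_idx <- which(geom$compartments == 2L)
  vent_idx <- which(geom$compartments == 3L)
  sm <- gaussian_smooth(rr$volumes$data, config$fwhm_mm, geom$voxel_size,
                        geom$mask)
  msm <- t(matrix(sm, prod(geom$dim), dim(sm)[4]))
  raw <- t(matrix(rr$volumes$data, prod(geom$dim), dim(rr$volumes$data)[4]))
  if (rr$volumes$n_dummy > 0) {
    msm <- msm[-seq_len(rr$volumes$n_dummy), , drop = FALSE]
    raw <- raw[-seq_len(rr$volumes$n_dummy), , drop = FALSE]
  }
  pct <- scale_to_percent(msm[, roi_idx, drop = FALSE], config$n_baseline)
  # tissue nuisance means come from unsmoothed data (the desk-scale
  # equivalent of eroded tissue masks: no smoothing leakage of the task
  # effect into the white-matter/ventricle summaries)
  pct_tis <- scale_to_percent(raw[, c(wm_idx, vent_idx), drop = FALSE],
                              config$n_baseline)
  y <- rowMeans(pct)
  wm <- rowMeans(pct_tis[, seq_along(wm_idx), drop = FALSE])
  vent <- rowMeans(pct_tis[, length(wm_idx) + seq_along(vent_idx),
                           drop = FALSE])
  leg <- legendre_basis(n, config$legendre_order)
  vt <- (seq_len(n) - 1) * tr
  peaks_all <- detect_cardiac_peaks(rr$physio)
  resp_all <- rr$physio$resp
  ptime <- rr$physio$time
  mot <- as.matrix(rr$motion)
  # protected task model: fitted jointly so nuisance betas are free of task
  # variance, but retained in the exported feedback signal
  task_cols <- NULL
  if (any(c("FOCUS", "DESCRIBE") %in% sched$condition)) {
    task_cols <- cbind(
      FOCUS = if ("FOCUS" %in% sched$condition)
        hrf_convolve(boxcar(sched, "FOCUS"), tr = tr),
      DESCRIBE = if ("DESCRIBE" %in% sched$condition)
        hrf_convolve(boxcar(sched, "DESCRIBE"), tr = tr))
  }
  n_task <- if (is.null(task_cols)) 0L else ncol(task_cols)
  k <- n_task + 6 + 8 + 1 + 1 + config$legendre_order + 1
  nm <- c(colnames(task_cols),
          colnames(mot),
          c("c_cos1", "c_sin1", "c_cos2", "c_sin2",
            "r_cos1", "r_sin1", "r_cos2", "r_sin2"),
          "wm", "vent", colnames(leg))
  state <- rtp_init(k, nm, config$gate_extra,
                    protect = seq_len(n_task))
  residual <- rep(NA_real_, n)
  exported <- logical(n)
  for (v in seq_len(n)) {
    if (v <= config$n_baseline) next
    # causality: physiology truncated to samples observed by this volume
    n_upto <- sum(ptime <= vt[v] + 1e-9)
    peaks_v <- peaks_all[peaks_all <= vt[v] + 1e-9]
    r8 <- if (length(peaks_v) >= 2) {
      phc <- suppressWarnings(cardiac_phase(peaks_v, vt[v]))
      phr <- respiratory_phase(resp_all[seq_len(n_upto)], vt[v])
      c(cos(phc), sin(phc), cos(2 * phc), sin(2 * phc),
        cos(phr), sin(phr), cos(2 * phr), sin(2 * phr))
    } else numeric(8)
    x_v <- c(if (n_task) task_cols[v, ], mot[v, ], r8, wm[v], vent[v],
             leg[v, ])
    st <- rtp_step(state, y[v], x_v)
    state <- st$state
    residual[v] <- st$residual
    exported[v] <- st$exported
  }
  out <- tibble::tibble(volume = 0:(n - 1), time = vt,
                        condition = labels_for_volumes(sched),
                        roi_scaled = as.numeric(y), residual = residual,
                        exported = exported)
  structure(out,
            log = list(gate = state$gate, dropped = state$col_names[state$dropped],
                       regressors = nm, n_baseline = config$n_baseline),
            run = run, schedule = sched,
            class = c("rtp_result", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
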