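# Offline preprocessing, run-level GLM with PSC contrasts, ROI extraction,
# group t-maps, and PPI connectivity.

#' Despike a time series
#'
#' MAD-clip despiking: points further than `k` robust SDs from an 11-point
#' running median are replaced by the clip boundary
#' `runmed(x) +/- k * MAD(x - runmed(x))`.
#'
#' @param x numeric series, length >= 10.
#' @param window running-median window (odd).
#' @param k clip threshold in MAD units.
#' @return despiked series, same length.
#' @export
despike <- function(x, window = 11, k = 4) {
  stopifnot(length(x) >= 10)
  med <- stats::runmed(x, window, endrule = "median")
  s <- stats::mad(x - med)
  if (s == 0) return(x)
  pmin(pmax(x, med - k * s), med + k * s)
}

#' Offline preprocessing of one run
#'
#' Mirrors the offline chain: discard the first `n_discard` raw volumes
#' (dummies plus the first task volumes), despike each voxel, regress out the
#' RETROICOR basis and the RVT regressor (keeping each voxel's mean), then
#' scale each voxel to percent change relative to its own run mean. Voxels
#' with near-zero mean are dropped from the mask.
#'
#' @param subject an `nf_subject`.
#' @param run run name.
#' @param n_discard raw volumes discarded from the start of the run (default
#'   5: the 3 dummies plus 2 task volumes).
#' @param despike_series despike each voxel series first.
#' @param voxels optional linear voxel indices to restrict the analysis to
#'   (ROI-level fast path); default all mask voxels.
#' @return list of class `offline_run`: `series` (time x voxel percent
#'   matrix), `vox_keep` (kept linear voxel indices), `n_discard`,
#'   `drop_lead` (retained-grid volumes dropped, for design alignment),
#'   `schedule`, `geometry`, `motion`, `physio`, `fd`.
#' @export
preprocess_offline <- function(subject, run, n_discard = 5,
                               despike_series = TRUE, voxels = NULL) {
  stopifnot(inherits(subject, "nf_subject"))
  if (!run %in% names(subject$runs)) stop("subject has no run ", run)
  rr <- subject$runs[[run]]
  geom <- subject$geometry
  sched <- rr$schedule
  tr <- attr(sched, "tr")
  n_dummy <- rr$volumes$n_dummy
  stopifnot(n_discard >= n_dummy)
  drop_lead <- n_discard - n_dummy
  vox_all <- if (is.null(voxels)) seq_len(prod(geom$dim)) else sort(voxels)
  raw <- t(matrix(rr$volumes$data, prod(geom$dim),
                  dim(rr$volumes$data)[4])[vox_all, , drop = FALSE])
  m <- raw[-seq_len(n_discard), , drop = FALSE]
  nt <- nrow(m)
  if (despike_series) m <- apply(m, 2, despike)
  # volume times on the retained grid, shifted by the extra dropped volumes
  vt <- (drop_lead + seq_len(nt) - 1) * tr
  r8 <- retroicor_regressors(rr$physio, vt)
  rvt <- rvt_regressor(rr$physio, vt)
  xp <- scale(cbind(r8, rvt = rvt), center = TRUE, scale = FALSE)
  # remove physiological components, keeping each voxel's mean; the task
  # model joins the fit (protected) so physiological betas are estimated
  # free of task variance and no task amplitude is stripped here
  tcols <- NULL
  if (any(c("FOCUS", "DESCRIBE") %in% sched$condition)) {
    keep_rows <- (drop_lead + 1):attr(sched, "n_volumes")
    tcols <- cbind(
      if ("FOCUS" %in% sched$condition)
        hrf_convolve(boxcar(sched, "FOCUS"), tr = tr)[keep_rows],
      if ("DESCRIBE" %in% sched$condition)
        hrf_convolve(boxcar(sched, "DESCRIBE"), tr = tr)[keep_rows])
  }
  n_prot <- if (is.null(tcols)) 0L else ncol(tcols)
  beta <- qr.coef(qr(cbind(tcols, xp)), m)
  m <- m - xp %*% beta[n_prot + seq_len(ncol(xp)), , drop = FALSE]
  mu <- colMeans(m)
  keep_local <- which(abs(mu) > 1e-6 & as.logical(geom$mask)[vox_all])
  vox_keep <- vox_all[keep_local]
  pct <- 100 * sweep(sweep(m[, keep_local, drop = FALSE], 2, mu[keep_local]),
                     2, mu[keep_local], "/")
  fd <- framewise_displacement(rr$motion)
  structure(list(series = pct, vox_keep = vox_keep, n_discard = n_discard,
                 drop_lead = drop_lead, schedule = sched, geometry = geom,
                 motion = rr$motion, physio = rr$physio, fd = fd),
            class = "offline_run")
}

#' Offline GLM design matrix
#'
#' Columns: HRF-convolved Focus and Describe boxcars, 12 motion regressors
#' (six parameters and their backward-difference derivatives, first row 0),
#' three ventricle principal components (centered voxel series, unit norm,
#' sign fixed so the largest-magnitude loading is positive), the white-matter
#' average, and Legendre polynomials of order 0..4 — 23 columns. All-zero or
#' linearly dependent columns are dropped with a warning.
#'
#' @param schedule an `nf_schedule`.
#' @param motion motion trace (6 columns, retained-grid rows).
#' @param ventricle_series time x voxel matrix of ventricle voxels (percent).
#' @param wm_series white-matter average series (or time x voxel matrix).
#' @param drop_lead leading retained-grid volumes dropped offline.
#' @param legendre_order polynomial drift order.
#' @param hrf [hrf_params()].
#' @return design matrix with named columns and attribute `dropped`.
#' @export
build_design_matrix <- function(schedule, motion, ventricle_series, wm_series,
                                drop_lead = 2, legendre_order = 4,
                                hrf = hrf_params()) {
  tr <- attr(schedule, "tr")
  n_full <- attr(schedule, "n_volumes")
  keep <- (drop_lead + 1):n_full
  task <- cbind(
    FOCUS = hrf_convolve(boxcar(schedule, "FOCUS"), hrf, tr),
    DESCRIBE = hrf_convolve(boxcar(schedule, "DESCRIBE"), hrf, tr))[keep, ,
                                                                    drop = FALSE]
  mot <- as.matrix(motion)[keep, , drop = FALSE]
  dmot <- rbind(0, diff(mot))
  colnames(dmot) <- paste0("d_", colnames(mot))
  vent_pc <- ventricle_pcs(ventricle_series, 3)
  wm <- if (is.matrix(wm_series)) rowMeans(wm_series) else as.numeric(wm_series)
  leg <- legendre_basis(length(keep), legendre_order)
  x <- cbind(task, mot, dmot, vent_pc, wm = wm, leg)
  prune_design(x)
}

# drop all-zero and linearly dependent columns, warn with names
prune_design <- function(x, tol = 1e-10) {
  zero <- which(colSums(abs(x)) < tol)
  if (length(zero)) {
    warning("dropping all-zero design column(s): ",
            paste(colnames(x)[zero], collapse = ", "))
    x <- x[, -zero, drop = FALSE]
  }
  q <- qr(x, tol = 1e-8)
  if (q$rank < ncol(x)) {
    dep <- colnames(x)[sort(q$pivot[(q$rank + 1):ncol(x)])]
    warning("dropping linearly dependent design column(s): ",
            paste(dep, collapse = ", "))
    x <- x[, setdiff(colnames(x), dep), drop = FALSE]
  }
  structure(x, dropped = setdiff(c(names(zero), character(0)), colnames(x)))
}

#' Ventricle principal components
#'
#' SVD of the centered time x voxel matrix; returns the first `k` left
#' singular vectors (unit norm), each sign-flipped so its largest-magnitude
#' voxel loading is positive.
#'
#' @param series time x voxel matrix.
#' @param k number of components.
#' @return matrix time x k, columns `vent_pc1..k`.
#' @export
ventricle_pcs <- function(series, k = 3) {
  stopifnot(ncol(series) >= k)
  s <- svd(scale(series, center = TRUE, scale = FALSE), nu = k, nv = k)
  u <- s$u
  for (j in seq_len(k)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) u[, j] <- -u[, j]
  }
  colnames(u) <- paste0("vent_pc", seq_len(k))
  u
}

#' Fit the run-level GLM
#'
#' Ordinary least squares of each (percent-scaled) voxel series on the
#' design. With a unit-peak HRF on percent-scaled data, task betas are
#' percent-signal-change estimates directly. Contrasts: Focus-Describe,
#' Focus-Rest and Describe-Rest (rest is the implicit baseline, so the task
#' betas are the versus-rest contrasts).
#'
#' @param series time x voxel matrix (or vector for a single ROI series).
#' @param design design matrix from [build_design_matrix()].
#' @param censor optional logical vector, `TRUE` = drop that volume.
#' @return list of class `nf_glm`: `betas` (regressor x voxel), `contrasts`
#'   (3 x voxel), `sigma2`, `dof`, `design`, `censor`.
#' @export
fit_run_glm <- function(series, design, censor = NULL) {
  y <- if (is.null(dim(series))) matrix(series, ncol = 1) else series
  x <- as.matrix(design)
  stopifnot(nrow(y) == nrow(x))
  if (!is.null(censor)) {
    stopifnot(length(censor) == nrow(x))
    y <- y[!censor, , drop = FALSE]
    x <- x[!censor, , drop = FALSE]
  }
  q <- qr(x)
  if (q$rank < ncol(x)) stop("design matrix is rank deficient after pruning")
  dof <- nrow(x) - ncol(x)
  if (dof < 10) stop("insufficient degrees of freedom: ", dof)
  betas <- qr.coef(q, y)
  res <- y - x %*% betas
  sigma2 <- colSums(res^2) / dof
  bf <- if ("FOCUS" %in% rownames(betas)) betas["FOCUS", ] else 0
  bd <- if ("DESCRIBE" %in% rownames(betas)) betas["DESCRIBE", ] else 0
  contrasts <- rbind(FOCUS_VS_DESCRIBE = bf - bd,
                     FOCUS_VS_REST = bf,
                     DESCRIBE_VS_REST = bd)
  structure(list(betas = betas, contrasts = contrasts, sigma2 = sigma2,
                 dof = dof, design = x, censor = censor),
            class = "nf_glm")
}

#' Fit the offline GLM for one preprocessed run
#'
#' Convenience wrapper: builds the standard design from the preprocessed
#' run's own compartments and fits the GLM over all kept voxels.
#'
#' @param prep an `offline_run` from [preprocess_offline()].
#' @param legendre_order drift order.
#' @return an `nf_glm` with attributes `vox_keep` and `geometry`.
#' @export
fit_offline_glm <- function(prep, legendre_order = 4) {
  stopifnot(inherits(prep, "offline_run"))
  comp <- as.integer(prep$geometry$compartments)[prep$vox_keep]
  design <- build_design_matrix(
    prep$schedule, prep$motion, prep$series[, comp == 3L, drop = FALSE],
    rowMeans(prep$series[, comp == 2L, drop = FALSE]),
    drop_lead = prep$drop_lead, legendre_order = legendre_order)
  fit <- fit_run_glm(prep$series, design)
  attr(fit, "vox_keep") <- prep$vox_keep
  attr(fit, "geometry") <- prep$geometry
  fit
}

#' Mean contrast over a spherical ROI
#'
#' @param fit an `nf_glm` with `vox_keep`/`geometry` attributes (from
#'   [fit_offline_glm()]), or a named list `list(map =, vox_keep =,
#'   geometry =)` with a voxelwise contrast vector.
#' @param roi an [roi_spec()].
#' @param contrast contrast name.
#' @return scalar mean percent signal change over in-ROI voxels.
#' @export
extract_roi_psc <- function(fit, roi = roi_spec(),
                            contrast = "FOCUS_VS_DESCRIBE") {
  if (inherits(fit, "nf_glm")) {
    map <- fit$contrasts[contrast, ]
    vox <- attr(fit, "vox_keep")
    geom <- attr(fit, "geometry")
  } else {
    map <- fit$map
    vox <- fit$vox_keep
    geom <- fit$geometry
  }
  stopifnot(!is.null(vox), !is.null(geom))
  idx <- roi_voxels(roi, geom$dim, geom$affine)
  sel <- vox %in% idx
  if (!any(sel)) stop("ROI does not intersect the analysis mask")
  mean(map[sel])
}

#' Group one-sample t-map with cluster table
#'
#' Per-voxel one-sample t of subject contrast maps against zero, plus a table
#' of face-connected suprathreshold clusters (peak voxel and extent; no
#' extent-calibrated correction is applied).
#'
#' @param maps list of 3D arrays (one per subject) on a common grid, or a
#'   subjects x voxel matrix with a `dims` argument.
#' @param p_thresh voxelwise two-sided p threshold defining clusters.
#' @param dims grid dimensions when `maps` is a matrix.
#' @return list of class `nf_tmap`: `t` (array), `p` (array), `n`,
#'   `clusters` (tibble: `cluster`, `sign`, `extent`, `peak_t`, `peak_i/j/k`
#'   0-based).
#' @export
group_voxel_ttest <- function(maps, p_thresh = 0.001, dims = NULL) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    stopifnot(all(vapply(maps, function(m) identical(dim(m), dims), TRUE)))
    y <- do.call(rbind, lapply(maps, as.numeric))
  } else {
    y <- maps
    stopifnot(!is.null(dims))
  }
  n <- nrow(y)
  stopifnot(n >= 3)
  mu <- colMeans(y)
  sd_ <- apply(y, 2, stats::sd)
  t_ <- rep(NA_real_, ncol(y))
  ok <- sd_ > 0
  t_[ok] <- mu[ok] / (sd_[ok] / sqrt(n))
  p_ <- 2 * stats::pt(-abs(t_), df = n - 1)
  clusters <- cluster_table(array(t_, dims), array(p_, dims), p_thresh)
  structure(list(t = array(t_, dims), p = array(p_, dims), n = n,
                 clusters = clusters),
            class = "nf_tmap")
}

# face-connected components of the suprathreshold mask, split by sign
cluster_table <- function(t_arr, p_arr, p_thresh) {
  dims <- dim(t_arr)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- !is.na(t_arr) & p_arr < p_thresh & sign(t_arr) == sgn
    lab <- label_components(mask)
    if (max(lab) == 0) next
    for (cl in seq_len(max(lab))) {
      idx <- which(lab == cl)
      peak <- idx[which.max(abs(t_arr[idx]))]
      ijk <- arrayInd(peak, dims) - 1L
      out[[length(out) + 1]] <- tibble::tibble(
        sign = sgn, extent = length(idx), peak_t = t_arr[peak],
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(cluster = integer(0), sign = numeric(0),
                          extent = integer(0), peak_t = numeric(0),
                          peak_i = integer(0), peak_j = integer(0),
                          peak_k = integer(0)))
  }
  res <- dplyr::bind_rows(out) |> dplyr::arrange(dplyr::desc(.data$extent))
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(nrow(res))), res)
}

# flood-fill labelling of face-connected (6-neighbour) components
label_components <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  current <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      ijk <- arrayInd(v, dims)
      for (d in seq_len(6)) {
        w <- ijk + nb[d, ]
        if (any(w < 1) || any(w > dims)) next
        wi <- w[1] + (w[2] - 1) * dims[1] + (w[3] - 1) * dims[1] * dims[2]
        if (mask[wi] && lab[wi] == 0L) {
          lab[wi] <- current
          queue <- c(queue, wi)
        }
      }
    }
  }
  lab
}

#' Psychophysiological interaction analysis
#'
#' The PPI regressor is the mean-centered HRF-convolved Focus boxcar
#' multiplied by the seed (ROI) series; the physiological regressor is the
#' seed series orthogonalized to the PPI regressor. The design is
#' `[PPI, physiological, Focus, Describe, nuisance]`; volumes with framewise
#' displacement strictly greater than `fd_thresh` are censored (rows deleted)
#' before fitting.
#'
#' @param series time x voxel matrix (percent units).
#' @param roi_series seed series, same length.
#' @param schedule an `nf_schedule`.
#' @param nuisance nuisance matrix (motion, drift, ...), same rows.
#' @param fd framewise displacement per volume.
#' @param fd_thresh censoring threshold in mm.
#' @param drop_lead leading retained-grid volumes already dropped.
#' @param hrf_task use the HRF-convolved psychological regressor (`TRUE`) or
#'   the raw +/--coded boxcar (`FALSE`).
#' @return list of class `nf_ppi`: `beta`, `t` (per voxel), `censored`
#'   (volume indices removed), `dof`, `design_names`.
#' @export
run_ppi <- function(series, roi_series, schedule, nuisance = NULL,
                    fd = NULL, fd_thresh = 0.3, drop_lead = 0,
                    hrf_task = TRUE) {
  y <- if (is.null(dim(series))) matrix(series, ncol = 1) else series
  nt <- nrow(y)
  stopifnot(length(roi_series) == nt)
  tr <- attr(schedule, "tr")
  keep_rows <- (drop_lead + 1):attr(schedule, "n_volumes")
  stopifnot(length(keep_rows) == nt)
  task_f <- hrf_convolve(boxcar(schedule, "FOCUS"), tr = tr)[keep_rows]
  task_d <- hrf_convolve(boxcar(schedule, "DESCRIBE"), tr = tr)[keep_rows]
  psych <- if (hrf_task) task_f - mean(task_f) else
    (boxcar(schedule, "FOCUS")[keep_rows] * 2 - 1)
  ppi <- psych * roi_series
  if (sum(abs(ppi)) < 1e-12)
    stop("PPI regressor is identically zero (empty seed series?)")
  phys <- roi_series - ppi * sum(ppi * roi_series) / sum(ppi^2)
  x <- cbind(PPI = ppi, PHYS = phys, FOCUS = task_f, DESCRIBE = task_d,
             if (!is.null(nuisance)) as.matrix(nuisance) else
               cbind(intercept = rep(1, nt)))
  censored <- integer(0)
  if (!is.null(fd)) {
    stopifnot(length(fd) == nt)
    censored <- which(fd > fd_thresh)
    if (length(censored) > nt / 2)
      stop("more than 50% of volumes censored (",
           length(censored), " of ", nt, ")")
    if (length(censored)) {
      y <- y[-censored, , drop = FALSE]
      x <- x[-censored, , drop = FALSE]
    }
  }
  x <- prune_design(x)
  if (!"PPI" %in% colnames(x)) stop("PPI column dropped: design degenerate")
  q <- qr(x)
  dof <- nrow(x) - ncol(x)
  betas <- qr.coef(q, y)
  res <- y - x %*% betas
  sigma2 <- colSums(res^2) / dof
  xtxinv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * xtxinv[which(colnames(x) == "PPI"),
                             which(colnames(x) == "PPI")])
  structure(list(beta = betas["PPI", ], t = betas["PPI", ] / se,
                 censored = censored, dof = dof, design_names = colnames(x)),
            class = "nf_ppi")
}

#' ROI-level percent-signal-change recovery for one run
#'
#' Fast path for parameter-recovery studies: restricts offline preprocessing
#' to the voxels the ROI-level GLM actually needs (target sphere,
#' white-matter and ventricle compartments), fits the standard design to the
#' ROI mean series, and returns the requested contrast.
#'
#' @param subject an `nf_subject`.
#' @param run run name.
#' @param roi an [roi_spec()]; defaults to the subject geometry's.
#' @param contrast contrast name.
#' @return scalar percent signal change.
#' @export
roi_psc_offline <- function(subject, run, roi = subject$geometry$roi,
                            contrast = "FOCUS_VS_DESCRIBE") {
  geom <- subject$geometry
  roi_idx <- roi_voxels(roi, geom$dim, geom$affine)
  need <- sort(unique(c(roi_idx, which(geom$compartments %in% c(2L, 3L)))))
  prep <- preprocess_offline(subject, run, voxels = need)
  comp <- as.integer(geom$compartments)[prep$vox_keep]
  design <- build_design_matrix(
    prep$schedule, prep$motion, prep$series[, comp == 3L, drop = FALSE],
    rowMeans(prep$series[, comp == 2L, drop = FALSE]),
    drop_lead = prep$drop_lead)
  y <- rowMeans(prep$series[, prep$vox_keep %in% roi_idx, drop = FALSE])
  fit <- fit_run_glm(y, design)
  fit$contrasts[contrast, 1]
}
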