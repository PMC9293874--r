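# Synthetic subjects with known ground truth: geometry, physiology, motion,
# and the multiplicative percent-scale BOLD signal model.

#' Desk-scale acquisition geometry
#'
#' A small isotropic grid with labelled compartments standing in for anatomy:
#' a spherical neurofeedback target (PCC), a white-matter slab, a ventricle
#' box, and gray matter elsewhere. The affine places the world origin so that
#' the configured target center falls exactly on a voxel center, so ROI code
#' exercises real world-to-voxel math.
#'
#' @param n grid size per axis in voxels (>= 20, so that the task effect
#'   region clears the nuisance compartments).
#' @param voxel_size isotropic voxel edge in mm.
#' @param roi_center world (mm) coordinates of the target sphere center;
#'   default is the PCC meta-analytic coordinate (-5, -55, 23).
#' @param roi_radius target sphere radius in mm.
#' @param effect_margin_mm margin by which the simulated task effect region
#'   extends beyond the measurement sphere (deactivation in real data covers
#'   more than the 7-mm target, so spatial smoothing does not dilute the ROI
#'   mean); default one smoothing FWHM.
#' @return list of class `nf_geometry` with fields `dim`, `voxel_size`,
#'   `affine` (4x4, world = affine %*% c(ijk0, 1)), `mask` (logical array),
#'   `compartments` (integer array: 0 gray, 1 ROI, 2 white matter,
#'   3 ventricle), `effect` (logical array: task effect region), and `roi`
#'   (the [roi_spec()]).
#' @export
default_geometry <- function(n = 24, voxel_size = 2,
                             roi_center = c(-5, -55, 23), roi_radius = 7,
                             effect_margin_mm = 6) {
  stopifnot(n >= 20, voxel_size > 0, roi_radius > 0, effect_margin_mm >= 0)
  origin <- roi_center - voxel_size * floor(n / 2)
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- origin
  dims <- c(n, n, n)
  comp <- array(0L, dims)
  roi <- roi_spec(roi_center, roi_radius)
  comp[roi_voxels(roi, dims, affine)] <- 1L
  comp[1:3, , ] <- 2L                                   # white-matter slab
  ctr <- floor(n / 2) + 1
  comp[(n - 2):(n - 1), ctr + (-1:1), ctr + (-1:1)] <- 3L   # ventricle box
  eff <- array(FALSE, dims)
  eff[roi_voxels(roi_spec(roi_center, roi_radius + effect_margin_mm),
                 dims, affine)] <- TRUE
  if (any(eff & comp > 1L))
    stop("task effect region overlaps a nuisance compartment; ",
         "enlarge the grid or reduce effect_margin_mm")
  if (!all(c(1L, 2L, 3L) %in% comp))
    stop("geometry must contain ROI, white-matter and ventricle compartments")
  structure(list(dim = dims, voxel_size = rep(voxel_size, 3), affine = affine,
                 mask = array(TRUE, dims), compartments = comp, effect = eff,
                 roi = roi, effect_margin_mm = effect_margin_mm),
            class = "nf_geometry")
}

# gray-matter box used as the PPI coupling target, away from the ROI sphere
# and outside the task effect region
coupling_voxels <- function(geometry) {
  n <- geometry$dim[1]
  ctr <- floor(n / 2) + 1
  m <- array(FALSE, geometry$dim)
  m[ctr + (-1:1), 2:4, ctr + (-1:1)] <- TRUE
  which(m & geometry$compartments == 0L & !geometry$effect)
}

#' Ground-truth signal parameters
#'
#' Amplitudes are percent-signal units throughout, matching the scale of the
#' study's outcomes (ROI deactivation around -0.5% during Focus-on-Breath,
#' around +0.2% during Describe).
#'
#' @param focus_effect_roi percent signal change in the target ROI during
#'   Focus-on-Breath blocks.
#' @param describe_effect_roi percent change during Describe blocks.
#' @param drift_coef Legendre drift coefficients (orders 0..length-1), percent.
#' @param cardiac_amp,resp_amp RETROICOR-basis physiological amplitudes, percent.
#' @param motion_coupling percent per mm/degree for the six motion parameters.
#' @param noise_sd thermal (white) noise standard deviation, percent.
#' @param subject_sd between-subject SD of the Focus effect, percent.
#' @param wm_amp,vent_amp amplitudes of slow compartment-specific fluctuation.
#' @param heart_rate_bpm,resp_rate_bpm,physio_variability physiology settings.
#' @param walk_sd,spike_prob,spike_size motion random-walk settings.
#' @param baseline_scale multiplier on the compartment baseline intensities;
#'   percent-scale outputs are invariant to it.
#' @param focus_effect_by_run optional named numeric vector overriding
#'   `focus_effect_roi` for specific run types (e.g. a stronger deactivation
#'   in NF runs than in OBS/TRS).
#' @return list of class `nf_ground_truth`.
#' @export
ground_truth <- function(focus_effect_roi = -0.5, describe_effect_roi = 0.2,
                         drift_coef = c(0, 0.3, -0.2, 0.1, 0.05),
                         cardiac_amp = 0.1, resp_amp = 0.15,
                         motion_coupling = rep(0.05, 6),
                         noise_sd = 1, subject_sd = 0.1,
                         wm_amp = 0.3, vent_amp = 0.3,
                         heart_rate_bpm = 70, resp_rate_bpm = 16,
                         physio_variability = 0.05,
                         walk_sd = 0.01, spike_prob = 0.01, spike_size = 0.25,
                         baseline_scale = 1, focus_effect_by_run = NULL) {
  stopifnot(noise_sd >= 0, subject_sd >= 0,
            is.finite(focus_effect_roi), is.finite(describe_effect_roi),
            length(motion_coupling) == 6)
  structure(as.list(environment()), class = "nf_ground_truth")
}

#' Generate cardiac and respiratory waveforms
#'
#' Cardiac: Gaussian pressure pulses at jittered inter-beat intervals.
#' Respiration: quasi-sinusoid with slowly varying amplitude and period.
#' Both are sampled on the 25-ms physiological clock and are pure functions
#' of their arguments and the seed.
#'
#' @param duration_s recording length in seconds.
#' @param heart_rate_bpm,resp_rate_bpm mean rates.
#' @param variability fractional jitter of inter-beat interval, respiratory
#'   period and amplitude (0 disables all jitter).
#' @param seed integer seed.
#' @return a [physio_recording()].
#' @export
generate_physio <- function(duration_s, heart_rate_bpm = 70,
                            resp_rate_bpm = 16, variability = 0.05,
                            seed = 1) {
  stopifnot(duration_s > 0, heart_rate_bpm > 0, resp_rate_bpm > 0,
            variability >= 0)
  withr::with_seed(seed, {
    dt <- PHYSIO_DT
    n <- round(duration_s / dt)
    t <- (seq_len(n) - 1) * dt
    ibi0 <- 60 / heart_rate_bpm
    n_beats <- ceiling(duration_s / ibi0 * 1.5) + 2
    ibi <- pmax(ibi0 * (1 + variability * stats::rnorm(n_beats)), 0.3)
    beats <- cumsum(c(0, ibi))
    beats <- beats[beats < duration_s]
    cardiac <- numeric(n)
    w <- 0.06                               # pulse width, s
    for (b in beats) {
      i <- which(abs(t - b) <= 4 * w)
      cardiac[i] <- cardiac[i] + exp(-((t[i] - b)^2) / (2 * w^2))
    }
    f0 <- resp_rate_bpm / 60
    slow <- function() {
      k <- max(4, ceiling(duration_s / 5))
      stats::spline(seq(0, duration_s, length.out = k), stats::rnorm(k),
                    xout = t)$y
    }
    freq <- f0 * (1 + variability * slow())
    amp <- 1 + variability * slow()
    resp <- amp * sin(2 * pi * cumsum(freq) * dt)
    physio_recording(cardiac, resp)
  })
}

#' Generate a six-parameter motion trace
#'
#' A bounded random walk (clipped at +/- 2 mm / 2 degrees) in three
#' translations and three rotations, with optional transient spikes added to
#' the translations so that framewise displacement exceeds the 0.3-mm
#' censoring threshold at a controllable rate.
#'
#' @param n_volumes retained volumes (rows).
#' @param walk_sd per-step SD of the random walk.
#' @param spike_prob per-volume probability of a transient spike.
#' @param spike_size spike amplitude (mm) added to each translation axis.
#' @param seed integer seed.
#' @return tibble with columns `trans_x, trans_y, trans_z` (mm) and
#'   `rot_x, rot_y, rot_z` (degrees).
#' @export
generate_motion <- function(n_volumes, walk_sd = 0.01, spike_prob = 0,
                            spike_size = 0.25, seed = 1) {
  stopifnot(n_volumes >= 1)
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_volumes * 6, sd = walk_sd), n_volumes, 6)
    m <- apply(m, 2, cumsum)
    m <- matrix(pmin(pmax(m, -2), 2), n_volumes, 6)
    if (spike_prob > 0) {
      at <- which(stats::runif(n_volumes) < spike_prob)
      m[at, 1:3] <- m[at, 1:3] + spike_size
    }
    colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    tibble::as_tibble(m)
  })
}

#' A 4D synthetic BOLD series
#'
#' @param data 4D array (x, y, z, t) including `n_dummy` leading dummy volumes.
#' @param geometry an `nf_geometry`.
#' @param tr repetition time, seconds.
#' @param n_dummy leading dummy volumes.
#' @return list of class `volume_series`.
#' @export
volume_series <- function(data, geometry, tr = 2, n_dummy = 3) {
  stopifnot(length(dim(data)) == 4, all(dim(data)[1:3] == geometry$dim))
  structure(list(data = data, geometry = geometry, tr = tr,
                 n_dummy = n_dummy),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_series> ", paste(d[1:3], collapse = "x"), " voxels, ",
      d[4], " volumes (", x$n_dummy, " dummy) @ TR ", x$tr, " s\n", sep = "")
  invisible(x)
}

# time x voxel matrix of the retained (post-dummy) volumes
vs_matrix <- function(vs, retained = TRUE) {
  d <- dim(vs$data)
  m <- t(matrix(vs$data, prod(d[1:3]), d[4]))
  if (retained && vs$n_dummy > 0) m <- m[-seq_len(vs$n_dummy), , drop = FALSE]
  m
}

# fixed RETROICOR-basis weights used by the signal model
RETRO_W <- c(0.8, 0.6, 0.4, 0.3)

# smooth zero-mean unit-scale fluctuation (moving-average filtered noise)
slow_fluct <- function(n) {
  x <- stats::filter(stats::rnorm(n + 30), rep(1 / 15, 15), sides = 1)
  x <- x[31:(n + 30)]
  as.numeric(scale(x)) * 1
}

#' Generate one synthetic subject
#'
#' Voxel signal follows a multiplicative percent-scale model:
#' `x = baseline * (1 + (task + drift + physio + motion + compartment +
#' noise) / 100)`, so percent signal change has exact ground truth. Task
#' effects (HRF-convolved Focus and Describe boxcars) apply in the target ROI
#' only; an optional coupling box whose fluctuation tracks the ROI with a
#' task-modulated gain supports PPI testing.
#'
#' @param schedules named list of [build_run_schedule()] outputs, names =
#'   run types.
#' @param geometry an `nf_geometry` from [default_geometry()].
#' @param truth an [ground_truth()] object.
#' @param seed integer seed.
#' @param id subject identifier.
#' @param coupling optional `list(base =, gain =)` for the PPI coupling box.
#' @return list of class `nf_subject` with per-run `volumes`
#'   ([volume_series()]), `physio`, `motion`, plus `ground_truth` and `seed`.
#' @export
generate_subject <- function(schedules, geometry = default_geometry(),
                             truth = ground_truth(), seed = 1,
                             id = "sub-01", coupling = NULL) {
  stopifnot(inherits(geometry, "nf_geometry"),
            inherits(truth, "nf_ground_truth"),
            length(schedules) >= 1, !is.null(names(schedules)))
  if (!all(c(1L, 2L, 3L) %in% geometry$compartments))
    stop("geometry must contain ROI, white-matter and ventricle compartments")
  runs <- vector("list", length(schedules))
  names(runs) <- names(schedules)
  run_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1,
                                           length(schedules)))
  for (r in seq_along(schedules)) {
    truth_r <- truth
    rn <- names(schedules)[r]
    if (!is.null(truth$focus_effect_by_run) &&
        rn %in% names(truth$focus_effect_by_run))
      truth_r$focus_effect_roi <- truth$focus_effect_by_run[[rn]]
    runs[[r]] <- generate_run(schedules[[r]], geometry, truth_r,
                              run_seeds[r], coupling)
  }
  structure(list(id = id, runs = runs, geometry = geometry,
                 ground_truth = truth, seed = seed),
            class = "nf_subject")
}

generate_run <- function(schedule, geometry, truth, seed, coupling = NULL) {
  tr <- attr(schedule, "tr")
  n <- attr(schedule, "n_volumes")
  n_dummy <- attr(schedule, "n_dummy")
  vt <- (seq_len(n) - 1) * tr
  physio <- generate_physio(n * tr, truth$heart_rate_bpm, truth$resp_rate_bpm,
                            truth$physio_variability, seed = seed + 1L)
  motion <- generate_motion(n, truth$walk_sd, truth$spike_prob,
                            truth$spike_size, seed = seed + 2L)
  withr::with_seed(seed, {
    task_focus <- if ("FOCUS" %in% schedule$condition) {
      truth$focus_effect_roi * hrf_convolve(boxcar(schedule, "FOCUS"), tr = tr)
    } else numeric(n)
    task_desc <- if ("DESCRIBE" %in% schedule$condition) {
      truth$describe_effect_roi * hrf_convolve(boxcar(schedule, "DESCRIBE"),
                                               tr = tr)
    } else numeric(n)
    task <- task_focus + task_desc
    drift <- legendre_basis(n, length(truth$drift_coef) - 1) %*%
      truth$drift_coef
    r8 <- retroicor_regressors(physio, vt)
    physio_pct <- truth$cardiac_amp * (r8[, 1:4] %*% RETRO_W) +
      truth$resp_amp * (r8[, 5:8] %*% RETRO_W)
    motion_pct <- as.matrix(motion) %*% truth$motion_coupling
    g_wm <- truth$wm_amp * slow_fluct(n)
    g_vent <- truth$vent_amp * slow_fluct(n)
    shared <- drop(drift + physio_pct + motion_pct)
    # compartment percent profiles, time x {gray, roi, wm, ventricle}
    prof <- cbind(gray = shared + 0.5 * g_wm + 0.5 * g_vent,
                  roi = shared + 0.5 * g_wm + 0.5 * g_vent + task,
                  wm = shared + g_wm,
                  vent = shared + drop(physio_pct) + g_vent)
    nvox <- prod(geometry$dim)
    comp <- as.integer(geometry$compartments)
    # gray voxels inside the task effect region share the ROI profile
    comp_eff <- comp
    comp_eff[comp == 0L & as.logical(geometry$effect)] <- 1L
    base_by_comp <- truth$baseline_scale * c(1000, 1000, 800, 600)[comp + 1L]
    baseline <- base_by_comp * (1 + 0.05 * stats::rnorm(nvox))
    pct <- t(prof)[comp_eff + 1L, , drop = FALSE]       # voxel x time
    if (!is.null(coupling)) {
      cv <- coupling_voxels(geometry)
      roi_fluct <- prof[, "roi"] - mean(prof[, "roi"])
      task01 <- boxcar(schedule, "FOCUS")
      gain_t <- coupling$base + coupling$gain * task01
      pct[cv, ] <- pct[cv, , drop = FALSE] +
        rep(gain_t * roi_fluct, each = length(cv))
    }
    if (truth$noise_sd > 0)
      pct <- pct + matrix(stats::rnorm(nvox * n, sd = truth$noise_sd), nvox, n)
    dat <- baseline * (1 + pct / 100)
    if (n_dummy > 0) {
      dum <- baseline * (1 + matrix(stats::rnorm(nvox * n_dummy,
                                                 sd = truth$noise_sd),
                                    nvox, n_dummy) / 100)
      dat <- cbind(dum, dat)
    }
    vols <- volume_series(array(dat, c(geometry$dim, n + n_dummy)),
                          geometry, tr, n_dummy)
    list(schedule = schedule, volumes = vols, physio = physio,
         motion = motion)
  })
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from the master seed, and
#' each subject's Focus effect is drawn with the between-subject SD
#' `truth$subject_sd` around `truth$focus_effect_roi`.
#'
#' @param n_subjects cohort size.
#' @param schedules named list of run schedules shared by all subjects.
#' @param geometry,truth,coupling as in [generate_subject()].
#' @param master_seed integer master seed.
#' @return list of `nf_subject` objects.
#' @export
generate_cohort <- function(n_subjects, schedules,
                            geometry = default_geometry(),
                            truth = ground_truth(), master_seed = 1,
                            coupling = NULL) {
  stopifnot(n_subjects >= 1)
  draws <- withr::with_seed(master_seed, list(
    seeds = sample.int(.Machine$integer.max - 1, n_subjects),
    eff = stats::rnorm(n_subjects, truth$focus_effect_roi, truth$subject_sd)))
  purrr::map(seq_len(n_subjects), function(i) {
    tr_i <- truth
    tr_i$focus_effect_roi <- draws$eff[i]
    generate_subject(schedules, geometry, tr_i, seed = draws$seeds[i],
                     id = sprintf("sub-%02d", i), coupling = coupling)
  })
}

#' Simulate a long table of ROI percent-signal-change values
#'
#' ROI-level fast path for group-statistics simulations: draws one PSC value
#' per subject and run from a random-intercept model
#' `value = run effect + subject intercept + residual`, without generating
#' volumes.
#'
#' @param n_subjects number of subjects.
#' @param run_effects named numeric vector of per-run mean effects.
#' @param subject_sd SD of the subject random intercept.
#' @param resid_sd residual SD.
#' @param seed integer seed.
#' @return tibble with columns `subject`, `run`, `measure`, `value`, `age`,
#'   `sex` (one row per subject-run).
#' @export
simulate_roi_psc_table <- function(n_subjects,
                                   run_effects = c(OBS = 0, NF1 = 0, NF2 = 0,
                                                   NF3 = 0, TRS = 0),
                                   subject_sd = 0.3, resid_sd = 0.3,
                                   seed = 1) {
  stopifnot(n_subjects >= 2, !is.null(names(run_effects)))
  withr::with_seed(seed, {
    subj <- sprintf("sub-%02d", seq_len(n_subjects))
    intercepts <- stats::rnorm(n_subjects, 0, subject_sd)
    age <- sample(13:17, n_subjects, replace = TRUE)
    sex <- sample(c("F", "M"), n_subjects, replace = TRUE)
    tidyr::expand_grid(subject = subj, run = names(run_effects)) |>
      dplyr::mutate(
        measure = "psc",
        value = run_effects[.data$run] +
          intercepts[match(.data$subject, subj)] +
          stats::rnorm(dplyr::n(), 0, resid_sd),
        age = age[match(.data$subject, subj)],
        sex = sex[match(.data$subject, subj)])
  })
}
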