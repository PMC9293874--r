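# Block-design paradigm: run schedules, volume labels, boxcars, HRF.

#' Conditions and run types of the neurofeedback session
#'
#' The paradigm has three conditions (Rest baseline, Describe active control,
#' Focus-on-Breath mindfulness) and six run types: a resting-state run, an
#' Observe run without feedback, three neurofeedback runs with progressively
#' deeper target levels, and a Transfer run without feedback.
#'
#' @name paradigm-constants
#' @keywords internal
NULL

nf_conditions <- c("REST", "DESCRIBE", "FOCUS")
nf_run_types <- c("REST_RUN", "OBS", "NF1", "NF2", "NF3", "TRS")

#' Neurofeedback target levels by run type
#'
#' Target percent-signal-change levels (relative to the preceding rest block)
#' shown as the green bar: -0.5, -0.75 and -1.0 for NF1, NF2, NF3. Runs
#' without feedback (OBS, TRS, REST_RUN) have no target (`NA`).
#'
#' @param run_type one of `"REST_RUN"`, `"OBS"`, `"NF1"`, `"NF2"`, `"NF3"`, `"TRS"`.
#' @return a single numeric target level in percent units, or `NA_real_`.
#' @export
#' @examples
#' nf_target_level("NF1")
nf_target_level <- function(run_type) {
  run_type <- match.arg(run_type, nf_run_types)
  switch(run_type, NF1 = -0.5, NF2 = -0.75, NF3 = -1.0, NA_real_)
}

#' Timing configuration for a run
#'
#' Defaults encode the session layout: a 66-s leading rest block followed by
#' three cycles of Describe (20 s), Rest (30 s), Focus-on-Breath (70 s), on a
#' 2-s TR grid with 3 leading dummy volumes (discarded before volume 0).
#' Resting-state runs are a single 360-s rest block. The cycle order keeps a
#' 30-s rest immediately before every Focus block, which the feedback baseline
#' rule requires.
#'
#' @param lead_rest_s leading rest duration in seconds.
#' @param cycle data frame with columns `condition` and `duration` (seconds)
#'   describing one task cycle, in order.
#' @param n_cycles number of cycles after the leading rest.
#' @param rest_run_s duration of a resting-state run in seconds.
#' @param tr repetition time in seconds.
#' @param n_dummy dummy volumes acquired before the first retained volume.
#' @return a list of class `nf_timing`.
#' @export
nf_timing <- function(lead_rest_s = 66,
                      cycle = tibble::tibble(
                        condition = c("DESCRIBE", "REST", "FOCUS"),
                        duration = c(20, 30, 70)),
                      n_cycles = 3,
                      rest_run_s = 360,
                      tr = 2,
                      n_dummy = 3) {
  stopifnot(lead_rest_s >= 0, n_cycles >= 1, tr > 0, n_dummy >= 0,
            all(cycle$condition %in% nf_conditions), all(cycle$duration > 0))
  structure(list(lead_rest_s = lead_rest_s, cycle = cycle,
                 n_cycles = n_cycles, rest_run_s = rest_run_s,
                 tr = tr, n_dummy = n_dummy),
            class = "nf_timing")
}

new_nf_schedule <- function(blocks, run_type, tr, n_dummy, n_volumes,
                            target_level) {
  structure(blocks,
            run_type = run_type, tr = tr, n_dummy = n_dummy,
            n_volumes = n_volumes, target_level = target_level,
            class = c("nf_schedule", class(tibble::tibble())))
}

#' Build the block schedule for one run
#'
#' Assembles the ordered blocks of a run from a timing configuration and
#' validates them: durations positive, onsets strictly increasing,
#' non-overlapping, total duration a whole number of TRs, and every
#' Focus-on-Breath block immediately preceded by a rest block of at least
#' 3 TRs (needed by the feedback baseline rule).
#'
#' @param run_type one of `"REST_RUN"`, `"OBS"`, `"NF1"`, `"NF2"`, `"NF3"`, `"TRS"`.
#' @param timing an [nf_timing()] configuration.
#' @return a tibble of class `nf_schedule` with columns `condition`, `onset`,
#'   `duration` (seconds from the first retained volume), and attributes
#'   `run_type`, `tr`, `n_dummy`, `n_volumes`, `target_level`.
#' @export
#' @examples
#' sched <- build_run_schedule("NF1")
#' attr(sched, "target_level")
build_run_schedule <- function(run_type, timing = nf_timing()) {
  run_type <- match.arg(run_type, nf_run_types)
  stopifnot(inherits(timing, "nf_timing"))
  tr <- timing$tr
  if (run_type == "REST_RUN") {
    blocks <- tibble::tibble(condition = "REST", onset = 0,
                             duration = timing$rest_run_s)
  } else {
    cyc <- timing$cycle[rep(seq_len(nrow(timing$cycle)), timing$n_cycles), ]
    cond <- c(if (timing$lead_rest_s > 0) "REST", cyc$condition)
    dur <- c(if (timing$lead_rest_s > 0) timing$lead_rest_s, cyc$duration)
    blocks <- tibble::tibble(condition = cond,
                             onset = cumsum(c(0, dur[-length(dur)])),
                             duration = dur)
  }
  total <- sum(blocks$duration)
  if (abs(total / tr - round(total / tr)) > 1e-9)
    stop("total run duration (", total, " s) is not a whole number of TRs")
  n_volumes <- as.integer(round(total / tr))
  validate_schedule_blocks(blocks, tr)
  new_nf_schedule(blocks, run_type, tr, timing$n_dummy, n_volumes,
                  nf_target_level(run_type))
}

validate_schedule_blocks <- function(blocks, tr) {
  stopifnot(all(blocks$duration > 0),
            all(diff(blocks$onset) > 0),
            all(blocks$onset + blocks$duration <=
                  c(blocks$onset[-1], Inf) + 1e-9))
  is_focus <- blocks$condition == "FOCUS"
  for (i in which(is_focus)) {
    ok <- i > 1 && blocks$condition[i - 1] == "REST" &&
      blocks$duration[i - 1] >= 3 * tr
    if (!ok)
      stop("every FOCUS block must be immediately preceded by a REST block ",
           "of at least 3 TRs (block ", i, " violates this)")
  }
  invisible(blocks)
}

#' @export
print.nf_schedule <- function(x, ...) {
  cat("<nf_schedule> run ", attr(x, "run_type"),
      ", ", attr(x, "n_volumes"), " volumes @ TR ", attr(x, "tr"), " s",
      if (!is.na(attr(x, "target_level")))
        paste0(", target ", attr(x, "target_level"), "%"),
      "\n", sep = "")
  NextMethod()
}

#' Per-volume condition labels
#'
#' Volume `v` (0-based, after dummy removal) is acquired at time `v * tr` and
#' labelled by the block whose half-open interval `[onset, onset + duration)`
#' contains that time.
#'
#' @param schedule an `nf_schedule`.
#' @return character vector of length `n_volumes`.
#' @export
labels_for_volumes <- function(schedule) {
  stopifnot(inherits(schedule, "nf_schedule"))
  n <- attr(schedule, "n_volumes")
  if (n == 0L) return(character(0))
  t <- (seq_len(n) - 1) * attr(schedule, "tr")
  idx <- findInterval(t, schedule$onset)
  stopifnot(all(idx >= 1),
            all(t < schedule$onset[idx] + schedule$duration[idx]))
  schedule$condition[idx]
}

#' Condition boxcar on the TR grid
#'
#' @param schedule an `nf_schedule`.
#' @param condition one of `"REST"`, `"DESCRIBE"`, `"FOCUS"`.
#' @param n_volumes number of volumes; defaults to the schedule's.
#' @return 0/1 numeric vector; all zeros with a warning if the condition does
#'   not occur in the schedule.
#' @export
boxcar <- function(schedule, condition, n_volumes = attr(schedule, "n_volumes")) {
  condition <- match.arg(condition, nf_conditions)
  if (n_volumes == 0L) return(numeric(0))
  if (!condition %in% schedule$condition)
    warning("condition ", condition, " does not occur in this schedule")
  lab <- labels_for_volumes(schedule)
  as.numeric(lab[seq_len(n_volumes)] == condition)
}

#' Hemodynamic response function parameters
#'
#' Double-gamma kernel parameterized by the *mode* of each gamma component:
#' the response peaks at `peak_delay` seconds and the undershoot bottoms out
#' near `undershoot_delay` seconds. The kernel is normalized to unit peak so
#' that a convolved boxcar plateaus at the effect amplitude in percent units.
#'
#' @param peak_delay peak delay in seconds.
#' @param undershoot_delay undershoot delay in seconds.
#' @param peak_disp,undershoot_disp dispersions (gamma scale) in seconds.
#' @param undershoot_ratio relative undershoot amplitude.
#' @param length_s kernel support in seconds (at least 24).
#' @return a list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       undershoot_ratio = 1 / 6, length_s = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > peak_delay,
            peak_disp > 0, undershoot_disp > 0,
            undershoot_ratio >= 0, length_s >= 24)
  p <- structure(list(peak_delay = peak_delay,
                      undershoot_delay = undershoot_delay,
                      peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                      undershoot_ratio = undershoot_ratio,
                      length_s = length_s),
                 class = "hrf_params")
  k <- hrf_kernel(p, dt = 0.1)
  if (sum(k) * 0.1 <= 0) stop("HRF kernel must integrate to a positive value")
  p
}

#' Sample the HRF kernel
#'
#' @param params an [hrf_params()] object.
#' @param dt sampling interval in seconds.
#' @return numeric kernel sampled at `0, dt, 2 dt, ...` up to `length_s`,
#'   normalized to unit peak.
#' @export
hrf_kernel <- function(params = hrf_params(), dt = 2) {
  stopifnot(inherits(params, "hrf_params"), dt > 0)
  t <- seq(0, params$length_s, by = dt)
  # gamma density with mode m and scale d: shape = 1 + m/d
  g <- function(m, d) stats::dgamma(t, shape = 1 + m / d, scale = d)
  h <- g(params$peak_delay, params$peak_disp) -
    params$undershoot_ratio * g(params$undershoot_delay, params$undershoot_disp)
  h / max(h)
}

#' Convolve a TR-grid vector with the HRF
#'
#' Discrete causal convolution with the double-gamma kernel sampled at the
#' TR, truncated to the input length. The sampled kernel is rescaled to unit
#' *sum* so that a sustained block plateaus exactly at the input amplitude:
#' on percent-scaled data the task beta of this regressor is then a percent
#' signal change directly.
#'
#' @param x numeric vector on the TR grid (e.g. a boxcar).
#' @param params an [hrf_params()] object.
#' @param tr repetition time in seconds.
#' @return numeric vector the same length as `x`.
#' @export
hrf_convolve <- function(x, params = hrf_params(), tr = 2) {
  stopifnot(tr > 0)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  k <- hrf_kernel(params, dt = tr)
  k <- k / sum(k)
  out <- stats::convolve(x, rev(k), type = "open")
  out[seq_len(n)]
}

#' Read and write BIDS-style events files
#'
#' Tab-separated files with columns `onset`, `duration`, `condition`
#' round-trip a run schedule.
#'
#' @param schedule an `nf_schedule`.
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   an `nf_schedule`.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "nf_schedule"))
  readr::write_tsv(tibble::as_tibble(schedule)[, c("onset", "duration", "condition")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param run_type,tr,n_dummy run metadata not stored in the events file.
#' @export
read_events <- function(path, run_type, tr = 2, n_dummy = 3) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("onset", "duration", "condition") %in% names(ev)))
  blocks <- tibble::tibble(condition = as.character(ev$condition),
                           onset = as.numeric(ev$onset),
                           duration = as.numeric(ev$duration))
  validate_schedule_blocks(blocks, tr)
  total <- max(blocks$onset + blocks$duration)
  new_nf_schedule(blocks, run_type, tr, n_dummy,
                  as.integer(round(total / tr)), nf_target_level(run_type))
}
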