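# Neurofeedback value and bar display rules.

#' Preceding-rest feedback baseline
#'
#' Mean of the ROI residuals over a rest block's volumes, excluding the
#' block's first two volumes (they still carry the delayed hemodynamic
#' response of the preceding Describe block).
#'
#' @param roi_series per-volume ROI residual series for the whole run
#'   (percent units), 0-based volume indexing.
#' @param rest_block one-row data frame (or list) with `onset` and `duration`
#'   in seconds.
#' @param tr repetition time in seconds.
#' @return baseline value (scalar).
#' @export
rest_baseline <- function(roi_series, rest_block, tr = 2) {
  v0 <- floor(rest_block$onset / tr)
  v1 <- ceiling((rest_block$onset + rest_block$duration) / tr) - 1
  vols <- v0:v1
  if (length(vols) < 3)
    stop("rest block spans fewer than 3 volumes; baseline undefined")
  use <- vols[-(1:2)] + 1L            # drop first two volumes; 1-based index
  mean(roi_series[use])
}

#' Per-volume neurofeedback values
#'
#' For each Focus-on-Breath block, the feedback value of volume `v` (0-based
#' within the block) is the ROI residual minus the preceding rest block's
#' baseline — a difference in percent units, since residuals are already
#' percent-scaled. No value is emitted for the first two Focus volumes
#' (hemodynamic delay gate).
#'
#' @param roi_series per-volume ROI residual series (percent units).
#' @param schedule an `nf_schedule`; every FOCUS block must be preceded by a
#'   REST block.
#' @return tibble with columns `volume`, `block` (Focus block number),
#'   `within` (0-based volume index within the block), `nf_value` (`NA`
#'   before the onset gate), `baseline`, `target_level`.
#' @export
nf_values <- function(roi_series, schedule) {
  stopifnot(inherits(schedule, "nf_schedule"))
  tr <- attr(schedule, "tr")
  focus_rows <- which(schedule$condition == "FOCUS")
  out <- purrr::map_dfr(seq_along(focus_rows), function(b) {
    i <- focus_rows[b]
    if (i == 1 || schedule$condition[i - 1] != "REST")
      stop("FOCUS block ", b, " has no preceding REST block")
    base <- rest_baseline(roi_series, schedule[i - 1, ], tr)
    v0 <- floor(schedule$onset[i] / tr)
    nv <- floor((schedule$onset[i] + schedule$duration[i]) / tr) - v0
    within <- 0:(nv - 1)
    tibble::tibble(
      volume = v0 + within, block = b, within = within,
      nf_value = ifelse(within >= 2, roi_series[v0 + within + 1] - base,
                        NA_real_),
      baseline = base,
      target_level = attr(schedule, "target_level"))
  })
  out
}

#' Moving-average bar heights within a Focus block
#'
#' The displayed bar is the moving average of the current and up to the two
#' available preceding feedback values:
#' `h_1 = x_1`, `h_2 = (x_1 + x_2) / 2`, `h_k = (x_{k-2} + x_{k-1} + x_k) / 3`.
#'
#' @param nf_values_in_block feedback values in within-block order.
#' @return smoothed series, same length.
#' @export
bar_heights <- function(nf_values_in_block) {
  x <- as.numeric(nf_values_in_block)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- numeric(n)
  for (k in seq_len(n)) {
    h[k] <- mean(x[max(1, k - 2):k])
  }
  h
}

#' Bar display state and fill fraction
#'
#' OBS and TRS runs show no bar. In neurofeedback runs the bar is blue when
#' the height is at or below zero (deactivation toward the target; zero
#' displays blue as a non-punitive tie-break) and red when positive. The fill
#' fraction is the height relative to the run's target level, clamped to
#' `[0, 1.25]`.
#'
#' @param bar_height bar height(s), percent units.
#' @param run_type run type; feedback only in NF1/NF2/NF3.
#' @param target_level target level; defaults to the run's.
#' @param clamp upper clamp on the fill fraction.
#' @return tibble with columns `state` (`"blue"`, `"red"`, `"hidden"`) and
#'   `fill` (`NA` when hidden).
#' @export
display_state <- function(bar_height, run_type,
                          target_level = nf_target_level(run_type),
                          clamp = 1.25) {
  run_type <- match.arg(run_type, nf_run_types)
  if (!run_type %in% c("NF1", "NF2", "NF3")) {
    return(tibble::tibble(state = rep("hidden", length(bar_height)),
                          fill = NA_real_))
  }
  state <- ifelse(bar_height > 0, "red", "blue")
  fill <- pmin(pmax(bar_height / target_level, 0), clamp)
  tibble::tibble(state = state, fill = fill)
}

#' Full feedback trace for a run
#'
#' Combines the real-time ROI residual series with the feedback rules into a
#' per-volume trace: feedback value, bar height, display state.
#'
#' @param rtp_result an [run_realtime()] result (or a tibble with `volume`,
#'   `condition`, `residual`).
#' @param schedule the run schedule; defaults to the one attached to
#'   `rtp_result`.
#' @param run_type run type; defaults to the schedule's.
#' @return tibble of class `feedback_trace`: `volume`, `condition`,
#'   `residual`, `block`, `nf_value`, `bar`, `state`, `fill`.
#' @export
feedback_trace <- function(rtp_result, schedule = attr(rtp_result, "schedule"),
                           run_type = attr(schedule, "run_type")) {
  stopifnot(!is.null(schedule))
  nf <- nf_values(rtp_result$residual, schedule)
  nf <- nf |>
    dplyr::group_by(.data$block) |>
    dplyr::mutate(bar = {
      b <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$nf_value)
      b[ok] <- bar_heights(.data$nf_value[ok])
      b
    }) |>
    dplyr::ungroup()
  disp <- display_state(nf$bar, run_type,
                        target_level = attr(schedule, "target_level") %|na|%
                          -0.5)
  disp$state[is.na(nf$bar)] <- "hidden"
  disp$fill[is.na(nf$bar)] <- NA_real_
  out <- tibble::tibble(volume = rtp_result$volume,
                        condition = rtp_result$condition,
                        residual = rtp_result$residual) |>
    dplyr::left_join(
      dplyr::bind_cols(nf[, c("volume", "block", "within", "nf_value", "bar")],
                       disp),
      by = "volume")
  structure(out, run_type = run_type,
            class = c("feedback_trace", class(out)))
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a
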