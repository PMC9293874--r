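# Physiological and motion nuisance series: RETROICOR, RVT, FD.

PHYSIO_DT <- 0.025

#' Construct a physiological recording
#'
#' Cardiac (photoplethysmograph) and respiratory (belt) waveforms on a shared
#' 25-ms clock whose origin is the first retained fMRI volume.
#'
#' @param cardiac,resp numeric waveforms of equal length.
#' @param dt sample interval in seconds; must be 0.025.
#' @return a tibble of class `physio_recording` with columns `time`,
#'   `cardiac`, `resp`.
#' @export
physio_recording <- function(cardiac, resp, dt = PHYSIO_DT) {
  stopifnot(length(cardiac) == length(resp), abs(dt - PHYSIO_DT) < 1e-12)
  structure(tibble::tibble(time = (seq_along(cardiac) - 1) * dt,
                           cardiac = as.numeric(cardiac),
                           resp = as.numeric(resp)),
            dt = dt,
            class = c("physio_recording", class(tibble::tibble())))
}

physio_channel <- function(physio, channel = c("cardiac", "resp")) {
  channel <- match.arg(channel)
  if (inherits(physio, "physio_recording")) {
    list(x = physio[[channel]], t = physio$time)
  } else {
    stopifnot(is.numeric(physio))
    list(x = physio, t = (seq_along(physio) - 1) * PHYSIO_DT)
  }
}

#' Detect cardiac beat peaks
#'
#' Local maxima above an adaptive threshold (median + `c_mad` times the MAD of
#' the waveform), with a minimum refractory interval of 0.25 s between
#' accepted peaks. On a flat crest of two equal adjacent samples the first
#' index wins.
#'
#' @param physio a `physio_recording` or a numeric cardiac waveform sampled at
#'   25 ms.
#' @param c_mad threshold multiplier on the MAD.
#' @param refractory minimum inter-peak interval in seconds.
#' @return numeric vector of peak times in seconds.
#' @export
detect_cardiac_peaks <- function(physio, c_mad = 1, refractory = 0.25) {
  ch <- physio_channel(physio, "cardiac")
  x <- ch$x
  n <- length(x)
  stopifnot(n >= 3)
  thr <- stats::median(x) + c_mad * stats::mad(x)
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > thr]
  if (x[1] > x[2] && x[1] > thr) cand <- c(1L, cand)      # boundary crest
  if (x[n] > x[n - 1] && x[n] > thr) cand <- c(cand, n)
  if (length(cand) == 0L)
    stop("no cardiac peaks found: waveform has no local maxima above threshold")
  times <- ch$t[cand]
  keep <- rep(TRUE, length(times))
  last <- times[1]
  for (j in seq_along(times)[-1]) {
    if (times[j] - last < refractory) keep[j] <- FALSE else last <- times[j]
  }
  times[keep]
}

#' Cardiac phase at arbitrary times
#'
#' Linear phase within each inter-beat interval:
#' `phi = 2 pi (t - t_k) / (t_{k+1} - t_k)` for the enclosing beat pair.
#' Times outside the covered span are extrapolated from the nearest interval,
#' with a warning.
#'
#' @param peak_times beat times in seconds, strictly increasing, length >= 2.
#' @param t times at which to evaluate the phase.
#' @return phases in `[0, 2 pi)`.
#' @export
cardiac_phase <- function(peak_times, t) {
  stopifnot(length(peak_times) >= 2, all(diff(peak_times) > 0))
  if (any(t < peak_times[1] | t >= peak_times[length(peak_times)]))
    warning("times outside beat coverage: extrapolating from nearest interval")
  k <- findInterval(t, peak_times)
  k <- pmin(pmax(k, 1L), length(peak_times) - 1L)
  phi <- 2 * pi * (t - peak_times[k]) / (peak_times[k + 1] - peak_times[k])
  phi %% (2 * pi)
}

#' Respiratory phase at arbitrary times
#'
#' Amplitude-histogram-equalized phase: `phi = pi * H(a(t)) / H_total *
#' sign(da/dt)`, where `H` is the cumulative histogram of the waveform
#' amplitudes over 100 fixed-width bins spanning the observed range. The
#' derivative sign comes from centered differences; zero-derivative samples
#' inherit the previous sign.
#'
#' @param physio a `physio_recording` or numeric respiratory waveform.
#' @param t times at which to evaluate the phase.
#' @param n_bins number of histogram bins.
#' @return phases in `(-pi, pi]`.
#' @export
respiratory_phase <- function(physio, t, n_bins = 100) {
  ch <- physio_channel(physio, "resp")
  x <- ch$x
  n <- length(x)
  stopifnot(n >= 3)
  rng <- range(x)
  if (diff(rng) <= 0) stop("respiratory waveform is constant; phase undefined")
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE),
                               1L), n_bins), nbins = n_bins)
  cum <- cumsum(counts)
  # centered-difference sign per sample; zeros inherit the previous sign
  d <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  s <- sign(d)
  if (s[1] == 0) s[1] <- 1
  for (i in seq_len(n)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  a_t <- stats::approx(ch$t, x, xout = t, rule = 2)$y
  bin <- pmin(pmax(findInterval(a_t, brk, rightmost.closed = TRUE), 1L), n_bins)
  nearest <- pmin(pmax(round(t / PHYSIO_DT) + 1, 1L), n)
  pi * cum[bin] / cum[n_bins] * s[nearest]
}

#' RETROICOR Fourier regressors at volume times
#'
#' Eight columns: cosine and sine of the first and second harmonic of the
#' cardiac phase, then the same for the respiratory phase, evaluated at the
#' volume acquisition times.
#'
#' @param physio a `physio_recording`.
#' @param volume_times acquisition times of the retained volumes, seconds.
#' @param peak_times optional precomputed cardiac peak times.
#' @return numeric matrix `length(volume_times) x 8` with columns
#'   `c_cos1, c_sin1, c_cos2, c_sin2, r_cos1, r_sin1, r_cos2, r_sin2`.
#' @export
retroicor_regressors <- function(physio, volume_times, peak_times = NULL) {
  if (is.null(peak_times)) peak_times <- detect_cardiac_peaks(physio)
  phc <- suppressWarnings(cardiac_phase(peak_times, volume_times))
  phr <- respiratory_phase(physio, volume_times)
  m <- cbind(cos(phc), sin(phc), cos(2 * phc), sin(2 * phc),
             cos(phr), sin(phr), cos(2 * phr), sin(2 * phr))
  colnames(m) <- c("c_cos1", "c_sin1", "c_cos2", "c_sin2",
                   "r_cos1", "r_sin1", "r_cos2", "r_sin2")
  m
}

#' Respiration volume per time
#'
#' Per breath (consecutive respiratory peaks), the peak-to-trough amplitude
#' divided by the breath period, linearly interpolated to the volume times.
#'
#' @param physio a `physio_recording` or numeric respiratory waveform.
#' @param volume_times acquisition times in seconds.
#' @return numeric RVT vector, one value per volume time.
#' @export
rvt_regressor <- function(physio, volume_times) {
  ch <- physio_channel(physio, "resp")
  x <- ch$x
  peaks <- extrema_times(x, ch$t)
  troughs <- extrema_times(-x, ch$t)
  if (length(peaks) < 2 || length(troughs) < 2)
    stop("too few breaths to compute RVT (need >= 2 peaks and troughs)")
  pv <- stats::approx(ch$t, x, xout = peaks)$y
  tv <- stats::approx(ch$t, x, xout = troughs)$y
  rvt_t <- numeric(length(peaks) - 1)
  rvt_v <- numeric(length(peaks) - 1)
  for (i in seq_len(length(peaks) - 1)) {
    period <- peaks[i + 1] - peaks[i]
    inside <- which(troughs > peaks[i] & troughs < peaks[i + 1])
    trough <- if (length(inside)) min(tv[inside]) else min(tv)
    rvt_t[i] <- (peaks[i] + peaks[i + 1]) / 2
    rvt_v[i] <- (pv[i] - trough) / period
  }
  stats::approx(rvt_t, rvt_v, xout = volume_times, rule = 2)$y
}

# interior local maxima of a waveform (first index wins on plateaus)
extrema_times <- function(x, t) {
  n <- length(x)
  i <- 2:(n - 1)
  t[i[x[i] > x[i - 1] & x[i] >= x[i + 1]]]
}

#' Framewise displacement
#'
#' Power convention: `FD_t = sum |delta translation| + 50 mm * sum
#' |delta rotation|` with rotations converted from degrees to radians and
#' `FD_0 = 0`.
#'
#' @param motion data frame or matrix with 6 columns: three translations in
#'   mm, three rotations in degrees, one row per retained volume.
#' @param head_radius_mm lever arm converting rotations to displacement.
#' @return numeric FD vector in mm, same length as `nrow(motion)`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6) stop("motion trace must have exactly 6 columns, got ", ncol(m))
  if (nrow(m) == 0L) return(numeric(0))
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE] * pi / 180))
  fd
}
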