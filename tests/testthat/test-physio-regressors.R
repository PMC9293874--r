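# RETROICOR phases, RVT, framewise displacement.

# 1-Hz train of narrow bumps with crests at 0.5, 1.5, ... seconds
pulse_train <- function(duration = 10, crest_offset = 0.5) {
  t <- seq(0, duration - 0.025, by = 0.025)
  crests <- seq(crest_offset, duration - 0.5, by = 1)
  x <- rowSums(vapply(crests, function(b) exp(-(t - b)^2 / (2 * 0.05^2)),
                      numeric(length(t))))
  list(t = t, x = x, crests = crests)
}

test_that("cardiac peaks land on dense-grid argmax crests", {
  p <- pulse_train()
  peaks <- detect_cardiac_peaks(p$x)
  expect_length(peaks, 10)
  # oracle: argmax over the dense grid near each crest
  oracle <- vapply(p$crests, function(b) {
    i <- which(abs(p$t - b) < 0.4)
    p$t[i[which.max(p$x[i])]]
  }, 0)
  expect_equal(peaks, oracle, tolerance = 1e-9)
})

test_that("peak detection rejects flat input and breaks plateau ties low", {
  expect_error(detect_cardiac_peaks(rep(1, 400)), "no cardiac peaks")
  # two identical adjacent samples at a crest: first index wins
  x <- c(0, 0, 1, 2, 2, 1, 0, 0, 0, 0, 0, 3, 1, 0)
  peaks <- detect_cardiac_peaks(x, c_mad = 0.5)
  expect_equal(peaks[1], 3 * 0.025)
})

test_that("cardiac phase is linear within the enclosing beat interval", {
  beats <- c(0, 1, 2)
  expect_equal(cardiac_phase(beats, 0.5), pi)
  expect_equal(cardiac_phase(beats, 0), 0)
  expect_equal(cardiac_phase(beats, 1.25), pi / 2)
  expect_warning(cardiac_phase(beats, 2.5), "extrapolating")
  # irregular beats: phase from the enclosing interval
  expect_equal(suppressWarnings(cardiac_phase(c(0, 1, 3), 2)), pi)
})

test_that("respiratory phase equalizes the amplitude histogram", {
  t <- seq(0, 20 - 0.025, by = 0.025)
  x <- sin(2 * pi * t / 4)
  # at the waveform maximum the cumulative histogram is full: |phi| = pi
  expect_equal(abs(respiratory_phase(x, 1)), pi, tolerance = 0.05)
  # direct histogram oracle at an arbitrary time
  t0 <- 0.4                                  # rising part of the first cycle
  brk <- seq(min(x), max(x), length.out = 101)
  cum <- cumsum(tabulate(pmin(pmax(findInterval(x, brk,
                                                rightmost.closed = TRUE),
                                   1L), 100L), nbins = 100))
  a0 <- sin(2 * pi * t0 / 4)
  bin <- min(max(findInterval(a0, brk, rightmost.closed = TRUE), 1L), 100L)
  expect_equal(respiratory_phase(x, t0), pi * cum[bin] / cum[100],
               tolerance = 1e-6)
  # median amplitude: rising -> +pi/2, falling counterpart -> -pi/2
  expect_equal(respiratory_phase(x, 0), pi / 2, tolerance = 0.05)
  expect_equal(respiratory_phase(x, 2), -pi / 2, tolerance = 0.05)
  expect_error(respiratory_phase(rep(2, 400), 1), "constant")
})

test_that("phase is invariant to cardiac amplitude and monotone resp scaling", {
  p <- pulse_train()
  pk1 <- detect_cardiac_peaks(p$x)
  pk2 <- detect_cardiac_peaks(5 * p$x)
  expect_equal(pk1, pk2)
  t <- seq(0, 20 - 0.025, by = 0.025)
  x <- sin(2 * pi * t / 4)
  ph1 <- respiratory_phase(x, c(0.3, 1.1, 2.7))
  ph2 <- respiratory_phase(2 * x + 3, c(0.3, 1.1, 2.7))  # monotone transform
  expect_equal(order(ph1), order(ph2))
})

test_that("RETROICOR columns are the phase harmonics at volume times", {
  beats <- 0:12
  t <- seq(0, 24 - 0.025, by = 0.025)
  resp <- sin(2 * pi * t / 4)
  ph <- physio_recording(rep(0, length(t)), resp)
  # volume exactly at a beat: cardiac phase 0 -> columns [1, 0, 1, 0]
  r <- retroicor_regressors(ph, c(3, 3.25), peak_times = beats)
  expect_equal(unname(r[1, 1:4]), c(1, 0, 1, 0), tolerance = 1e-9)
  # phase pi/2 -> [0, 1, -1, 0]
  expect_equal(unname(r[2, 1:4]), c(0, 1, -1, 0), tolerance = 1e-9)
  vt <- seq(2, 20, by = 2)
  m <- retroicor_regressors(ph, vt, peak_times = beats)
  expect_equal(dim(m), c(10, 8))
  expect_true(all(m >= -1 & m <= 1))
})

test_that("regressing out the RETROICOR basis removes signals built from it", {
  set.seed(4)
  p <- generate_physio(440, seed = 11)
  vt <- seq(0, 424, by = 2)
  m <- retroicor_regressors(p, vt)
  for (i in 1:5) {
    w <- rnorm(8)
    sig <- drop(m %*% w)
    res <- stats::lm.fit(cbind(1, m), sig)$residuals
    expect_lt(sqrt(sum(res^2)) / sqrt(sum(sig^2)), 1e-8)
  }
})

test_that("RVT matches the per-breath oracle", {
  t <- seq(0, 40 - 0.025, by = 0.025)
  x <- 1.5 * sin(2 * pi * t / 4)             # amplitude A = 1.5, period T = 4
  vt <- seq(4, 32, by = 2)
  expect_equal(rvt_regressor(x, vt), rep(2 * 1.5 / 4, length(vt)),
               tolerance = 0.01)
  expect_equal(rvt_regressor(2 * x, vt), 2 * rvt_regressor(x, vt),
               tolerance = 1e-9)             # linearity in amplitude
  # chirp: per-breath hand computation
  phase <- 2 * pi * (t / 5 + t^2 / 400)
  xc <- sin(phase)
  rvt <- rvt_regressor(xc, c(10, 20))
  peaks <- rtnf:::extrema_times(xc, t)
  stopifnot(length(peaks) > 4)
  hand <- function(tt) {
    i <- findInterval(tt, peaks)
    mids <- (peaks[-length(peaks)] + peaks[-1]) / 2
    vals <- vapply(seq_len(length(peaks) - 1), function(j) {
      seg <- t >= peaks[j] & t <= peaks[j + 1]
      (max(xc[seg]) - min(xc[seg])) / (peaks[j + 1] - peaks[j])
    }, 0)
    stats::approx(mids, vals, xout = tt, rule = 2)$y
  }
  expect_equal(rvt, hand(c(10, 20)), tolerance = 0.08)
  expect_error(rvt_regressor(sin(2 * pi * t[1:100] / 20), 1), "too few")
})

test_that("framewise displacement follows the Power convention", {
  m0 <- matrix(1, 10, 6)
  expect_equal(framewise_displacement(m0), rep(0, 10))
  m <- matrix(0, 5, 6)
  m[3, 1:3] <- 0.1                           # translation step of 0.1 mm each
  fd <- framewise_displacement(m)
  expect_equal(fd[3], 0.3)
  expect_equal(fd[4], 0.3)                   # stepping back counts too
  m2 <- matrix(0, 4, 6)
  m2[2, 4] <- 0.01 * 180 / pi                # 0.01 rad on one rotation axis
  expect_equal(framewise_displacement(m2)[2], 0.5)
  expect_equal(framewise_displacement(m2)[1], 0)
  expect_error(framewise_displacement(matrix(0, 5, 4)), "6 columns")
})
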