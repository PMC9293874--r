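# Group statistical battery.

test_that("one-sample t matches the closed form", {
  r <- one_sample_t(c(2, 0, 4, 2))
  expect_equal(r$t, 2.449, tolerance = 1e-3)
  expect_equal(r$cohen_d, 1.2247, tolerance = 1e-4)
  expect_equal(r$df, 3)
  z <- one_sample_t(c(-1, 1, -2, 2))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_error(one_sample_t(c(1, 1)), "zero variance")
  # property: closed form on random inputs
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    r <- one_sample_t(x)
    expect_equal(r$t, mean(x) / (sd(x) / sqrt(length(x))), tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(r$t), length(x) - 1), tolerance = 1e-10)
  }
})

test_that("mixed model reduces to per-condition means in balanced data", {
  # zero between-subject variance: fixed effects equal the condition means
  tab <- simulate_roi_psc_table(12, run_effects = c(OBS = -0.2, NF1 = -0.7,
                                                    TRS = -0.3),
                                subject_sd = 0, resid_sd = 0.2, seed = 6)
  fit <- suppressWarnings(lme_condition(tab))
  means <- tapply(tab$value, tab$run, mean)
  est <- fit$fixed$estimate
  names(est) <- fit$fixed$term
  expect_equal(unname(est["(Intercept)"]), unname(means["NF1"]),
               tolerance = 1e-6)
  expect_equal(unname(est["(Intercept)"] + est[".condOBS"]),
               unname(means["OBS"]), tolerance = 1e-6)
  expect_true(all(c("r2_marginal", "cohens_f") %in% names(fit)))
})

test_that("mixed model detects a one-SD condition shift", {
  rej <- 0
  for (i in 1:40) {
    tab <- simulate_roi_psc_table(
      20, run_effects = c(OBS = 0, NF1 = -0.3, NF2 = -0.3, NF3 = -0.3,
                          TRS = 0),
      subject_sd = 0.3, resid_sd = 0.3, seed = 1000 + i)
    fit <- suppressWarnings(lme_condition(tab))
    if (fit$anova$p[fit$anova$term == ".cond"] < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 40, 0.8)
})

test_that("Tukey pairwise table has all pairs with monotone adjustment", {
  tab <- simulate_roi_psc_table(15, run_effects = c(OBS = 0, NF1 = -0.6,
                                                    NF2 = -0.6, NF3 = -0.5,
                                                    TRS = -0.1),
                                subject_sd = 0.25, resid_sd = 0.25, seed = 2)
  fit <- lme_condition(tab)
  tk <- tukey_pairwise(fit)
  expect_equal(nrow(tk), choose(5, 2))
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  # adjusted p is never below the unadjusted two-sided p of the same t
  raw <- 2 * pnorm(-abs(tk$t))
  expect_true(all(tk$p_adj >= raw - 1e-8))
})

test_that("noise-free equal condition means give adjusted p of 1", {
  tab <- tidyr::expand_grid(subject = sprintf("s%02d", 1:8),
                            run = c("OBS", "NF1", "NF2", "NF3", "TRS"))
  subj_eff <- stats::setNames(seq(-0.3, 0.4, length.out = 8),
                              sprintf("s%02d", 1:8))
  tab$value <- subj_eff[tab$subject]           # no condition effect, no noise
  fit <- suppressWarnings(lme_condition(tab))
  tk <- tukey_pairwise(fit)
  expect_equal(tk$t, rep(0, 10))
  expect_equal(tk$p_adj, rep(1, 10))
})

test_that("Cohen's f transforms R-squared as stated", {
  expect_equal(cohens_f(0.2), 0.5)
  expect_equal(cohens_f(0), 0)
  expect_equal(cohens_f(0.5), 1)
  expect_error(cohens_f(1), "less than 1")
})

test_that("ICC(3,k) matches the definitional ANOVA oracle", {
  icc_oracle <- function(m) {
    # definitional sums of squares of the two-way subjects x runs ANOVA
    n <- nrow(m); k <- ncol(m); g <- mean(m)
    ss_r <- k * sum((rowMeans(m) - g)^2)
    ss_c <- n * sum((colMeans(m) - g)^2)
    ss_e <- sum((m - outer(rowMeans(m), rep(1, k)) -
                   outer(rep(1, n), colMeans(m)) + g)^2)
    bms <- ss_r / (n - 1); ems <- ss_e / ((n - 1) * (k - 1))
    (bms - ems) / bms
  }
  set.seed(5)
  for (i in 1:100) {
    m <- matrix(sample(0:20, 18, replace = TRUE), 6, 3)
    if (sd(rowMeans(m)) == 0) next
    expect_equal(icc3k(m)$icc, icc_oracle(m), tolerance = 1e-10)
  }
  # identical columns: EMS = 0, ICC = 1
  v <- c(1, 4, 2, 8, 5, 7)
  expect_equal(icc3k(cbind(v, v, v))$icc, 1)
  expect_error(icc3k(matrix(c(1, NA, 3, 4, 5, 6), 3)), "missing")
})

test_that("ICC is near zero for independent noise", {
  # the estimator is consistent; at n = 100 subjects the small-sample
  # negative bias of (BMS - EMS)/BMS is below 0.01
  set.seed(6)
  vals <- replicate(200, icc3k(matrix(rnorm(500), 100, 5))$icc)
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(200) + 0.02)
})

test_that("ICC confidence bounds bracket the estimate", {
  set.seed(7)
  m <- matrix(rnorm(30), 10, 3) + rnorm(10) * 2
  r <- icc3k(m)
  expect_lt(r$ci_low, r$icc)
  expect_gt(r$ci_high, r$icc)
})

test_that("correlation table applies the declared Bonferroni family", {
  x <- data.frame(a = 1:10)
  y <- data.frame(b = 2 * (1:10) + 1, c = rnorm(10))
  r <- pearson_bonferroni(x, y)
  expect_equal(r$r[r$y == "b"], 1, tolerance = 1e-12)
  expect_true(all(r$p_adj <= 1))
  expect_equal(r$p_adj, pmin(1, 2 * r$p))
  r4 <- pearson_bonferroni(x, y, family_size = 40)
  expect_equal(r4$p_adj, pmin(1, 40 * r4$p))
  y$flat <- 5
  expect_warning(r2 <- pearson_bonferroni(x, y), "zero-variance")
  expect_false("flat" %in% r2$y)
})

test_that("RM-ANOVA power is alpha at f = 0 and monotone in n, f, rho", {
  expect_equal(rm_anova_power(34, 5, 0, 0.5, 0.05), 0.05, tolerance = 1e-10)
  p <- vapply(c(10, 20, 34, 60), function(n) rm_anova_power(n, 5, 0.25), 0)
  expect_true(all(diff(p) > 0))
  pf_ <- vapply(c(0.1, 0.25, 0.4), function(f) rm_anova_power(34, 5, f), 0)
  expect_true(all(diff(pf_) > 0))
  pr <- vapply(c(0.2, 0.5, 0.8), function(r) rm_anova_power(34, 5, 0.25, r), 0)
  expect_true(all(diff(pr) > 0))
  expect_error(rm_anova_power(34, 5, 0.25, rho = 1), "rho")
})
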