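# Group-level statistical battery: t-tests, mixed models, Tukey follow-ups,
# effect sizes, ICC(3,k), Bonferroni-adjusted correlations, RM-ANOVA power.

#' One-sample t-test with Cohen's d
#'
#' `t = mean / (sd / sqrt(n))`, two-sided p on `n - 1` degrees of freedom,
#' `d = mean / sd`.
#'
#' @param values numeric vector, `n >= 2`, non-zero variance.
#' @return one-row tibble: `estimate`, `t`, `df`, `p`, `cohen_d`, `n`.
#' @export
one_sample_t <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  stopifnot(n >= 2)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: one-sample t undefined")
  t_ <- mean(x) / (s / sqrt(n))
  tibble::tibble(estimate = mean(x), t = t_, df = n - 1,
                 p = 2 * stats::pt(-abs(t_), n - 1),
                 cohen_d = mean(x) / s, n = n)
}

#' Linear mixed-effects model across conditions
#'
#' Random-intercept model `value ~ condition (+ age + sex) + (1 | subject)`
#' fitted by REML, with the omnibus condition F using Satterthwaite
#' denominator degrees of freedom and a Nakagawa-style marginal R-squared
#' (fixed-effect variance over total variance). A singular fit falls back to
#' ordinary least squares with a warning.
#'
#' @param data long table with columns `subject`, `run` (or `timepoint`),
#'   `value`, and optionally `age`, `sex`.
#' @param covariates character vector of covariate column names to include.
#' @param condition name of the condition column.
#' @return list of class `nf_lme`: `fit` (lmerMod or lm), `anova` (tibble of
#'   fixed-effect F tests), `fixed` (tibble of coefficients), `r2_marginal`,
#'   `cohens_f`, `singular`.
#' @export
lme_condition <- function(data, covariates = character(0),
                          condition = "run") {
  stopifnot(condition %in% names(data), "value" %in% names(data),
            "subject" %in% names(data),
            all(covariates %in% names(data)))
  d <- dplyr::mutate(data,
                     .cond = factor(.data[[condition]]),
                     subject = factor(.data$subject))
  stopifnot(nlevels(d$.cond) >= 2, nlevels(d$subject) >= 3)
  rhs <- paste(c(".cond", covariates), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject)"))
  fit <- tryCatch(suppressMessages(lmerTest::lmer(form, data = d)),
                  error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit)
  if (singular) {
    warning("singular or degenerate mixed-model fit; falling back to OLS")
    fit_ols <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = d)
    an <- stats::anova(fit_ols)
    an_tbl <- tibble::tibble(term = rownames(an)[rownames(an) != "Residuals"],
                             df1 = an$Df[rownames(an) != "Residuals"],
                             df2 = an$Df[rownames(an) == "Residuals"],
                             f = an$`F value`[rownames(an) != "Residuals"],
                             p = an$`Pr(>F)`[rownames(an) != "Residuals"])
    co <- summary(fit_ols)$coefficients
    fixed <- tibble::tibble(term = rownames(co), estimate = co[, 1],
                            se = co[, 2], stat = co[, 3], p = co[, 4])
    r2 <- summary(fit_ols)$r.squared
    out_fit <- fit_ols
  } else {
    an <- stats::anova(fit, ddf = "Satterthwaite")
    an_tbl <- tibble::tibble(term = rownames(an), df1 = an$NumDF,
                             df2 = an$DenDF, f = an$`F value`,
                             p = an$`Pr(>F)`)
    co <- summary(fit)$coefficients
    fixed <- tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                            se = co[, "Std. Error"], stat = co[, "t value"],
                            p = co[, "Pr(>|t|)"])
    vf <- stats::var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    r2 <- vf / (vf + sum(vc$vcov))
    out_fit <- fit
  }
  structure(list(fit = out_fit, anova = an_tbl, fixed = fixed,
                 r2_marginal = r2, cohens_f = cohens_f(r2),
                 singular = singular, condition = condition),
            class = "nf_lme")
}

#' Tukey-adjusted pairwise condition comparisons
#'
#' All pairwise contrasts between condition levels from a fitted
#' [lme_condition()] model, family-wise adjusted with the single-step
#' (multivariate-t) method of `multcomp::glht`, i.e. Tukey's HSD family.
#' Degenerate noise-free contrasts (estimate 0, SE 0) report `t = 0`,
#' adjusted `p = 1` by convention.
#'
#' @param model an `nf_lme` from [lme_condition()].
#' @return tibble with one row per pair: `contrast`, `estimate`, `se`, `t`,
#'   `p_adj`.
#' @export
tukey_pairwise <- function(model) {
  stopifnot(inherits(model, "nf_lme"))
  glht_fit <- multcomp::glht(model$fit,
                             linfct = multcomp::mcp(.cond = "Tukey"))
  sm <- summary(glht_fit)
  est <- as.numeric(sm$test$coefficients)
  se <- as.numeric(sm$test$sigma)
  t_ <- as.numeric(sm$test$tstat)
  p_ <- as.numeric(sm$test$pvalues)
  degen <- abs(est) < 1e-12 & se < 1e-12
  t_[degen] <- 0
  p_[degen] <- 1
  tibble::tibble(contrast = names(sm$test$coefficients),
                 estimate = est, se = se, t = t_, p_adj = p_)
}

#' Cohen's f from a model R-squared
#'
#' `f = sqrt(R^2 / (1 - R^2))`.
#'
#' @param r2 R-squared in `[0, 1)`.
#' @return Cohen's f.
#' @export
cohens_f <- function(r2) {
  stopifnot(r2 >= 0)
  if (r2 >= 1) stop("R-squared must be strictly less than 1")
  sqrt(r2 / (1 - r2))
}

#' ICC(3, k): two-way mixed, consistency of averages
#'
#' From the subjects x measurements ANOVA decomposition,
#' `ICC = (BMS - EMS) / BMS`, with the 95% confidence interval from
#' F-distribution bounds on `BMS / EMS`.
#'
#' @param m numeric matrix, subjects in rows, repeated measurements (runs) in
#'   columns; no missing cells.
#' @param conf confidence level.
#' @return one-row tibble: `icc`, `ci_low`, `ci_high`, `f`, `df1`, `df2`,
#'   `n`, `k`.
#' @export
icc3k <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed in ICC(3,k)")
  n <- nrow(m)
  k <- ncol(m)
  stopifnot(n >= 3, k >= 2)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  icc <- (bms - ems) / bms
  f <- bms / ems
  a <- 1 - conf
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- f / stats::qf(1 - a / 2, df1, df2)
  fu <- f * stats::qf(1 - a / 2, df2, df1)
  tibble::tibble(icc = icc, ci_low = 1 - 1 / fl, ci_high = 1 - 1 / fu,
                 f = f, df1 = df1, df2 = df2, n = n, k = k)
}

#' Pairwise Pearson correlations with Bonferroni adjustment
#'
#' Correlates every column of `x` with every column of `y`; adjusted
#' `p = min(1, m * p)` where `m` is the declared family size (default: the
#' number of tests performed). Zero-variance columns are flagged and
#' excluded.
#'
#' @param x,y data frames or matrices of numeric columns.
#' @param family_size Bonferroni family size `m`.
#' @return tibble with columns `x`, `y`, `n`, `r`, `p`, `p_adj`; attribute
#'   `excluded` names any zero-variance columns.
#' @export
pearson_bonferroni <- function(x, y, family_size = NULL) {
  x <- as.data.frame(x)
  y <- as.data.frame(y)
  bad_x <- names(x)[vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0,
                           TRUE)]
  bad_y <- names(y)[vapply(y, function(v) stats::sd(v, na.rm = TRUE) == 0,
                           TRUE)]
  if (length(c(bad_x, bad_y)))
    warning("excluding zero-variance column(s): ",
            paste(c(bad_x, bad_y), collapse = ", "))
  x <- x[setdiff(names(x), bad_x)]
  y <- y[setdiff(names(y), bad_y)]
  pairs <- tidyr::expand_grid(x = names(x), y = names(y))
  m <- family_size %||% nrow(pairs)
  res <- purrr::map2_dfr(pairs$x, pairs$y, function(cx, cy) {
    ok <- stats::complete.cases(x[[cx]], y[[cy]])
    stopifnot(sum(ok) >= 3)
    ct <- stats::cor.test(x[[cx]][ok], y[[cy]][ok])
    tibble::tibble(x = cx, y = cy, n = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value,
                   p_adj = min(1, m * ct$p.value))
  })
  structure(res, excluded = c(bad_x, bad_y))
}

#' Power of the repeated-measures ANOVA condition test
#'
#' Within-subject F test under compound symmetry: noncentrality
#' `lambda = n m f^2 / (1 - rho)`, numerator df `m - 1`, denominator df
#' `(n - 1)(m - 1)`, power `P(F' > F_crit)` with `F'` noncentral F.
#' Nonsphericity correction is fixed at 1 (compound symmetry assumed).
#'
#' @param n subjects.
#' @param m_conditions repeated conditions per subject.
#' @param f Cohen's f for the condition effect (relative to total SD).
#' @param rho within-subject correlation, `0 <= rho < 1`.
#' @param alpha test size.
#' @return power (scalar in `[0, 1]`).
#' @export
rm_anova_power <- function(n, m_conditions, f, rho = 0.5, alpha = 0.05) {
  stopifnot(n >= 2, m_conditions >= 2, f >= 0)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  df1 <- m_conditions - 1
  df2 <- (n - 1) * (m_conditions - 1)
  lambda <- n * m_conditions * f^2 / (1 - rho)
  crit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = lambda)
}
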