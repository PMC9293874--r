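# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a run-level GLM
#'
#' @param x an `nf_glm`.
#' @param voxel column (voxel) index to report; defaults to all, stacked.
#' @param ... unused.
#' @return tibble with `voxel`, `term`, `estimate` rows for every regressor
#'   and contrast.
#' @export
tidy.nf_glm <- function(x, voxel = NULL, ...) {
  vox <- voxel %||% seq_len(ncol(x$betas))
  b <- rbind(x$betas, x$contrasts)[, vox, drop = FALSE]
  tibble::tibble(voxel = rep(vox, each = nrow(b)),
                 term = rep(rownames(b), length(vox)),
                 estimate = as.numeric(b))
}

#' @rdname tidy.nf_glm
#' @export
glance.nf_glm <- function(x, ...) {
  tibble::tibble(n_volumes = nrow(x$design), n_regressors = ncol(x$design),
                 dof = x$dof, n_censored = sum(x$censor %||% 0),
                 mean_sigma2 = mean(x$sigma2))
}

#' Tidy a PPI result
#'
#' @param x an `nf_ppi`.
#' @param ... unused.
#' @return tibble with one row per voxel: `voxel`, `beta`, `t`.
#' @export
tidy.nf_ppi <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$beta), beta = as.numeric(x$beta),
                 t = as.numeric(x$t))
}

#' @rdname tidy.nf_ppi
#' @export
glance.nf_ppi <- function(x, ...) {
  tibble::tibble(dof = x$dof, n_censored = length(x$censored),
                 n_regressors = length(x$design_names))
}

#' Tidy a mixed-model condition analysis
#'
#' @param x an `nf_lme`.
#' @param effects `"fixed"` for coefficients or `"anova"` for the omnibus
#'   F table.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.nf_lme <- function(x, effects = c("fixed", "anova"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$fixed else x$anova
}

#' @rdname tidy.nf_lme
#' @export
glance.nf_lme <- function(x, ...) {
  tibble::tibble(r2_marginal = x$r2_marginal, cohens_f = x$cohens_f,
                 singular = x$singular)
}
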