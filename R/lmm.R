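## Per-marker linear mixed-effects sub-model.
##
## Fixed effects: intercept, time (months), arm, arm x time, baseline
## marker value; random intercept and slope per subject with an
## unstructured 2x2 covariance. PSA is modelled on the log(x+1) scale.

#' Specification of the longitudinal sub-model for one marker
#'
#' @param marker Marker name.
#' @param reml Use restricted maximum likelihood (default) or ML.
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(marker, reml = TRUE) {
  stop_if_not(marker %in% marker_names(), "unknown marker: ", marker)
  structure(list(marker = marker, reml = reml,
                 transform = if (marker == "PSA") "log1p" else "identity"),
            class = "lmm_spec")
}

# Long-format series + subjects -> analysis frame on the modelling scale.
# The time-0 measurement is the recorded baseline itself, which already
# enters the fixed effects as a covariate; it is dropped as a response
# (keeping it would count the same number twice and deflate the
# random-intercept variance).
lmm_frame <- function(series, subjects, marker) {
  s <- series[series$marker == marker & series$time_months > 0, ,
              drop = FALSE]
  stop_if_not(nrow(s) > 0, "no observations for marker ", marker)
  idx <- match(s$id, subjects$id)
  stop_if_not(!anyNA(idx), "series ids missing from subjects table")
  data.frame(
    id = s$id,
    y = marker_to_model_scale(marker, s$value),
    time = s$time_months,
    arm = subjects$arm[idx],
    base = marker_to_model_scale(marker,
                                 subjects[[paste0("baseline_", marker)]][idx])
  )
}

#' Fit the linear mixed-effects sub-model for a marker
#'
#' `y ~ time + arm + arm:time + baseline` with per-subject random
#' intercept and slope (unstructured covariance), fitted by (RE)ML via
#' \pkg{lme4}.
#'
#' @param series Long-format marker table (`id`, `marker`, `time_months`,
#'   `value`).
#' @param subjects Subjects table (for `arm` and baseline values).
#' @param spec An [lmm_spec()].
#' @return An object of class `serojm_lmm` with elements `beta` (named
#'   fixed effects), `beta_se`, `D` (2x2 random-effect covariance),
#'   `sigma`, `loglik`, `converged`, `n_subjects`, `n_obs`.
#' @export
fit_lmm <- function(series, subjects, spec) {
  stop_if_not(inherits(spec, "lmm_spec"), "spec must be an lmm_spec")
  df <- lmm_frame(series, subjects, spec$marker)
  stop_if_not(length(unique(df$id)) >= 2 && nrow(df) >= 4,
              "need >= 2 observations for >= 2 subjects")
  stop_if_not(all(is.finite(df$time)), "visit times must be finite")
  X <- model.matrix(~ 1 + time + arm + arm:time + base, df)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effect design (e.g. a single treatment arm ",
         "with `arm` among the fixed effects)")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- lme4::lmer(y ~ 1 + time + arm + arm:time + base + (1 + time | id),
                    data = df, REML = spec$reml, control = ctrl)
  fe <- lme4::fixef(fit)
  ord <- c("(Intercept)", "time", "arm", "time:arm", "base")
  fe <- fe[ord]
  se <- sqrt(diag(as.matrix(vcov(fit))))[ord]
  names(fe) <- names(se) <-
    c("intercept", "time", "arm", "arm_time", "base")
  vc <- lme4::VarCorr(fit)
  D <- as.matrix(vc$id)[1:2, 1:2]
  dimnames(D) <- list(c("b0", "b1"), c("b0", "b1"))
  conv <- length(fit@optinfo$conv$lme4) == 0
  structure(list(marker = spec$marker, spec = spec,
                 beta = fe, beta_se = se, D = D,
                 sigma = attr(vc, "sc"),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = conv,
                 n_subjects = length(unique(df$id)), n_obs = nrow(df)),
            class = "serojm_lmm")
}

#' @export
print.serojm_lmm <- function(x, ...) {
  cat("Linear mixed-effects sub-model:", x$marker,
      if (x$marker == "PSA") "(log(x+1) scale)" else "", "\n")
  cat(sprintf("  %d subjects, %d observations, logLik %.2f%s\n",
              x$n_subjects, x$n_obs, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(rbind(estimate = x$beta, se = x$beta_se), 4))
  cat("  random-effect SDs:", round(sqrt(diag(x$D)), 4),
      " corr:", round(stats::cov2cor(x$D)[1, 2], 3),
      " residual SD:", round(x$sigma, 4), "\n")
  invisible(x)
}

# Fixed-effect part of the linear predictor at times t for one subject.
lmm_fixed_part <- function(beta, arm, base, t) {
  beta[["intercept"]] + beta[["time"]] * t + beta[["arm"]] * arm +
    beta[["arm_time"]] * arm * t + beta[["base"]] * base
}

# Empirical-Bayes posterior of (b0, b1) given a subject's history
# (Gaussian conjugate algebra; no survival conditioning).
eb_posterior <- function(beta, D, sigma, arm, base, times, y_model) {
  Dinv <- solve(D + diag(1e-8 * max(diag(D)), 2))
  if (length(times) == 0)
    return(list(mean = c(0, 0), var = D))
  Z <- cbind(1, times)
  r <- y_model - lmm_fixed_part(beta, arm, base, times)
  P <- crossprod(Z) / sigma^2 + Dinv
  V <- solve(P)
  list(mean = drop(V %*% (crossprod(Z, r) / sigma^2)), var = V)
}

#' Subject-specific current value of a marker
#'
#' Plugs the empirical-Bayes (posterior mean, equal to the posterior
#' mode in this Gaussian model) random effects given the subject's
#' history into the linear predictor. With an empty history the
#' population (fixed-effects-only) prediction is returned.
#'
#' @param fit A [fit_lmm()] result.
#' @param subject One-row subject data (uses `arm` and the marker's
#'   baseline).
#' @param history Data frame with `time_months` and `value`
#'   (native scale) up to the time of prediction; may have zero rows.
#' @param t_query Months (vectorised), `>= 0`.
#' @param scale `"model"` (default) or `"native"` reporting scale.
#' @return Predicted current value(s).
#' @export
predict_current_value <- function(fit, subject, history, t_query,
                                  scale = c("model", "native")) {
  scale <- match.arg(scale)
  stop_if_not(all(t_query >= 0), "t_query must be >= 0")
  base <- marker_to_model_scale(fit$marker,
                                subject[[paste0("baseline_", fit$marker)]])
  if (is.null(history) || nrow(history) == 0) {
    post <- list(mean = c(0, 0), var = fit$D)
  } else {
    post <- eb_posterior(fit$beta, fit$D, fit$sigma, subject$arm, base,
                         history$time_months,
                         marker_to_model_scale(fit$marker, history$value))
  }
  m <- lmm_fixed_part(fit$beta, subject$arm, base, t_query) +
    post$mean[1] + post$mean[2] * t_query
  if (scale == "native") marker_from_model_scale(fit$marker, m) else m
}
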