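## Landmark dynamic prediction: conditional survival beyond a landmark
## time t given the marker history up to t, with the subject's random
## effects conditioned on both the measurements and survival to t.
## Beyond t the subject's trajectory extrapolates the fitted linear
## predictor (no future measurements are used).

# One-subject internal frame shaped like build_jm_data output.
subject_pred_data <- function(fit, subject, history, t) {
  mdat <- list()
  for (m in fit$markers) {
    s <- fit$scales[[m]]
    h <- history[history$marker == m & history$time_months <= t &
                   history$time_months > 0, , drop = FALSE]
    base <- marker_to_model_scale(m, subject[[paste0("baseline_", m)]]) / s
    tt <- h$time_months
    y <- marker_to_model_scale(m, h$value) / s
    mdat[[m]] <- list(
      y = y, t = tt, id_idx = rep(1L, length(tt)),
      off = c(0L, length(tt)),
      X = cbind(1, tt, subject$arm, subject$arm * tt, base),
      arm = subject$arm, base = base)
  }
  list(subjects = subject, status = 0, Ti = t,
       W = surv_design(subject), knots = fit$knots, mdat = mdat,
       markers = fit$markers)
}

#' Posterior random effects given a subject's history
#'
#' Conditions the subject's random effects on the marker measurements
#' up to the landmark `t` and on survival to `t`, under the fitted
#' joint model. Returns the posterior mode, a Gaussian (Laplace)
#' covariance from the curvature at the mode, and optionally draws from
#' that normal approximation.
#'
#' @param fit A `serojm_jm` object.
#' @param subject One-row subject data (baseline covariates).
#' @param history Long-format marker measurements for this subject
#'   (rows after `t` are ignored); may be empty, in which case the
#'   population random-effect distribution (conditioned on survival to
#'   `t`) is used and a message is emitted.
#' @param t Landmark time (months); the subject is assumed event-free
#'   at `t`.
#' @param n_draws Number of draws from the normal approximation
#'   (0 = none).
#' @return List with `mode` (length 2 x markers: b0, b1 per marker),
#'   `var`, and `draws` (matrix) if requested.
#' @export
posterior_random_effects <- function(fit, subject, history, t,
                                     n_draws = 0) {
  if (is.null(history) || nrow(history) == 0) {
    message("empty marker history: using the population random-effect ",
            "distribution conditioned on survival")
    history <- data.frame(id = numeric(0), marker = character(0),
                          time_months = numeric(0), value = numeric(0))
  }
  dat <- subject_pred_data(fit, subject, history, t)
  md <- subject_b_mode(1, dat, fit$long, fit$gamma, fit$alpha, fit$loglam,
                       trunc_time = t)
  V <- solve(-md$H)
  out <- list(mode = md$b, var = V)
  if (n_draws > 0) {
    z <- matrix(rnorm(n_draws * length(md$b)), n_draws)
    out$draws <- sweep(z %*% chol((V + t(V)) / 2), 2, -md$b)
  }
  out
}

# survival ratio S(u | b) / S(t | b) for draw-specific (A, B), vectorised
# over draws and horizons; the last baseline segment is extended beyond
# the knot support.
cond_surv_draws <- function(A, B, knots, loglam, t, horizons) {
  lam <- exp(loglam)
  Kseg <- length(lam)
  upper <- max(knots)
  Hdiff <- matrix(0, length(A), length(horizons))
  for (h in seq_along(horizons)) {
    u <- horizons[h]
    acc <- numeric(length(A))
    for (j in seq_len(Kseg)) {
      lo <- knots[j]
      hi <- if (j == Kseg) Inf else knots[j + 1]
      a <- pmax(lo, t); bnd <- pmin(hi, u)
      if (bnd <= a) next
      # I0 over [a, bnd] per draw
      c_ <- B
      small <- abs(c_) * max(abs(a), abs(bnd), 1) < 1e-7
      I0 <- ifelse(small,
                   (bnd - a) + c_ * (bnd^2 - a^2) / 2,
                   exp(c_ * a) * expm1(c_ * (bnd - a)) / c_)
      acc <- acc + lam[j] * exp(A) * I0
    }
    Hdiff[, h] <- acc
  }
  exp(-Hdiff)
}

#' Conditional survival beyond a landmark
#'
#' `pi(u | t) = E_b[S(u | b, w) / S(t | b, w)]` over the subject's
#' random-effect posterior (Monte Carlo over draws from the Laplace
#' normal approximation, or the plug-in mode), with the survival
#' function from the fitted piecewise-constant hazard and the subject's
#' extrapolated linear predictor.
#'
#' @inheritParams posterior_random_effects
#' @param horizons Horizon times `u >= t` (months).
#' @param n_draws Monte Carlo draws (default 500); ignored for
#'   `method = "laplace"`.
#' @param method `"mc"` (default) or `"laplace"` (plug-in posterior
#'   mode, faster).
#' @return Data frame of class `dynamic_prediction` with columns `id`,
#'   `landmark`, `horizon`, `pi_hat`, `risk`.
#' @export
conditional_survival <- function(fit, subject, t, horizons,
                                 history = NULL, n_draws = 500,
                                 method = c("mc", "laplace")) {
  method <- match.arg(method)
  stop_if_not(all(horizons >= t), "horizons must be >= landmark t")
  if (any(horizons > max(fit$knots)))
    warning("horizon(s) beyond the fitted baseline-hazard support (",
            round(max(fit$knots), 1), " months): last-segment hazard ",
            "extrapolated")
  post <- posterior_random_effects(fit, subject, history, t,
                                   n_draws = if (method == "mc")
                                     n_draws else 0)
  bdr <- if (method == "mc") post$draws else
    matrix(post$mode, 1, byrow = TRUE)
  K <- length(fit$markers)
  eta_w <- drop(surv_design(subject) %*% fit$gamma[surv_covariate_names()])
  A <- rep(eta_w, nrow(bdr)); B <- numeric(nrow(bdr))
  for (k in seq_len(K)) {
    m <- fit$markers[k]
    beta <- fit$long[[m]]$beta
    base <- marker_to_model_scale(m, subject[[paste0("baseline_", m)]]) /
      fit$scales[[m]]
    fpA <- beta[1] + beta[3] * subject$arm + beta[5] * base
    fpB <- beta[2] + beta[4] * subject$arm
    A <- A + fit$alpha[[m]] * (fpA + bdr[, 2 * k - 1])
    B <- B + fit$alpha[[m]] * (fpB + bdr[, 2 * k])
  }
  S <- cond_surv_draws(A, B, fit$knots, fit$loglam, t, horizons)
  pi_hat <- pmin(pmax(colMeans(S), 0), 1)
  structure(data.frame(id = subject$id, landmark = t, horizon = horizons,
                       pi_hat = pi_hat, risk = 1 - pi_hat),
            class = c("dynamic_prediction", "data.frame"))
}

#' Dynamic predictions for many subjects
#'
#' Vectorised wrapper around [conditional_survival()] for a cohort:
#' predictions use only each subject's measurements up to the landmark
#' and condition on survival to it.
#'
#' @param fit A `serojm_jm` object.
#' @param subjects Subjects table (only at-risk rows are sensible).
#' @param series Long-format marker table.
#' @param landmark Landmark time t (months).
#' @param horizons Horizon grid `u >= t`.
#' @param n_draws,method Passed to [conditional_survival()].
#' @return Data frame `id`, `landmark`, `horizon`, `pi_hat`, `risk`.
#' @export
predict_dynamic <- function(fit, subjects, series, landmark, horizons,
                            n_draws = 100, method = "mc") {
  out <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects[i, , drop = FALSE]
    hist_i <- series[series$id == sub$id, , drop = FALSE]
    out[[i]] <- suppressMessages(conditional_survival(
      fit, sub, landmark, horizons, history = hist_i,
      n_draws = n_draws, method = method))
  }
  do.call(rbind, out)
}
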