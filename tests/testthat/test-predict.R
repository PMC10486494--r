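# A frozen single-marker joint fit with hand-set parameters, so every
# prediction check is deterministic.
frozen_fit <- function(alpha = -0.2, gamma = NULL) {
  if (is.null(gamma))
    gamma <- setNames(c(0.25, 0.5, 0.4, 0.1, 0.2, -0.02, -0.04, 0.05,
                        -0.45), surv_covariate_names())
  serojm:::new_serojm_jm(
    backend = "full_likelihood", endpoint = "OS", markers = "Hb",
    scales = c(Hb = 1),
    long = list(Hb = list(beta = c(0.3, 0.01, 0.2, -0.005, 0.97),
                          sigma = 0.5,
                          D = matrix(c(0.8^2, -0.005, -0.005, 0.04^2), 2))),
    gamma = gamma, alpha = c(Hb = alpha),
    gamma_se = setNames(rep(0.1, 9), surv_covariate_names()),
    alpha_se = c(Hb = 0.05),
    loglam = log(c(0.01, 0.02, 0.03, 0.05)), knots = c(0, 15, 30, 45, 61),
    loglik = NA, converged = TRUE, interval = "wald", meta = list())
}

pred_subject <- function(arm = 0, hb = 13) {
  data.frame(id = 1, arm = arm, ecog = 0, skeletal_ge10 = 1,
             liver_met = 0, nodal_n1 = 0, gleason_9_10 = 0,
             worst_pain = 1, baseline_Hb = hb, baseline_PSA = 10,
             baseline_NLR = 2, baseline_PLR = 140, baseline_LMR = 5)
}

hb_history <- function(times, values) {
  data.frame(id = 1, marker = "Hb", time_months = times, value = values)
}

test_that("conditional survival is 1 at the landmark and nonincreasing", {
  fit <- frozen_fit()
  sub <- pred_subject()
  h <- hb_history(c(0, 6, 12, 24), c(13, 12.8, 12.5, 12.2))
  set.seed(1)
  pr <- conditional_survival(fit, sub, 24, c(24, 30, 36, 48, 60),
                             history = h, n_draws = 200)
  expect_equal(pr$pi_hat[1], 1)
  expect_true(all(diff(pr$pi_hat) <= 1e-12))
  expect_true(all(pr$pi_hat >= 0 & pr$pi_hat <= 1))
  expect_equal(pr$risk, 1 - pr$pi_hat)
})

test_that("alpha = 0 reduces to the Cox-only survival ratio", {
  fit <- frozen_fit(alpha = 0)
  sub <- pred_subject(arm = 1, hb = 12)
  h <- hb_history(c(0, 6, 12), c(12, 12.4, 12.1))
  set.seed(2)
  pr <- conditional_survival(fit, sub, 12, c(18, 30, 54), history = h,
                             n_draws = 50)
  eta <- drop(serojm:::surv_design(sub) %*% fit$gamma)
  H <- function(t) serojm:::pc_cumhaz(t, eta, 0, fit$knots, fit$loglam)
  expected <- exp(-(vapply(c(18, 30, 54), H, numeric(1)) - H(12)))
  expect_equal(pr$pi_hat, expected, tolerance = 1e-6)
})

test_that("posterior random effects match the conjugate normal oracle", {
  fit <- frozen_fit(alpha = 0)   # survival does not inform b when alpha=0
  sub <- pred_subject()
  h <- hb_history(c(0, 3, 9), c(13.5, 13.0, 12.4))
  post <- posterior_random_effects(fit, sub, h, 12)
  p <- fit$long$Hb
  # oracle on the post-baseline rows (the time-0 row is the baseline
  # covariate itself and is not used as a response)
  hp <- h[h$time_months > 0, ]
  oracle <- serojm:::eb_posterior(
    setNames(p$beta, c("intercept", "time", "arm", "arm_time", "base")),
    p$D, p$sigma, sub$arm, 13, hp$time_months, hp$value)
  expect_equal(post$mode, oracle$mean, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(post$var, oracle$var, tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("survival conditioning shifts the posterior toward low risk", {
  sub <- pred_subject()
  h <- hb_history(0, 13)
  # alpha < 0: high Hb protective, so surviving to 24 months favours
  # higher Hb levels (larger b0) than the alpha = 0 posterior
  p0 <- posterior_random_effects(frozen_fit(alpha = 0), sub, h, 24)
  p1 <- posterior_random_effects(frozen_fit(alpha = -0.8), sub, h, 24)
  expect_gt(p1$mode[1], p0$mode[1])
})

test_that("a rising PSA history lowers predicted survival", {
  fit <- serojm:::new_serojm_jm(
    backend = "full_likelihood", endpoint = "OS", markers = "PSA",
    scales = c(PSA = 1),
    long = list(PSA = list(beta = c(0.1, -0.005, -0.1, -0.002, 0.95),
                           sigma = 0.3,
                           D = matrix(c(0.5^2, 0, 0, 0.03^2), 2))),
    gamma = setNames(numeric(9), surv_covariate_names()),
    alpha = c(PSA = 0.3),
    gamma_se = setNames(rep(0.1, 9), surv_covariate_names()),
    alpha_se = c(PSA = 0.05),
    loglam = log(c(0.02, 0.03, 0.04, 0.05)), knots = c(0, 15, 30, 45, 61),
    loglik = NA, converged = TRUE, interval = "wald", meta = list())
  sub <- pred_subject()
  tt <- c(0, 6, 12, 18, 24)
  rising <- data.frame(id = 1, marker = "PSA", time_months = tt,
                       value = expm1(2.3 + 0.08 * tt))
  flat <- data.frame(id = 1, marker = "PSA", time_months = tt,
                     value = expm1(rep(2.3, 5)))
  set.seed(3)
  pr_r <- conditional_survival(fit, sub, 24, 60, history = rising,
                               n_draws = 300)
  set.seed(3)
  pr_f <- conditional_survival(fit, sub, 24, 60, history = flat,
                               n_draws = 300)
  expect_lt(pr_r$pi_hat, pr_f$pi_hat)
})

test_that("plug-in chaining is consistent across landmarks", {
  fit <- frozen_fit(alpha = 0)   # posterior identical at all landmarks
  sub <- pred_subject()
  h <- hb_history(c(0, 6, 12), c(13, 12.9, 12.7))
  p_t_u <- conditional_survival(fit, sub, 12, 60, history = h,
                                method = "laplace")$pi_hat
  p_t_s <- conditional_survival(fit, sub, 12, 36, history = h,
                                method = "laplace")$pi_hat
  p_s_u <- conditional_survival(fit, sub, 36, 60, history = h,
                                method = "laplace")$pi_hat
  expect_equal(p_t_u, p_t_s * p_s_u, tolerance = 1e-6)
})

test_that("empty history falls back to the population distribution", {
  fit <- frozen_fit()
  sub <- pred_subject()
  expect_message(
    post <- posterior_random_effects(fit, sub, NULL, 6),
    "population")
  expect_equal(length(post$mode), 2)
})

test_that("horizons beyond the baseline-hazard support are flagged", {
  fit <- frozen_fit()
  sub <- pred_subject()
  h <- hb_history(0, 13)
  expect_warning(
    conditional_survival(fit, sub, 24, c(24, 80), history = h,
                         method = "laplace"),
    "extrapolat")
})

test_that("later landmarks improve prediction of the true trajectory", {
  # with history observed on the generating line, the EB slope estimate
  # tightens as the landmark grows
  fit <- frozen_fit(alpha = 0)
  sub <- pred_subject()
  b_true <- c(0.5, -0.05)
  tt_all <- c(0, 3, 6, 9, 12, 15, 18, 21, 24)
  mk_val <- function(t) 0.3 + 0.97 * 13 + b_true[1] +
    (0.01 + b_true[2]) * t
  err <- vapply(c(6, 24), function(lm_t) {
    h <- hb_history(tt_all[tt_all <= lm_t],
                    mk_val(tt_all[tt_all <= lm_t]))
    post <- posterior_random_effects(fit, sub, h, lm_t)
    sum(abs(post$mode - b_true))
  }, numeric(1))
  expect_lt(err[2], err[1])
})
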