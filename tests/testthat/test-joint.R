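library(survival)

# Minimal hand-built cohort for likelihood oracles.
tiny_joint_data <- function(n = 2, visits = c(0, 3, 8), seed = 5,
                            sd_b0 = 0.6, sd_b1 = 0.05, sigma = 0.4) {
  set.seed(seed)
  subs <- data.frame(
    id = seq_len(n), arm = rep(0:1, length.out = n),
    ecog = rep(c(0, 1), length.out = n), skeletal_ge10 = 1, liver_met = 0,
    nodal_n1 = 0, gleason_9_10 = rep(c(1, 0), length.out = n),
    worst_pain = 2, baseline_Hb = round(rnorm(n, 13, 1), 1),
    baseline_PSA = 12, baseline_NLR = 2, baseline_PLR = 140,
    baseline_LMR = 5,
    event_time = round(runif(n, 6, 20), 1),
    event = rep(c(1L, 0L), length.out = n))
  subs$cause <- ifelse(subs$event == 1, "prostate-cancer", "censored")
  series <- do.call(rbind, lapply(seq_len(n), function(i) {
    mu <- subs$baseline_Hb[i] + 0.3 * rnorm(1) + 0.02 * visits
    toy_series(i, visits, "Hb", round(mu + rnorm(length(visits), 0, 0.3), 2))
  }))
  params <- list(
    long = list(Hb = list(beta = c(0.4, 0.015, 0.2, -0.01, 0.95),
                          sigma = sigma,
                          D = matrix(c(sd_b0^2, 0.2 * sd_b0 * sd_b1,
                                       0.2 * sd_b0 * sd_b1, sd_b1^2), 2))),
    gamma = setNames(c(0.25, 0.5, 0.4, 0.1, 0.2, -0.02, -0.04, 0.05,
                       -0.45), surv_covariate_names()),
    alpha = c(Hb = -0.22))
  list(subjects = subs, series = series, params = params)
}

test_that("joint likelihood separates into LMM + survival when alpha = 0", {
  skip_if_not_installed("mvtnorm")
  d <- tiny_joint_data(n = 6)
  d$params$alpha <- c(Hb = 0)
  spec <- joint_model_spec(markers = "Hb", n_quad = 9, n_segments = 3)
  dat <- serojm:::build_jm_data(d$subjects, d$series, "Hb", "OS", 3)
  d$params$loglam <- log(c(0.02, 0.03, 0.04))
  got <- joint_log_likelihood(d$params, d, spec)

  # independent oracle: closed-form Gaussian marginal + survival term
  p <- d$params$long$Hb
  ll_lmm <- 0
  for (i in seq_len(nrow(d$subjects))) {
    md <- dat$mdat$Hb
    sel <- (md$off[i] + 1):md$off[i + 1]
    Z <- cbind(1, md$t[sel])
    V <- Z %*% p$D %*% t(Z) + p$sigma^2 * diag(length(sel))
    mu <- drop(md$X[sel, , drop = FALSE] %*% p$beta)
    ll_lmm <- ll_lmm + mvtnorm::dmvnorm(md$y[sel], mu, V, log = TRUE)
  }
  eta <- drop(dat$W %*% d$params$gamma)
  lam <- exp(d$params$loglam)
  ll_surv <- 0
  for (i in seq_len(nrow(d$subjects))) {
    Ti <- dat$Ti[i]
    width <- pmax(pmin(dat$knots[-1], Ti) - dat$knots[-length(dat$knots)], 0)
    H <- exp(eta[i]) * sum(lam * width)
    ll_surv <- ll_surv - H +
      dat$status[i] * (log(lam[serojm:::pc_segment(Ti, dat$knots)]) + eta[i])
  }
  expect_equal(got, ll_lmm + ll_surv, tolerance = 1e-6)
})

test_that("quadrature agrees with a brute-force double integral", {
  d <- tiny_joint_data(n = 2)
  spec <- joint_model_spec(markers = "Hb", n_quad = 9, n_segments = 2)
  dat <- serojm:::build_jm_data(d$subjects, d$series, "Hb", "OS", 2)
  d$params$loglam <- log(c(0.025, 0.04))
  got <- joint_log_likelihood(d$params, d, spec)

  p <- d$params$long$Hb
  eta <- drop(dat$W %*% d$params$gamma)
  al <- d$params$alpha[["Hb"]]
  brute <- 0
  for (i in 1:2) {
    md <- dat$mdat$Hb
    sel <- (md$off[i] + 1):md$off[i + 1]
    mu_fix <- drop(md$X[sel, , drop = FALSE] %*% p$beta)
    Amf <- p$beta[1] + p$beta[3] * md$arm[i] + p$beta[5] * md$base[i]
    Bmf <- p$beta[2] + p$beta[4] * md$arm[i]
    g0 <- seq(-5, 5, length.out = 401) * sqrt(p$D[1, 1])
    g1 <- seq(-5, 5, length.out = 401) * sqrt(p$D[2, 2])
    f <- matrix(0, length(g0), length(g1))
    for (a in seq_along(g0)) for (b in seq_along(g1)) {
      b0 <- g0[a]; b1 <- g1[b]
      lobs <- sum(dnorm(md$y[sel], mu_fix + b0 + b1 * md$t[sel],
                        p$sigma, log = TRUE))
      A <- eta[i] + al * (Amf + b0); B <- al * (Bmf + b1)
      H <- serojm:::pc_cumhaz(dat$Ti[i], A, B, dat$knots, d$params$loglam)
      lsurv <- -H + dat$status[i] *
        (d$params$loglam[serojm:::pc_segment(dat$Ti[i], dat$knots)] +
           A + B * dat$Ti[i])
      lpri <- mvtnorm::dmvnorm(c(b0, b1), sigma = p$D, log = TRUE)
      f[a, b] <- exp(lobs + lsurv + lpri)
    }
    brute <- brute + log(sum(f) * diff(g0)[1] * diff(g1)[1])
  }
  expect_equal(got, brute, tolerance = 1e-3)
})

test_that("adaptive quadrature is stable in the number of nodes", {
  d <- tiny_joint_data(n = 6)
  dat <- serojm:::build_jm_data(d$subjects, d$series, "Hb", "OS", 3)
  d$params$loglam <- log(c(0.02, 0.03, 0.04))
  lls <- vapply(c(5, 15), function(q)
    joint_log_likelihood(d$params, d,
                         joint_model_spec(markers = "Hb", n_quad = q,
                                          n_segments = 3)), numeric(1))
  expect_lt(abs(diff(lls)), 1e-4)
})

test_that("hazard-ratio table reports the stated scales and strict flag", {
  mk_fit <- function(alpha, alpha_se) serojm:::new_serojm_jm(
    backend = "full_likelihood", endpoint = "OS", markers = "PSA",
    scales = c(PSA = 1), long = list(),
    gamma = setNames(numeric(9), surv_covariate_names()),
    alpha = c(PSA = alpha),
    gamma_se = setNames(rep(1, 9), surv_covariate_names()),
    alpha_se = c(PSA = alpha_se),
    loglam = 0, knots = c(0, 10), loglik = 0, converged = TRUE,
    interval = "wald", meta = list())
  tab <- hazard_ratio_table(mk_fit(0, 0.1))
  row <- tab[tab$parameter == "current_PSA", ]
  expect_equal(row$hazard_ratio, 1)
  expect_equal(row$scale, "per 1 log(PSA+1) unit")
  tab2 <- hazard_ratio_table(mk_fit(log(1.24), 0.05))
  expect_equal(tab2$hazard_ratio[tab2$parameter == "current_PSA"], 1.24)
  # strict inequality at the significance threshold
  z_at <- 2.8600    # two-sided p just above 0.004 (p ~ 0.00424)
  z_in <- 2.9000    # two-sided p just below 0.004 (p ~ 0.00373)
  t_at <- hazard_ratio_table(mk_fit(z_at * 0.1, 0.1))
  t_in <- hazard_ratio_table(mk_fit(z_in * 0.1, 0.1))
  expect_false(t_at$significant[t_at$parameter == "current_PSA"])
  expect_true(t_in$significant[t_in$parameter == "current_PSA"])
})

test_that("two-stage and full-likelihood backends agree in direction", {
  al <- default_alpha(); al["Hb"] <- log(0.75)
  co <- test_cohort(n = 250, seed = 61, alpha = al, othercause = 0)
  dat <- list(subjects = co$subjects, series = co$series)
  f_ts <- fit_univariate_joint(dat, "Hb",
                               joint_model_spec(backend = "two_stage"))
  f_fl <- suppressWarnings(fit_univariate_joint(
    dat, "Hb", joint_model_spec(backend = "full_likelihood", n_quad = 5)))
  expect_lt(f_ts$alpha, 0)
  expect_lt(f_fl$alpha, 0)
  expect_equal(sign(f_ts$alpha), sign(f_fl$alpha))
  # protective association detected by both
  expect_lt(exp(f_fl$alpha), 0.95)
})

test_that("a single-marker multivariate request degenerates cleanly", {
  co <- test_cohort(n = 150, seed = 62)
  dat <- list(subjects = co$subjects, series = co$series)
  spec <- joint_model_spec(backend = "two_stage", shrinkage = "none")
  f1 <- fit_multivariate_joint(dat, "Hb", spec)
  f2 <- fit_univariate_joint(dat, "Hb", spec)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-10)
})

test_that("reported hazard ratio is invariant to the time unit", {
  # months -> years on a small cohort: same data, rescaled times
  al <- default_alpha(); al["Hb"] <- log(0.8)
  co <- test_cohort(n = 150, seed = 63, alpha = al, othercause = 0)
  dat1 <- list(subjects = co$subjects, series = co$series)
  subs2 <- co$subjects; subs2$event_time <- subs2$event_time / 12
  ser2 <- co$series; ser2$time_months <- ser2$time_months / 12
  dat2 <- list(subjects = subs2, series = ser2)
  f1 <- fit_univariate_joint(dat1, "Hb",
                             joint_model_spec(backend = "two_stage"))
  f2 <- fit_univariate_joint(dat2, "Hb",
                             joint_model_spec(backend = "two_stage"))
  expect_equal(unname(f1$alpha), unname(f2$alpha), tolerance = 0.02)
})

test_that("horseshoe shrinkage requires the MCMC backend", {
  expect_error(joint_model_spec(shrinkage = "horseshoe",
                                backend = "two_stage"), "bayesian_mcmc")
  expect_error(joint_model_spec(markers = character(0)), "nonempty")
})
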