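## Bayesian backend: Metropolis-within-Gibbs sampler for univariate and
## multivariate joint models, with optional horseshoe shrinkage on the
## association coefficients (Makalic-Schmidt inverse-gamma parameter
## expansion, so every shrinkage scale is a Gibbs draw).
##
## Conjugate Gibbs updates: residual variances (inverse-gamma),
## random-effect covariances (inverse-Wishart), piecewise-constant
## baseline hazard levels (gamma, via closed-form exposures), horseshoe
## locals/global. Metropolis random-walk blocks (adapted during warmup):
## per-marker fixed effects, survival coefficients, association
## coefficients, and the subject random effects (vectorised across
## subjects).

rinvgamma1 <- function(shape, scale) 1 / rgamma(length(scale), shape,
                                                rate = scale)

riwish <- function(nu, Psi) {
  W <- stats::rWishart(1, nu, solve(Psi))[, , 1]
  solve(W)
}

fit_jm_mcmc <- function(data, markers, spec) {
  warmup <- spec$mcmc$warmup %||% 500
  n_iter <- spec$mcmc$iter %||% 1000
  set.seed(spec$mcmc$seed %||% 1L)
  horseshoe <- spec$shrinkage == "horseshoe"

  dat <- build_jm_data(data$subjects, data$series, markers, spec$endpoint,
                       spec$n_segments)
  n <- nrow(dat$subjects)
  K <- length(markers)
  Kseg <- length(dat$knots) - 1L
  p_gamma <- ncol(dat$W)

  # initial values from the two-stage approximation
  ts_spec <- spec; ts_spec$backend <- "two_stage"
  init <- fit_two_stage(data, markers, ts_spec)
  long <- init$long
  gamma <- init$gamma
  alpha <- pmin(pmax(init$alpha, -2), 2)
  loglam <- init$loglam
  # clamp two-stage loglam to the knots of this build (same construction)
  stopifnot(length(loglam) == Kseg)

  # per-marker state
  st <- list()
  for (m in markers) {
    md <- dat$mdat[[m]]
    lp <- long[[m]]
    b <- matrix(0, n, 2)
    fp <- marker_fixed_parts(md, lp$beta)
    for (i in seq_len(n)) {
      sel <- seq.int(md$off[i] + 1L, length.out = md$off[i + 1] - md$off[i])
      b[i, ] <- eb_posterior_scaled(
        lp, md$t[sel],
        md$y[sel] - drop(md$X[sel, , drop = FALSE] %*% lp$beta))
    }
    st[[m]] <- list(beta = lp$beta, sigma2 = lp$sigma^2, D = lp$D, b = b,
                    Xbeta = drop(md$X %*% lp$beta),
                    D_init = lp$D,
                    prop_beta = chol(diag(pmax(lp$beta^2, 1e-4) * 1e-4 +
                                            1e-6)),
                    ls_beta = 0, ls_b = 0)
    st[[m]]$resid <- md$y - st[[m]]$Xbeta - b[md$id_idx, 1] -
      b[md$id_idx, 2] * md$t
  }

  # survival linear predictor pieces
  Amat <- sapply(markers, function(m)
    marker_fixed_parts(dat$mdat[[m]], st[[m]]$beta)$A + st[[m]]$b[, 1])
  Bmat <- sapply(markers, function(m)
    marker_fixed_parts(dat$mdat[[m]], st[[m]]$beta)$B + st[[m]]$b[, 2])
  Acur <- drop(dat$W %*% gamma) + drop(Amat %*% alpha)
  Bcur <- drop(Bmat %*% alpha)
  sll <- cpp_surv_loglik(dat$Ti, dat$status, Acur, Bcur, dat$knots, loglam)

  # proposals
  cox0 <- fit_cox(dat$subjects, spec$endpoint)
  prop_gamma <- if (nrow(cox0$coxph$var) == p_gamma)
    chol(cox0$coxph$var + diag(1e-8, p_gamma)) else
      chol(diag(0.01, p_gamma))
  ls_gamma <- 0
  ls_alpha <- rep(log(0.1), K)
  # adaptive joint (gamma, alpha) block: running covariance of the chain
  # learned during warmup resolves the baseline-vs-current-value ridge
  d_ga <- p_gamma + K
  am_n <- 0; am_mean <- numeric(d_ga); am_S <- matrix(0, d_ga, d_ga)
  am_chol <- NULL; ls_am <- log(0.3)
  # horseshoe state
  lam2 <- rep(1, K); nu_hs <- rep(1, K); tau2 <- spec$tau0^2; xi <- 1
  alpha_prior_sd <- 10

  dcnt <- tabulate(pc_segment(dat$Ti[dat$status == 1], dat$knots),
                   nbins = Kseg)

  tot <- warmup + n_iter
  dr_ga <- matrix(NA_real_, n_iter, p_gamma + K,
                  dimnames = list(NULL, c(surv_covariate_names(), markers)))
  dr_loglam <- matrix(NA_real_, n_iter, Kseg)
  dr_long <- lapply(markers, function(m)
    matrix(NA_real_, n_iter, 9,
           dimnames = list(NULL, c(paste0("beta", 1:5), "sigma2",
                                   "sd0", "sd1", "rho"))))
  names(dr_long) <- markers
  acc <- list(beta = setNames(numeric(K), markers),
              b = setNames(numeric(K), markers), gamma = 0,
              alpha = numeric(K))

  alpha_logprior <- function(a, k) {
    if (horseshoe) dnorm(a, 0, sqrt(lam2[k] * tau2), log = TRUE)
    else dnorm(a, 0, alpha_prior_sd, log = TRUE)
  }

  for (it in seq_len(tot)) {
    adapt <- it <= warmup
    an <- 1 / sqrt(max(it, 10))       # Robbins-Monro adaptation gain

    for (k in seq_len(K)) {
      m <- markers[k]
      md <- dat$mdat[[m]]
      sk <- st[[m]]

      # sigma2 Gibbs
      n_obs <- length(md$y)
      sk$sigma2 <- rinvgamma1(0.01 + n_obs / 2, 0.01 + sum(sk$resid^2) / 2)

      # D Gibbs (inverse-Wishart, weak data-scaled prior)
      Sb <- crossprod(sk$b)
      sk$D <- riwish(4 + n, sk$D_init + Sb)

      # beta MH block
      step <- exp(sk$ls_beta)
      prop <- sk$beta + step * drop(rnorm(5) %*% sk$prop_beta)
      Xb_new <- drop(md$X %*% prop)
      res_new <- sk$resid + sk$Xbeta - Xb_new
      fp_new <- marker_fixed_parts(md, prop)
      A_new <- Acur + alpha[k] * (fp_new$A + sk$b[, 1] - Amat[, k])
      B_new <- Bcur + alpha[k] * (fp_new$B + sk$b[, 2] - Bmat[, k])
      sll_new <- cpp_surv_loglik(dat$Ti, dat$status, A_new, B_new,
                                 dat$knots, loglam)
      dll <- (sum(sk$resid^2) - sum(res_new^2)) / (2 * sk$sigma2) +
        sum(sll_new) - sum(sll) +
        sum(dnorm(prop, 0, 100, log = TRUE)) -
        sum(dnorm(sk$beta, 0, 100, log = TRUE))
      ok <- is.finite(dll) && log(runif(1)) < dll
      if (ok) {
        sk$beta <- prop; sk$Xbeta <- Xb_new; sk$resid <- res_new
        Amat[, k] <- fp_new$A + sk$b[, 1]
        Bmat[, k] <- fp_new$B + sk$b[, 2]
        Acur <- A_new; Bcur <- B_new; sll <- sll_new
      }
      if (adapt) sk$ls_beta <- sk$ls_beta + an * ((ok) - 0.25)
      if (!adapt) acc$beta[k] <- acc$beta[k] + ok

      # b MH (vectorised across subjects)
      stepb <- exp(sk$ls_b)
      chD <- chol(sk$D + diag(1e-10, 2))
      eps <- matrix(rnorm(2 * n), n, 2) %*% chD * stepb
      b_new <- sk$b + eps
      # per-subject longitudinal SSR change
      d0 <- eps[md$id_idx, 1]; d1 <- eps[md$id_idx, 2] * md$t
      res_new <- sk$resid - d0 - d1
      ssr_old <- rowsum_safe(sk$resid^2, md$id_idx, n)
      ssr_new <- rowsum_safe(res_new^2, md$id_idx, n)
      Din <- solve(sk$D)
      qf <- function(bm) rowSums((bm %*% Din) * bm)
      A_new <- Acur + alpha[k] * eps[, 1]
      B_new <- Bcur + alpha[k] * eps[, 2]
      sll_new <- cpp_surv_loglik(dat$Ti, dat$status, A_new, B_new,
                                 dat$knots, loglam)
      dlli <- (ssr_old - ssr_new) / (2 * sk$sigma2) +
        (qf(sk$b) - qf(b_new)) / 2 + sll_new - sll
      take <- is.finite(dlli) & log(runif(n)) < dlli
      if (any(take)) {
        sk$b[take, ] <- b_new[take, ]
        keep_obs <- take[md$id_idx]
        sk$resid[keep_obs] <- res_new[keep_obs]
        Amat[take, k] <- Amat[take, k] + eps[take, 1]
        Bmat[take, k] <- Bmat[take, k] + eps[take, 2]
        Acur[take] <- A_new[take]; Bcur[take] <- B_new[take]
        sll[take] <- sll_new[take]
      }
      rate <- mean(take)
      if (adapt) sk$ls_b <- sk$ls_b + an * (rate - 0.35)
      if (!adapt) acc$b[k] <- acc$b[k] + rate
      st[[m]] <- sk
    }

    # gamma MH block
    step <- exp(ls_gamma)
    prop <- gamma + step * drop(rnorm(p_gamma) %*% prop_gamma)
    A_new <- Acur + drop(dat$W %*% (prop - gamma))
    sll_new <- cpp_surv_loglik(dat$Ti, dat$status, A_new, Bcur,
                               dat$knots, loglam)
    dll <- sum(sll_new) - sum(sll) +
      sum(dnorm(prop, 0, 10, log = TRUE)) -
      sum(dnorm(gamma, 0, 10, log = TRUE))
    ok <- is.finite(dll) && log(runif(1)) < dll
    if (ok) { gamma <- setNames(prop, names(gamma)); Acur <- A_new
              sll <- sll_new }
    if (adapt) ls_gamma <- ls_gamma + an * ((ok) - 0.25)
    if (!adapt) acc$gamma <- acc$gamma + ok

    # alpha single-coordinate MH
    for (k in seq_len(K)) {
      prop_a <- alpha[k] + exp(ls_alpha[k]) * rnorm(1)
      A_new <- Acur + (prop_a - alpha[k]) * Amat[, k]
      B_new <- Bcur + (prop_a - alpha[k]) * Bmat[, k]
      sll_new <- cpp_surv_loglik(dat$Ti, dat$status, A_new, B_new,
                                 dat$knots, loglam)
      dll <- sum(sll_new) - sum(sll) +
        alpha_logprior(prop_a, k) - alpha_logprior(alpha[k], k)
      ok <- is.finite(dll) && log(runif(1)) < dll
      if (ok) { alpha[k] <- prop_a; Acur <- A_new; Bcur <- B_new
                sll <- sll_new }
      if (adapt) ls_alpha[k] <- ls_alpha[k] + an * ((ok) - 0.44)
      if (!adapt) acc$alpha[k] <- acc$alpha[k] + ok
    }

    # adaptive joint (gamma, alpha) block along the learned covariance
    th_ga <- c(gamma, alpha)
    am_n <- am_n + 1
    dlt <- th_ga - am_mean
    am_mean <- am_mean + dlt / am_n
    am_S <- am_S + tcrossprod(dlt, th_ga - am_mean)
    if (adapt && am_n > 50 && am_n %% 25 == 0) {
      C <- am_S / (am_n - 1) + diag(1e-8, d_ga)
      am_chol <- tryCatch(chol((2.38^2 / d_ga) * C),
                          error = function(e) NULL)
    }
    if (!is.null(am_chol)) {
      prop <- th_ga + exp(ls_am) * drop(rnorm(d_ga) %*% am_chol)
      pg <- prop[seq_len(p_gamma)]; pa <- prop[p_gamma + seq_len(K)]
      A_new <- Acur + drop(dat$W %*% (pg - gamma)) +
        drop(Amat %*% (pa - alpha))
      B_new <- Bcur + drop(Bmat %*% (pa - alpha))
      sll_new <- cpp_surv_loglik(dat$Ti, dat$status, A_new, B_new,
                                 dat$knots, loglam)
      dll <- sum(sll_new) - sum(sll) +
        sum(dnorm(pg, 0, 10, log = TRUE)) -
        sum(dnorm(gamma, 0, 10, log = TRUE)) +
        sum(vapply(seq_len(K), function(k)
          alpha_logprior(pa[k], k) - alpha_logprior(alpha[k], k),
          numeric(1)))
      ok <- is.finite(dll) && log(runif(1)) < dll
      if (ok) {
        gamma <- setNames(pg, names(gamma))
        alpha <- setNames(pa, names(alpha))
        Acur <- A_new; Bcur <- B_new; sll <- sll_new
      }
      if (adapt) ls_am <- ls_am + an * ((ok) - 0.25)
    }

    # horseshoe Gibbs
    if (horseshoe) {
      lam2 <- rinvgamma1(1, 1 / nu_hs + alpha^2 / (2 * tau2))
      nu_hs <- rinvgamma1(1, 1 + 1 / lam2)
      tau2 <- rinvgamma1((K + 1) / 2,
                         1 / xi + sum(alpha^2 / lam2) / 2)
      xi <- rinvgamma1(1, 1 / spec$tau0^2 + 1 / tau2)
    }

    # baseline hazard Gibbs
    E <- colSums(cpp_pc_exposures(dat$Ti, Acur, Bcur, dat$knots))
    lam <- rgamma(Kseg, 0.01 + dcnt, rate = 0.01 + E)
    loglam <- log(pmax(lam, 1e-300))
    sll <- cpp_surv_loglik(dat$Ti, dat$status, Acur, Bcur, dat$knots,
                           loglam)

    if (it > warmup) {
      s <- it - warmup
      dr_ga[s, ] <- c(gamma, alpha)
      dr_loglam[s, ] <- loglam
      for (m in markers) {
        Dm <- st[[m]]$D
        dr_long[[m]][s, ] <- c(st[[m]]$beta, st[[m]]$sigma2,
                               sqrt(Dm[1, 1]), sqrt(Dm[2, 2]),
                               Dm[1, 2] / sqrt(Dm[1, 1] * Dm[2, 2]))
      }
    }
  }

  acc$gamma <- acc$gamma / n_iter
  acc$alpha <- acc$alpha / n_iter
  acc$beta <- acc$beta / n_iter
  acc$b <- acc$b / n_iter
  flat <- c(acc$gamma, acc$alpha, acc$beta)
  diverged <- any(flat < 0.02) || any(flat > 0.98)
  if (diverged)
    warning("MCMC mixing diagnostics out of range (acceptance rates: ",
            paste(round(flat, 3), collapse = ", "), ")")

  post_long <- list()
  for (m in markers) {
    med <- apply(dr_long[[m]], 2, median)
    D <- matrix(c(med["sd0"]^2, med["rho"] * med["sd0"] * med["sd1"],
                  med["rho"] * med["sd0"] * med["sd1"], med["sd1"]^2), 2, 2)
    post_long[[m]] <- list(beta = unname(med[1:5]),
                           sigma = sqrt(med[["sigma2"]]), D = D)
  }
  gi <- seq_len(p_gamma); ai <- p_gamma + seq_len(K)
  med <- apply(dr_ga, 2, median)

  new_serojm_jm(
    backend = "bayesian_mcmc", endpoint = spec$endpoint, markers = markers,
    scales = spec$scales, long = post_long,
    gamma = setNames(med[gi], surv_covariate_names()),
    alpha = setNames(med[ai], markers),
    gamma_se = setNames(apply(dr_ga[, gi, drop = FALSE], 2, sd),
                        surv_covariate_names()),
    alpha_se = setNames(apply(dr_ga[, ai, drop = FALSE], 2, sd), markers),
    loglam = apply(dr_loglam, 2, median), knots = dat$knots,
    loglik = NA_real_, converged = !diverged, interval = "posterior",
    draws = dr_ga, shrinkage = spec$shrinkage,
    meta = list(warmup = warmup, iter = n_iter, seed = spec$mcmc$seed,
                acceptance = acc, n_subjects = n,
                n_events = sum(dat$status)))
}

rowsum_safe <- function(x, idx, n) {
  out <- numeric(n)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs))] <- rs
  out
}
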