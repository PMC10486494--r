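## Joint-model likelihood machinery.
##
## The longitudinal and survival sub-models are linked through the
## shared random effects via a current-value association: the log
## hazard at time t adds `alpha_k * m_k(t)` for each modelled marker,
## where m_k is the marker's full linear predictor (fixed + random
## parts) on its reporting scale. Internally every marker is divided by
## its association scaling, so alpha is per reporting unit throughout.

#' Joint model specification
#'
#' @param endpoint `"OS"` or `"PCSS"`.
#' @param markers Subset of the five marker names.
#' @param shrinkage `"none"` or `"horseshoe"` (association coefficients
#'   only; requires the `bayesian_mcmc` backend).
#' @param backend `"two_stage"` (BLUP current values in a time-varying
#'   Cox fit; fast approximation), `"full_likelihood"` (adaptive
#'   Gauss-Hermite marginal likelihood; univariate markers), or
#'   `"bayesian_mcmc"` (Metropolis-within-Gibbs; required for the
#'   horseshoe).
#' @param n_quad Gauss-Hermite nodes per random-effect dimension.
#' @param n_segments Baseline-hazard segments (piecewise constant on
#'   event-time quantile knots).
#' @param tau0 Global horseshoe scale.
#' @param mcmc List of `warmup`, `iter`, `seed` for the MCMC backend.
#' @return An object of class `joint_model_spec`.
#' @export
joint_model_spec <- function(endpoint = c("OS", "PCSS"),
                             markers = marker_names(),
                             shrinkage = c("none", "horseshoe"),
                             backend = c("full_likelihood", "two_stage",
                                         "bayesian_mcmc"),
                             n_quad = 9, n_segments = 6, tau0 = 1,
                             mcmc = list(warmup = 500, iter = 1000,
                                         seed = 1L)) {
  endpoint <- match.arg(endpoint)
  shrinkage <- match.arg(shrinkage)
  backend <- match.arg(backend)
  stop_if_not(length(markers) >= 1, "marker set must be nonempty")
  stop_if_not(all(markers %in% marker_names()),
              "unknown marker(s): ",
              paste(setdiff(markers, marker_names()), collapse = ", "))
  if (shrinkage == "horseshoe" && backend != "bayesian_mcmc")
    stop("horseshoe shrinkage requires backend = 'bayesian_mcmc'")
  stop_if_not(tau0 > 0, "tau0 must be > 0")
  structure(list(endpoint = endpoint, markers = markers,
                 scales = setNames(marker_scale(markers), markers),
                 shrinkage = shrinkage, backend = backend,
                 n_quad = n_quad, n_segments = n_segments, tau0 = tau0,
                 mcmc = mcmc),
            class = "joint_model_spec")
}

# Internal fitting frame: subjects ordered by id; per-marker scaled
# observation blocks ordered by subject; survival pieces and knots.
build_jm_data <- function(subjects, series, markers, endpoint,
                          n_segments = 6) {
  subjects <- subjects[order(subjects$id), , drop = FALSE]
  status <- endpoint_status(subjects, endpoint)
  stop_if_not(sum(status) >= 1, "no events for endpoint ", endpoint)
  ev <- subjects$event_time[status == 1]
  knots <- pc_knots(ev, n_segments,
                    upper = max(subjects$event_time) * 1.001)
  mdat <- list()
  for (m in markers) {
    s <- marker_scale(m)
    fr <- lmm_frame(series, subjects, m)
    fr <- fr[order(match(fr$id, subjects$id), fr$time), , drop = FALSE]
    idx <- match(fr$id, subjects$id)
    cnt <- tabulate(idx, nbins = nrow(subjects))
    mdat[[m]] <- list(
      y = fr$y / s, t = fr$time, id_idx = idx,
      off = c(0L, cumsum(cnt)),
      X = cbind(1, fr$time, fr$arm, fr$arm * fr$time, fr$base / s),
      arm = subjects$arm,
      base = marker_to_model_scale(
        m, subjects[[paste0("baseline_", m)]]) / s)
  }
  list(subjects = subjects, status = as.double(status),
       Ti = subjects$event_time, W = surv_design(subjects),
       knots = knots, mdat = mdat, markers = markers)
}

# Per-marker fixed parts of the scaled current value given beta:
# m_k(t) = Amf + b0 + (Bmf + b1) t.
marker_fixed_parts <- function(md, beta) {
  list(A = beta[1] + beta[3] * md$arm + beta[5] * md$base,
       B = beta[2] + beta[4] * md$arm)
}

# ---- multivariate subject-level log posterior of b (Laplace / EB) ----

# f_i(b) for subject i with b = (b0_1, b1_1, ..., b0_K, b1_K); returns
# value, gradient, Hessian. `cond` chooses event-density (delta) or
# survival-only conditioning; longitudinal data may be truncated.
subject_logpost_b <- function(b, i, dat, long, gamma, alpha, loglam,
                              trunc_time = NULL) {
  K <- length(dat$markers)
  if (any(!is.finite(b)))
    return(list(f = -Inf, g = numeric(2 * K),
                H = diag(-1, 2 * K)))
  lam <- exp(loglam)
  Ti <- if (is.null(trunc_time)) dat$Ti[i] else trunc_time
  delta <- if (is.null(trunc_time)) dat$status[i] else 0
  v0 <- numeric(2 * K); v1 <- numeric(2 * K)
  A <- sum(dat$W[i, ] * gamma); B <- 0
  f <- 0; g <- numeric(2 * K); H <- matrix(0, 2 * K, 2 * K)
  for (k in seq_len(K)) {
    m <- dat$markers[k]
    md <- dat$mdat[[m]]
    p <- long[[m]]
    j0 <- 2 * k - 1; j1 <- 2 * k
    fp <- list(A = p$beta[1] + p$beta[3] * md$arm[i] +
                 p$beta[5] * md$base[i],
               B = p$beta[2] + p$beta[4] * md$arm[i])
    al <- alpha[[m]]
    A <- A + al * (fp$A + b[j0]); B <- B + al * (fp$B + b[j1])
    v0[j0] <- al; v1[j1] <- al
    # longitudinal block (possibly truncated history)
    sel <- (md$off[i] + 1):md$off[i + 1]
    sel <- sel[md$off[i] < md$off[i + 1]]
    if (length(sel) > 0 && !is.null(trunc_time))
      sel <- sel[md$t[sel] <= trunc_time]
    if (length(sel) > 0) {
      tt <- md$t[sel]
      r <- md$y[sel] - drop(md$X[sel, , drop = FALSE] %*% p$beta) -
        b[j0] - b[j1] * tt
      f <- f - length(sel) * (log(p$sigma) + 0.5 * log(2 * pi)) -
        sum(r^2) / (2 * p$sigma^2)
      g[j0] <- g[j0] + sum(r) / p$sigma^2
      g[j1] <- g[j1] + sum(r * tt) / p$sigma^2
      H[j0, j0] <- H[j0, j0] - length(sel) / p$sigma^2
      H[j0, j1] <- H[j1, j0] <- H[j0, j1] - sum(tt) / p$sigma^2
      H[j1, j1] <- H[j1, j1] - sum(tt^2) / p$sigma^2
    }
    Dinv <- solve(p$D + diag(1e-8 * max(diag(p$D)), 2))
    bb <- b[c(j0, j1)]
    f <- f - log(2 * pi) - 0.5 * determinant(p$D)$modulus[1] -
      0.5 * drop(bb %*% Dinv %*% bb)
    g[c(j0, j1)] <- g[c(j0, j1)] - drop(Dinv %*% bb)
    H[c(j0, j1), c(j0, j1)] <- H[c(j0, j1), c(j0, j1)] - Dinv
  }
  # survival part
  S0 <- S1 <- S2 <- 0
  for (j in seq_len(length(dat$knots) - 1L)) {
    u <- dat$knots[j]
    if (u >= Ti) break
    v <- min(dat$knots[j + 1L], Ti)
    S0 <- S0 + lam[j] * seg_I0(B, u, v)
    S1 <- S1 + lam[j] * seg_I1(B, u, v)
    S2 <- S2 + lam[j] * seg_I2(B, u, v)
  }
  eA <- exp(A); S0 <- S0 * eA; S1 <- S1 * eA; S2 <- S2 * eA
  if (!is.finite(S0) || !is.finite(S1) || !is.finite(S2))
    return(list(f = -Inf, g = numeric(2 * K), H = diag(-1, 2 * K)))
  f <- f - S0
  g <- g - (v0 * S0 + v1 * S1)
  H <- H - (S0 * tcrossprod(v0) + S1 * (tcrossprod(v0, v1) +
            tcrossprod(v1, v0)) + S2 * tcrossprod(v1))
  if (delta > 0.5) {
    jseg <- pc_segment(Ti, dat$knots)
    f <- f + loglam[jseg] + A + B * Ti
    g <- g + v0 + v1 * Ti
  }
  list(f = f, g = g, H = H)
}

seg_I1 <- function(c, u, v) {
  if (abs(c) * max(abs(u), abs(v), 1) < 1e-7) {
    (v^2 - u^2) / 2 + c * (v^3 - u^3) / 3 + c^2 * (v^4 - u^4) / 8
  } else {
    (exp(c * v) * (c * v - 1) - exp(c * u) * (c * u - 1)) / c^2
  }
}
seg_I2 <- function(c, u, v) {
  if (abs(c) * max(abs(u), abs(v), 1) < 1e-7) {
    (v^3 - u^3) / 3 + c * (v^4 - u^4) / 4 + c^2 * (v^5 - u^5) / 10
  } else {
    (exp(c * v) * (c^2 * v^2 - 2 * c * v + 2) -
       exp(c * u) * (c^2 * u^2 - 2 * c * u + 2)) / c^3
  }
}

# Newton ascent of the (concave) subject log posterior.
subject_b_mode <- function(i, dat, long, gamma, alpha, loglam,
                           trunc_time = NULL, b_init = NULL) {
  K <- length(dat$markers)
  b <- b_init %||% numeric(2 * K)
  fb <- subject_logpost_b(b, i, dat, long, gamma, alpha, loglam, trunc_time)
  for (it in 1:50) {
    step <- tryCatch(-solve(fb$H, fb$g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    sc <- 1
    repeat {
      bn <- b + sc * step
      fn <- subject_logpost_b(bn, i, dat, long, gamma, alpha, loglam,
                              trunc_time)
      if ((is.finite(fn$f) && fn$f >= fb$f - 1e-12) || sc < 1e-6) break
      sc <- sc / 2
    }
    if (!is.finite(fn$f)) break
    moved <- sum(abs(bn - b))
    b <- bn; fb <- fn
    if (moved < 1e-10) break
  }
  list(b = b, f = fb$f, H = fb$H)
}

# ---- user-facing joint log-likelihood ----

#' Joint log-likelihood of a parameter set
#'
#' Evaluates the marginal joint log-likelihood
#' `sum_i log int prod_visits N(y | m_i(t; b), sigma) *
#' h_i(T_i | b)^delta_i * exp(-int_0^{T_i} h_i) * p(b) db`.
#' For a single marker the 2-dimensional random-effect integral uses
#' adaptive Gauss-Hermite quadrature; with several markers a Laplace
#' approximation at the per-subject posterior mode is used. The hazard
#' integral is closed-form per baseline segment.
#'
#' @param params List with `long` (per marker: `beta` length-5
#'   (intercept, time, arm, arm x time, baseline), `sigma`, `D` 2x2, all
#'   on the association reporting scale), `gamma` (nine named survival
#'   coefficients), `alpha` (named per marker, per reporting unit), and
#'   `loglam` (log baseline hazard per segment).
#' @param data List with `subjects` and `series` tables.
#' @param spec A [joint_model_spec()].
#' @return Scalar log-likelihood.
#' @export
joint_log_likelihood <- function(params, data, spec) {
  dat <- build_jm_data(data$subjects, data$series, spec$markers,
                       spec$endpoint, spec$n_segments)
  loglam <- params$loglam
  stop_if_not(length(loglam) == length(dat$knots) - 1L,
              "loglam must have one value per baseline segment (",
              length(dat$knots) - 1L, ")")
  gamma <- params$gamma[surv_covariate_names()]
  if (length(spec$markers) == 1L) {
    m <- spec$markers
    p <- params$long[[m]]
    md <- dat$mdat[[m]]
    gh <- gh_rule(spec$n_quad)
    sds <- sqrt(diag(p$D))
    rho <- p$D[1, 2] / prod(sds)
    res <- cpp_jm_marg_loglik(
      md$y, md$X, md$t, as.integer(md$off), dat$W, md$arm, md$base,
      dat$Ti, dat$status, p$beta, log(p$sigma),
      log(sds[1]), log(sds[2]), atanh(min(max(rho, -0.999), 0.999)),
      gamma, params$alpha[[m]], loglam, dat$knots, gh$x, gh$w, FALSE,
      matrix(0, 0, 2))
    return(res$loglik)
  }
  # multivariate: Laplace at the subject modes
  K <- length(spec$markers)
  total <- 0
  for (i in seq_len(nrow(dat$subjects))) {
    md <- subject_b_mode(i, dat, params$long, gamma, params$alpha, loglam)
    M <- -md$H
    ld <- determinant(M)$modulus[1]
    total <- total + md$f + K * log(2 * pi) - 0.5 * ld
  }
  total
}
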