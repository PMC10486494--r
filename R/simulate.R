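## Synthetic trial-cohort generator.
##
## Emulates the data structure of a two-arm mHSPC trial: ~1138 subjects,
## baseline covariates drawn to match published marginals, five marker
## trajectories from linear mixed models (random intercept + slope,
## arm x time effects), and event times whose log hazard is linearly
## associated with the markers' current model-implied values.

#' Trajectory parameters for one marker
#'
#' Describes the generating linear mixed model for a marker on its
#' modelling scale (`log(x+1)` for PSA, native units otherwise):
#' `m(t) = beta0 + b0 + (beta_t + b1) t + beta_arm arm + beta_arm_t arm t
#' + beta_base baseline`, with `(b0, b1)` bivariate normal and Gaussian
#' residual noise on observations.
#'
#' @param marker Marker name (`"Hb"`, `"NLR"`, `"PLR"`, `"LMR"`, `"PSA"`).
#' @param beta0,beta_t,beta_arm,beta_arm_t,beta_base Fixed effects
#'   (time in months).
#' @param sd_b0,sd_b1 Random intercept / slope standard deviations.
#' @param corr_b0b1 Random-effect correlation.
#' @param sd_resid Residual standard deviation.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(marker, beta0, beta_t, beta_arm, beta_arm_t,
                              beta_base, sd_b0, sd_b1, corr_b0b1, sd_resid) {
  stop_if_not(marker %in% marker_names(), "unknown marker: ", marker)
  stop_if_not(all(c(sd_b0, sd_b1, sd_resid) >= 0),
              "standard deviations must be non-negative")
  stop_if_not(abs(corr_b0b1) <= 1, "|corr_b0b1| must be <= 1")
  structure(list(marker = marker, beta0 = beta0, beta_t = beta_t,
                 beta_arm = beta_arm, beta_arm_t = beta_arm_t,
                 beta_base = beta_base, sd_b0 = sd_b0, sd_b1 = sd_b1,
                 corr_b0b1 = corr_b0b1, sd_resid = sd_resid),
            class = "trajectory_params")
}

default_marker_params <- function() {
  # Trajectories are anchored at the recorded baseline (beta_base = 1,
  # beta0 = 0): the random intercept is the subject's deviation from
  # their own baseline, and the time-0 series value equals the recorded
  # baseline by construction.
  list(
    Hb  = trajectory_params("Hb",  0, 0.012,  0.25,  0.008, 1,
                            0.90, 0.035, -0.20, 0.65),
    NLR = trajectory_params("NLR", 0, 0.012, -0.08, -0.004, 1,
                            0.50, 0.020,  0.10, 0.50),
    PLR = trajectory_params("PLR", 0, 0.60,  -4.0,  -0.25,  1,
                            32,   1.60,   0.10, 26),
    LMR = trajectory_params("LMR", 0, -0.010, 0.08,  0.004, 1,
                            1.00, 0.030, -0.10, 0.85),
    PSA = trajectory_params("PSA", 0, -0.004, -0.12, -0.002, 1,
                            0.40, 0.010, -0.20, 0.25)
  )
}

#' Survival-process parameters for the generator
#'
#' Weibull baseline hazard for prostate-cancer death, log-linear effects
#' of the nine baseline covariates (`gamma`), current-value association
#' coefficients per marker on their reporting scales (`alpha`, log HR per
#' scale unit), and a constant competing hazard for other-cause death.
#'
#' @param shape,scale Weibull baseline hazard parameters (months). If
#'   `scale` is `NA` it is calibrated so the pooled median death time is
#'   `target_median` months.
#' @param gamma Named vector over the nine survival covariates.
#' @param alpha Named vector of association log hazard ratios per
#'   reporting-scale unit (Hb per g/dL, NLR per point, PLR per 100,
#'   LMR per 5, PSA per log(x+1) unit).
#' @param othercause_hazard Constant per-month hazard of non-cancer death.
#' @param target_median Calibration target for pooled median overall
#'   survival, months.
#' @return An object of class `survival_params`.
#' @export
survival_params <- function(shape = 1.3, scale = NA_real_,
                            gamma = default_gamma(),
                            alpha = default_alpha(),
                            othercause_hazard = 0.002,
                            target_median = 44) {
  stop_if_not(shape > 0, "shape must be > 0")
  stop_if_not(is.na(scale) || scale > 0, "scale must be > 0 (or NA)")
  stop_if_not(othercause_hazard >= 0, "othercause_hazard must be >= 0")
  gamma <- gamma[surv_covariate_names()]
  stop_if_not(!anyNA(gamma), "gamma must be named over the nine covariates")
  alpha <- alpha[marker_names()]
  alpha[is.na(alpha)] <- 0
  names(alpha) <- marker_names()
  structure(list(shape = shape, scale = scale, gamma = gamma, alpha = alpha,
                 othercause_hazard = othercause_hazard,
                 target_median = target_median),
            class = "survival_params")
}

#' @rdname survival_params
#' @export
default_gamma <- function() {
  c(ecog = log(1.31), skeletal_ge10 = log(1.69), liver_met = log(1.56),
    nodal_n1 = log(1.08), gleason_9_10 = log(1.22),
    baseline_Hb = log(0.99), log_baseline_PSA = log(0.96),
    worst_pain = log(1.05), arm = -log(1.61))
}

#' @rdname survival_params
#' @export
default_alpha <- function() {
  setNames(numeric(5), marker_names())
}

# Baseline covariate marginals (independent draws; only marginals are
# published for the emulated trial).
default_baseline_params <- function() {
  list(
    p_ecog = 0.448, p_skeletal = 0.654, p_liver = 0.051,
    p_nodal = 0.465, p_gleason = 0.520,
    pain_probs = c(0.30, 0.22, 0.12, 0.09, 0.08, 0.06,
                   0.04, 0.03, 0.03, 0.02, 0.01),
    Hb  = list(dist = "normal", mean = 13.25, sd = 1.75),
    PSA = list(dist = "lognormal", meanlog = log(16.5), sdlog = 2.33),
    NLR = list(dist = "lognormal", meanlog = log(2.2), sdlog = 0.466),
    PLR = list(dist = "lognormal", meanlog = log(138), sdlog = 0.389),
    LMR = list(dist = "lognormal", meanlog = log(4.75), sdlog = 0.391)
  )
}

#' Simulation configuration
#'
#' @param n_subjects Cohort size before inclusion filtering.
#' @param arm_allocation Proportion allocated to the experimental
#'   (abiraterone + ADT) arm; allocation is exact
#'   (`round(n * arm_allocation)` subjects).
#' @param followup_max Administrative censoring time, months.
#' @param visit_rule List with `monthly_until` (months of monthly visits)
#'   and `thereafter_every` (months between later visits).
#' @param marker_params Named list of [trajectory_params()] (defaults for
#'   all five markers).
#' @param survival_params A [survival_params()] object.
#' @param censoring_rate Per-month exponential rate of random dropout.
#' @param missing_visit_prob Probability a scheduled post-baseline visit
#'   is skipped (baseline is never skipped).
#' @param baseline_params Marginal distributions of baseline covariates.
#' @param seed Integer seed; the generator is reproducible given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1138, arm_allocation = 563 / 1138,
                       followup_max = 60,
                       visit_rule = list(monthly_until = 12,
                                         thereafter_every = 2),
                       marker_params = default_marker_params(),
                       survival_params = serojm::survival_params(),
                       censoring_rate = 0.003,
                       missing_visit_prob = 0.1,
                       baseline_params = default_baseline_params(),
                       seed = 1L) {
  stop_if_not(is.numeric(n_subjects) && n_subjects >= 2,
              "n_subjects must be >= 2")
  stop_if_not(is_prob(arm_allocation), "arm_allocation must be in [0, 1]")
  stop_if_not(followup_max > 0, "followup_max must be > 0")
  stop_if_not(censoring_rate >= 0, "censoring_rate must be >= 0")
  stop_if_not(is_prob(missing_visit_prob),
              "missing_visit_prob must be in [0, 1]")
  stop_if_not(inherits(survival_params, "survival_params"),
              "survival_params must be a survival_params() object")
  stop_if_not(all(vapply(marker_params, inherits, TRUE, "trajectory_params")),
              "marker_params must be trajectory_params() objects")
  stop_if_not(length(seed) == 1 && is.finite(seed), "seed must be an integer")
  structure(list(n_subjects = as.integer(n_subjects),
                 arm_allocation = arm_allocation,
                 followup_max = followup_max, visit_rule = visit_rule,
                 marker_params = marker_params,
                 survival_params = survival_params,
                 censoring_rate = censoring_rate,
                 missing_visit_prob = missing_visit_prob,
                 baseline_params = baseline_params,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Model-implied marker value at a time point
#'
#' The generating linear predictor
#' `beta0 + b0 + (beta_t + b1) t + beta_arm arm + beta_arm_t arm t +
#' beta_base baseline` on the marker's modelling scale.
#'
#' @param params A [trajectory_params()] object.
#' @param subject One-row subject data frame (uses `arm` and the
#'   marker's baseline column).
#' @param random_effects Numeric length-2 vector `(b0, b1)`.
#' @param marker Marker name; must match `params$marker`.
#' @param t Time in months (vectorised), `t >= 0`.
#' @return Modelling-scale value(s) of the latent trajectory.
#' @export
true_marker_value <- function(params, subject, random_effects, marker, t) {
  stop_if_not(identical(marker, params$marker),
              "marker does not match params: ", marker)
  stop_if_not(all(t >= 0), "t must be >= 0")
  base_native <- subject[[paste0("baseline_", marker)]]
  base <- marker_to_model_scale(marker, base_native)
  with(params,
       beta0 + random_effects[1] +
         (beta_t + random_effects[2]) * t +
         beta_arm * subject$arm + beta_arm_t * subject$arm * t +
         beta_base * base)
}

# Draw baseline covariates and per-subject latent trajectories; returns
# subjects (without outcomes), intercept/slope matrices on modelling
# scale, and the random-effect draws.
draw_baselines <- function(config) {
  n <- config$n_subjects
  bp <- config$baseline_params
  n_exp <- round(n * config$arm_allocation)
  arm <- c(rep(1L, n_exp), rep(0L, n - n_exp))
  draw1 <- function(spec) {
    if (spec$dist == "normal") rnorm(n, spec$mean, spec$sd)
    else rlnorm(n, spec$meanlog, spec$sdlog)
  }
  subjects <- data.frame(
    id = seq_len(n), arm = arm,
    ecog = rbinom(n, 1, bp$p_ecog),
    skeletal_ge10 = rbinom(n, 1, bp$p_skeletal),
    liver_met = rbinom(n, 1, bp$p_liver),
    nodal_n1 = rbinom(n, 1, bp$p_nodal),
    gleason_9_10 = rbinom(n, 1, bp$p_gleason),
    worst_pain = sample(0:10, n, replace = TRUE, prob = bp$pain_probs),
    baseline_Hb = pmax(draw1(bp$Hb), marker_registry()$floor[1]),
    baseline_PSA = draw1(bp$PSA),
    baseline_NLR = pmax(draw1(bp$NLR), 0.1),
    baseline_PLR = pmax(draw1(bp$PLR), 5),
    baseline_LMR = pmax(draw1(bp$LMR), 0.1)
  )
  mk <- names(config$marker_params)
  a <- matrix(0, n, length(mk), dimnames = list(NULL, mk))
  bsl <- a
  reff <- vector("list", length(mk)); names(reff) <- mk
  for (m in mk) {
    p <- config$marker_params[[m]]
    z <- matrix(rnorm(2 * n), n, 2)
    Sig <- matrix(c(p$sd_b0^2, p$corr_b0b1 * p$sd_b0 * p$sd_b1,
                    p$corr_b0b1 * p$sd_b0 * p$sd_b1, p$sd_b1^2), 2, 2)
    ch <- chol(Sig + diag(1e-12, 2))
    b <- z %*% ch
    base <- marker_to_model_scale(m, subjects[[paste0("baseline_", m)]])
    a[, m] <- p$beta0 + b[, 1] + p$beta_arm * subjects$arm +
      p$beta_base * base
    bsl[, m] <- p$beta_t + b[, 2] + p$beta_arm_t * subjects$arm
    reff[[m]] <- b
  }
  list(subjects = subjects, intercepts = a, slopes = bsl,
       random_effects = reff)
}

#' Simulate event times under the current-value hazard
#'
#' Prostate-cancer death times are drawn by inverting the cumulative
#' hazard `H(t) = int h0(s) exp(gamma'w + sum_k alpha_k m_k(s)/s_k) ds`
#' against `-log(U)`; `H` is accumulated on a dense time grid (step 0.02
#' months) and inverted by monotone interpolation. Other-cause death is
#' exponential with constant hazard; the earliest of cancer death,
#' other-cause death, random censoring, and administrative censoring at
#' `followup_max` determines the record.
#'
#' @param sp A [survival_params()] object (with a concrete `scale`).
#' @param subjects Subjects table (covariates; see [simulate_cohort()]).
#' @param trajectories List with `intercepts` and `slopes` matrices
#'   (n x markers, modelling scale).
#' @param followup_max Administrative censoring time, months.
#' @param censoring_rate Per-month random-censoring rate.
#' @return `subjects` with `event_time`, `event`, `cause` columns added.
#' @export
simulate_event_times <- function(sp, subjects, trajectories,
                                 followup_max = 60, censoring_rate = 0) {
  n <- nrow(subjects)
  AB <- hazard_lin_pred(sp, subjects, trajectories)
  if (any(!is.finite(AB$A)) || any(!is.finite(AB$B))) {
    bad <- which(!is.finite(AB$A) | !is.finite(AB$B))
    stop("non-finite hazard linear predictor for subject(s) ",
         paste(head(subjects$id[bad], 5), collapse = ", "))
  }
  H <- cumhaz_grid(sp, AB, followup_max)
  if (any(!is.finite(H$H[, ncol(H$H)]))) {
    bad <- which(!is.finite(H$H[, ncol(H$H)]))
    stop("hazard overflow (runaway trajectory) for subject(s) ",
         paste(head(subjects$id[bad], 5), collapse = ", "))
  }
  e <- -log(runif(n))
  t_pc <- invert_cumhaz(H$tgrid, H$H, e)        # Inf if beyond follow-up
  t_oc <- if (sp$othercause_hazard > 0)
    rexp(n, sp$othercause_hazard) else rep(Inf, n)
  t_cn <- if (censoring_rate > 0) rexp(n, censoring_rate) else rep(Inf, n)
  t_all <- pmin(t_pc, t_oc, t_cn, followup_max)
  cause <- ifelse(t_pc <= t_all, "prostate-cancer",
                  ifelse(t_oc <= t_all, "other", "censored"))
  subjects$event_time <- pmax(t_all, 1e-6)
  subjects$event <- as.integer(cause != "censored")
  subjects$cause <- cause
  subjects
}

# A_i = gamma'w_i + sum_k alpha_k a_ik / s_k ; B_i likewise from slopes.
hazard_lin_pred <- function(sp, subjects, trajectories) {
  W <- surv_design(subjects)
  A <- drop(W %*% sp$gamma)
  B <- numeric(nrow(subjects))
  for (m in colnames(trajectories$intercepts)) {
    sc <- marker_scale(m)
    al <- sp$alpha[[m]] %||% 0
    if (is.na(al)) al <- 0
    A <- A + al * trajectories$intercepts[, m] / sc
    B <- B + al * trajectories$slopes[, m] / sc
  }
  list(A = A, B = B)
}

cumhaz_grid <- function(sp, AB, followup_max, step = NULL) {
  # ~0.02-month resolution, capped at 3000 cells for very long follow-up
  if (is.null(step)) step <- max(0.02, followup_max / 3000)
  tgrid <- seq(0, followup_max, by = step)
  h0 <- (sp$shape / sp$scale) * (tgrid / sp$scale)^(sp$shape - 1)
  h0[1] <- if (sp$shape >= 1) h0[1] else h0[2]  # guard t = 0 for shape < 1
  # hazard matrix n x length(tgrid): h0(t) * exp(A + B t)
  hz <- exp(outer(AB$B, tgrid) + AB$A)
  hz <- sweep(hz, 2, h0, `*`)
  inc <- 0.5 * step * (hz[, -1, drop = FALSE] + hz[, -ncol(hz), drop = FALSE])
  H <- cbind(0, t(apply(inc, 1, cumsum)))
  list(tgrid = tgrid, H = H)
}

invert_cumhaz <- function(tgrid, H, e) {
  n <- nrow(H)
  out <- rep(Inf, n)
  for (i in seq_len(n)) {
    Hi <- H[i, ]
    if (e[i] >= Hi[length(Hi)]) next
    m <- findInterval(e[i], Hi)
    dH <- Hi[m + 1] - Hi[m]
    frac <- if (dH > 0) (e[i] - Hi[m]) / dH else 0
    out[i] <- tgrid[m] + frac * (tgrid[m + 1] - tgrid[m])
  }
  out
}

# Calibrate the Weibull scale so the pooled probability of death by
# `target_median` months is 1/2 (deterministic in the drawn covariates).
calibrate_scale <- function(sp, subjects, trajectories, followup_max) {
  if (!is.na(sp$scale)) return(sp)
  sp_try <- sp; sp_try$scale <- followup_max  # reference scale
  AB <- hazard_lin_pred(sp_try, subjects, trajectories)
  tm <- min(sp$target_median, followup_max)
  H <- cumhaz_grid(sp_try, AB, tm)
  Hm <- H$H[, ncol(H$H)]
  f <- function(logc) {
    mean(1 - exp(-exp(logc) * Hm - sp$othercause_hazard * tm)) - 0.5
  }
  logc <- uniroot(f, c(-25, 25))$root
  sp$scale <- sp_try$scale / exp(logc / sp$shape)
  sp
}

#' Visit grid of the trial schedule
#'
#' Monthly visits through `monthly_until` months, then every
#' `thereafter_every` months up to `followup_max`.
#' @param followup_max Months of follow-up.
#' @param visit_rule See [sim_config()].
#' @return Numeric vector of scheduled visit times (months).
#' @export
visit_grid <- function(followup_max = 60,
                       visit_rule = list(monthly_until = 12,
                                         thereafter_every = 2)) {
  g1 <- seq(0, min(visit_rule$monthly_until, followup_max), by = 1)
  g2 <- if (followup_max > visit_rule$monthly_until)
    seq(visit_rule$monthly_until + visit_rule$thereafter_every,
        followup_max, by = visit_rule$thereafter_every) else numeric(0)
  c(g1, g2)
}

#' Truncate a marker series to the visit schedule with missingness
#'
#' Keeps scheduled visits before the subject's event time (deaths) or up
#' to and including it (censored subjects, who attend the final visit);
#' each post-baseline visit is independently skipped with probability
#' `missing_visit_prob`; the baseline visit is never skipped. A skipped
#' clinic visit drops all markers measured at that visit.
#'
#' @param config A [sim_config()] (visit rule and missingness).
#' @param subject Subjects table rows with `id`, `event_time`, `event`.
#' @param series Long-format marker series (`id`, `marker`, `time_months`,
#'   `value`) on the full grid.
#' @return Filtered series.
#' @export
apply_visit_schedule <- function(config, subject, series) {
  stop_if_not(all(series$id %in% subject$id),
              "series contains subjects absent from the subject table")
  et <- subject$event_time[match(series$id, subject$id)]
  ev <- subject$event[match(series$id, subject$id)]
  keep <- ifelse(ev == 1, series$time_months < et, series$time_months <= et)
  series <- series[keep, , drop = FALSE]
  # one missingness draw per subject-visit (shared across markers)
  sv <- unique(series[series$time_months > 0, c("id", "time_months")])
  if (nrow(sv) > 0 && config$missing_visit_prob > 0) {
    sv$skip <- runif(nrow(sv)) < config$missing_visit_prob
    key <- paste(series$id, series$time_months)
    skip_keys <- paste(sv$id, sv$time_months)[sv$skip]
    series <- series[!(key %in% skip_keys & series$time_months > 0), ,
                     drop = FALSE]
  }
  rownames(series) <- NULL
  series
}

#' Keep subjects meeting the longitudinal inclusion rule
#'
#' Retains subjects for whom every one of the five markers has a baseline
#' measurement and at least two post-baseline measurements.
#'
#' @param subjects Subjects table.
#' @param series Long-format marker series.
#' @return List with `subjects`, `series`, `n_excluded`, and the
#'   `excluded_ids`.
#' @export
apply_inclusion_filter <- function(subjects, series) {
  mk <- unique(series$marker)
  ok <- rep(TRUE, nrow(subjects))
  for (m in mk) {
    s <- series[series$marker == m, ]
    has_base <- tapply(s$time_months, s$id, function(t) any(t == 0))
    n_post <- tapply(s$time_months, s$id, function(t) sum(t > 0))
    idx <- match(subjects$id, as.numeric(names(has_base)))
    ok_m <- !is.na(idx) & has_base[idx] & n_post[idx] >= 2
    ok <- ok & ifelse(is.na(ok_m), FALSE, ok_m)
  }
  excluded <- subjects$id[!ok]
  if (length(excluded) > 0)
    message(length(excluded), " subject(s) excluded by the inclusion rule: ",
            paste(head(excluded, 10), collapse = ", "),
            if (length(excluded) > 10) ", ..." else "")
  list(subjects = subjects[ok, , drop = FALSE],
       series = series[series$id %in% subjects$id[ok], , drop = FALSE],
       n_excluded = length(excluded), excluded_ids = excluded)
}

#' Simulate a synthetic trial cohort
#'
#' Generates baseline covariates, latent marker trajectories, event
#' times under the current-value hazard, and observed marker series on
#' the trial visit schedule. The returned `truth` element echoes every
#' generating parameter (including the calibrated baseline-hazard scale
#' and the per-subject random effects) for parameter-recovery tests.
#'
#' @param config A [sim_config()] object.
#' @return List with `subjects` (one row per subject), `series`
#'   (long format: `id`, `marker`, `time_months`, `value` on native
#'   scale), and `truth`.
#' @export
simulate_cohort <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  dr <- draw_baselines(config)
  sp <- calibrate_scale(config$survival_params, dr$subjects,
                        dr[c("intercepts", "slopes")], config$followup_max)
  subjects <- simulate_event_times(
    sp, dr$subjects, dr[c("intercepts", "slopes")],
    followup_max = config$followup_max,
    censoring_rate = config$censoring_rate)

  grid <- visit_grid(config$followup_max, config$visit_rule)
  mk <- names(config$marker_params)
  n <- nrow(subjects)
  full <- expand.grid(time_months = grid, id = subjects$id,
                      marker = mk, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  full <- full[, c("id", "marker", "time_months")]
  idx <- match(full$id, subjects$id)
  mcol <- match(full$marker, colnames(dr$intercepts))
  mmod <- dr$intercepts[cbind(idx, mcol)] +
    dr$slopes[cbind(idx, mcol)] * full$time_months
  noise_sd <- vapply(config$marker_params, `[[`, numeric(1), "sd_resid")
  ymod <- mmod + rnorm(nrow(full)) * noise_sd[match(full$marker, mk)]
  full$value <- ymod
  series <- apply_visit_schedule(config, subjects, full)
  # native scale with positivity floors; baseline visit equals the
  # recorded baseline exactly
  reg <- marker_registry()
  for (m in mk) {
    sel <- series$marker == m
    v <- marker_from_model_scale(m, series$value[sel])
    fl <- reg$floor[match(m, reg$marker)]
    n_low <- sum(v < fl)
    if (n_low > 0)
      warning(n_low, " simulated ", m,
              " value(s) truncated at the positivity floor ", fl)
    series$value[sel] <- pmax(v, fl)
  }
  idx2 <- match(series$id, subjects$id)
  at_base <- series$time_months == 0
  base_mat <- as.matrix(subjects[, paste0("baseline_", mk), drop = FALSE])
  series$value[at_base] <-
    base_mat[cbind(idx2[at_base],
                   match(paste0("baseline_", series$marker[at_base]),
                         colnames(base_mat)))]

  truth <- list(config = config, survival_params = sp,
                intercepts = dr$intercepts, slopes = dr$slopes,
                random_effects = dr$random_effects)
  list(subjects = subjects, series = series, truth = truth)
}

#' Write a simulated cohort to delimited text files
#'
#' Writes `subjects.csv` (one row per subject), `markers.csv`
#' (long format: id, marker, time_months, value) and `truth.json`
#' (generating parameters) into `dir`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  write.csv(cohort$series, file.path(dir, "markers.csv"), row.names = FALSE)
  tr <- cohort$truth
  echo <- list(
    n_subjects = tr$config$n_subjects,
    arm_allocation = tr$config$arm_allocation,
    followup_max = tr$config$followup_max,
    censoring_rate = tr$config$censoring_rate,
    missing_visit_prob = tr$config$missing_visit_prob,
    seed = tr$config$seed,
    survival = list(shape = tr$survival_params$shape,
                    scale = tr$survival_params$scale,
                    gamma = as.list(tr$survival_params$gamma),
                    alpha = as.list(tr$survival_params$alpha),
                    othercause_hazard = tr$survival_params$othercause_hazard),
    markers = lapply(tr$config$marker_params, unclass)
  )
  jsonlite::write_json(echo, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
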