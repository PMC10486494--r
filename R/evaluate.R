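## Model evaluation: IPCW weights, time-varying Brier score,
## calibration indices (ICI, E50, E90), and the five-fold
## cross-validation harness.

#' Inverse-probability-of-censoring weights at a horizon
#'
#' Kaplan-Meier estimate `G` of the censoring distribution on the
#' scored data; subjects with an event before `u` get `1 / G(T_i-)`,
#' subjects still at risk at `u` get `1 / G(u)`, subjects censored
#' before `u` get 0.
#'
#' @param outcomes Data frame with `time` and `status` (1 = event).
#' @param u Horizon (same time unit).
#' @return Numeric weight per subject.
#' @export
ipcw_weights <- function(outcomes, u) {
  stop_if_not(all(c("time", "status") %in% names(outcomes)),
              "outcomes needs `time` and `status` columns")
  cens <- 1 - outcomes$status
  G <- survival::survfit(Surv(outcomes$time, cens) ~ 1)
  Gfun <- stepfun(G$time, c(1, G$surv))
  Gleft <- function(t) Gfun(t - 1e-9)
  w <- numeric(nrow(outcomes))
  ev_before <- outcomes$status == 1 & outcomes$time <= u
  # censored exactly at u counts as at risk (survived to the horizon)
  at_risk <- outcomes$time > u |
    (outcomes$time == u & outcomes$status == 0)
  Gu <- Gleft(u)
  if (any(at_risk) || any(ev_before)) {
    denom_ev <- Gleft(outcomes$time[ev_before])
    if (any(denom_ev <= 0) || (any(at_risk) && Gu <= 0))
      stop("censoring survival G is 0 at or before horizon u = ", u,
           ": horizon beyond support")
    w[ev_before] <- 1 / denom_ev
    w[at_risk] <- 1 / Gu
  }
  if (all(w == 0))
    stop("all subjects censored before horizon u = ", u,
         ": Brier score undefined")
  w
}

#' IPCW Brier score at a horizon
#'
#' `sum_i w_i (1(T_i > u) - pi_i(u))^2 / n` with IPCW weights; 0 is
#' perfect, and an uninformative constant prediction of 0.5 scores 0.25
#' on uncensored data.
#'
#' @param predictions Predicted survival probabilities `pi(u)` aligned
#'   with `outcomes` rows.
#' @param outcomes Data frame with `time` and `status`.
#' @param u Horizon.
#' @return Scalar Brier score with attribute `n_effective` (sum of
#'   weights).
#' @export
brier_score <- function(predictions, outcomes, u) {
  stop_if_not(length(predictions) == nrow(outcomes),
              "predictions and outcomes refer to different subject sets")
  w <- ipcw_weights(outcomes, u)
  surv_ind <- as.numeric(outcomes$time > u |
                           (outcomes$time == u & outcomes$status == 0))
  bs <- sum(w * (surv_ind - predictions)^2) / nrow(outcomes)
  attr(bs, "n_effective") <- sum(w > 0)
  bs
}

weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(p, function(pp) x[which(cw >= pp)[1]], numeric(1))
}

#' Calibration indices at a horizon (ICI, E50, E90)
#'
#' The observed event probability is obtained by an IPCW-weighted
#' local-linear smoother (`loess`, degree 1, fixed span) of the event
#' indicator on the complementary log-log of the predicted risk,
#' evaluated at each subject's predicted risk. ICI is the weighted mean
#' absolute difference between smoothed observed and predicted risk;
#' E50 and E90 are the weighted median and 90th percentile of the same
#' absolute differences.
#'
#' @param predictions Predicted survival probabilities `pi(u)`.
#' @param outcomes Data frame with `time`, `status`.
#' @param u Horizon.
#' @param span Fixed loess span.
#' @return Named vector `c(ICI, E50, E90)`.
#' @export
calibration_metrics <- function(predictions, outcomes, u, span = 0.75) {
  stop_if_not(length(predictions) == nrow(outcomes),
              "predictions and outcomes refer to different subject sets")
  w <- ipcw_weights(outcomes, u)
  keep <- w > 0
  risk <- pmin(pmax(1 - predictions[keep], 1e-6), 1 - 1e-6)
  obs <- as.numeric(outcomes$time[keep] <= u &
                      outcomes$status[keep] == 1)  # event by u (w > 0 only)
  ww <- w[keep]
  if (sd(risk) < 1e-8) {
    warning("all predictions identical: calibration smoother degenerate, ",
            "returning the pooled observed-predicted difference")
    d <- abs(weighted.mean(obs, ww) - mean(risk))
    return(c(ICI = d, E50 = d, E90 = d))
  }
  cll <- log(-log(1 - risk))
  fitl <- loess(obs ~ cll, weights = ww, degree = 1, span = span,
                family = "gaussian",
                control = loess.control(surface = "direct"))
  smoothed <- pmin(pmax(predict(fitl, newdata = data.frame(cll = cll)),
                        0), 1)
  adiff <- abs(smoothed - risk)
  c(ICI = weighted.mean(adiff, ww),
    E50 = weighted_quantile(adiff, ww, 0.5),
    E90 = weighted_quantile(adiff, ww, 0.9))
}

make_folds <- function(status, k, seed) {
  set.seed(seed)
  fold <- integer(length(status))
  for (s in unique(status)) {
    idx <- which(status == s)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  # guard: every fold needs at least one event
  tries <- 0
  while (any(tapply(status, fold, sum) == 0) && tries < 20) {
    warning("fold with zero events: re-stratifying")
    fold <- make_folds(status, k, seed + 1000 + tries)
    tries <- tries + 1
  }
  fold
}

#' Cross-validated dynamic evaluation
#'
#' Five-fold (by default) cross-validation stratified by event
#' indicator: each fold's model is fitted on the remaining folds,
#' held-out subjects at risk at the landmark are predicted from their
#' history up to the landmark only, and the pooled predictions are
#' scored with IPCW Brier and calibration indices over a horizon grid.
#'
#' @param cohort List with `subjects` and `series` (post inclusion
#'   filter).
#' @param spec A [joint_model_spec()] (markers, endpoint, backend).
#' @param k Number of folds (>= 2).
#' @param landmark Landmark time (months, default 24).
#' @param horizons Horizon grid (default every 3 months to 60).
#' @param seed Seed controlling folds and prediction draws.
#' @param n_draws Monte Carlo draws per prediction.
#' @param predict_override Optional function
#'   `f(subjects, landmark, horizons)` returning a prediction table
#'   (`id`, `horizon`, `pi_hat`) used instead of model fitting — for
#'   harness validation with oracle predictions.
#' @return List of class `evaluation_report`: `folds`, `predictions`,
#'   `brier` (per horizon), `calibration` (per horizon), `landmark`,
#'   `meta`.
#' @export
cross_validate <- function(cohort, spec = joint_model_spec(), k = 5,
                           landmark = 24,
                           horizons = NULL, seed = 1L, n_draws = 100,
                           predict_override = NULL) {
  stop_if_not(k >= 2, "k must be >= 2")
  subjects <- cohort$subjects
  series <- cohort$series
  if (is.null(horizons))
    horizons <- seq(landmark + 3, 60, by = 3)
  status <- endpoint_status(subjects, spec$endpoint)
  fold <- make_folds(status, k, seed)
  at_risk <- subjects$event_time > landmark
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- subjects$id[fold == f & at_risk]
    if (length(test_ids) == 0) next
    test_sub <- subjects[subjects$id %in% test_ids, , drop = FALSE]
    if (!is.null(predict_override)) {
      pr <- predict_override(test_sub, landmark, horizons)
    } else {
      train <- list(
        subjects = subjects[fold != f, , drop = FALSE],
        series = series[series$id %in% subjects$id[fold != f], ,
                        drop = FALSE])
      fit <- if (length(spec$markers) == 1L)
        fit_univariate_joint(train, spec$markers, spec)
      else fit_multivariate_joint(train, spec$markers, spec)
      set.seed(seed + f)
      hist_lm <- series[series$time_months <= landmark, , drop = FALSE]
      pr <- predict_dynamic(fit, test_sub, hist_lm, landmark, horizons,
                            n_draws = n_draws)
    }
    pr$fold <- f
    preds[[f]] <- pr
  }
  preds <- do.call(rbind, preds)
  scored <- subjects[match(unique(preds$id), subjects$id), , drop = FALSE]
  outcomes <- data.frame(time = scored$event_time,
                         status = endpoint_status(scored, spec$endpoint))
  bri <- cal <- NULL
  for (u in horizons) {
    pu <- preds[preds$horizon == u, , drop = FALSE]
    pu <- pu[match(scored$id, pu$id), ]
    b <- tryCatch(brier_score(pu$pi_hat, outcomes, u),
                  error = function(e) NA_real_)
    cm <- tryCatch(calibration_metrics(pu$pi_hat, outcomes, u),
                   error = function(e)
                     c(ICI = NA_real_, E50 = NA_real_, E90 = NA_real_))
    bri <- rbind(bri, data.frame(horizon = u, brier = as.numeric(b),
                                 n_effective =
                                   attr(b, "n_effective") %||% NA))
    cal <- rbind(cal, data.frame(horizon = u, ICI = cm[["ICI"]],
                                 E50 = cm[["E50"]], E90 = cm[["E90"]]))
  }
  structure(list(folds = data.frame(id = subjects$id, fold = fold),
                 predictions = preds, brier = bri, calibration = cal,
                 landmark = landmark,
                 meta = list(k = k, seed = seed, n_draws = n_draws,
                             endpoint = spec$endpoint,
                             markers = spec$markers,
                             backend = spec$backend)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Cross-validated dynamic evaluation (", x$meta$endpoint,
      "), landmark ", x$landmark, " months, k = ", x$meta$k, "\n", sep = "")
  cat("  markers:", paste(x$meta$markers, collapse = ", "),
      " backend:", x$meta$backend, "\n")
  cat(sprintf("  Brier over horizons: %.3f - %.3f\n",
              min(x$brier$brier, na.rm = TRUE),
              max(x$brier$brier, na.rm = TRUE)))
  ici <- x$calibration$ICI
  if (any(is.finite(ici)))
    cat(sprintf("  ICI over horizons:   %.3f - %.3f\n",
                min(ici, na.rm = TRUE), max(ici, na.rm = TRUE)))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$brier, file.path(dir, "brier.csv"), row.names = FALSE)
  write.csv(report$calibration, file.path(dir, "calibration.csv"),
            row.names = FALSE)
  write.csv(report$predictions, file.path(dir, "predictions.csv"),
            row.names = FALSE)
  write.csv(report$folds, file.path(dir, "folds.csv"), row.names = FALSE)
  invisible(dir)
}
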