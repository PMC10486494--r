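## Decision-curve analysis: net benefit of acting on the model's
## predicted event risk at a horizon, versus treat-all and treat-none,
## with censoring handled by the same IPCW weights as the Brier module.

#' Net-benefit curve at a horizon
#'
#' `NB_model(p) = TP(p)/n - p/(1-p) * FP(p)/n`, where a subject is
#' flagged when the predicted event risk by horizon `u` is at least
#' `p`, and TP / FP are IPCW estimates of event and event-free status
#' by `u`. `NB_all(p) = prev - p/(1-p) * (1 - prev)` with `prev` the
#' IPCW event prevalence by `u`; treat-none is identically 0.
#'
#' @param predictions Predicted event probabilities by `u`
#'   (risk = 1 - survival probability), one per subject.
#' @param outcomes Data frame with `time`, `status`.
#' @param u Horizon.
#' @param thresholds Threshold probabilities strictly inside (0, 1);
#'   values above 0.99 are dropped with a warning (the odds weight
#'   explodes).
#' @return Data frame of class `net_benefit_curve`: `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`.
#' @export
net_benefit_curve <- function(predictions, outcomes, u,
                              thresholds = seq(0.01, 0.60, by = 0.01)) {
  stop_if_not(length(predictions) == nrow(outcomes),
              "predictions and outcomes refer to different subject sets")
  stop_if_not(all(thresholds > 0), "thresholds must be in (0, 1)")
  if (any(thresholds > 0.99)) {
    warning("thresholds above 0.99 dropped (odds weight p/(1-p) explodes)")
    thresholds <- thresholds[thresholds <= 0.99]
  }
  n <- nrow(outcomes)
  w <- ipcw_weights(outcomes, u)
  event_by_u <- as.numeric(outcomes$time <= u & outcomes$status == 1)
  free_by_u <- as.numeric(outcomes$time > u |
                            (outcomes$time == u & outcomes$status == 0))
  prev <- sum(w * event_by_u) / n
  surv <- sum(w * free_by_u) / n
  nb_model <- nb_all <- numeric(length(thresholds))
  for (j in seq_along(thresholds)) {
    p <- thresholds[j]
    flag <- predictions >= p
    tp <- sum(w * event_by_u * flag) / n
    fp <- sum(w * free_by_u * flag) / n
    odds <- p / (1 - p)
    nb_model[j] <- tp - odds * fp
    nb_all[j] <- prev - odds * surv
  }
  structure(data.frame(threshold = thresholds, nb_model = nb_model,
                       nb_all = nb_all, nb_none = 0),
            class = c("net_benefit_curve", "data.frame"))
}

#' Interval of thresholds where the model beats both default strategies
#'
#' Returns the thresholds at which `nb_model > max(nb_all, 0)`, the
#' qualitative signature of a clinically useful model on a decision
#' curve.
#'
#' @param curve A [net_benefit_curve()] result.
#' @param margin Superiority margin (default 0).
#' @return Numeric vector of thresholds (possibly empty).
#' @export
nb_superior_thresholds <- function(curve, margin = 0) {
  sel <- curve$nb_model > pmax(curve$nb_all, 0) + margin
  curve$threshold[sel]
}

#' Write a net-benefit curve as delimited text
#' @param curve A [net_benefit_curve()] result.
#' @param path Output CSV path.
#' @return The curve, invisibly.
#' @export
write_net_benefit <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(curve)
}
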