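## Cox proportional-hazards sub-model for the nine baseline covariates,
## with the Breslow cumulative baseline hazard needed for absolute-risk
## predictions. PCSS treats other-cause deaths as censored.

#' Fit the baseline Cox sub-model
#'
#' Covariates: ECOG (0 vs >=1), skeletal lesions (>=10), liver
#' metastasis, nodal stage N1, Gleason 9-10, baseline Hb, log(baseline
#' PSA + 1), worst pain score (0-10, continuous), and treatment arm.
#' Breslow tie handling.
#'
#' @param subjects Subjects table with `event_time`, `event`, `cause`.
#' @param endpoint `"OS"` (death from any cause) or `"PCSS"`
#'   (prostate-cancer death; other deaths censored).
#' @return An object of class `serojm_cox` wrapping the
#'   \code{\link[survival]{coxph}} fit with `gamma`, `gamma_se`,
#'   `loglik`, and the endpoint/ties tags.
#' @export
fit_cox <- function(subjects, endpoint = c("OS", "PCSS")) {
  endpoint <- match.arg(endpoint)
  status <- endpoint_status(subjects, endpoint)
  stop_if_not(sum(status) >= 1, "no events for endpoint ", endpoint)
  W <- surv_design(subjects)
  keep <- apply(W, 2, function(x) var(x) > 0)
  if (!all(keep))
    message("dropping constant covariate(s): ",
            paste(colnames(W)[!keep], collapse = ", "))
  W <- W[, keep, drop = FALSE]
  stop_if_not(ncol(W) >= 1, "no non-constant covariates")
  df <- data.frame(time = subjects$event_time, status = status, W)
  fml <- stats::as.formula(paste(
    "Surv(time, status) ~",
    paste(colnames(W), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow", x = TRUE)
  if (any(is.na(coef(fit))))
    stop("collinear covariates in the Cox sub-model: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  se <- setNames(sqrt(diag(fit$var)), names(coef(fit)))
  big <- abs(coef(fit)) > 10
  if (any(big))
    warning("possible separation for covariate(s): ",
            paste(names(coef(fit))[big], collapse = ", "))
  structure(list(coxph = fit, gamma = coef(fit), gamma_se = se,
                 loglik = fit$loglik[2], endpoint = endpoint,
                 ties = "breslow", n_events = sum(status)),
            class = "serojm_cox")
}

endpoint_status <- function(subjects, endpoint) {
  if (endpoint == "OS") as.integer(subjects$event == 1)
  else as.integer(subjects$cause == "prostate-cancer")
}

#' Breslow cumulative baseline hazard
#'
#' Step function `H0(t)` jumping only at observed event times; at
#' covariate value zero (uncentered), so
#' `exp(-H0(t) * exp(gamma'w))` is the model survival probability.
#'
#' @param fit A [fit_cox()] result (or a `coxph` fit).
#' @return A function `H0(t)`, with the step coordinates attached as
#'   attributes `time` and `hazard`.
#' @export
breslow_baseline <- function(fit) {
  cph <- if (inherits(fit, "serojm_cox")) fit$coxph else fit
  bh <- survival::basehaz(cph, centered = FALSE)
  sf <- stats::stepfun(bh$time, c(0, bh$hazard))
  attr(sf, "time") <- bh$time
  attr(sf, "hazard") <- bh$hazard
  sf
}

#' @export
print.serojm_cox <- function(x, ...) {
  cat("Cox sub-model (", x$endpoint, ", Breslow ties), ",
      x$n_events, " events\n", sep = "")
  tab <- data.frame(HR = exp(x$gamma),
                    lower = exp(x$gamma - 1.96 * x$gamma_se),
                    upper = exp(x$gamma + 1.96 * x$gamma_se),
                    p = 2 * pnorm(-abs(x$gamma / x$gamma_se)))
  print(round(tab, 4))
  invisible(x)
}
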