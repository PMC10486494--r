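## Shared helpers: marker registry, transforms, validation, quadrature.

# The five serological markers, their association reporting scales
# (hazard ratios are quoted per `scale` units of the current value),
# the modelling transform, and a positivity floor used when simulated
# measurement noise would push a native value non-positive.
marker_registry <- function() {
  data.frame(
    marker = c("Hb", "NLR", "PLR", "LMR", "PSA"),
    scale  = c(1, 1, 100, 5, 1),
    transform = c("identity", "identity", "identity", "identity", "log1p"),
    floor  = c(3, 0.05, 5, 0.05, 0),
    stringsAsFactors = FALSE
  )
}

#' Names of the five modelled serological markers
#' @return `c("Hb", "NLR", "PLR", "LMR", "PSA")`.
#' @export
marker_names <- function() marker_registry()$marker

marker_scale <- function(marker) {
  reg <- marker_registry()
  i <- match(marker, reg$marker)
  if (anyNA(i)) stop("unknown marker(s): ",
                     paste(marker[is.na(i)], collapse = ", "))
  reg$scale[i]
}

#' Transform a marker from native to modelling scale
#'
#' PSA is modelled as `log(x + 1)`; all other markers on their native
#' scale.
#' @param marker Marker name.
#' @param x Native-scale values.
#' @return Modelling-scale values.
#' @export
marker_to_model_scale <- function(marker, x) {
  if (marker == "PSA") log1p(x) else x
}

#' @rdname marker_to_model_scale
#' @export
marker_from_model_scale <- function(marker, x) {
  if (marker == "PSA") expm1(x) else x
}

# Survival sub-model baseline covariates, in reporting order.
surv_covariate_names <- function() {
  c("ecog", "skeletal_ge10", "liver_met", "nodal_n1", "gleason_9_10",
    "baseline_Hb", "log_baseline_PSA", "worst_pain", "arm")
}

# Design matrix of the nine baseline covariates from a subjects table.
surv_design <- function(subjects) {
  W <- cbind(
    ecog = subjects$ecog,
    skeletal_ge10 = subjects$skeletal_ge10,
    liver_met = subjects$liver_met,
    nodal_n1 = subjects$nodal_n1,
    gleason_9_10 = subjects$gleason_9_10,
    baseline_Hb = subjects$baseline_Hb,
    log_baseline_PSA = log1p(subjects$baseline_PSA),
    worst_pain = subjects$worst_pain,
    arm = subjects$arm
  )
  storage.mode(W) <- "double"
  W
}

# Gauss-Hermite rule (physicists' convention, weights include e^{-x^2}).
gh_rule <- function(n) {
  gq <- statmod::gauss.quad(n, kind = "hermite")
  list(x = gq$nodes, w = gq$weights)
}

stop_if_not <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

is_prob <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) &&
  p >= 0 && p <= 1

# Piecewise-constant baseline-hazard knots: interior knots at event-time
# quantiles, closed on [0, upper].
pc_knots <- function(event_times, n_segments = 6, upper = NULL) {
  stop_if_not(length(event_times) >= 1, "need at least one event time")
  if (is.null(upper)) upper <- max(event_times) * 1.001
  qs <- quantile(event_times, probs = seq_len(n_segments - 1) / n_segments,
                 names = FALSE, type = 7)
  knots <- unique(c(0, qs, upper))
  if (length(knots) < 3) knots <- c(0, upper / 2, upper)
  sort(knots)
}

# Segment index of times within a knot vector (1-based, clamped).
pc_segment <- function(t, knots) {
  pmin(pmax(findInterval(t, knots, rightmost.closed = TRUE), 1L),
       length(knots) - 1L)
}

# R-side closed-form cumulative hazard for one subject with
# h(t) = lambda_seg(t) * exp(A + B t).  Used by prediction code.
pc_cumhaz <- function(t, A, B, knots, loglam) {
  lam <- exp(loglam)
  H <- numeric(length(t))
  for (m in seq_along(t)) {
    tt <- t[m]
    acc <- 0
    for (j in seq_len(length(knots) - 1L)) {
      u <- knots[j]
      if (u >= tt) break
      v <- min(knots[j + 1L], tt)
      acc <- acc + lam[j] * exp(A) * seg_I0(B, u, v)
    }
    H[m] <- acc
  }
  H
}

seg_I0 <- function(c, u, v) {
  if (abs(c) * max(abs(u), abs(v), 1) < 1e-7) {
    (v - u) + c * (v^2 - u^2) / 2 + c^2 * (v^3 - u^3) / 6
  } else {
    exp(c * u) * expm1(c * (v - u)) / c
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
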