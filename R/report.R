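## Reporting: arm-wise baseline summary table and the end-to-end
## pipeline (simulate -> filter -> fit -> cross-validate -> decision
## curves) with a machine-readable run manifest.

#' Baseline characteristics table by treatment arm
#'
#' Medians with interquartile ranges for continuous variables
#' (Wilcoxon rank-sum p-values) and counts with percentages for
#' categorical variables (chi-square test without continuity
#' correction).
#'
#' @param subjects Subjects table.
#' @return Data frame with columns `variable`, `arm1` (experimental),
#'   `arm0` (control), `p_value`.
#' @export
baseline_table <- function(subjects) {
  two_arms <- length(unique(subjects$arm)) == 2
  if (!two_arms)
    warning("single treatment arm: descriptive table only, no p-values")
  g1 <- subjects[subjects$arm == 1, , drop = FALSE]
  g0 <- subjects[subjects$arm == 0, , drop = FALSE]
  cont <- c("worst_pain", "baseline_PSA", "baseline_Hb", "baseline_NLR",
            "baseline_PLR", "baseline_LMR")
  cat_ <- c("ecog", "skeletal_ge10", "liver_met", "nodal_n1",
            "gleason_9_10")
  fmt_mi <- function(x) sprintf("%.1f (%.1f, %.1f)", median(x),
                                quantile(x, 0.25), quantile(x, 0.75))
  fmt_np <- function(x) sprintf("%d (%.1f%%)", sum(x), 100 * mean(x))
  rows <- list(data.frame(variable = "n",
                          arm1 = as.character(nrow(g1)),
                          arm0 = as.character(nrow(g0)),
                          p_value = NA_real_))
  for (v in cat_) {
    p <- if (two_arms && var(subjects[[v]]) > 0)
      suppressWarnings(chisq.test(table(subjects$arm, subjects[[v]]),
                                  correct = FALSE)$p.value)
    else NA_real_
    rows[[v]] <- data.frame(variable = v, arm1 = fmt_np(g1[[v]]),
                            arm0 = fmt_np(g0[[v]]), p_value = p)
  }
  for (v in cont) {
    p <- if (two_arms)
      suppressWarnings(wilcox.test(subjects[[v]] ~ subjects$arm)$p.value)
    else NA_real_
    rows[[v]] <- data.frame(variable = v, arm1 = fmt_mi(g1[[v]]),
                            arm0 = fmt_mi(g0[[v]]), p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param out_dir Artifact directory.
#' @param sim A [sim_config()].
#' @param endpoint `"OS"` or `"PCSS"`.
#' @param markers Marker set for the multivariate models.
#' @param backend Fitting backend for the univariate and multivariate
#'   stages (`"two_stage"` by default for speed; `"full_likelihood"` /
#'   `"bayesian_mcmc"` as in [joint_model_spec()]).
#' @param landmarks Landmark times for cross-validated evaluation.
#' @param k Cross-validation folds.
#' @param dca_horizon Horizon for decision curves (months).
#' @param n_draws Monte Carlo draws per prediction.
#' @param seed Seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("serojm_run_"),
                            sim = sim_config(),
                            endpoint = "OS",
                            markers = marker_names(),
                            backend = "two_stage",
                            landmarks = c(12, 24), k = 5,
                            dca_horizon = 60, n_draws = 100,
                            seed = 1L) {
  structure(list(out_dir = out_dir, sim = sim, endpoint = endpoint,
                 markers = markers, backend = backend,
                 landmarks = landmarks, k = k,
                 dca_horizon = dca_horizon, n_draws = n_draws,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr, log) {
  log(paste0("stage: ", name))
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulate a cohort, apply the inclusion filter, summarise baseline
#' characteristics, fit univariate joint models per marker, fit
#' multivariate models without and with PSA, cross-validate dynamic
#' predictions at the configured landmarks, compute decision curves for
#' both multivariate models, and write all tables plus a run manifest.
#'
#' @param config A [pipeline_config()].
#' @return The artifact directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log <- function(msg) cat(format(Sys.time(), "%H:%M:%S "), msg, "\n",
                           file = log_path, append = TRUE)

  cohort <- pipeline_stage("simulate", {
    co <- simulate_cohort(config$sim)
    write_cohort(co, file.path(config$out_dir, "cohort"))
    co
  }, log)
  flt <- pipeline_stage("inclusion_filter", {
    f <- apply_inclusion_filter(cohort$subjects, cohort$series)
    writeLines(c(paste("excluded:", f$n_excluded),
                 paste(f$excluded_ids, collapse = ",")),
               file.path(config$out_dir, "exclusions.txt"))
    f
  }, log)
  pipeline_stage("baseline_table", {
    write.csv(baseline_table(flt$subjects),
              file.path(config$out_dir, "table1.csv"), row.names = FALSE)
  }, log)

  spec_of <- function(markers, shrink = "none") joint_model_spec(
    endpoint = config$endpoint, markers = markers,
    shrinkage = if (config$backend == "bayesian_mcmc") shrink else "none",
    backend = config$backend,
    mcmc = list(warmup = 300, iter = 600, seed = config$seed))

  fits_uni <- pipeline_stage("univariate_fits", {
    out <- list()
    for (m in config$markers) {
      out[[m]] <- fit_univariate_joint(
        list(subjects = flt$subjects, series = flt$series), m, spec_of(m))
      write_hr_table(out[[m]],
                     file.path(config$out_dir,
                               paste0("univariate_", m, ".csv")))
    }
    out
  }, log)

  mk_nopsa <- setdiff(config$markers, "PSA")
  fits_mv <- pipeline_stage("multivariate_fits", {
    out <- list()
    if (length(mk_nopsa) >= 2) {
      out$no_psa <- fit_multivariate_joint(
        list(subjects = flt$subjects, series = flt$series), mk_nopsa,
        spec_of(mk_nopsa, "horseshoe"))
      write_hr_table(out$no_psa,
                     file.path(config$out_dir, "multivariate_noPSA.csv"))
    }
    if ("PSA" %in% config$markers && length(config$markers) >= 2) {
      out$with_psa <- fit_multivariate_joint(
        list(subjects = flt$subjects, series = flt$series), config$markers,
        spec_of(config$markers, "horseshoe"))
      write_hr_table(out$with_psa,
                     file.path(config$out_dir, "multivariate_withPSA.csv"))
    }
    out
  }, log)

  eval_spec <- joint_model_spec(endpoint = config$endpoint,
                                markers = config$markers,
                                backend = if (config$backend ==
                                              "bayesian_mcmc")
                                  "two_stage" else config$backend)
  reports <- pipeline_stage("cross_validation", {
    out <- list()
    for (lm_t in config$landmarks) {
      rep_l <- cross_validate(
        list(subjects = flt$subjects, series = flt$series), eval_spec,
        k = config$k, landmark = lm_t, seed = config$seed,
        n_draws = config$n_draws)
      write_evaluation(rep_l,
                       file.path(config$out_dir,
                                 paste0("cv_landmark_", lm_t)))
      out[[as.character(lm_t)]] <- rep_l
    }
    out
  }, log)

  pipeline_stage("decision_curves", {
    lm_t <- max(config$landmarks)
    rep_l <- reports[[as.character(lm_t)]]
    pu <- rep_l$predictions[rep_l$predictions$horizon ==
                              config$dca_horizon, , drop = FALSE]
    if (nrow(pu) > 0) {
      sc <- flt$subjects[match(pu$id, flt$subjects$id), , drop = FALSE]
      outc <- data.frame(time = sc$event_time,
                         status = endpoint_status(sc, config$endpoint))
      curve <- net_benefit_curve(pu$risk, outc, config$dca_horizon)
      write_net_benefit(curve,
                        file.path(config$out_dir, "decision_curve.csv"))
    }
  }, log)

  manifest <- list(
    package_version = as.character(utils::packageVersion("serojm")),
    seed = config$seed, endpoint = config$endpoint,
    markers = config$markers, backend = config$backend,
    landmarks = config$landmarks, k = config$k,
    n_subjects = config$sim$n_subjects, sim_seed = config$sim$seed,
    n_after_filter = nrow(flt$subjects))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("done")
  invisible(config$out_dir)
}
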