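test_that("configuration validation rejects invalid fields", {
  expect_error(sim_config(n_subjects = 1), "n_subjects")
  expect_error(sim_config(arm_allocation = 1.2), "arm_allocation")
  expect_error(sim_config(missing_visit_prob = -0.1), "missing_visit_prob")
  expect_error(survival_params(shape = -1), "shape")
  expect_error(trajectory_params("Hb", 0, 0, 0, 0, 1, -1, 0, 0, 1),
               "non-negative")
  expect_error(trajectory_params("XYZ", 0, 0, 0, 0, 1, 1, 0, 0, 1),
               "unknown marker")
})

test_that("trial-sized cohort has the exact arm allocation", {
  co <- test_full_cohort()
  expect_equal(nrow(co$subjects), 1138)
  expect_equal(sum(co$subjects$arm), 563)
})

test_that("identical configurations give byte-identical cohorts", {
  cfg <- sim_config(n_subjects = 60, seed = 33)
  a <- quiet_cohort(cfg)
  b <- quiet_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$series, b$series)
})

test_that("model-implied marker value is the stated linear predictor", {
  sub <- data.frame(arm = 1, baseline_Hb = 13)
  p0 <- trajectory_params("Hb", 0, 0, 0, 0, 0, 1, 1, 0, 1)
  expect_equal(true_marker_value(p0, sub, c(0, 0), "Hb", c(0, 7, 30)),
               c(0, 0, 0))
  p1 <- trajectory_params("Hb", 2, 0, 0, 0, 0.8, 1, 1, 0, 1)
  sub0 <- data.frame(arm = 0, baseline_Hb = 12)
  expect_equal(true_marker_value(p1, sub0, c(0, 0), "Hb", 0), 2 + 0.8 * 12)
  # hand computation with every coefficient active, t = 12
  p2 <- trajectory_params("Hb", 1.5, 0.02, 0.3, -0.01, 0.7, 1, 1, 0, 1)
  sub1 <- data.frame(arm = 1, baseline_Hb = 14)
  hand <- 1.5 + 0.25 + (0.02 + 0.05) * 12 + 0.3 + (-0.01) * 12 + 0.7 * 14
  expect_equal(true_marker_value(p2, sub1, c(0.25, 0.05), "Hb", 12), hand)
  expect_error(true_marker_value(p2, sub1, c(0, 0), "NLR", 1), "marker")
})

test_that("visit schedule is monthly then bimonthly, truncated at the event", {
  cfg <- sim_config(n_subjects = 2, missing_visit_prob = 0)
  sub <- data.frame(id = 1, event_time = 6.5, event = 1)
  s <- toy_series(1, visit_grid(60))
  got <- apply_visit_schedule(cfg, sub, s)
  expect_equal(got$time_months, 0:6)
  sub$event_time <- 20
  expect_equal(apply_visit_schedule(cfg, sub, s)$time_months,
               c(0:12, 14, 16, 18))
  # administratively censored at 60 months: attends the final visit
  sub2 <- data.frame(id = 1, event_time = 60, event = 0)
  expect_equal(length(apply_visit_schedule(cfg, sub2, s)$time_months), 37)
})

test_that("assessment counts at defaults are near the trial's median of 25", {
  co <- test_full_cohort()
  cnt <- table(co$series$id[co$series$marker == "Hb"])
  expect_gt(median(cnt), 17)
  expect_lt(median(cnt), 33)
})

test_that("baseline visits are never dropped and equal recorded baselines", {
  co <- test_cohort(n = 80, seed = 5)
  base <- co$series[co$series$time_months == 0, ]
  counts <- table(base$id)
  expect_true(all(counts == 5))
  hb <- base[base$marker == "Hb", ]
  expect_equal(hb$value,
               co$subjects$baseline_Hb[match(hb$id, co$subjects$id)])
})

test_that("inclusion rule keeps exactly the qualifying subjects", {
  subs <- data.frame(id = 1:10, arm = rep(0:1, 5))
  mk <- marker_names()
  series <- do.call(rbind, lapply(1:10, function(i) {
    do.call(rbind, lapply(mk, function(m) {
      times <- if (i == 3) c(0, 1)            # one post-baseline only
      else if (i == 7 && m == "PSA") c(1, 2, 3)  # no baseline for PSA
      else if (i == 9 && m == "LMR") c(0, 2)  # fails for a single marker
      else c(0, 1, 2)
      toy_series(i, times, m)
    }))
  }))
  expect_message(flt <- apply_inclusion_filter(subs, series), "excluded")
  expect_equal(nrow(flt$subjects), 7)
  expect_equal(flt$n_excluded, 3)
  expect_setequal(flt$excluded_ids, c(3, 7, 9))
  expect_false(any(flt$series$id %in% c(3, 7, 9)))
})

test_that("null-association event times match the Weibull baseline", {
  # shape 1, fixed scale, no covariate effects: exponential event times
  ga0 <- setNames(numeric(9), surv_covariate_names())
  sp <- survival_params(shape = 1, scale = 25, gamma = ga0,
                        alpha = default_alpha(), othercause_hazard = 0)
  cfg <- sim_config(n_subjects = 1500, seed = 77, censoring_rate = 0,
                    followup_max = 2000, survival_params = sp)
  co <- quiet_cohort(cfg)
  tt <- co$subjects$event_time[co$subjects$event == 1]
  expect_gt(length(tt), 1400)
  ks <- suppressWarnings(stats::ks.test(tt, "pexp", rate = 1 / 25))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(tt), 25, tolerance = 0.1)
})

test_that("flat single-marker trajectory gives the closed-form hazard", {
  # constant hazard h0 * exp(alpha * m) with m constant in time
  mp <- default_marker_params()
  mp$Hb <- trajectory_params("Hb", 0, 0, 0, 0, 1, 0, 0, 0, 0.3)
  al <- default_alpha(); al["Hb"] <- -0.1
  ga0 <- setNames(numeric(9), surv_covariate_names())
  bp <- default_baseline_params()
  bp$Hb <- list(dist = "normal", mean = 13, sd = 0)   # all subjects equal
  sp <- survival_params(shape = 1, scale = 20, gamma = ga0, alpha = al,
                        othercause_hazard = 0)
  cfg <- sim_config(n_subjects = 1200, seed = 13, censoring_rate = 0,
                    followup_max = 5000, marker_params = mp,
                    baseline_params = bp, survival_params = sp)
  co <- quiet_cohort(cfg)
  rate <- (1 / 20) * exp(-0.1 * 13)
  tt <- co$subjects$event_time[co$subjects$event == 1]
  ks <- suppressWarnings(stats::ks.test(tt, "pexp", rate = rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("piecewise-constant cumulative hazard matches segment sums", {
  # two-segment toy: m(t) piecewise via exposure integrals
  knots <- c(0, 4, 10)
  A <- 0.3; B <- 0.05
  E <- cpp_pc_exposures(7, A, B, knots)
  hand1 <- exp(A) * (exp(B * 4) - 1) / B
  hand2 <- exp(A) * (exp(B * 7) - exp(B * 4)) / B
  expect_equal(unname(E[1, ]), c(hand1, hand2), tolerance = 1e-10)
  # zero-slope limit
  E0 <- cpp_pc_exposures(7, A, 0, knots)
  expect_equal(unname(E0[1, ]), exp(A) * c(4, 3), tolerance = 1e-9)
})

test_that("other-cause deaths dominate when their hazard dominates", {
  sp <- survival_params(shape = 1, scale = 400,
                        gamma = setNames(numeric(9),
                                         surv_covariate_names()),
                        othercause_hazard = 0.08)
  cfg <- sim_config(n_subjects = 800, seed = 21, censoring_rate = 0,
                    survival_params = sp)
  co <- quiet_cohort(cfg)
  dead <- co$subjects[co$subjects$event == 1, ]
  # constant-hazard competing risks: P(other | death) = h_o / (h_o + h_c)
  h_c <- 1 / 400
  expected <- 0.08 / (0.08 + h_c)
  expect_equal(mean(dead$cause == "other"), expected, tolerance = 0.03)
})

test_that("raising an association coefficient shortens event times", {
  meds <- vapply(c(0, 0.3), function(a) {
    al <- default_alpha(); al["NLR"] <- a
    cfg <- sim_config(n_subjects = 400, seed = 3,
                      survival_params = survival_params(
                        alpha = al, othercause_hazard = 0, scale = 90))
    co <- quiet_cohort(cfg)
    median(co$subjects$event_time[co$subjects$cause == "prostate-cancer"])
  }, numeric(1))
  expect_lt(meds[2], meds[1])
})

test_that("baseline marker medians track the published marginals", {
  co <- test_full_cohort()
  s <- co$subjects
  expect_equal(median(s$baseline_Hb), 13.25, tolerance = 0.1)
  expect_equal(median(s$baseline_NLR), 2.2, tolerance = 0.1)
  expect_equal(median(s$baseline_PLR), 138, tolerance = 0.1)
  expect_equal(median(s$baseline_LMR), 4.75, tolerance = 0.1)
})

test_that("cohort tables round-trip through the delimited-text writer", {
  co <- test_cohort(n = 40, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co$raw, dir)
  subs <- read.csv(file.path(dir, "subjects.csv"))
  expect_equal(nrow(subs), 40)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 9)
  expect_equal(truth$survival$shape, co$truth$survival_params$shape)
})
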