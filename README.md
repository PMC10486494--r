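# serojm

Joint longitudinal–survival modelling of serological marker
trajectories for dynamic prognostication in metastatic
hormone-sensitive prostate cancer (mHSPC).

## The problem

In men starting systemic therapy for de novo mHSPC, simple laboratory
markers — hemoglobin (Hb), neutrophil-to-lymphocyte ratio (NLR),
platelet-to-lymphocyte ratio (PLR), lymphocyte-to-monocyte ratio
(LMR), and PSA — are measured at every clinic visit (monthly in year
one, bimonthly thereafter). Their *trajectories* reflect
treatment-induced changes in the disease process, and a model that
uses them can re-prognosticate a patient continuously rather than once
at baseline. `serojm` is for biostatisticians and outcomes researchers
who want to fit, evaluate, and stress-test such dynamic models without
access to restricted trial data.

## The model

Each marker follows a linear mixed model (PSA on the log(x+1) scale)

y_ik(t) = β₀ + β_t·t + β_arm·arm + β_arm:t·arm·t + β_b·baseline
          + u_ik + v_ik·t + ε,

and the hazard of death at time t is linked to the markers' *current
model-implied values* m_ik(t) (a "current-value association"):

h_i(t) = h₀(t) · exp( γ′wᵢ + Σ_k α_k · m_ik(t)/s_k ),

with nine baseline covariates w (ECOG, skeletal lesions ≥10, liver
metastasis, nodal stage, Gleason 9–10, baseline Hb, log baseline PSA,
worst pain score, treatment arm) and reporting scales s_k so that
exp(α_k) is a hazard ratio per 1 g/dL Hb, 1 NLR point, 100 PLR points,
5 LMR points, or 1 log-unit of PSA. Backends: full marginal likelihood
with adaptive Gauss–Hermite quadrature (univariate), a fast two-stage
approximation, and a Metropolis-within-Gibbs sampler with horseshoe
shrinkage on the association coefficients (multivariate). Dynamic
predictions condition a subject's random effects on their marker
history up to a landmark (12/24 months) and on survival to it, and are
scored by cross-validated IPCW Brier scores, calibration indices
(ICI/E50/E90), and decision-curve net benefit.

Because the motivating trial data are access-restricted, the package
includes a first-class synthetic cohort generator
(`simulate_cohort()`) that emulates the trial's structure — 1138
subjects split 563/575 across arms, published baseline marginals, the
monthly-then-bimonthly visit grid, and event times driven by the
current-value hazard — so every claim is testable by parameter
recovery.

## Worked example

```r
library(serojm)

# a 600-subject cohort whose Hb trajectories carry a protective
# association (HR 0.77 per g/dL) with overall survival
al <- default_alpha(); al["Hb"] <- log(0.77)
cfg <- sim_config(n_subjects = 600, seed = 11,
                  survival_params = survival_params(alpha = al,
                                                    othercause_hazard = 0))
co  <- simulate_cohort(cfg)
flt <- apply_inclusion_filter(co$subjects, co$series)  # baseline + >=2 visits
dat <- list(subjects = flt$subjects, series = flt$series)

fit <- fit_univariate_joint(dat, "Hb",
                            joint_model_spec(backend = "full_likelihood"))
hazard_ratio_table(fit)
```

On this seed the fitted association row prints

```
   parameter      scale hazard_ratio  lower_ci  upper_ci    p_value
  current_Hb per 1 g/dL      0.7494    0.6772    0.8293    2.4e-08
```

i.e. each 1 g/dL increase in the current (model-implied) Hb level
multiplies the death hazard by about 0.75 — recovering the generating
value 0.77 within its confidence interval, and flagged significant at
the analysis threshold p < 0.004. `conditional_survival()` then turns
the fit into per-patient survival curves beyond a landmark, and
`cross_validate()` / `net_benefit_curve()` quantify discrimination,
calibration, and clinical utility. `run_pipeline(pipeline_config())`
executes the whole sequence (simulate → filter → univariate and
multivariate fits → cross-validated evaluation at landmarks 12 and 24
→ decision curves) and writes all tables plus a reproducibility
manifest.

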