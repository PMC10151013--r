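# kneebis

Free-living knee bioimpedance cleaning and momentary pain modelling.

`kneebis` is for researchers analysing wearable **bioimpedance spectroscopy**
(BIS) data from the knee — resistance *R* and reactance *X* at several
stimulus frequencies, from longitudinal and transverse tetrapolar electrode
placements — collected alongside **experience-sampling (ESM)** phone-call
self-reports of momentary osteoarthritis (OA) pain. It turns raw device logs
into an answer to the question: *does this person's knee-tissue impedance
predict whether they are in pain right now?*

The pipeline:

1. **Synthetic cohorts** (`simulate_study()`): full studies — participants,
   randomised ESM schedules, 2.5-minute multi-frequency logs with labelled
   artifacts, and pain reports from a known generative model — so everything
   downstream is testable without any data download.
2. **Ingest** (`read_device_log()`, `segment_sessions()`,
   `check_selftest()`): the device-log CSV dialect, battery-discharge wear
   session segmentation, on-board self-test verification.
3. **Artifact QC** (`classify_samples()`, `filter_call_periods()`): an
   ordered decision tree — wear-day alignment, ±10% self-test, phase band
   (−50°, 0°), resistance band (0, 212) Ω, the >25% per-call-period rule, and
   the 3-of-4-periods-per-day rule. All bounds strict; every drop carries one
   reason code.
4. **Feature reduction** (`window_samples()`, `reduce_study()`,
   `spearman_screen()`): call-period windowing, per-length transform
   PLR = R/L and PLX = X/L (Ω/m), per-period mean and CV, Spearman
   redundancy screen (keeping 128 kHz resistance and 40 kHz reactance).
5. **Mixed models** (`glmm_logit()`, `run_model_family()`): from-scratch
   random-intercept logistic regression fitted by maximum likelihood with
   **adaptive Gauss–Hermite quadrature**,

   logit P(y<sub>ij</sub> = 1 | u<sub>j</sub>) = γ₀₀ + γ₀₁ Group<sub>j</sub> + γ₁₀ PLZ<sub>ij</sub> + γ₂₀ CV<sub>ij</sub> + u<sub>j</sub> [+ γ₁₁ PLZ·Group + γ₂₁ CV·Group],  u<sub>j</sub> ~ N(0, σ²ᵤ)

   with Wald inference, odds ratios, and the latent-threshold ICC
   σ²ᵤ / (σ²ᵤ + π²/3) from the null model. The family: null, model 1 (main
   effects), model 2 (+ group interactions), model 3 (OA subset), each over
   {R 128 kHz, X 40 kHz} × {longitudinal, transverse}.
6. **Pain probability** (`probability_curve()`, `timeline()`): conditional
   probability curves P(pain) = logistic(β₀ + β₁·metric) and per-call-period
   probability timelines, from a fit or from directly supplied coefficients.

## Worked example

```r
library(kneebis)

cfg     <- cohort_config(n_participants = 20, n_days = 7, seed = 42)
study   <- simulate_study(cfg)       # raw logs + ESM reports, known truth
reduced <- reduce_study(study)       # QC tree + windowing + mean/CV reduction
nrow(reduced)
#> [1] 1042

fit_null_models(reduced)             # is multilevel modelling warranted?
#>   config       icc within_person_share sigma_u2 n_obs
#> 1   long 0.6638886           0.3361114 6.498161   521
#> 2  trans 0.6638886           0.3361114 6.498161   521

fit <- fit_model(model_spec("model3", "r128", "trans"), reduced)
fit
#> Random-intercept logistic mixed model (adaptive GHQ, 25 nodes)
#>   n_obs = 261, n_groups = 10, logLik = -122.723, sigma_u^2 = 5.845
#>                beta exp(beta)     SE     p
#> (Intercept) -6.1351    0.0022 4.4685 0.170
#> plz          0.0141    1.0142 0.0102 0.168
#> cv          -0.2127    0.8084 0.3183 0.504

head(timeline(curve_from_fit(fit, "plr128"), reduced, "P15"), 4)
#>   participant_id day call    value probability
#> 1            P15   1    1 462.1532       0.593
#> 2            P15   1    2 471.6588       0.625
#> 3            P15   1    3 470.3888       0.621
#> 4            P15   1    4 480.7741       0.655

group_contrast(reduced, "plr128", "trans", subset = "OA_only")
#>   group pain     mean   n
#> 1     1    0 418.6008 158
#> 2     1    1 430.8548 103
```

Reading the output: the null-model ICC of 0.66 says about two-thirds of the
variance in the pain outcome lies *between* participants, justifying the
random intercept (the longitudinal and transverse rows coincide here because
both configurations kept the same call periods, hence the same outcomes).
The model-3 fit estimates the within-OA association between per-length
128 kHz transverse resistance and momentary pain: the odds of pain multiply
by exp(β) = 1.0142 per Ω/m (not significant at this 20-participant scale —
single synthetic studies of this size are noisy by design). The timeline
maps participant P15's day-1 call periods through the fitted logistic curve,
and the group contrast shows kept OA periods averaging ~12 Ω/m higher PLR
during pain than without, the direction the generator's positive interaction
truth implies.

A command-line front end covers the same stages
(`simulate`, `ingest`, `reduce`, `fit`, `predict`); see
`inst/cli/kneebis` and `?kneebis_cli`.

## Documentation

`vignettes/kneebis-methods.Rmd` describes the models, the decision-tree
semantics, every stated-world choice in the synthetic generator, numerical
tolerances, and known limitations.
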