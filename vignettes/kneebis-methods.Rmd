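---
title: "Models and methods in kneebis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in kneebis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneebis)
```

## The problem

Knee osteoarthritis (OA) pain fluctuates over hours and days, but clinical
assessment sees only sparse snapshots. A wearable brace that measures the
knee's tissue bioimpedance — resistance $R$ and reactance $X$ at several
stimulus frequencies, from two tetrapolar electrode placements (longitudinal
along the limb, transverse across the joint) — can sample continuously during
free living, while experience-sampling (ESM) phone calls capture momentary
pain self-reports a few times a day. `kneebis` implements the full analysis
chain that connects the two: cleaning free-living impedance logs, reducing
them to per-call-period metrics, and modelling the momentary probability of
pain.

## Artifact cleaning: an ordered decision tree

Free-living impedance data contain electrode disconnects, deep phase
excursions, and spikes that do not represent tissue. Cleaning is an ordered
sequence of binary checks; a "no" at any step classifies the affected scope
as artifact:

1. **Day alignment** — the number of distinguishable battery-discharge wear
   sessions must equal the participant's reported wear days. Sessions are
   split on silence gaps > 120 min or battery jumps > +0.2 V (both
   configurable); the underlying notion of "distinguishable" is not defined
   numerically anywhere authoritative, so these are package choices.
2. **Self-test** — each session's on-board impedance self-test must be within
   ±10% of nominal at every tested frequency (boundary inclusive).
3. **Phase band** — $-50^\circ < \Theta < 0^\circ$, with
   $\Theta = \mathrm{atan2}(X, R)$ in degrees.
4. **Resistance band** — $0\,\Omega < R < 212\,\Omega$.
5. **Period rule** — a call period must have strictly more than 25%
   artifact-free data.
6. **Day rule** — at least 3 of a day's 4 call periods must pass the period
   rule, or the whole day is dropped.

All four range bounds are strict, so boundary values (e.g. exactly
212 $\Omega$) are artifacts. Checks short-circuit: a sample dropped for
misalignment is never re-labelled for phase. The 25% fraction is computed per
electrode configuration independently, because the two configurations are
analysed as independent datasets downstream; a transverse disconnect should
not discard longitudinal data. Days with fewer than 4 answered calls apply
the day rule as `min(3, answered)` qualifying periods — an answered period
with no assigned samples still counts as answered, and when a day fails, the
day-level reason code overrides any period-level one (each drop decision
carries exactly one reason). The 25% denominator counts logged epochs, not
expected epochs for the window duration.

## Windowing and feature reduction

Each answered ESM call owns the window *(previous answered call, this call]*;
the first window of a day is anchored at the day's first logged sample. This
mirrors the ESM question ("pain since the last call") and uses maximal clean
data; samples after a day's last call are unassigned. A sample exactly at a
call timestamp belongs to that call (right-closed).

Within a kept window, impedance is normalised for knee size by the electrode
spacing $L$: $\mathrm{PLR}_i = R_i / L$, $\mathrm{PLX}_i = X_i / L$
($\Omega$/m). Each period is reduced to an arithmetic mean and a coefficient
of variation, $\mathrm{CV} = 100\,s / |\bar{x}|$ with the $n-1$ standard
deviation; the absolute mean keeps reactance CVs positive, and a period needs
at least two clean samples for a CV (otherwise it is excluded from models
that use CV). $L$ is assumed constant within a participant, so reducing
per-length or raw values is equivalent for the mean and, given constant $L$,
also for the CV.

Redundant metrics are screened with Spearman rank correlation across
frequencies; metrics linked by $|\rho| > 0.9$ collapse to one representative,
preferring 128 kHz resistance and 40 kHz reactance — the conventional choice
when the rule is ambiguous about which cluster member to keep.

## The mixed-model family

Momentary pain is binarized (default: rating ≥ 1 at the call; an "any" mode
additionally counts between-call pain) and modelled with random-intercept
logistic regression, observations $i$ nested in participants $j$:

$$\mathrm{logit}\,P(y_{ij}=1 \mid u_j) = \gamma_{00} + \gamma_{01}\,\mathrm{Group}_j
 + \gamma_{10}\,\mathrm{PLZ}_{ij} + \gamma_{20}\,\mathrm{CV}_{ij} + u_j
 \;[+\; \gamma_{11}\,\mathrm{PLZ}_{ij}\mathrm{Group}_j
 + \gamma_{21}\,\mathrm{CV}_{ij}\mathrm{Group}_j],$$

with $u_j \sim N(0, \sigma_u^2)$. The family comprises a null
(intercept-only) model, model 1 (main effects), model 2 (plus
group-by-metric interactions), and model 3 (model 2 on the OA subset, which
removes all Group terms). Each non-null model is fitted four ways —
{resistance 128 kHz, reactance 40 kHz} × {longitudinal, transverse} — for 12
fits in the battery. Predictors enter uncentred and unscaled, so coefficients
are per raw $\Omega$/m and per CV percent. No multiplicity correction is
applied across the battery; the tabulated output records the number of Wald
tests performed.

### Estimation

The marginal likelihood integrates $u_j$ out per participant. Each integral
is approximated by **adaptive Gauss–Hermite quadrature** (default 25 nodes):
Newton iteration finds the posterior mode of $u_j$, the quadrature rule is
recentred and rescaled by the mode and curvature, and the log-sum-exp of the
node contributions gives the group's log-likelihood. At $\sigma_u = 0$ the
code returns the ordinary logistic log-likelihood exactly rather than a
degenerate quadrature. Gauss–Hermite nodes come from the Golub–Welsch
eigen-decomposition of the Hermite Jacobi matrix, verified against closed
forms in the tests.

Optimisation is BFGS over $(\gamma, \log\sigma_u)$ with
internally-standardised predictor columns (mapped back exactly afterwards;
the raw metric scale of ~400 $\Omega$/m would otherwise produce a badly
conditioned optimisation). The gradient is analytic via the Fisher identity
— the posterior-weighted score, evaluated on the same adaptive quadrature
grid as the likelihood; it agrees with central finite differences to
$10^{-9}$ relative in the tests' spot checks. Starting values are the
ordinary logistic fit with $\sigma_u = 1$. Wald standard errors come from
the inverse observed information (central-difference Hessian) at the
optimum; $|\beta| > 15$ raises a quasi-separation flag without suppressing
the fit. The test suite
cross-checks coefficients, $\sigma_u^2$, and log-likelihood against
`lme4::glmer(nAGQ = 25)` (test-only oracle) and the marginal log-likelihood
against a dense-grid trapezoid oracle at $10^{-6}$ relative tolerance.

### ICC

For a binary outcome the null model's intraclass correlation uses the
latent-threshold convention, treating the level-1 residual as standard
logistic with variance $\pi^2/3$:
$\mathrm{ICC} = \sigma_u^2 / (\sigma_u^2 + \pi^2/3)$. The complementary
share $1 - \mathrm{ICC}$ is reported as the within-person variance
proportion. This convention is the one consistent with reporting ICC and
"% variance within individuals" that sum to 1.

## Probability curves and timelines

An OA-subset model (or directly supplied coefficients $\beta_0, \beta_1$)
defines $P(\text{pain}) = \mathrm{logistic}(\beta_0 + \beta_1 z)$ over a
per-length metric $z$. Evaluation outside the fitted operating range warns
but does not error, since extrapolated probabilities remain well-defined —
just unsupported by data. Timelines evaluate the curve at each kept call
period's mean metric, ordered by (day, call), with probabilities reported to
3 decimals; percent formatting belongs to the reporting layer. A published
coefficient pair for the reactance curve prints its second value ambiguously
(the intercept symbol appears twice); it is read here as the slope,
$\beta_1 = -0.023$, the only reading consistent with the reported direction
of the reactance effect.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: 20
participants (10 OA / 10 control), 7 wear days, 2.5-minute multi-frequency
sampling from both configurations, 4 calls/day randomised in 3-hour blocks
08:00–20:00, and a 94.2% response rate. Ground truth is explicit and saved:
every injected artifact is labelled, and the pain process is exactly the
model-2 likelihood above, so QC discrimination and parameter recovery can be
scored against truth.

Stated-world choices where no authoritative value exists:

- **Baselines**: per-participant lognormal per-length 128 kHz resistance
  around 430 (transverse) / 450 (longitudinal) $\Omega$/m (sdlog 0.14), so
  transverse values fall in the published operating range of roughly 370–500
  $\Omega$/m; reactance baselines normal around −25 / −27 $\Omega$/m.
- **Drift**: stationary AR(1) with per-sample correlation 0.99 and SD
  1.5 $\Omega$ — the simplest stationary model of slow postural drift.
- **Artifacts**: disconnect bursts (geometric length, mean 5 epochs;
  $R \in [300, 2000]\,\Omega$ with positive reactance), isolated spikes
  ($R \in [215, 400]\,\Omega$), and phase excursions (−85° to −55°). All
  three violate the acceptance bands by construction, which is what makes
  the perfect-discrimination QC test meaningful — and is also its limit:
  a green QC test says the tree implements its thresholds exactly, not that
  the thresholds catch every real-world artifact (e.g. in-band motion
  artifacts, which the tree does not target).
- **Battery**: linear 4.2 → 3.5 V per session, ≥ 2 h unpowered overnight
  gaps; self-tests within ±5% for healthy devices.
- **Ratings**: momentary ratings given a pain event are categorical over
  1–4 with weights (0.45, 0.30, 0.15, 0.10), echoing the predominance of
  low ratings in momentary OA pain data; this is a stand-in, not an
  inference about any study. Between-call pain flags have probability 0.08.
- **Geometry**: $L_\text{transverse} = 0.25 \times$ knee circumference,
  $L_\text{longitudinal} = 0.10$ m; circumference from a truncated normal
  (41.2 ± 4.4 cm, range 33–50.8).
- **Truth coefficients** (defaults): $\gamma_{00} = -7$,
  $\gamma_{01} = 0.5$, $\gamma_{10} = 0.007$, $\gamma_{20} = -0.05$,
  $\gamma_{11} = 0.007$, $\gamma_{21} = 0.05$, $\sigma_u = 2.16$ (latent
  ICC ≈ 0.59). Slopes sit at the published order of magnitude; the group
  split keeps control-group pain rare and OA-group pain intermittent.

Two generation paths exist deliberately. `simulate_study()` generates raw
logs and derives each call's true reduced metric from the *clean* generated
samples, so the pain process is coupled to the observable impedance — the
end-to-end path. `simulate_reduced_cohort()` draws reduced metrics
parametrically, which is what makes 50-replicate × 200-participant
parameter-recovery runs affordable; the model-2 interaction power harness is
likewise run at 12 replicates (scaled down from a notional 100) to stay
inside test runtime budgets.

What the generator does **not** emulate: the 64 Hz / 8-measurement averaging
inside one epoch (epochs are drawn directly at the 2.5-min level),
accelerometer/gyroscope channels, in-band motion or postural artifacts, and
electrode aging trends. Green tests therefore establish algorithmic
correctness against the stated world, not robustness to every failure mode
of real hardware.

## Numerical and degenerate-input choices

- Strict inequalities at every QC bound; tie-break at a call timestamp is
  right-closed window membership.
- CV uses $|\bar{x}|$ and $n-1$; fewer than 2 samples → CV missing.
- Quadrature: 25 nodes default. The suite checks that coefficients have
  converged by 51 → 101 nodes (< $10^{-5}$ scaled), that the 25-node fit is
  within $2.5 \times 10^{-4}$ (scaled by $\max(1, |\beta|)$) of the
  converged answer, and that metric-scale coefficients meet an absolute
  $10^{-4}$ bound. The residual 25-node error on the large intercept/group
  coefficients is intrinsic to 25-node adaptive GHQ at strong clustering
  ($\sigma_u \approx 2.4$) — `lme4` shows the same-order deviation — not an
  implementation artifact. After BFGS, a short Newton polish on the analytic
  score pins the optimum well below quadrature error. Posterior-mode Newton
  steps are capped at ±5 to prevent overshoot at extreme linear predictors.
- Degenerate designs (constant non-intercept columns, one-class outcomes)
  are errors naming the offending column; quasi-separation is flagged, not
  fatal. Non-convergence returns `converged = FALSE` rather than an error.
- Device-log round-trip resolution: 1 s timestamps, $10^{-3}\,\Omega$
  impedances.
- All randomness flows through explicit seeds; per-participant sub-seeds are
  small fixed offsets of the study seed, keeping every generated object
  reproducible in isolation.

## Known limitations

- The mixed models support a single random intercept only — no random
  slopes, crossed effects, or Bayesian estimation.
- The Spearman screen's cluster representative rule is a preference order,
  not an optimality criterion.
- Wald inference can be optimistic near separation with few groups; the
  battery output flags, but does not correct for, multiple testing.
- The decision tree cannot detect artifacts that stay inside the acceptance
  bands (e.g. contraction or posture effects); inertial-sensor fusion would
  be required.
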