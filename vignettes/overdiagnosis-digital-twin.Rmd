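---
title: "Overdiagnosis in stool-based screening: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overdiagnosis in stool-based screening: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odtwin)
```

## The estimation problem

Organised stool-test screening programmes observe cancers only through their
*detection modes*: confirmed detections at a first (prevalent) or repeat
screen, interval cancers surfacing clinically between screens, cancers among
invitees who never attend (refusers), and — where diagnostic confirmation of
a positive test is incomplete — cancers surfacing later among unconfirmed
positives. Overdiagnosis, the detection of lesions that would never have
surfaced clinically, is invisible in such data: a non-progressive preclinical
lesion and a progressive one look identical at the moment of detection.

`odtwin` addresses this in two stages. First it learns the hidden disease
process from the detection-mode counts of the *screened* population; then it
applies the learned process to an *unscreened* comparator population as if it
had been screened — the digital twin — and reads overdiagnosis off the excess
of the twin's predicted cancers S(t) over the comparator's observed cancers
U(t), as `(S(t)/U(t) - 1) * 100%`.

## The natural-history model

The core model is a continuous-time Markov chain with states Normal,
preclinical detectable phase (PCDP), Clinical, and other-cause Death, with
constant intensities per person-year:

* `lambda1` — preclinical incidence (Normal to PCDP),
* `lambda2` — progression (PCDP to Clinical); `1/lambda2` is the mean sojourn
  time (MST) of progressive preclinical disease,
* `delta` — other-cause mortality, applied from every alive state
  ([mortality_schedule()], constant or piecewise-constant in time).

The overdiagnosis-embedded variant adds a non-progressive PCDP state: screen-
detectable, never surfacing, leaving only through Death. Its share of
preclinical onsets (`nonprog_fraction`) is a *generative* quantity: the
simulator uses it, but the likelihood never estimates it, because aggregate
detection-mode counts cannot identify it separately — the digital-twin
comparison infers the excess instead. That asymmetry is deliberate and is
exactly what the synthetic-twin validation exercises. The adenoma-extended
variants prepend Normal to Adenoma to PCDP (`lambda1a`, `lambda1b`) and give
screens a second detection channel with its own sensitivity.

Transition probabilities are closed-form sums of exponentials for the
non-adenoma chains and matrix exponentials otherwise; piecewise-constant
mortality is handled exactly by multiplying the homogeneous pieces.
Time-homogeneous intensities (no age dependence outside `delta`) keep the
model at the granularity the aggregate data can support.

### Numerical choices

The two-exponential form of the Normal-to-PCDP entry,
`lambda1 (e^{-at} - e^{-bt})/(b - a)`, loses precision by cancellation as the
rates approach each other. The implementation uses the algebraically
equivalent cancellation-free form `lambda1 e^{-at} t phi((b-a)t)` with
`phi(x) = (1 - e^{-x})/x` evaluated via `expm1`, which needs no branch at
all; the Normal-to-Clinical entry switches to a second-order expansion around
the equal-rate limit when the relative rate separation falls below `1e-4`.
Both regimes agree with a matrix-exponential oracle to better than `1e-10`
across the tested grid, and exactly equal rates are legal input. Death-column
entries are computed as exact zeros when `delta = 0` rather than as `1 -`
(row sum), so that the no-mortality invariant holds to the bit.

## From chain to detection modes

[mode_probabilities()] propagates a subject through the programme. The
conventions, each of which a user can override through
[screening_design()]:

* **Entry conditioning.** The disease process starts `lead_time` years
  (default 30; 20 in the FIT-programme preset) before the first screen, and
  the cohort is conditioned on being alive and not clinically diagnosed at
  entry. For a constant hazard the alive-conditioning cancels exactly, so the
  pre-entry segment is computed with the disease chain alone; for an
  age-varying hazard this is an approximation confined to the lead-in. Beyond
  about 25 years of lead-in the preclinical prevalence sits at its
  quasi-stationary value `lambda1/lambda2`, so the default is insensitive.
* **All-or-none attendance.** An invitee is a lifelong participant
  (probability `participation`) or a lifelong refuser, matching the clean
  participant/refuser strata of published trial tables, which carry no
  partial-attendance modes.
* **Confirmation.** A positive test is confirmed with probability
  `confirmation`; an unconfirmed positive leaves the programme and its later
  clinical cancer is recorded in the positive-unconfirmed modes. Trials
  without such rows use `confirmation = 1`.
* **Interval windows.** Interval cancers are ascertained between consecutive
  screens and, after the final screen, for one further inter-screen gap
  (`interval_cap = "next_screen"`). Clinical cases beyond that window are not
  in the detection-mode table; the digital twin carries them as an explicit
  *post-programme clinical* component up to the follow-up horizon. This
  convention, rather than extending the final window to the horizon, is what
  reconciles the published trial tables (whose participant cancer totals are
  visibly window-capped) with the published twin predictions (which exceed
  the table totals by just that component); `interval_cap = "followup"` is
  available.

The likelihood ([log_likelihood()]) is multinomial over the exhaustive
subject-fate partition within each stratum — the per-subject exact-time
likelihood is unavailable from aggregate counts — with the negative-test
"Normal" cells treated as bookkeeping complements (they are test counts, not
subject fates, and can exceed the cohort size). Fates with positive counts on
zero probability yield `-Inf` with a warning so optimisers can back away.

## Estimation

[od_fit()] optimises on log-rates and logit-sensitivities (Nelder-Mead,
restarted once from its own optimum), then optionally samples by random-walk
Metropolis. Priors are inverse-gamma(0.001, 0.001) on each intensity — placed
on the rates themselves, the natural reading of "priors for the transition
parameters" — and uniform(0, 1) (beta(1, 1), configurable) on each
sensitivity, for which no prior is documented. A single global step-size
multiplier adapts towards 25% acceptance during burn-in only, preserving
detailed balance afterwards; chains are bit-reproducible under the
configuration seed. Credible intervals are equal-tailed type-7
(linear-interpolation) quantiles throughout. Default chain settings
(2 chains of 20,000 with 5,000 burn-in) are this package's choice; the
analyses in the test-suite use shorter, empirically adequate chains.

Identifiability caveats:

* the adenoma-variant parameters cannot be learned from cancer-only
  detection-mode tables (there are no adenoma modes); `od_fit()` refuses, and
  adenoma analyses take their rates as inputs;
* `lambda2` and the sensitivity are *jointly* weakly identified — a
  high-sensitivity/short-sojourn ridge fits screen-detection data nearly as
  well as a moderate pair. At trial scale this shows up as very wide
  intervals, and the fitted point can sit on the ridge. The preclinical
  incidence `lambda1`, anchored by refuser and interval cancers, is robust.

## The digital twin

[predict_screened_twin()] computes S(t) as cohort-size-weighted sums of the
detection-mode expectations over rounds — screen-detected, interval,
unconfirmed, post-programme clinical, refuser — the package's re-derivation
of the twin imputation; it is validated against the individual-level
simulator (agreement within Monte-Carlo error across scenarios) and against
the published trial predictions (within 3% at the published parameters).
Components always sum to S(t).

In the adenoma variants a removed adenoma contributes a *polypectomy offset*:
the probability that it would have become a preclinical cancer during
follow-up while its host was alive. Counting would-be preclinical (not merely
would-be clinical) cancers is what makes adenoma removal inflate rather than
deflate the overdiagnosis estimate — removal of a lesion that would never
have surfaced is precisely overdiagnosis — and gives the sweep over adenoma
sensitivity ([adenoma_sensitivity_sweep()]) its rising, few-percentage-point
shape.

The competing-risk adjustment ([competing_risk_adjustment()]) deflates the
comparator by `kappa = lambda2/(lambda2 + delta)`, the chance of surviving
other-cause death over one preclinical sojourn: the unscreened world
undercounts lesions whose hosts die before surfacing, which a screened twin
would have detected. It is the identity at `delta = 0`, always raises the
percentage for `delta > 0`, and is monotone in `delta`. The exact published
adjustment is not derivable from the available material; this construction is
the package's own and adjusted results are always flagged.

When no concurrent comparator exists, [project_control_incidence()] imputes
U(t) from a pre-screening baseline at a default growth of 4.5% per year, and
[implied_control_incidence()] reports the control preclinical incidence
implied by U(t) as a diagnostic.

## The simulator and what passing tests do (and do not) show

[simulate_cohort()] draws exponential waiting times per intensity, a
Bernoulli non-progressive label per onset, competing death from the mortality
schedule, all-or-none participation, and independent per-screen detection; a
detected subject exits (treatment interrupts progression; detected adenomas
are removed). It emits the detection-mode table plus ground-truth labels: a
subject is *overdiagnosed* iff screen-detected and (non-progressive, or dead
of other causes before the latent clinical date). [simulate_control()]
replays identical latent histories without screening, so a cohort and its
control are a genuinely matched twin pair under one seed.

The generator emulates the statistical structure the analysis assumes —
exponential sojourns, homogeneous intensities, independent screens,
all-or-none attendance. It does not emulate age structure beyond the
mortality schedule, attendance attrition, test-positivity in disease-free
subjects, or secular incidence trends; passing the synthetic-twin validation
therefore demonstrates internal consistency of the pipeline, not robustness
to those real-data features.

**Study conditions of the shipped experiments** (chosen once, stated here as
the package's own design):

* *FIT-programme preset* (`rct_design("taiwan")`): biennial screens at years
  0–8, horizon 11 years, participation 0.70, confirmation 1, `delta = 0.01`
  per person-year (a typical all-cause order of magnitude at screening ages;
  not an estimate from any registry), 20 years of pre-entry disease accrual;
  generating rates `lambda1 = 0.00141`, `lambda2 = 0.386`, sensitivity 0.80,
  non-progressive fraction 0.05.
* *Synthetic-twin validation*: one million subjects under that preset.
* *Parameter recovery*: five replicates of two million subjects under an
  annual five-round design (screens 0–4 years, horizon 7), chosen because
  annual re-screening of missed lesions separates sensitivity from the
  sojourn time far better than a biennial design — recovery is assessed as
  bias across replicates, under 5% for each parameter; interval calibration
  uses twenty replicates of 200,000 subjects.

## Known limitations

* The S(t)/U(t) estimand counts screen-detected cancers whose latent clinical
  date lies beyond the follow-up horizon as excess. In the synthetic-twin
  experiment this lead-time contamination is about 3 percentage points at an
  11-year horizon with screening to year 8 — the pipeline tracks the *true
  excess* to about 1 point, but sits above the *labelled true overdiagnosis*
  by more than the 2-point validation bound. Longer post-screening washout
  shrinks the gap; any incidence-based estimator at finite follow-up shares
  it.
* The published trials do not print their round structure, per-round
  attendance, or confirmation rates. The shipped designs reconstruct them
  from the printed repeat-test totals (screens at 0/2/4 years for the UK
  trial, 0/2/4/6 for Funen; horizons 8.5 and 10 years; confirmation 0.85 and
  1). Under these assumptions the refitted preclinical incidence matches the
  published scale, but the progression/sensitivity pair lands on the
  high-sensitivity ridge rather than on the published values, whose exact
  likelihood structure is not reproducible.
* Single-lesion model: after a polypectomy the subject leaves the cancer
  pathway; second primaries and surveillance are out of scope, as are
  stage-shift, quantitative hemoglobin cut-offs, and mortality benefit.

## A worked miniature

```{r example, eval = FALSE}
counts <- make_rct_fixture("funen")
design <- rct_design("funen")
fit <- od_fit(counts, design, mort = mortality_schedule(0.01),
              method = "mcmc",
              control = od_mcmc_control(n_iter = 3000, n_burnin = 1000,
                                        n_chains = 2, seed = 1))
summary(fit)
gof(fit)
tw <- predict(fit, cohort_size = 30966, followup = 10)
overdiagnosis(tw, U_t = 483, draws = fit$draws)
```
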