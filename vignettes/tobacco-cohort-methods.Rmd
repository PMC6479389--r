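---
title: "Methods: a multi-state cohort model of tobacco-use transitions and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-state cohort model of tobacco-use transitions and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstcohort)
```

## The model

`mstcohort` follows a closed cohort of never-users of tobacco as it ages in
5-year steps, moving between use states according to age-specific transition
probabilities and dying according to state-specific hazards. It is an
expected-value (deterministic mass-flow) Markov model, not an agent
simulation: at the cohort sizes of interest (10^5–10^6 persons) demographic
sampling noise is negligible next to parameter uncertainty, so all reported
uncertainty comes from parameter draws.

### State space

A category-level diagram (never user, current cigarette smoker, current
moist-smokeless-tobacco user, dual user, and former-use categories) is too
coarse for mortality, which depends on *how long* someone smoked and how
long ago they quit. Each simulated state is therefore a use category plus
four duration counters in 5-year bins: years smoked (YSM), years since
quitting smoking (YQSM), years of MST use, and years since quitting MST.
The fourth counter is not part of the classic three-covariate mortality
design; it exists because the former-MST hazard multiplier needs a
time-since-quitting covariate of its own — on mixed pathways (smoke, switch,
quit) reusing YQSM would conflate quitting cigarettes with quitting MST.

Durations accrue by the category occupied during an interval: smoking
categories (current cigarette, dual) accrue YSM; MST categories (current
MST, dual) accrue MST years — dual users accrue both; anyone with a smoking
history who is not currently smoking accrues YQSM, and symmetrically for
MST. Transitions are listed in an editable edge catalogue
(`default_edge_catalogue()`); staying is the residual probability, so no
self-loops appear. Published category-level enumerations (one common
formulation uses 29 states) can be reproduced by editing the catalogue; the
duration expansion is generated, not hard-coded. Counters are capped at
`max_bins` (default 12 bins = 60 years): beyond the cap the hazard
saturates, which both bounds the state space and keeps covariates inside
the range any plausible mortality dataset can inform.

### Mortality

Three Poisson regressions with log link and `log(person-years/100,000)`
offset give rates per 100,000 person-years:

* never-users: intercept, AGE, AGE²;
* current smokers: plus YSM and YSM×AGE;
* former smokers: plus YSM, YQSM, YSM×AGE and YQSM×AGE.

AGE is the band midpoint in years (bands are half-open `[a, a+5)`). Fitting
is maximum likelihood via `stats::glm`; the uncertainty layer draws
coefficients from the asymptotic normal approximation to the posterior
under a flat prior, which at person-year exposures typical of large cohort
tables is indistinguishable from MCMC output and removes the need for a
sampler dependency.

A pathway's hazard composes multiplicatively on the relative-risk scale:
the never-user rate, times a smoking-history multiplier (the current-smoker
relative risk while smoking, the former-smoker relative risk afterwards),
times an MST multiplier. MST risk is tied to cigarette risk by the excess
relative risk ratio `ERR = (RR_MST − 1)/(RR_cig − 1)`: the current-MST
multiplier is `1 + ERR_cur × (RR_cur − 1)` and the former-MST multiplier is
`1 + ERR_for × (RR_for − 1)`. Defaults are `ERR_cur = 0.09` and
`ERR_for = 0.04` (dimensionless; 0 = never-user risk, 1 =
cigarette-equivalent). Dual use carries cigarette-level risk unmodified.
This excess-risk formulation was chosen over a plain product of relative
risks because it reproduces the boundary identities exactly: at `ERR = 0`
an MST user survives like a never-user, at `ERR = 1` like a smoker of equal
duration — both are asserted in the test suite. Since no MST-specific
duration model exists, MST years stand in on the YSM axis when evaluating
the cigarette relative risk being scaled; this is an assumption, logged
here, and the saturating cap bounds its reach.

### Stepping order and survival

Within a step the cohort first transitions, durations accrue by the source
category, and the *destination* state's hazard applies over the interval
(`hazard_timing = "destination"`, switchable to `"source"`; nothing in the
underlying formulation pins this down, and the choice moves results by less
than one step's mortality). Rates convert to probabilities with the
constant-within-interval exponential `exp(−5·h/100,000)` rather than the
linear `1 − 5·h/100,000`: the two agree to first order but only the
exponential is guaranteed to stay in `[0, 1]` at the oldest ages. Mass is
conserved identically — survivors plus cumulative deaths equal the initial
size to 1e-9 relative at every step, and the engine is verified against
exhaustive pathway enumeration on small catalogues to the same tolerance.

## Scenarios and uncertainty

The Modified Case derives from the Base Case by applying edge-wise relative
changes and two rerouted diversions. Relative changes come from pre/post
behavioural-intention proportions in a test (claim-exposed) and control
condition: `((test_post/test_pre) − (ctrl_post/ctrl_pre)) /
(ctrl_post/ctrl_pre)`. The bundled preset carries the four published rows
(−5% never-user MST initiation, +21% switching, +24% dual uptake, +6% dual
to exclusive MST, as whole percents). Internally the unrounded values
propagate; `use_rounded = TRUE` reproduces whole-percent arithmetic (1.4% ×
1.21 = 1.694%, printed as 1.7%) exactly.

The diversions are hypothetical flows that a pre-market intention study
cannot measure: *would-be smokers* (default 1% of the never-to-cigarette
initiation flow rerouted to MST initiation) and *would-be quitters*
(default 5% of the cessation flow rerouted to switching). They reroute,
never create, flow, so with diversions alone every source category's
outgoing mass is conserved. The would-be-quitter flow adds to the ordinary
switching edge (additive, not overlapping) — users scanning one edge at a
time should know the modified switching rate is the scaled base rate *plus*
the diverted cessation share.

Rate uncertainty is a truncated normal on `[0, 1]` centred on each
initiation and cessation rate with SD 0.02 (probability points), sampled by
inverse CDF; rows whose drawn outgoing rates exceed 1 are redrawn (with
supplied quantiles the redraw sequence is a deterministic function of the
originals, preserving sharing). Scenario comparisons use common random
numbers: one quantile per (age, edge) and one coefficient draw feed both
scenarios, so comparing a scenario against itself yields exactly zero at
every age and credible intervals reflect the scenario contrast, not shared
noise. Intervals are equal-tailed 2.5/97.5 percentiles across draws. The
conventional full analysis uses 10,000 draws (the default); the test suite
runs 10–100 draws on shortened horizons purely for runtime, which widens
nothing because the zero-difference and coherence properties being tested
are draw-count-invariant.

## Populations, life tables, sensitivity

Time-staggered birth cohorts each enter at age band 0–4 in their birth
quinquennium and are propagated independently with their vintage's table
(vintage-specific tables before 1980, a constant table after, following the
availability of historical initiation/cessation series; all bundled
presets use a single constant vintage). Calendar alignment: a cohort born
in `[y, y+5)` occupies age band `[a, a+5)` during years `[y+a, y+a+5)`.
When a scenario begins mid-history (`switch_year`), each cohort switches
tables at the age it reaches that year, so earlier years are identical by
construction. Ages beyond the oldest modelled cohort report zero.

Life tables are abridged: `L_x = 5·(a·l_x + (1−a)·l_{x+5})` with
`ax_fraction = 0.5` by default (deaths uniform within the band; the
convention is exposed because published tables differ and totals move by
less than one band width). The final band is open-ended and closed with
constant-hazard person-years `l/h`, with `h` supplied, derived from a
supplied expectation, or estimated from the last closed band —
`life_table_from_run()` uses the never-user hazard at the final age. `T_x`
differences between scenarios are identical whether taken on the `T`
columns or by backward-cumulating `L` differences; both routes are tested.

The sensitivity grid pins one or two edges of the Modified-Case table to
absolute rates (the published convention scans switching over 0.84–1.96%
and MST initiation over 0.96–3.2%) while holding everything else at the
Modified Case, one deterministic comparison per point. The net-neutral
region is exactly the non-positive cells, unsmoothed.

## The synthetic world

No input dataset is redistributable, so `gen_mortality()`,
`gen_transitions()`, `gen_intentions()` and `gen_cohort_sizes()` emulate
the four input shapes with known ground truth under one seed.

* **Mortality truth** (`default_beta_truth()`) is Gompertz-like: never-user
  rates rise log-linearly in age (about 86 per 100,000 person-years at age
  17.5 to about 11,000 at 87.5), long-duration smokers carry a relative
  risk around 2–2.7 that fades slightly with age, and quitting confers a
  benefit that decays with age. Exposures default to 500,000 person-years
  per never-user cell (half/quarter for current/former), giving fits whose
  3-standard-error recovery of the truth is itself an acceptance property.
* **Transitions** anchor the rates a scenario analysis would cite
  (switching 1.4%, MST initiation 1.6%, dual-to-MST 17.4% per 5-year step)
  and fill the rest with realistic values: cigarette initiation
  concentrated at ages 10–30 peaking at 10%, cessation rising from 8% to
  22% with age, relapse zero. Rates are constant over calendar time.
* **Intentions** carry the four published pre/post rows verbatim as data.
* **Cohort sizes** ramp from about 4.9 to 11.5 million per quinquennium
  with a mid-century boom.

What the generator does *not* emulate: cohort effects in smoking uptake,
calendar trends in cessation, cause-specific mortality, dose (cigarettes
per day), migration, or female cohorts. A green test therefore establishes
that the machinery is correct — conservation, oracle equivalence, ERR
identities, recovery, ordering — not that any particular published headline
number is reproduced; headline magnitudes here are of the published order
but belong to this synthetic world.

## Numerical and degenerate-input choices

* Rates outside `[0, 1]` after scaling are clipped with a warning; deltas
  below −1 are rejected.
* Zero-death mortality datasets, singular designs and non-converged fits
  are rejected with diagnostics rather than returned.
* Survivor series must be non-increasing to enter a life table; a flat tail
  with no closure information is an error, not a guess.
* All randomness flows through explicit seeds or supplied quantiles; run
  manifests record seed, versions and input checksums.

## Known limitations

Five-year resolution hides within-interval transitions (someone who starts
and quits inside one band never appears). The fitted former-smoker model at
`YQSM = 0` is not constrained to equal the current-smoker model, so freshly
switched pathways can differ from continuing smokers by fitting noise
(observed at the 1e-8 relative scale); sign-sensitive invariants are
therefore stated against the exact-truth models. The would-be-quitter
diversion is, in isolation, a small harm under zero relapse — diverted
quitters keep 9% of the smoking excess instead of quitting cleanly — which
is visible in the attribution output and is the expected behaviour of the
ERR formulation, not a defect.
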