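---
title: "Multi-surveyor removal and CMR for sessile organisms: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-surveyor removal and CMR for sessile organisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r}
library(sessilecmr)
```

## The estimation problem

Closed-population abundance estimation normally requires that marked
and unmarked animals re-mix between capture occasions. Sessile targets
— here, butterfly larvae overwintering in leaf shelters
("hibernacula") fixed to host plants — cannot mix. The design this
package supports replaces animal movement with surveyor movement: a
sequence of independent surveyors, each unaware of the others' finds,
searches the same plot once. Each surveyor is one occasion; an
individual's detection history is the 0/1 vector across surveyors. Two
search patterns of two people are (approximately) independent random
samples of the plot, which restores the exchangeability that moving
animals normally provide.

Three estimators coexist deliberately, from weakest assumptions to
strongest:

1. the **minimum larva number** (MLN), a direct count of distinct
   individuals found — always valid, always an underestimate under
   imperfect detection;
2. the **permutation removal estimator**, regression-based, needing
   only a roughly constant per-occasion detection rate;
3. the **Huggins conditional-likelihood CMR**, fully parametric,
   supporting per-surveyor and per-experience detection structure, and
   delivering the tightest intervals.

Agreement among the three on the same data is itself a diagnostic: the
model-based estimates should only slightly exceed the MLN when
cumulative detection is near-complete.

### Assumptions

* **Demographic and geographic closure.** No entries or exits during
  the survey window. Shelters that disappeared mid-study violate this;
  `filter_closure()` removes individuals flagged `lost` before any
  estimation (they stay in the data files so mortality summaries can
  still see them — removal happens at analysis time).
* **Equal detectability among individuals** within an occasion. This
  is the assumption the package can *test* (see the frequency-band
  check below) rather than take on faith.
* **Independence across occasions**, guaranteed by the field protocol
  (surveyors search one after another, markings removed in between).
* **No behavioural response**: a shelter cannot learn to avoid being
  found, so capture and recapture probabilities are fixed equal
  (`p = c`) throughout — there is no trap-shyness mechanism to model.

## The removal estimator

Order the occasions; let `x_t` be the number of distinct individuals
detected before occasion `t` and `y_t` the number newly detected at
`t`. With constant detection probability `p` and true size `N`,
`E[y_t | x_t] = p (N − x_t)`, a straight line in `x_t` with x-intercept
`N`. `leslie_fit()` estimates the line by ordinary (unweighted) least
squares — the classical Leslie–Davis form; no weighting is applied
because none is part of that form — and reports the x-intercept when
the slope is strictly negative.

Any surveyor order is as valid as any other, so
`permutation_removal()` resamples the order uniformly (default 10,000
permutations, sampled with replacement from the `T!` orders even when
`T!` is small, keeping the percentile machinery uniform), refits the
regression for each, and summarises the finite x-intercepts by their
median and 2.5/97.5 percentiles (type-7 linear interpolation, the same
convention everywhere in the package).

**Degenerate permutations.** An order can produce a non-negative
slope (e.g. when a high-yield surveyor lands late) or no slope at all
(all `x_t` equal). Such permutations admit no finite abundance and are
excluded from the median and percentiles; their count `n_degenerate`
is always reported so the exclusion is auditable. An estimate below
the MLN is possible (regression undershoot) and is flagged
(`below_mln`), not corrected.

A useful exact special case: with two occasions and symmetric catches
(`n1 = n2 = n`, overlap `m2`), the two-point regression line has
x-intercept `n²/m2`, the Lincoln–Petersen value. With asymmetric
catches the two-point x-intercept is `n1²/(n1 + m2 − n2)`, which is
*not* Lincoln–Petersen — the removal regression and two-occasion CMR
are different estimators, and the tests assert each one's own closed
form.

## The Huggins model

For individual `i` with history `D_it` over the occasions of its plot,
the conditional likelihood contribution is

```
Π_t p_t^{D_it} (1 − p_t)^{1 − D_it}  /  p*_i ,   p*_i = 1 − Π_t (1 − p_t)
```

— conditioning on "detected at least once" removes `N` from the
likelihood, so detection parameters can be estimated first and
abundance recovered afterwards by Horvitz–Thompson:
`N̂_g = Σ_{i ∈ g} 1/p*_i` per plot (group) `g`.

Detection structures (`fit_huggins(ds, model = ...)`):

* `"m0"` — one constant `p`;
* `"mt"` — one `p` per *surveyor*. Surveyors overlap plots, and a
  surveyor's skill travels with them, so the occasion identity is the
  surveyor, shared across every plot they searched — the only
  structure consistent with pooling surveyor-specific estimates across
  plots;
* `"experience"` — `logit p = β0 + β1·expert`, a two-level occasion
  covariate separating expert from novice detection.

All parameters live on the logit scale (estimates stay inside (0,1);
the standard link for Huggins-family software). Because no
individual-level covariates are in scope, the likelihood factorises
over occasions and depends on the data only through each plot's `M`
(individuals observed) and per-occasion totals `n_t`; the
implementation exploits this, and the test suite checks it against a
brute-force enumeration of all `2^T` histories.

**Optimisation.** BFGS with the analytic gradient, started from the
logit of the naive detection rate with fallback starts at
`logit p ∈ {−2, −1, 0}`, followed by Newton polishing so the
convergence criterion (gradient norm < 1e-6 on the link scale) is met
rather than BFGS's looser relative-likelihood stop. Standard errors
come from the inverse of a central-difference observed information.
Estimates with `|logit p| > 10` are flagged as boundary (complete or
zero detection); a boundary fit is reported, not hidden.

**Abundance variance and intervals.** `abundance()` uses the Huggins
two-term variance: the binomial-type term `M (1 − p*)/p*²` plus a
delta-method term `J V Jᵀ` with `J` the numeric Jacobian of `N̂(β)`
(central differences, relative step 1e-5) and `V` the parameter
covariance. The 95% interval is log-normal on `f0 = N̂ − M`:

```
C = exp(1.96 √(ln(1 + var(N̂)/f0²))),   CI = (M + f0/C,  M + f0·C)
```

chosen because its lower bound can never fall below the `M`
individuals actually in hand — the behaviour field intervals should
have. When `f0 ≤ 0` the interval collapses to `(M, M)`.

A second exact identity anchors the implementation: with two occasions
and time-dependent detection, the conditional MLE is `p1 = m2/n2`,
`p2 = m2/n1`, giving `N̂ = n1·n2/m2` — exactly Lincoln–Petersen. The
tests assert this on random matrices. (The constant-`p` two-occasion
fit equals Lincoln–Petersen only for symmetric catches; the symmetric
case is tested for it.)

## Reduced-effort evaluation

`reduced_effort_scan()` refits the model for every k-subset of each
plot's experts, k = 2…6 by default, restricted to the experts who
actually searched that plot. Two-surveyor subsets are fitted as M0 —
two occasions carry almost no information about time dependence —
larger subsets as Mt. Each refit is scored against the *full-effort*
(all surveyors, both experience levels) estimate of the same plot:

* relative error `|N̂_i − N̂_f| / N̂_f` (accuracy),
* relative CI width `(ucl − lcl)/N̂_i` (precision),

and summaries are arithmetic means over reliable refits per k.

**The reliability rule** is explicit because some subsets are
inestimable: a refit is reliable when the optimiser converged *away
from the parameter boundary*, the abundance variance is finite, and
`ucl < 50·N̂`. The boundary clause matters: two surveyors sharing no
recaptures drive `p` to zero, where the gradient vanishes (so a
convergence test alone passes), `N̂` explodes, yet `var/f0² ≈ 1/M`
keeps the *relative* interval deceptively narrow — the boundary flag
is the clean detector of this failure mode. Unreliable refits are
flagged and excluded from means, never dropped silently.

`single_surveyor_scan()` evaluates the cheapest possible scheme — one
expert's count divided by a previously estimated detection probability
(their own, or the expert-group mean) — which lands near the accuracy
of two-surveyor CMR but cannot quantify its own uncertainty from one
survey.

## The equal-detectability check

`detectability_check()` tests the one assumption that is both critical
and checkable. Under equal detectability, conditional on surveyor `j`
having found `n_j` individuals, those `n_j` are a uniform simple
random sample *without replacement* from the `N` individuals (a
surveyor finds `n_j` distinct shelters — hence hypergeometric, not
binomial, sampling). The check simulates complete detection histories
that way (default 10,000 replicates), holding each surveyor's total at
its observed value and taking `N` as the rounded full-effort CMR
estimate, then compares the observed number of individuals detected
`k = 0, 1, …, T` times against the per-k median and 2.5/97.5
percentile envelope. The `k = 0` bin is the assumed-but-unseen
remainder `N − MLN`.

Individual heterogeneity — some shelters intrinsically easier to find
— inflates the tails (more never/rarely-detected *and* more
often-detected individuals than the envelope allows), which is exactly
where the tests look for it. The check is visual/flag-based by design;
no formal goodness-of-fit p-value is attached, because the simulated
bands are the reference a surveyor actually interprets.

## The synthetic-data generator

`simulate_population()` draws `D[i,t] ~ Bernoulli(p_t · h_i)`
independently, with `h_i ≡ 1` unless heterogeneity is enabled.
Individuals never detected are excluded from the observed dataset (as
in the field) but preserved, with their multipliers, in the
`ground_truth` attribute.

The default configuration *is* the emulated study design, fixed once:

* three plots of 916, 807 and 2952 m² with true abundances 32, 18, 28
  (host plants 137/121/118, matching densities of roughly 15, 15 and
  4 bushes per 100 m²);
* six experts and seven novices; seven surveyors search all three
  plots, two search two, four search one, giving 10/9/10 occasions on
  plots A/B/C. Five experts cover every plot and the sixth skips plot
  B, so the expert-subset scan has `C(6,k)` subsets on A and C and
  `C(5,k)` on B — 140 refits over k = 2…6;
* fixed per-surveyor detection probabilities with a best expert at
  0.51 and *occasion-weighted* group means of exactly 0.35 (experts)
  and 0.16 (novices). The weighting matters: a pooled
  experience-covariate fit estimates the occasion-weighted group rate,
  and high-probability surveyors search more plots, so unweighted
  roster means would not be the quantity the model recovers;
* 34/75 of observed shelters empty (end-of-winter mortality), a 39:2
  ratio of focal to congener species among occupied ones, and a 3/78
  chance a shelter disappears mid-study (the closure violation
  `filter_closure()` removes).

Heterogeneity is parametrised as `h_i = 2·Beta(1/s, 1/s)`: mean 1 for
any dispersion `s`, ranging over (0, 2), with `p_t·h_i` clipped to
[0, 1] after multiplication — the simplest one-knob violation
generator for the equal-detectability check. Species, occupancy and
loss labels attach to observed individuals only, as in field data.

Seeding: one root seed, with a deterministic substream per plot, so
editing one plot's configuration leaves the other plots' draws
untouched; the removal and detectability simulations derive their own
substreams the same way.

**What the generator does not emulate** — and therefore what passing
tests do not demonstrate about field data: spatial structure (host
plants, search paths; detections are exchangeable within an occasion
by construction), within-surveyor variation between plots (one `p` per
surveyor everywhere), correlated misses (a hidden shelter missed by
*everyone* for the same physical reason — in the model this is only
expressible through `h_i`), day-to-day condition effects, and
observer-matching errors (the simulator's identities are exact;
re-identifying unmarked shelters in the field is not).

## Numerical and formatting conventions

* Occasion indices are 0-based internally, 1-based in output; CSV
  column order encodes the search order, and a surveyor who did not
  search a plot is an empty cell (structurally absent), never a 0.
* Percentiles: `stats::quantile` type 7 everywhere.
* Detection matrices round-trip losslessly through CSV and through a
  MARK-style `.inp` encounter-history format (`.` marks occasions a
  surveyor did not search; plot membership is one-hot group columns).
* Likelihood evaluations clip `p` to `[1e-12, 1 − 1e-12]`; the
  assumed population size for the detectability check is the rounded
  CMR estimate (integer draws require an integer population).

## Problem sizes in the test suite

The statistical validation runs at sizes chosen to make Monte-Carlo
error small relative to the tolerances asserted: abundance recovery
with 500 replicates of `N = 200` over six occasions at `p = 0.3`
(mean within 2%, interval coverage within [92%, 98%]); removal
recovery with 200 replicates of `N = 30` over ten occasions at
`p = 0.3` (600 permutations per replicate — the median point estimate
is stable well below the 10,000-permutation production default);
detectability calibration over 200 seeds with 400-replicate bands;
heterogeneity power at dispersion 2 and `N = 100`, where the tail
signal is unambiguous; and the effort-monotonicity comparison over 200
simulated six-expert datasets at `N = 30`, `p = 0.35`.

## Known limitations

* Variance and interval conventions (Huggins two-term variance,
  log-normal `f0` interval) follow the MARK defaults; other software
  choices would shift interval endpoints slightly.
* The experience model treats experience as binary; per-surveyor
  variation within a level is real (the Mt fit shows it) and is
  deliberately not propagated into the experience-level intervals.
* The removal estimator's percentile interval reflects permutation
  variability only, not regression residual variance, and can be
  anti-conservative for very few occasions.
* All estimators assume correct individual identification between
  occasions; matching errors in the field bias detection histories in
  ways no closed-population model can absorb.
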