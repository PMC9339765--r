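# sessilecmr

Abundance estimation for **sessile organisms** — organisms (or life
stages) that do not move — from repeated searches by **multiple
independent surveyors**. The motivating system is overwintering
butterfly larvae: each larva spends the winter in a leaf shelter
(*hibernaculum*) fixed to its host plant, so classical
capture–mark–recapture (CMR), which relies on animals re-mixing between
occasions, seems inapplicable. The trick is to swap the randomness: if
every search occasion is carried out by a **different, uninformed
surveyor**, the random search paths of the surveyors substitute for
random movement of the animals, and closed-population removal and CMR
machinery applies unchanged. One occasion = one surveyor's complete
search of a plot.

The package is aimed at population ecologists and conservation
practitioners who design or analyse such multi-surveyor surveys
(butterfly larvae and eggs, and by extension other detectable immobile
targets: plants, fungi, corals).

## What it computes

Given per-plot binary detection matrices `D[i, t]` (individual ×
surveyor-occasion):

* **Minimum larva number (MLN)** — the count of distinct individuals
  ever detected; a model-free lower bound.
* **Permutation removal estimate** — individuals found by earlier
  surveyors count as "removed", so new detections `y_t` decline
  linearly in the number previously detected `x_t`; the x-intercept of
  the Leslie–Davis regression estimates abundance `N`. Because
  surveyors are exchangeable, the surveyor order is reshuffled (10,000
  permutations by default) and the estimate is the median x-intercept
  with a 2.5–97.5 percentile interval.
* **Huggins closed-population CMR** — the conditional likelihood

  `L(β) ∝ Π_i Π_t p_t^{D_it} (1 − p_t)^{1 − D_it} / p*_i`,
  `p*_i = 1 − Π_t (1 − p_t)`,

  conditions on each individual being seen at least once, so abundance
  drops out of the likelihood and detection can carry covariates.
  Capture and recapture probabilities are shared (`p = c`): a shelter
  cannot respond to having been found. Detection structures: constant
  (M0), surveyor-specific (Mt, shared across plots a surveyor
  searched), or experience-structured
  (`logit p = β0 + β1·expert`). Abundance per plot is Horvitz–Thompson
  `N̂ = Σ_i 1/p*_i` with the Huggins two-term variance and a MARK-style
  log-normal interval on `f0 = N̂ − M` whose lower bound never falls
  below the number observed `M`.
* **Reduced-effort evaluation** — refits over *every* k-subset of a
  plot's expert surveyors (k = 2…6), scoring each refit by relative
  error `|N̂_i − N̂_f| / N̂_f` against the full-effort estimate and by
  relative CI width `(ucl − lcl)/N̂_i`, to answer "how many surveyors
  does a monitoring scheme need?"
* **Equal-detectability check** — simulates detection histories in
  which each surveyor's observed total is a uniform random sample from
  the assumed population, and compares observed per-individual
  detection-count frequencies against the simulated 95% envelopes.
* **Ecological summaries** — larvae per 100 m² / per 100 host plants,
  empty-shelter (overwinter mortality) fractions, and adult recruitment
  from larval abundance × survival.

A seeded synthetic-data generator (`simulate_population()`) emulates
the full study design — three plots, six experts and seven novices
with fixed detection probabilities, optional individual detectability
heterogeneity — so every stage is testable without field data.

## Worked example

```r
library(sessilecmr)

ds <- simulate_population(sim_config(seed = 42)) |> filter_closure()

mln(ds)
#> # A tibble: 3 × 2
#>   plot_id   mln
#>   <chr>   <int>
#> 1 A          29
#> 2 B          16
#> 3 C          24

permutation_removal(ds, n_perm = 10000, seed = 42)
#> # A tibble: 3 × 9
#>   plot_id   mln estimate   lcl   ucl n_perm n_degenerate below_mln  seed
#> 1 A          29     30.8  26.3  48.4  10000            0 FALSE        42
#> 2 B          16     16.3  14.3  24.3  10000            0 FALSE        42
#> 3 C          24     24.2  21.4  32.9  10000            0 FALSE        42

fit <- fit_huggins(ds, "mt")
abundance(fit)
#> # A tibble: 3 × 8
#>   plot_id m_obs p_star n_hat    f0    se   lcl   ucl
#> 1 A          29  0.965  30.1 1.06  1.09   29.2  34.6
#> 2 B          16  0.955  16.7 0.747 0.909  16.1  20.8
#> 3 C          24  0.960  25.0 0.998 1.06   24.2  29.5

experience_probs(fit_huggins(ds, "experience"))
#> # A tibble: 2 × 4
#>   experience estimate   lcl   ucl
#> 1 expert        0.356 0.308 0.407
#> 2 novice        0.142 0.106 0.188

effort_summary(reduced_effort_scan(ds))
#> # A tibble: 5 × 5
#>       k n_models n_reliable mean_rel_error mean_rel_ci_width
#> 1     2       40         40         0.307              1.88
#> 2     3       50         50         0.143              0.843
#> 3     4       35         35         0.0879             0.534
#> 4     5       13         13         0.0651             0.382
#> 5     6        2          2         0.0556             0.293
```

Reading the output: the three plots were generated with 32/18/28
individuals. The direct counts (MLN 29/16/24) miss the few individuals
nobody found; the removal medians (30.8/16.3/24.2) and the CMR
estimates (30.1/16.7/25.0) both recover close to the truth, with the
CMR intervals visibly tighter than the permutation intervals — the
same ordering the method is designed to show. The experience model
separates expert (0.356) from novice (0.142) detection, and the effort
scan shows accuracy and precision improving steadily from two to six
surveyors: with four experts the mean error is below 10% and the mean
relative CI width about 53%, which is why a three-to-four-expert
scheme is the practical recommendation.

Plots: `autoplot(fit)` (per-surveyor detection probabilities),
`autoplot(scan, metric = "rel_ci_width")`,
`autoplot(detectability_check(ds, "A", seed = 1))`.

Small example CSVs in the package layout live under `inst/extdata/`
(`synthetic_detections.csv`, `synthetic_surveyors.csv`,
`synthetic_plots.csv`; generated by the simulator) and load with
`read_detections()`.

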