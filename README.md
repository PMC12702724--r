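# cpetentropy

Complexity analysis of breath-by-breath cardiopulmonary exercise testing
(CPET) data. The package is aimed at exercise physiologists and
biostatisticians who want to go beyond peak and threshold summaries of a
progressive (ramp) CPET and quantify how *predictable* the breath-by-breath
signals are — oxygen uptake (V̇O₂), carbon-dioxide output (V̇CO₂), minute
ventilation (V̇E), heart rate (HR), respiratory rate (RR) and tidal volume
(VT) — and how that predictability changes with exercise intensity, age and
sex in pediatric cohorts.

## What it computes

**Sample Entropy.** For a signal `x` of length `N`, embedding dimension `m`
and similarity radius `r`, templates `x_m(i) = (x_i, …, x_{i+m-1})` are
compared under the Chebyshev distance, `‖x_m(i) − x_m(j)‖∞ ≤ r`, over all
ordered pairs `i ≠ j` with `i, j ∈ 1:(N−m)` (self-matches excluded).  With
`B^m(r)` and `A^m(r)` the match probabilities at lengths `m` and `m+1`
(shared normalization `Z = (N−m)(N−m−1)`),

    SampEn(x, m, r) = −log( A^m(r) / B^m(r) )

Low SampEn means template matches tend to stay matched one step ahead — a
regular, predictable signal; high SampEn means unpredictability.

**The pipeline around it.** Ramp-CPET signals trend strongly, and SampEn
assumes (weak) stationarity, so each per-breath signal is cleaned with the
standard CPET artifact rules (work-rate percentile-line filter, absolute
physiological bounds, a 15-breath moving-window 3σ rule, and a 30-s
missing-data participant exclusion), first-differenced
(`x̃_t = x_t − x_{t−1}`), standardized, and screened with the Augmented
Dickey–Fuller test under Holm–Šidák correction across the whole run.
SampEn is computed per participant × metric × segment (pre-midpoint,
post-midpoint, full test). Group cells are then compared with a robust
Bayesian model,

    y ~ Student-t(μ, σ, ν),   μ ~ N(2, 1),  σ ~ U(0.05, 0.5),  ν ~ logN(1, 1)

fitted jointly per comparison (shared ν) by MCMC, 4 chains × 1000 retained
draws. Differences are summarized per draw — raw `μ_post − μ_pre` for the
midpoint contrast, percent differences for age and sex — and each contrast
reports the posterior direction probability `P(Δ ≥ 0 | y)`, significant
when `< 0.05` or `> 0.95`.

Because real pediatric CPET datasets are access-restricted, the package
ships a synthetic ramp-CPET cohort generator with controllable complexity
structure (per-half, per-cell AR(1) innovation processes), truth-tagged
artifact injection, and per-breath HR assignment redundancy, so every stage
is testable end to end.

## Worked example

```r
library(cpetentropy)

spec   <- cohort_spec(n_per_group = c(male_younger = 10, male_older = 10,
                                      female_younger = 10, female_older = 10),
                      seed = 42)
cohort <- generate_cohort(spec)
fit    <- cpet_entropy(cohort, seed = 42)
summary(fit)
```

The summary prints one table per comparison family. With this seed the
midpoint family begins:

```
== Pre vs post midpoint (delta = post - pre) ==
metr  sex     age         n1    n2     delta       sd       p  label
vo2   male    younger     10    10    -0.241    0.127   0.028  higher pre-midpoint
vo2   male    older        9    10    -0.493    0.142   0.001  higher pre-midpoint
ve    male    older       10    10    -0.412    0.127   0.000  higher pre-midpoint
hr    female  younger     10    10    -0.290    0.046   0.000  higher pre-midpoint
rr    male    older       10    10    -0.035    0.110   0.383  none
```

`delta` is the posterior mean change in SampEn from the pre- to the
post-midpoint half (here: V̇O₂ complexity drops by ≈0.24–0.49 nats after
the midpoint), `p` is `P(Δ ≥ 0 | y)`, and the label applies the 0.05/0.95
thresholds. The sex family reports percent differences, e.g.

```
vo2   -       older       10    10    -7.700    2.456   0.003  higher for female
```

older females carry ≈7.7% higher V̇O₂ SampEn than older males in this
synthetic cohort. `plot(fit, "midpoint")` draws the corresponding bar
chart, and `write_results(fit, dir)` serializes the stationarity report,
entropy table, posterior summaries, Δ table and a JSON configuration echo
that reproduces the run bit for bit.

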