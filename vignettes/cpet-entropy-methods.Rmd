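---
title: "Methods: breath-by-breath entropy analysis of ramp CPET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-by-breath entropy analysis of ramp CPET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model and the
assumptions behind each stage, the parameters that matter and their
defaults, what the synthetic cohort generator does and does not emulate,
and the numerical and design choices made where the method left room.

## The problem

A progressive (ramp) CPET records six physiological signals breath by
breath — V̇O₂, V̇CO₂, V̇E (L/min), HR (beats/min), RR (breaths/min) and VT
(L/breath) — over 8–12 minutes, typically ~300 breaths. Sample Entropy
(SampEn) quantifies the predictability of such a signal, but two properties
of ramp tests obstruct it: the signals are short, and they trend strongly
(non-stationarity inflates apparent complexity). The pipeline therefore
cleans each series, transforms it to weakly stationary form, verifies that
transformation, computes SampEn per test half, and compares groups with a
robust Bayesian model.

## Cleaning

Three removal rules run in sequence, each on the survivors of the previous;
order matters because moving statistics computed across out-of-range
spikes would be corrupted.

1. **Work-rate ramp filter.** A line is fitted through the participant's
   own (5th, 95th) percentiles of work rate and of time (in minutes):
   `S = (WR95 − WR5)/(c95 − c5)`. A breath is removed when its work rate
   falls below `S·c_t − 1` — one Watt below the percentile line. This
   removes warm-up breaths and ergometer dropouts; removal applies to the
   whole breath (a breath is one observation event). The placement of the
   "− 1" is typographically ambiguous in the formula this rule derives
   from, so both readings are implemented (`eq1_variant`); the default
   subtracts after the product. The rule is skipped with a warning when
   the percentiles are degenerate (constant work rate).
2. **Absolute physiological bounds.** V̇O₂, V̇CO₂ < 0.2 L/min; HR outside
   50–230 bpm; RR < 8 or > 75 br/min; VT < 0.1 or > 3.5 L. Inequalities
   are strict: boundary values are kept. V̇E has no absolute bound.
3. **Moving-window 3σ rule.** For each metric, over the surviving breaths
   in ordinal position (not wall-clock time), a centered 15-breath window
   gives `μ_t` and `σ_t` (population divisor 15, exactly the window
   length); breath `t` is removed when `|b_t − μ_t| > 3σ_t`. Positions
   within 7 breaths of either end have no full window and are not
   evaluated; constant windows (σ = 0) flag nothing; the rule runs in a
   single pass (no iterative re-flagging). Numerically the window variance
   is computed on globally centered values so constant windows give
   exactly zero.

After removal, a participant is excluded when any metric has a gap of 30
consecutive seconds or more, measured between present observations and
against the test's start and end. The gap is measured *after* cleaning,
since cleaning creates the gaps the rule guards against. Removed values
are kept as `NA` gaps — never interpolated — so gap durations stay
computable, and every removal is accounted per rule and metric in the
cleaning report.

## Stationarity

Each analyzable signal is first-differenced (`x̃_t = x_t − x_{t−1}`), then
standardized to zero mean and unit sample variance, then tested — in that
order. The unit-root test is an Augmented Dickey–Fuller regression with a
constant and no trend (differencing has already removed the ramp trend),
augmentation lag chosen by AIC over a common estimation sample up to the
Schwert bound `⌊12 (n/100)^{1/4}⌋`, and MacKinnon (1994) response-surface
p-values. Signals shorter than 20 observations get the conservative
p-value 1. The implementation was validated against an independent ADF
implementation to six decimals on the test statistic.

All ADF tests of one pipeline run — every participant × metric × segment —
form a single family corrected by the Holm–Šidák step-down (adjusted
`p_(i) = max_{j≤i} 1 − (1 − p_(j))^{m−j+1}`, rejections forming a prefix of
the sorted list). The widest family is the most conservative choice.
Signals that fail the corrected screen are excluded from the entropy stage
and logged; exclusion is the conservative action for a method that treats
stationarity as a precondition. A degenerate signal (constant after
differencing, up to a relative floating-point floor of 1e−9) is flagged
non-analyzable.

## Sample Entropy

Templates of length `m` are compared under the Chebyshev distance with an
inclusive radius (`≤ r`); self-matches are excluded; both the `m`- and
`(m+1)`-length template sums run over the same index range
`i, j ∈ 1:(N−m)` — the final `(m+1)`-template ends exactly at `x_N` — so
the match probabilities share the normalization `Z = (N−m)(N−m−1)` and lie
in [0, 1]. This follows the printed summation limits of the defining
equations and deviates from textbook variants that use `N−m−1` templates
at length `m+1`; the package documents and tests its convention
explicitly. When no `(m+1)`-pair matches, SampEn is undefined: the result
carries `defined = FALSE` and an `Inf` sentinel, and such rows are
excluded from group models rather than imputed.

Two implementations exist deliberately. `sampen_bruteforce()` is a plain
double loop over ordered template pairs — the reference. `sampen()`
reorganizes the computation around cumulative Chebyshev distance matrices
but must (and is tested to) return bit-identical match counts on every
input. Radii are in units of the standardized signal's SD, so no rescaling
happens inside the entropy routine.

**Parameter selection.** `select_sampen_params()` searches
`m ∈ {1,2,3} × r ∈ {0.05, …, 0.50}` and minimizes the median across
signals of a delta-method estimate of the relative error of SampEn
(match counts treated as binomial over their `Z` comparisons:
`var(log p) ≈ (1−p)/(pZ)`), plus a penalty `lam·r`. The penalty defaults
to 0.2 for all metrics and 0.006 for HR, whose low breath-to-breath
variability otherwise pins the search at large radii. Undefined grid
points contribute infinite error; ties break toward smaller `m`, then
smaller `r`. This objective is a documented surrogate for variance-aware
parameter selection, not a reimplementation of any specific published
optimizer, and its selections need not match any particular study's. The
pipeline defaults to fixed `m = 2, r = 0.2` for every metric;
`select_params = TRUE` switches the selection on.

## Segmentation and summary measures

The test midpoint is half the participant's total CPET time; breaths
strictly before it are "pre", breaths at or after it are "post" (the
boundary breath is post). Age groups use sex-specific cutoffs — males 13
years, females 12 — with boundary ages in the older group, consistent with
a "younger than" reading of the cutoffs. Two sensitivity schemes exist:
`female_cutoff_11` moves the female cutoff, and `exclusion_bands` drops
males aged [12.5, 13.5) and females [11, 12) to sharpen the groups.

V̇O₂ peak is the maximum 20-second rolling average of breath V̇O₂,
stepped every 5 s across the last two minutes of exercise, windows
half-open `[start, start+20)`; "exercise" ends at the recorded duration
(no recovery breaths are assumed in the files). The same window scheme
yields a peak respiratory-exchange-ratio check (RER > 1.0 indicates
maximal effort); it flags, never drops, participants, since the choice of
window for an RER criterion is not standardized.

## Bayesian group comparison

Within a group cell, defined SampEn values are modelled as
`y ~ Student-t(μ, σ, ν)` with `μ ~ N(2, 1)`, `σ ~ U(0.05, 0.5)` and
`ν ~ logNormal(1, 1)`. The Gaussian prior spans the entropy range of
healthy pediatric CPET; the bounded uniform keeps the scale physiological;
the heavy-tailed likelihood absorbs occasional extreme entropy estimates.
ν carries no group subscript: it is shared across the cells of one joint
fit. Each two-cell comparison is fitted jointly so that posterior draws
are paired by draw index — the Δ statistics subtract draw-by-draw, which
presumes joint sampling.

Sampling uses JAGS: 4 chains × 1000 retained draws (D = 4000) after 1000
warmup iterations per chain, seeds derived deterministically from the run
seed and the cell label. ν is sampled and diagnosed as `log ν` (the prior
is the identical log-normal either way): its heavy-tailed posterior mixes
poorly on the raw scale and also destabilizes the Gelman–Rubin statistic,
while on the log scale R̂ stays ≤ 1.01 with effective sample sizes well
above 400. Fits exceeding R̂ 1.05 are flagged with a warning, never
silently accepted.

Contrasts: midpoint `Δ = μ_post − μ_pre` (raw nats); age
`Δ = (μ_older − μ_younger)/μ_older × 100`; sex
`Δ = (μ_male − μ_female)/μ_female × 100`. Each reports
`P(Δ ≥ 0 | y)`, the fraction of non-negative draws — ties count as
non-negative exactly as the indicator is written; with continuous
posteriors tie mass is zero, and the degenerate identical-draws case gives
p = 1 by that convention. Significance applies the 0.05/0.95 thresholds.
Cells with fewer than 5 defined values are reported but excluded from
significance classification. A caveat worth stating: direction
probabilities are posterior summaries, not calibrated tests — under a true
null `P(Δ ≥ 0 | y)` is approximately uniform across replicated
experiments, so any interior band of width `w` captures ≈ `w` of null
replicates; only the tail thresholds themselves carry the intended
error-rate interpretation.

## The synthetic cohort generator

No public breath-by-breath pediatric CPET dataset exists at this scale, so
the generator emulates the study conditions: four sex × age cells of
40/45/40/45 participants; durations from a truncated normal (mean 582 s,
SD 57 s) within 8–12 min; breath times accumulating as `60/RR(t)` with RR
ramping 20 → 50 br/min (≈ 340 breaths over a 10-min test) plus log-normal
interval jitter; each metric a linear ramp plus a slowly mean-reverting
fluctuation (level AR coefficient 0.98) whose per-breath increments are
the controllable innovation process; work rate an ergometer ramp of
25 W/min through the origin preceded by a 15-s unloaded phase. The
warm-up is deliberately kept below ~2% of breaths: a longer unloaded
phase pushes the work-rate 5th percentile to zero while the time
percentile stays interior, the percentile line then overshoots the true
ramp, and the work-rate filter would flag every breath rather than just
the warm-up.

Complexity is manipulated through the innovation process of the
*differenced* signal, which is the quantity SampEn actually sees: iid
increments give a high-entropy differenced signal, AR(1) increments a
lower one. Defaults: φ 0.30 pre-midpoint and 0.70 post-midpoint for V̇O₂,
V̇CO₂, V̇E and HR (0.40 post for RR and VT, whose midpoint change should
stay small), innovation scales of roughly 1–2% of each metric's ramp
range. Per-cell complexity multipliers divide φ — larger multiplier, less
autocorrelation, higher entropy — with defaults 1.10 (younger males), 1.00
(older males), 1.15 (younger females), 1.25 (older females), chosen to
express the qualitative group structure of interest: entropy falls after
the midpoint, females run higher than males most visibly in the older
cells, younger males run higher than older males. HR is rounded to whole
beats and repeats the previous value with probability 0.3 (pre) / 0.5
(post), emulating per-breath assignment of a continuously measured HR;
within-test variance figures are not published for this kind of cohort, so
the noise scales are the package's own documented choices.

Artifact injection is truth-tagged: out-of-range values (HR 240, V̇O₂ 0.1
L/min, …) for bounded metrics, in-range spikes placed six local window SDs
from the window mean (signed away from the nearer bound so the
moving-window rule, not the bounds rule, is what catches them), and
optional ≥ 35-s missing-data gaps. Spikes avoid breaths already carrying a
bound artifact so every truth row stays checkable.

What the generator does **not** emulate: gas-exchange kinetics (no V̇O₂
slow component, no ventilatory-threshold break points), cardiolocomotor
coupling, measurement drift, or metric cross-correlation. Passing tests
therefore demonstrate that the pipeline recovers structure *of the kind it
models* — trend, innovation autocorrelation, redundancy, artifacts — not
that real pediatric data carry that structure. One emulation limit is
informative: per-test SampEn estimates at 100–200 breaths have sampling
SD (~0.2–0.3 nats) comparable to the induced pre/post gap, so the
generator's midpoint effect is decisive at cohort level but holds for
roughly three-quarters of individual participants; and because the HR
redundancy is identical across sexes, it dominates the HR channel and
masks between-sex complexity differences there — the same confound that
makes real HR entropy hard to interpret when HR is stored per breath.

## Numerical choices and determinism

Percentiles use R's default (type 7) quantile. CSV round-trips are exact
to 1e−9 (15 significant digits). The moving-window variance is computed on
globally centered values; negative variances from cancellation are clamped
to zero. Degenerate differenced signals are detected with a relative
1e−9 floor. All randomness — cohort generation, participant seeds, MCMC
chain seeds — derives deterministically from a single run seed (kept below
2³¹), so a configuration echo plus seed reproduces a run bit for bit.

Problem sizes in the shipped tests are chosen to exercise each property at
meaningful scale: the implementation-vs-oracle entropy sweep uses 200
random signals up to N = 300; the cleaning-fidelity cohort has 20
truth-tagged participants; ADF behavior is checked over 100 synthetic
participants; Bayesian recovery and null behavior use 20 replicates at the
cohort's male group size (n = 85) with the full D = 4000 draws; the
qualitative group-structure check runs the complete 170-participant
default cohort end to end.

## Known limitations

- SampEn on ~150-breath segments is noisy; single-participant values
  should not be over-interpreted, which is why inference happens at group
  level with a heavy-tailed likelihood.
- The ADF screen tests a unit root only; it cannot certify higher-order
  non-stationarity, and no KPSS-style complement is included.
- The (m, r) selection objective is a surrogate; selected parameters are
  reasonable, not canonical.
- Undefined SampEn values are excluded, not imputed; at very small radii
  this can bias a cell toward its more regular members, which the
  selection penalty discourages but cannot rule out.
- HR entropy inherits the per-breath assignment redundancy of the
  recording convention; comparisons on the HR channel confound complexity
  with redundancy.
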