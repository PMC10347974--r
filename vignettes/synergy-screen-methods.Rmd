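---
title: "Scoring and consolidating drug-combination screens"
author: "synergyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and consolidating drug-combination screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models it
fits, the conventions it fixes where the field has none, the numerical
choices inside the solvers, what the synthetic-data generator does and
does not emulate, and the limitations a user should keep in mind.

## The screen and its data model

A two-drug screen titrates each pair in an $n \times n$ checkerboard
(default $6 \times 6$) of constant-factor dilutions (default 3-fold),
with the top concentration anchored near the monotherapy absolute IC50
on that culture. Viability is an ATP-based luminescence readout
normalized to same-plate DMSO vehicle controls, so 1.0 is the control
level and values slightly above 1 are real (wells outgrowing control).

Internally a combination experiment is a `DoseMatrix`: a
$(n{+}1) \times (n{+}1) \times r$ replicate array whose first index on
each axis is dose 0. Storing the zero-dose edges explicitly matters
because every reference model needs the monotherapy responses measured
*on the same plate* as the combination wells; the $(0,0)$ well doubles
as an internal control check (its replicate mean should sit in
$[0.9, 1.1]$ after normalization — violations warn rather than error,
because with few replicates and realistic noise an occasional excursion
is expected). Missing wells are masked (`NA`) and never imputed; all
score sums skip them and report the well count used. A plate with more
than 20% of wells missing is rejected.

## Monotherapy curves

The four-parameter Hill curve
$v(d) = e_\infty + (e_0 - e_\infty)/(1 + (d/EC_{50})^h)$
is fitted by bounded least squares on all replicate points jointly
(fitting means would discard the replicate error structure). Bounds:
$e_0 \in [0.7, 1.2]$, $e_\infty \in [0, 1]$, $h \in [0.1, 10]$,
$EC_{50} \in [d_{\min}/100,\; d_{\max} \times 100]$. The optimizer
(L-BFGS-B on a smooth penalized SSR; the penalty keeps
$e_\infty \le e_0$) is started from three log-spaced $EC_{50}$ values
across the tested range, and the best of the three local fits is kept —
Hill least squares is multimodal in $EC_{50}$ when the transition sits
near the edge of the tested range.

A response whose per-dose means span less than 0.1 viability is flagged
*unidentifiable*: the level is reported but $EC_{50}$ and $h$ are `NA`.
Returning a fabricated $EC_{50}$ for a flat curve is the classic failure
mode of screening pipelines and is explicitly avoided; downstream,
unidentifiable fits disable the fit-based models (Loewe, Chou–Talalay)
for that matrix rather than silently degrade them.

The IC50 used throughout is the **absolute** one — the dose at which
viability crosses 50% of control, in closed form
$d = EC_{50}\,((e_0 - 0.5)/(0.5 - e_\infty))^{1/h}$ — not the relative
EC50. Screens anchor their top doses at "the IC50" of normalized
viability, which is the absolute definition; a drug whose floor is above
0.5 never reaches it and is "not reached". The sensitivity filter
retains a drug when its IC50 is reached within the tested range in at
least a configurable fraction of cultures (default: all). The fraction
is configurable because published screens state only that insensitive
monotherapies were excluded, not the exact rule.

## Reference models and the score convention

Per combination well, expected viability under each model:

* Bliss independence: $v_A v_B$ (inputs above 1 are clamped to 1 with a
  warning — a well outgrowing control has no meaningful kill
  probability);
* HSA: $\min(v_A, v_B)$;
* Loewe additivity: the $v$ solving $d_A/A(v) + d_B/B(v) = 1$ with
  $A, B$ the inverse Hill curves;
* Chou–Talalay (mutually non-exclusive):
  $CI = d_A/D_A + d_B/D_B + d_A d_B/(D_A D_B)$, with each drug's
  median-effect parameters taken from its Hill fit ($D_m = EC_{50}$,
  $m = h$) and the affected fraction mapped per drug as
  $f_a = (e_0 - v)/(e_0 - e_\infty)$, clamped to $[0.005, 0.995]$
  before inversion so a near-total-kill well cannot blow the index up.
  Deriving $(D_m, m)$ from the shared Hill fit (instead of a separate
  median-effect linear regression) keeps one fitting machinery for all
  models; the two differ only in how fitting error is weighted.

The per-well score is $(expected - observed) \times 100$ percentage
points, positive = synergy (observed viability below expectation), and
for Chou–Talalay $(1 - CI) \times 100$. The reported score is the
**sum over combination wells** — synergy and antagonism together —
with the positive-only and negative-only partial sums retained; the
synergy-only sums feed the validation clustering. Summed (rather than
averaged) percentage points are this package's fixed convention;
comparisons across differently sized or masked grids should use the
reported `nWells`. Minimum viability (lowest replicate-mean combination
well) is carried alongside as the tumoricidal-effect metric, because a
synergistic dose shift with no absolute kill is not a therapeutic
result.

### Loewe solver numerics

$g(v) = d_A/A(v) + d_B/B(v) - 1$ is strictly increasing on the shared
effect range $(\max(e_{\infty A}, e_{\infty B}),\ \min(e_{0A}, e_{0B}))$,
so the root is bracketed and solved with `uniroot` at tolerance $10^{-9}$.
Three degenerate regimes are handled explicitly:

* one or both doses zero: the monotherapy (or control) value is returned
  directly, no solving;
* $g > 0$ already at the bottom of the bracket: the combined dose demands
  an effect deeper than one curve's floor allows; Loewe has no solution
  and the well falls back to HSA, flagged and counted (`nFallback`).
  The same fallback covers fitted curve pairs with no shared effect
  range (one floor above the other's ceiling);
* $g < 0$ at the top of the bracket: for steep slopes ($h$ large) $g$
  stays negative until within bracket tolerance of the ceiling, so the
  root equals the bracket top to machine-relevant precision and is
  returned without solving.

A drug combined with itself reduces algebraically to the monotherapy at
the summed dose (sham invariance) — this is a test, not an assumption.

## z-consolidation, clustering, selection

Synergy sums and minimum viability live on incommensurable scales, so
each metric is standardized to mean 0, sample SD 1 ($n-1$ denominator)
over all non-missing combination × culture entries. Missing entries
stay missing through z-scaling; they are median-imputed (with a count)
only at the clustering step. z-scaling makes the downstream selection
invariant to per-metric affine rescaling of the raw scores.

Clustering operates on per-combination feature vectors — the median z
over cultures for each metric — because the screen's unit of decision
is the combination, not the combination × culture pair (the full
per-culture feature layout is available by passing a different feature
matrix). The mixture search covers $k$ in 1–9 and four covariance
families (diagonal/full × shared/per-cluster; mclust's EEI, VVI, EEE,
VVV), selected by BIC. The `bic` slot follows the lower-is-better
convention $-2\log L + p\log n$; mclust's internal sign is flipped on
the way out, and the convention is stated on the class. Mixture
initialization uses mclust's deterministic model-based hierarchical
agglomeration, so results are reproducible given the data; the recorded
seed governs the K-means restarts.

The *synergy with viability loss* cluster is the one maximizing the
median z over {Loewe, HSA, Bliss} subject to two conditions: its median
minimum-viability z is below 0, and its median synergy z exceeds a
margin (default 0.5, half a pooled SD). The margin exists because the
maximizing cluster always exists — on a screen with no synergy at all,
a single-cluster fit has median z $\approx 0$ and would otherwise be
returned on a coin flip. Half a standard deviation is the smallest
elevation one would defend as "elevated" on a z scale; it is a method
parameter, configurable, and the package's own operationalization.
The final set intersects the mixture cluster's members with the
analogous cluster from a K-means validation run on the synergy-only
metrics (Loewe, HSA, Bliss, Chou–Talalay positive sums + minimum
viability) — "consistent" means selected by both analyses. Either
side finding no qualifying cluster returns an empty set with a warning.

Replicate concordance is plain paired correlation (Pearson default,
Spearman optional) with a two-sided test, on at least 3 pairs.

## Longitudinal classification

Endpoint matrices from long-term, repeated-exposure assays go through
the identical Loewe engine (same code path; an unfittable endpoint edge
degrades the matrix to flagged HSA scoring). The call threshold comes
from a randomization null: the signs of the per-well deviations are
randomized ($\pm 1$ with equal probability) and the summed score is
recomputed, many times, seeded. A combination is longitudinally
synergistic when its observed sum exceeds the null's 95th percentile in
at least one culture (both the quantile and the culture rule are
configurable; published long-term screens state no numeric cut-off, so
this rule is the package's own).

Sign-randomization is used rather than shuffling well *positions*
because the summed score is position-invariant by identity — the sum of
(expected − observed) does not change when observed values trade
places — so a position permutation produces a degenerate null. Under
exchangeable symmetric noise around the expected surface, sign flips
are an exact randomization test, and its type-I rate at the 95th
percentile is ≈5% (checked by simulation in the acceptance suite, at
100 null matrices × 500 draws; tested type-I band 2–8%).

## The synthetic screen generator

`simulateScreen()` emulates: per-(drug, culture) Hill curves drawn from
configurable priors ($e_0 \in [0.95, 1.05]$ — DMSO normalization keeps
baselines near 1; $e_\infty \in [0, 0.4]$; $EC_{50}$ log-uniform on
$[0.01, 2]$ µM; $h \in [0.8, 2.5]$ — typical single-agent screen
ranges); top doses anchored at each drug's true absolute IC50 with a
fixed 10 µM fallback for insensitive curves; 6 × 6 three-fold grids
with zero-dose edges; multiplicative (Bliss-baseline) combination
responses $v_A v_B - \delta\, w$, where the designated synergistic
subset receives excess $\delta$ under a unimodal weight $w$ peaking
mid-grid (so the edges remain honest monotherapies and the excess
fades toward the rim; a flat weight is available and is what the exact
"$\delta \times 36 \times 100$ pp" arithmetic checks use); truncated
Gaussian replicate noise (at 0, clipped at 1.2); and raw RLU emission
with per-plate DMSO control wells, exercising the normalization path.

Defaults are the package's study conditions: 40 combinations (10
synergistic, $\delta = 0.15$) × 10 cultures, 2 technical replicates,
noise SD 0.05. The generator is bit-reproducible from its config.

What it does **not** emulate — and what passing recovery tests
therefore cannot show about real data: spatial plate effects and edge
evaporation; dispensing errors; Loewe-type (dose-shift) interactions as
the generating mechanism (a dose-shift alternative is noted in the
config design but the generative baseline is Bliss, so Loewe scores on
"null" synthetic combinations are not exactly zero — only Bliss is
nulled by construction); biological replicate variation between
passages; and any relationship between a culture's genotype and its
drug sensitivity. Recovery results (sensitivity/specificity of the
selection) are statements about the pipeline's statistics, not about
biology.

## Problem sizes and runtime choices

The test and acceptance runs use sizes chosen to make their estimates
stable while keeping a laptop-scale runtime: 20 simulated screens at
the 40 × 10 default for the recovery rates, 10 null screens for the
empty-selection rate, 200 Hill-recovery simulations (8 doses × 3
replicates, noise SD 0.05), 100 random Hill pairs against a
$10^{-5}$-resolution grid for the Loewe solver, 100–200 null matrices ×
500 sign draws for the longitudinal calibration, and 90-point blob sets
for the clustering harness. A full screen analysis (40 × 10 matrices:
800 edge fits, 14,400 Loewe roots) runs in roughly 10–15 seconds.

## Known limitations

* The Loewe HSA-fallback makes deep-effect wells conservative: a well
  whose expected effect is unreachable contributes an HSA deviation
  instead of a larger Loewe one. The per-combination fallback count is
  reported so such matrices can be flagged.
* Chou–Talalay parameters inherit Hill-fit error; near-flat curves with
  $e_0 - e_\infty$ barely above the flat threshold give unstable
  $D_m$. The fa clamp bounds, but does not remove, this.
* The selection margin (0.5 z) is a sensible default, not a calibrated
  quantity; screens with very weak but real synergy throughout will
  return empty sets.
* Biological replicate reproducibility is out of scope; concordance
  here is technical-replicate correlation only.
* No spatial/edge correction is applied; plates with systematic
  gradients should be corrected upstream.
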