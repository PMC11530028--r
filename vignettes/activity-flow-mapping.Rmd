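---
title: "Generating category selectivity from distributed activity flows: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating category selectivity from distributed activity flows: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actflowsel)
```

## The generative model and its assumptions

The package implements an activity-flow account of localized functional
selectivity: a held-out target region's task activation is modeled as the sum
of all other regions' activations weighted by their intrinsic (resting-state)
connectivity with the target,

$$\text{mapped}_j \;=\; \sum_{i \neq j} a_i \, w_{ij}.$$

The approach assumes (i) approximately linear superposition of task-evoked
signals at the fMRI time scale, (ii) that resting-state connectivity is a
valid estimate of the routes task activity takes, and (iii) that the target's
own activity can be held out without breaking the sum (no self-coupling term
is modeled). The success of the mapping is read as evidence that distributed
network interactions, rather than purely local computation, generate the
target's response.

Category selectivity is quantified on min-max-normalized activations
(`minmax_normalize()`, bounds $a = 0$, $b = 1$, reference min/max taken from
the *actual* activations across all 24 conditions) as the ratio of the mean
category response to the mean response of the other categories' conditions
(`category_selectivity()`; 1.0 = no selectivity). The distributed
contribution (`distributed_contribution()`) is $100 \times$ mapped/actual
selectivity per participant, averaged over participants after flagging
outliers beyond 5 scaled median absolute deviations.

## What the synthetic generator emulates

`generate_ground_truth()` builds a 60-region cortex organized into 12
networks (CAB-NP-style labels), with:

* four **functional complexes** (body, face, place, tool; two regions each)
  whose incoming weight rows are distinctive *connectivity fingerprints* —
  strong weights onto the source groups driven by the complex's own category
  conditions and onto V1 in proportion to V1's category tuning, weak baseline
  weights elsewhere. Distinctiveness (pairwise cosine < 0.9) is enforced by
  rejection sampling;
* a **V1 source set** (four regions in the first visual network) engaged by
  every driven condition with condition-specific patterns — the stimulus
  entry point for V1-initialized mapping;
* block-structured weights among the remaining regions (denser and stronger
  within network), scaled to a spectral radius of 0.5 so the resting model is
  stationary and comfortably subcritical ("high global coupling, no
  self-coupling": the weight diagonal is zero);
* a 2-D grid geometry from which `build_exclusion_mask()` derives
  dilated-mask source exclusion (radius 1 = rook neighbors), a scale-free
  stand-in for surface-based masks.

Rest is simulated from the contemporaneous linear structural equation model
$x = Wx + e$, i.e. $x = (I - W)^{-1} e$ with i.i.d. Gaussian innovations.
This choice (rather than a lagged VAR) makes connectivity recovery exactly
testable: for a node with no outgoing edges, the multiple regression of its
series on all others recovers its incoming weight row exactly. For that
reason the complexes are constructed as *sinks* (zero outgoing weights) —
their rows are precisely the rows the mapping equation consumes, and
`combinedfc()` recovers them consistently as rest grows. Regression rows of
non-sink nodes mix child and co-parent terms and are not expected to equal
the generative rows; the collider-pruning stage exists precisely to remove
the spurious co-parent edges.

The task is a block design: 24 conditions (8 encoding the four categories as
0-back/2-back pairs), 3 blocks per condition of 8 time points with 4-point
gaps, convolved with the canonical double-gamma HRF; condition-specific
drives are injected into dedicated source groups and V1, and BOLD noise is
Gaussian. One condition carries no drive at all, anchoring the minimum of
every region's condition profile at baseline — which the normalization
reference needs (see below).

### The distributed-vs-local mixture and why it is recoverable

Each complex's true activation profile is
$t = (1-\lambda) f + \lambda g$, where $f$ is the pure activity-flow profile
(its fingerprint applied to the source drives), $\lambda$ is
`local_fraction`, and $g$ is the **local component**: the flow profile with
responses to the *other* categories' conditions suppressed to baseline — a
winner-take-all sharpening, the kind of computation local recurrence is
usually credited with. This specific construction makes the contribution
estimand exact. With bounds $a = 0$ the min-max scale factor cancels from the
selectivity ratio, so selectivity depends only on condition means relative to
the profile minimum (pinned at the no-drive condition). The local term leaves
the category-condition mean of $t$ untouched and shrinks the non-category
mean by $(1-\lambda)$, hence, noiselessly and per participant,

$$\frac{\text{mapped selectivity}}{\text{actual selectivity}}
  = \frac{f_\text{cat}/f_\text{non}}{f_\text{cat}/((1-\lambda) f_\text{non})}
  = 1 - \lambda ,$$

so the group-mean contribution recovers $100(1-\lambda)$ by construction.
The mixture is defined at the complex (target) units; all other regions are
exogenous, stimulus-driven sources whose true activation equals their
injected drive — a unit cannot simultaneously be an exogenous source and be
generated by Eq.-1 flow over other units' final activations.

The generator does **not** emulate: hemodynamic nonlinearity, physiological
or structured noise, autocorrelated BOLD, surface geometry, inter-regional
conduction delays, or participant-level connectivity differences (only
drive jitter and measurement noise vary across participants). Passing tests
therefore show that the estimators are correct and calibrated under the
stated generative assumptions — not that real cortex satisfies them.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `local_fraction` | 0.25 | share of target activation generated locally |
| `noise_sd` | 0.5 | SD of rest innovations and BOLD noise (beta-level SE ≈ 0.07, i.e. high block-design SNR) |
| `drive_strength` | 3 | source drive amplitude (arbitrary BOLD units) |
| `n_timepoints_rest`, `n_runs_rest` | 1000, 2 | rest scan length per run / runs |
| `spectral_target` | 0.5 | spectral radius of the source subgraph |
| `alpha_partial`, `alpha_zero` | 0.01 | combinedFC stage-1/stage-2 levels |
| `n_penalties` | 100 | log-spaced lasso penalty grid (4 decades below the all-zero penalty) |
| `tolerance` (propagation) | 0.5e-4 | settling threshold = half-ULP of 4-decimal rounding |
| `n_mad` | 5 | MAD outlier cut (MAD scaled by 1.4826) |
| `n_perm` | analysis-dependent | 100,000-scale for selectivity tests in principle; smaller defaults here for tractability |

## Numerical and procedural choices

* **combinedFC significance rules.** Stage 1 keeps edges whose partial
  correlation (computed once from the inverse covariance) rejects zero in a
  two-sided Fisher-z test at `alpha_partial`; stage 2 *removes* kept edges
  whose bivariate correlation fails to reject zero at `alpha_zero`
  (operationalizing "statistically equal to zero"); stage 3 rescales
  surviving edges by per-target OLS. Singular covariances error with a
  pointer to the regularized variant.
* **Lasso penalty selection.** Leave-one-run-out CV on mean squared
  prediction error over 100 log-spaced penalties; the default picks the
  sparsest penalty within one standard error of the CV minimum, the usual
  parsimony convention when the support defines a graph (the plain minimizer
  is available via `rule = "min"` and tends to over-select).
* **Propagation.** Each step re-applies target-excludes-self mapping with
  exogenous units clamped; no spatial re-masking beyond step 1. The
  subsystem's spectral radius is checked up front and divergence raises an
  error naming it. The settle step is the first step whose re-mapping changes
  nothing beyond tolerance, so the reported state is a fixed point.
* **V1 centering.** The cross-V1 mean of the condition being mapped is
  subtracted from V1 sources for that condition only (step 1 only in
  multi-step variants).
* **Dominance analysis.** All $2^{12} - 1 = 4095$ non-empty predictor
  subsets are enumerated (candidate models include the full model);
  incremental R² contributions are averaged within each subset size, then
  across sizes (general dominance), which guarantees partial R² sums to the
  full R² and relative importances to 100%.
* **Max-T schemes.** Paired contrasts exchange condition labels, which for
  two conditions is a sign flip of the paired differences; one-sample tests
  against non-zero nulls (selectivity vs 1.0, contribution vs 50%) sign-flip
  participant deviations from the null mean, since label exchange is
  undefined there. Corrected p is $(1 + \#\{T_{\max} \ge t\})/(1 + n_{perm})$.
  Comparisons with zero spread and zero mean get $t = 0$ (corrected p of 1).
* **Degenerate inputs.** Flat normalization references return the constant
  lower bound with a warning; a zero-MAD cohort removes nothing, with a
  warning; all-zero lasso targets yield zero rows with a warning.
* **Null models.** Fingerprint substitution follows the replace-rows /
  zero-self-block / transpose-fill recipe exactly. "Maintaining edge strength
  and degree" is realized as binary-degree-preserving double-edge swaps plus
  a random permutation of the nonzero weight multiset over the rewired edges
  — exact strength sequences cannot generally be preserved at the same time,
  so the multiset is the feasible reading.

## Problem sizes

The shipped tests and drivers use a 60-region cortex, cohorts of 8–50
participants, rest scans of 600–10,000 time points, 100-replicate motif
sweeps at $n = 2000$, a 50-node sparse network at $n = 1200$, and 200
Monte-Carlo repetitions of 1000-permutation max-T runs — sizes chosen so the
whole suite runs in minutes on a laptop core while keeping Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* Real-data ingestion is limited to plain matrix TSV plus a partition table;
  CIFTI/grayordinate handling is out of scope.
* The vertex level is emulated by treating units as vertices with an
  aggregation map; there is no surface geometry.
* The contribution estimand is exact only under the generator's sharpening
  local component; other local computations (e.g., gain changes that also
  raise category means) would not yield $100(1-\lambda)$, and on real data
  the estimate is a lower bound on the distributed share, as model error
  also deflates it.
* Connectivity rows are identified for sink-like targets; causal direction
  among sources is not estimated.
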