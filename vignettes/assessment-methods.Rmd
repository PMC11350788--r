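---
title: "Methods: presence-background niche models and threat reclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background niche models and threat reclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nichecast)
```

# The assessment problem

Given presence-only occurrence records and co-registered climate rasters for
the present and for future scenarios, the pipeline estimates each species'
potential distribution now and in the future, computes the projected range
change, and maps it onto ordered threat categories. Species with too few
records for any distribution model are assessed from the geometry of their
records instead. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic validation does and
does not demonstrate.

# The maximum-entropy model

## Form and fitting

Habitat suitability is modelled presence–background: the landscape is a
finite set of background cells, each with a feature vector $z(x)$ built from
the screened climate layers (per variable, a linear and a squared term,
min–max normalized to $[0,1]$ over the training landscape). The model is the
Gibbs distribution

$$q_\lambda(x) = \frac{\exp(\lambda \cdot z(x))}{Z_\lambda}, \qquad
Z_\lambda = \sum_{x \in \text{background}} \exp(\lambda \cdot z(x)),$$

with $\lambda$ chosen to maximize the L1-penalized presence log-likelihood

$$\frac{1}{|P|}\sum_{x \in P} \lambda \cdot z(x) - \log Z_\lambda
  - \sum_j \beta_j |\lambda_j|.$$

This is the maximum-entropy distribution subject to the constraint that
fitted feature expectations match presence means within $\pm\beta_j$; the
equivalence is checked in the tests via the KKT condition
$|E_q z_j - \overline{z_j}^P| \le \beta_j$.

Two numerical decisions matter here and were made after the first
implementation attempt demonstrated they were not optional:

* **Second-order optimization.** A climatic niche a few degrees wide on a
  landscape spanning tens of degrees needs quadratic-feature coefficients of
  order $10^2$–$10^3$ on the $[0,1]$ feature scale, and the likelihood is
  extremely ill-conditioned in that direction (its curvature is the fitted
  feature covariance, which collapses as the model concentrates).
  First-order proximal updates stall at visibly too-flat fits whose moment
  violations hide inside the L1 slack. The solver is therefore a proximal
  Newton method: at each iterate the gradient
  $\bar z^P - E_q z$ and the $d \times d$ Hessian $-\mathrm{Cov}_q(z)$
  define a penalized quadratic subproblem, solved exactly by cyclic
  coordinate soft-thresholding, followed by backtracking on the true
  objective. With $d \le 20$ features the Hessian is cheap, and convergence
  takes 5–30 iterations. Defaults: `tol = 1e-5` (relative objective change),
  `max_iter = 500`.
* **Sample-size-scaled regularization.** The penalty is
  $\beta_j = \beta_0 \, s_j / \sqrt{m}$ with $s_j$ the feature's background
  standard deviation, $m$ the number of presences, and the single knob
  $\beta_0 = 0.05$ (`beta_scale`). The $1/\sqrt{m}$ factor makes the allowed
  slack on each constrained mean shrink like that mean's standard error —
  the same scaling the original MaxEnt tool uses. Without it the slack is
  constant in $m$, and on second moments (which are what pin down niche
  *width*) a constant slack inflates fitted niches several-fold regardless
  of how much data arrives; recovery of known synthetic niches fails.

Zero-variance features are dropped with a warning. Feature values outside
the training bounds during projection are clamped to $[0,1]$ (disable with
`clamp = FALSE`).

## Output, evaluation, replication

Reported suitability is the logistic transform
$p(x) = e^{H} q(x) / (1 + e^{H} q(x))$, where $H$ is the entropy of the
fitted distribution over the background; $p = 0.5$ at cells of
entropy-typical suitability, and a uniform model yields $p = 0.5$
everywhere. Discrimination is measured by the ROC AUC in its Mann–Whitney
form (probability that a presence outranks a background cell, ties half).

Each species is fitted `n_replicates = 7` times on independent 75/25
train/validation splits (`train_fraction = 0.75`, round-half-to-even with at
least one validation point) with per-replicate seeds derived from the
species seed; the logistic maps are averaged cell-wise, for training and for
every projection. Seven averaged models with replicate-level ROC logging is
the convention adopted here; the replicate count is a config knob.
Background cells are a uniform no-replacement sample capped at
`background_cap = 100000` (the entire landscape when smaller, as in the
synthetic study). A jackknife report (leave-one-variable-out /
only-one-variable training gains) is available as a diagnostic and never
feeds back into the model.

# Predictor screening

Collinear climate layers are screened once, on the current-scenario stack,
over a seeded sample of `sample_cells = 10000` cells:

1. While any pair has $|r| > 0.8$ (`r_max`), drop one member of the worst
   pair — the one with the larger mean $|r|$ against all layers. This
   tie-break is deterministic and order-independent, which the tests verify
   by permuting layer order.
2. Iteratively drop the layer with the largest VIF until all
   $\mathrm{VIF} = 1/(1-R^2) \le 10$ (`vif_max`), recomputing after each
   drop; one-shot removal can strand VIFs above the cutoff.

The retained set is then fixed for all scenarios and species, so projected
change is never confounded with predictor-set drift. (Per-species screening
would be a trivial loop over per-species stacks; the global set is the
default and only mode because the assessment compares ranges across
scenarios, not across predictor sets.) A constant layer has undefined
correlation; it is flagged and treated as $r = 0$ so the VIF stage can
still remove it.

# Habitat classes and ranges

Averaged suitability is cut into four habitability classes (non / low /
medium / high) by exact Fisher–Jenks natural breaks: the contiguous
partition of the sorted values minimizing total within-class sum of squared
deviations, found by dynamic programming (Rcpp; values centered on their
global mean and accumulated in extended precision, because the textbook
sum-of-squares identity cancels catastrophically on near-equal values).
Rasters larger than `sample_cells` are subsampled with a seed before
fitting. Each break is the smallest value of its upper class and intervals
are left-closed upward (a value equal to a break goes to the upper class),
so classification reproduces the fitted partition exactly; the convention is
tested at the boundaries.

Breaks are fitted on each species' *current* suitability and reused for that
species' future projections: thresholding current and future maps
identically is what makes the range change a statement about climate rather
than about threshold drift.

The potential range is the union of the low, medium and high classes. Areas
are geodesic: a cell at latitude $\varphi$ with resolution $\Delta$ has area
$R^2 \Delta_\mathrm{rad} (\sin\varphi_N - \sin\varphi_S)$, $R = 6371$ km;
the tests check that the global grid integrates to $4\pi R^2$ within 0.1 %.

# Threat categories

Projected loss $L = (A_\text{now} - A_\text{future})/A_\text{now}$ maps to
categories by the fixed thresholds: EX at $L = 1$ (within $10^{-12}$, to
absorb floating-point area sums), CR $\ge 0.8$, EN $\ge 0.5$, VU $\ge 0.3$,
NT $\ge 0.1$, LC otherwise; expansions ($L < 0$) are LC and flagged, so
loss histograms can show positive change. The mapping is monotone in $L$,
which is property-tested.

Species on the data-poor path (1–3 records, or a modelled current range of
zero area) are elevated from a baseline category: with three records by the
triangle area enclosed (below 100 / 500 / 10,000 km² ⇒ +3 / +2 / +1
levels; planar area under an equirectangular projection at the points' mean
latitude — adequate at these scales, and zero for collinear or duplicated
points); with two records by great-circle distance (below 10 / 50 / 500 km
⇒ +3 / +2 / +1); a single record always elevates three levels. Their status
is held constant across horizons within each scenario. Two design choices
are deliberate:

* **Elevation caps at CR.** EX is reachable only through $L = 1$; a
  geometry rule alone should not declare an extinction.
* **The baseline is LC** unless a species-level current category is
  supplied (`baseline` argument / metadata): the cascade elevates from a
  model-free floor, and the source procedure never names its starting
  category. Both the cap and the baseline are explicit knobs.

Richness maps count a species in a one-degree cell when any flagged
native-resolution cell overlaps it; richness change is the per-cell future
minus current count. Transition tables cross-tabulate baseline versus
projected categories.

# The synthetic study

## What the generator emulates

`generate_climate()` produces seeded smooth layers — a latitudinal gradient
(layer 1 is temperature-like: ~30 °C at the equator falling poleward), a
low-frequency sinusoid, and white noise — with optional near-duplicate
layers to exercise the correlation screen. Future stacks are additive
deltas; the study uses +1.8 / +2.4 °C (moderate pathway, 2050s / 2070s) and
+2.4 / +3.8 °C (severe), the magnitude range of CMIP6 global-mean warming,
with mild drying in the second layer.

Virtual species have Gaussian niches
$s(x) = \exp(-\tfrac12 (z - \mu)^\top \Sigma^{-1} (z - \mu))$; their true
range is the superlevel set $s \ge s^*$, recomputed under every scenario,
and the true loss fraction uses the same geodesic areas as the pipeline.
Presences are sampled proportional to suitability and placed at cell
centers, which removes sub-cell ambiguity when comparing against the truth.

Study conditions (fixed once, at design time):

* Grid 90 × 180 at 2° (the full 10-arc-minute convention of real stacks is
  available through `nc_grid`, but 2° keeps a 20-species study under a
  minute); 20 modelled species with 200 records each, 3 data-poor species
  with 1–3 records.
* $s^* = 0.05$: the true range is the climatic tolerance envelope at 5 % of
  peak suitability. The binarization being validated deliberately counts
  even low-habitability cells as range, so the commensurate truth is a
  broad envelope; a strict threshold (e.g. half-maximum) would make the
  recovery experiment measure threshold disagreement instead of pipeline
  error.
* Thermal niche sd 4–5 °C, centers −28…0 °C on the cool flank; the
  second-variable niche is broad (sd 15–30) and centered inside the
  thermal band. Warming then truncates ranges against the polar climate
  margin — trailing-edge loss, the dominant real-world geometry — and the
  center temperature dials the true loss fraction smoothly.
* Roster species whose true loss (severe 2070s) falls within 0.05 of a
  category threshold are redrawn, so category recovery is scored away from
  knife edges.

## What passing does and does not show

The acceptance suite shows that, under these conditions, the pipeline
recovers true loss fractions within ±0.10 with matching categories for at
least 90 % of the roster, that a well-separated narrow niche is ranked with
test AUC ≥ 0.9, that both numerical engines (Fisher–Jenks, the maxent
solver) match brute-force oracles, and that a full run is bit-reproducible
from its seed.

It does not show performance on real data: the generator has no spatial
sampling bias, no observation error in coordinates, no dispersal limits, no
land/sea mask, and additive (not pattern-changing) climate deltas. Two
limitations are structural and worth stating plainly:

* **Near-total losses are not recoverable at this scale.** A species whose
  true loss is 0.8–1.0 survives only as a polar sliver; whether the fitted
  range's warm edge survives a few-degree shift depends on the fitted niche
  width at exactly the scale of its uncertainty, so Jenks-binarized
  estimates cannot pin $L$ within ±0.10 there. The recovery roster
  therefore spans losses up to roughly 0.5; CR/EX behavior is exercised by
  the rule-level tests, not by end-to-end recovery.
* **The Jenks operating point is data-dependent.** Natural breaks on a
  logistic map place the first break low; the estimated range is a broad
  envelope whose effective suitability threshold varies by species. Loss
  *fractions* are much more stable than range *areas* — which is why the
  pipeline reports and is validated on fractions.

# Determinism

Every stochastic step (climate noise, species rosters, presence draws,
splits, background samples, subsamples for screening and breaks) takes an
explicit seed. Per-species seeds are a stable polynomial hash of the master
seed and the species id, so adding or removing one species never perturbs
another's results; per-replicate seeds derive from the species seed. Two
runs under one master seed produce byte-identical report bundles, verified
by hashing the written files.

# Degenerate inputs

Documented behaviors, each tested: empty occurrence files and missing
columns are errors; out-of-bounds coordinates are rejected and logged;
longitudes wrap into [−180, 180); records on cell edges belong to the
north-east cell (half-open cells); all-equal suitability cannot be cut into
classes; a singular niche covariance, an all-zero suitability surface, a
zero-area current range (rerouted data-poor), constant layers, perfectly
collinear predictors (infinite-VIF sentinel), and duplicate geometry points
all have defined outcomes rather than silent misbehavior.
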