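---
title: "Methods: presence-background niche modelling with nichecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background niche modelling with nichecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The model

`nichecast` implements the presence-background maximum-entropy approach to
species distribution modelling. Given presence cells and a background of
landscape cells described by environmental features $f(x) \in [0,1]^J$, the
model is the Gibbs distribution over background cells

$$ P_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z(\lambda)}, \qquad
   Z(\lambda) = \sum_{x \in \text{bg}} e^{\lambda \cdot f(x)}, $$

whose coefficients maximize the L1-penalized log-gain

$$ F(\lambda) = \frac{1}{m}\sum_{i=1}^{m} \lambda \cdot f(x_i)
   - \ln Z(\lambda) - \sum_j \beta_j |\lambda_j|. $$

The per-feature penalty follows the published MaxEnt default scheme:
$\beta_j = \mathrm{RM} \cdot \beta_{\text{class}}(m) \cdot s_j / \sqrt{m}$,
where $m$ is the presence count, $s_j$ the presence standard deviation of
feature $j$ (floored at 0.05, features spanning $[0,1]$), and
$\beta_{\text{class}}$ interpolates the class tables (linear/quadratic
$1.0 \to 0.2 \to 0.05$ at $m = 10, 30, 100$; product $0.5/0.3/0.1$; hinge
$0.5$ throughout; threshold $2.0/1.5/1.0$). The regularization multiplier
RM scales all penalties at once.

Feature classes are the standard five: Linear and Quadratic on min-max
scaled variables, pairwise Products, forward/reverse Hinges, and step
Thresholds, with knots at equally spaced background quantiles (10 per
variable and direction by default; MaxEnt uses up to 50 — the smaller
default keeps desk-scale tuning grids tractable and is configurable).

The default output is the cloglog transform
$1 - \exp(-e^{H} P_\lambda(x))$, with $H$ the entropy of the fitted Gibbs
distribution, the modern MaxEnt habitat suitability index (HSI) in
$[0, 1]$; logistic and raw outputs are available. On projection, variables
are clamped to the training range, so extrapolated predictions equal the
boundary prediction.

## The optimizer

Fitting is cyclic coordinate descent with Newton/soft-threshold
one-dimensional updates (the glmnet recipe applied to the Gibbs
likelihood), implemented in compiled code. Each accepted update is
backtracked until the penalized objective does not decrease, so the
recorded gain trace is monotone by construction; coordinates are visited
in a shuffled order drawn from the model seed; after each full sweep the
active set is iterated to convergence. Convergence is declared when a full
round improves the penalized gain by less than `tol` (default `1e-5`).

Two numerical notes. First, Linear and Quadratic features of one variable
are strongly collinear on $[0,1]$ (correlation often $> 0.95$), and the
optimum may place large opposite-signed coefficients on such a pair when
the response is sharply peaked. Coordinate descent crawls along that
valley, so the default cycle budget is generous (`max_cycles = 2000`);
with a budget of 500 the slowest linear-quadratic fits stop short of the
optimum, which measurably distorts downstream AICc comparisons.
Non-convergence is a warning flag on the model, not an error. Second, the
background weight vector is refreshed from the score vector after every
sweep to stop multiplicative drift in the incremental exponent updates.

Percent contribution credits each update's gain change to the updated
feature's variable (split equally for products), floors negatives at zero
and normalizes to 100. Because credit follows the optimization path, the
split between strongly collinear variables is path-dependent; the shuffled
visit order makes it unbiased on average, which is how the paired-layer
symmetry test reads it. Jackknife importance refits with each variable
alone and left out; replicate AUC uses 10 random 75/25 presence splits and
scores held-out presences against the background with the tie-aware
Mann-Whitney estimator.

## Model selection

`tune_sdm()` fits the full grid of six feature combinations (L, H, LQ,
LQH, LQPH, LQPHT) by eight regularization multipliers (0.5-4 in steps of
0.5), computes the landscape-normalized AICc (raw predictions renormalized
over the full valid grid; $k$ = nonzero coefficients;
$\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$, rows with
$n - k - 1 \le 0$ flagged invalid), and selects the $\Delta\mathrm{AICc} = 0$
row, breaking exact ties by smaller $k$, then smaller RM, then the listed
FC order. AICc is computed from single full-data fits; the replicate AUC
is computed for the winner only, which keeps the 48-candidate search
affordable.

## The synthetic world

All tests and the acceptance analysis run on generated data. The default
world is 120 x 90 cells at 0.25 degrees (lon 92-122 E, lat 18.5-41 N — a
subtropical-montane window), with eight correlated smooth random fields
emulating a bioclim-style roster: three temperature-like layers (bio2,
bio4, bio9), two precipitation-like layers (bio12, bio17, built with
target correlation 0.85 so collinearity pruning has a genuine decision),
elevation, a soil index, and a UV-B layer. Fields are low-pass-filtered
Gaussian noise mixed through a Cholesky factor of the target correlation
and rescaled to realistic means and standard deviations; everything is a
pure function of one integer seed.

The default truth is a linear-quadratic response on standardized layers
passed through the cloglog link, with three active variables of eight:
negative linear responses to bio2 and bio9 and a concave quadratic in
elevation. The coefficients (intercept $-4.5$; linear $-2.8$, $-2.2$;
quadratic $-2.5$) are chosen to give a strongly structured, low-prevalence
niche — about 10% of the landscape above HSI 0.2 and 7% above 0.6, with a
truth-score separability (AUC of the truth against its own landscape)
near 0.92. That regime matches the rare-species setting the pipeline
addresses: in the low-prevalence limit the cloglog link is
$\approx e^{\eta}$, so the log-density the sampler realizes is itself
linear-quadratic and parameter recovery is well-posed. Presence sampling
draws cells with probability proportional to truth (a contamination
fraction, default 0.05, drawn uniformly) and jitters one point inside
each cell, matching the one-record-per-cell world that grid thinning
assumes.

What the generator does not emulate: spatial sampling bias, coordinate
uncertainty, GCM physics (futures are shifted/scaled layers), categorical
soil classes, and irregular coastline masks. Passing tests therefore
demonstrate the correctness of the machinery and the statistical
behaviour of the method under its own assumptions, not performance on any
real landscape.

A note on selection consistency: with contaminated sampling the realized
log-density is a log-sum-exp mixture of the linear-quadratic truth and a
uniform floor — a shape hinge features express more parsimoniously than
linear-quadratic ones, so AICc legitimately drifts toward hinge models as
contamination grows. The selection-consistency experiment (which feature
family AICc picks when the truth is LQ) therefore samples without
contamination; the robustness of fitting under contamination is exercised
separately.

## Screening, classification, metrics, conservation

Variable screening follows the two-stage protocol: a preliminary LQ fit at
RM = 1 supplies percent contributions; zero-contribution variables are
dropped; then Pearson correlations over all jointly valid cells flag
pairs with $|r| > 0.80$ (strict), visited in decreasing $|r|$ with an
alphabetical tie-break, dropping the lower-contribution member.

HSI maps are classified with lower-closed brackets at 0.2 / 0.4 / 0.6
(top class closed at 1), the four-level codebook used throughout the
applied literature; the cuts are configuration, with these defaults
asserted in the replication setup. Areas use the spherical-zone cell area
on the R = 6371 km sphere and are reported in units of $10^4$ km$^2$;
change and rate-of-change chain sequentially within each scenario
(current, 2050, 2070, 2090), the only sequencing consistent with the
bundled case-study tables. Rounding to two decimals happens only at
report time.

Niche metrics follow the standard definitions: Schoener's
$D = 1 - \frac{1}{2}\sum_a |P_{ia} - P_{ja}|$ on surfaces normalized over
the joint valid mask; Levins breadth standardized as Shannon entropy over
$\ln R$ so it spans $[0,1]$ (the unnormalized sum is not bounded by 1, so
the standardized form — the one ENMTools reports — is adopted); binary
range overlap at HSI $\ge 0.4$ with the symmetric min-range denominator
(the asymmetric directional variant is computable from the same masks but
is not the default, since a lower-triangle report cannot distinguish
them).

Priority conservation cells are those where at least `min_species`
species (default 2) are moderately or highly suitable; the inclusive
reading ("two or more") is used because with three species a strict
"more than two" would collapse the criterion to triple overlap and
contradict pairwise coexistence mapping. Gap analysis overlays the
priority mask with a protected-area mask and reports
$100 \cdot (1 - \text{overlap}/\text{priority})$. Range centroids are
area-weighted means of cell centers over cells with HSI $\ge 0.2$ (the
total-suitable cutoff, parameterized); shifts are haversine distances and
initial bearings on the R = 6371 km sphere, chained between consecutive
periods within each scenario starting from the current centroid.

## Worked-example replication

The package bundles the printed summary tables of a published
three-species Magnoliaceae habitat study as plain CSVs
(`reference_table()`), and `replicate_worked_examples()` recomputes every
derived quantity from the printed primary columns: 27 change and 27
rate-of-change cells from the totals chain, the 96.84% unprotected share
from the printed priority (54.73) and overlap (1.73) areas, the 21.36%
share of a nominal 960 x 10^4 km^2 land area, and 27 centroid step
distances by haversine from the printed coordinates (within 3%, the
slack owed to 0.01-degree coordinate rounding and the unknown source
projection). Two rate cells in the second species' table are internally
inconsistent with their own printed totals (7.77 vs recomputed 8.02 and
-6.11 vs -5.88); every other derived cell reproduces to its printed
rounding. The recomputed arithmetic is taken as authoritative, and the
replication report shows the per-cell differences rather than hiding
them.

## Problem sizes and determinism

The test suite and acceptance analysis use the default 120 x 90 world
(10,800 cells; backgrounds capped at a seeded 10,000-cell sample, the
MaxEnt convention) with presence sample sizes 41, 12, 79 and 200, a
30 x 40 world for unit-level fitting tests, and 20-seed replication for
stochastic claims — sizes chosen so a full run stays desk-scale while the
spatial structure remains non-trivial. Every stochastic step takes an
explicit integer seed, and the pipeline derives stage seeds from one
master seed, so identical configurations reproduce outputs byte for
byte.

## Known limitations

No categorical features or bias grids; no spatial cross-validation
(replicates are random presence splits); ESRI ASCII is the only raster
interchange format; the sphere (not the WGS84 ellipsoid) is used for all
areas and distances, adequate at the 0.01-degree precision of the
bundled coordinates; AICc model selection with hinge features inherits
the known sensitivity of nonzero-coefficient counting to the knot
roster.
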