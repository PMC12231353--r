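---
title: "Surrogate-model exploration of locking-plate screw orientations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-model exploration of locking-plate screw orientations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screwscape)
```

## The problem

Proximal-humerus fractures fixed with locking plates fail distressingly
often, usually by screw cut-out through the weak bone of the humeral head.
Plates with variable-angle locking screws let the surgeon tilt each screw's
trajectory a few degrees away from the plate's nominal axis, and
finite-element (FE) studies show that those small choices change the
compressive strain in the bone around the screws — a recognised surrogate
for cut-out risk. But seven proximal screws, each tiltable in two planes
over five 5-degree steps, span $(5\times5)^7 \approx 6.1\times10^9$
configurations; no FE budget explores that. `screwscape` implements the
surrogate-modelling strategy for this problem: train small neural networks
on a modest designed sample of simulations, then let the cheap surrogates
sweep a reduced full factorial of $9^7 = 4\,782\,969$ configurations.

Because FE solutions on clinical CT geometry are not reproducible at desk
scale, the package ships a *synthetic strain oracle* — a documented,
parametric response surface standing in for the FE solver — so every stage
of the pipeline (geometry, design, training, exploration, statistics) is
fully testable. All geometry-dependent numbers are fixture-relative; none
are claims about any particular patient or implant.

## Screw geometry

Each proximal screw (ids 6–12, screw 6 the inferior-medial *calcar* screw)
is a capsule: a segment of radius 1.5 mm (a 3 mm-diameter cylinder) from a
fixed head point on the plate to a tip inside the humeral head. The joint
surface is modelled as a sphere; screw length is chosen so the tip stops a
fixed tip-to-joint distance (TJD, default 8 mm) short of the sphere along
the trajectory, by solving the ray–sphere quadratic and taking the far
root.

Tip tilts combine by tangent offsets,
$d(\delta_{dp},\delta_{ap}) = \mathrm{normalize}(n + \tan\delta_{dp}\,u_{dp}
+ \tan\delta_{ap}\,u_{ap})$, over an orthonormal frame
$(n, u_{dp}, u_{ap})$ per screw. Single-axis tilts are then exact rotations
by the stated angle and the composition is order-free — the natural reading
of a tip that moves on a grid. A *collision* is any pair of capsules whose
axis distance falls strictly below the sum of their radii; grazing contact
at exactly the sum does not count (the tie-break must be fixed somewhere,
and grazing contact is numerically unstable under either convention).
Distances use the exact closed-form segment–segment minimum with clamped
parameters; tests verify it against a brute-force nested grid-refinement
sampler, and collision detection against dense sampling on random capsule
pairs.

On a discrete angle grid each screw has only $L^2$ realizable poses, so
pairwise collision is precomputed as 21 boolean lookup tables (an exact
memoisation of the reference test), which makes exhaustive truth
computation over $9^7$ configurations affordable.

### The default fixture

The bundled geometry (`default_geometry()`,
`inst/extdata/geometry_default.json`) is synthetic and documented, not a
proprietary plate: a 40 mm-radius head sphere, seven heads on the lateral
cortex in a plate-like two-column layout, and neutral axes funnelled
convergently toward the medial head. Two properties anchor it: the neutral
configuration is collision-free, and adjacent screws tilted toward one
another (e.g. screws 7 and 8 at +10/−10 anterior–posterior) collide. The
funnel's convergence was calibrated so that roughly 80% of random
Latin-Hypercube tilt combinations collide — the attrition regime the study
design itself reports (500 draws surviving as 92, 7500 as 1341). That
choice matters: the collision boundary's learnability, and therefore every
classifier result below, is a property of this regime, and the package
makes it explicit rather than hiding it in an arbitrary fixture.

## The synthetic strain oracle

The oracle emits magnitudes of the 50th and 90th percentile minimum
principal strain (μstrain) around each screw and pooled over all screws.
It is log-additive: for screw $s$,

$$\log \varepsilon_{50,s} = \log b_s
 + \sum_k g_k\left(c_1\,\delta_{dp,k} + c_2\,\delta_{dp,k}^2
 + c_3\,\delta_{ap,k} + c_4\,\delta_{ap,k}^2\right)
 + \iota\,\mathrm{collision}
 - q \log\!\frac{E_s}{E_{\mathrm{ref},s}},$$

with self-coefficients when $k=s$, cross-coefficients otherwise, and
$g_k$ = `calcar_gain` (default 3) for the calcar screw, 1 otherwise. The
elastic modulus comes from the Morgan power law
$E = 6850\,\rho_{app}^{1.49}$ (MPa from g/cm³), so stiffer local bone means
lower peri-screw strain when the scale exponent $q > 0$. The 90th
percentile is a fixed ratio $\gamma_s > 1$ times the 50th. The pooled
"all-screws" percentile is the equal-weight geometric mean of the per-screw
values — the pooled-population convention is not derivable from first
principles, so it is declared, and everything downstream treats it as the
definition.

The default coefficients are not free knobs: with the calcar gain fixed at
3, the self and cross templates are *solved in closed form* so that the
calcar screw's marginal sweep over the 5-level grid spans −12.78% to
+36.45% on the all-screws 90th-percentile strain and −22.49% to +45.06% on
its own peri-screw strain — the qualitative structure the surface exists to
embody (a dominant calcar screw whose distal tilt raises strain). All
screws share one base template, so the calcar screw's mean absolute
log-effect exceeds every other screw's by exactly the gain factor; tests
assert this identity.

Noise is multiplicative lognormal with **unit median** (not unit mean) and
coefficient of variation `noise_cv` (default 0.02): median-based percentile
outputs compose cleanly, and one shared factor per key pair keeps
$\varepsilon_{90} \ge \varepsilon_{50}$ by construction. Draws are keyed by
`(seed, draw_index)` through a counter-based seed derivation, so records
are reproducible and order-independent.

Two deliberate departures from a literal FE emulation:

* **Colliding configurations get strain values** (inflated by
  $\iota = 0.15$ on the log scale). A real colliding construct cannot be
  simulated, but a 16-input surrogate with a collision input trained only
  on non-colliding rows would see a constant feature. Emitting (inflated)
  strain for colliding rows makes the collision input informative and the
  16- versus 14-input comparison meaningful.
* **The 16-input encoding.** Fourteen angles plus one binary flag is
  fifteen numbers; the stated architecture takes sixteen. The collision
  state is therefore encoded as a complementary indicator pair
  (`collide`, `clear`), preserving the [16, 10, 5, 1] shape and giving the
  binary state full-swing representation on both levels.

## Designs

Training designs are Latin Hypercubes in the 14-dimensional unit cube
snapped to the angle grid by equal-probability binning (each level owns an
equal slice of each axis), which preserves marginal stratification on a
discrete grid; exact duplicate rows are replaced by fresh draws (capped at
100·n attempts). Testing designs use the same machinery on the 3-level
grid. The 80/10/10 split rounds the validation and test sizes and gives the
remainder to training — 1341 rows split as 1073/134/134. The full-factorial
enumerator yields configurations in lexicographic order
(`s6_dp` slowest) in bounded-memory batches; tests check it against a
nested-loop oracle on small grids and count 4 782 969 rows on the reduced
grid.

## Surrogates and trainers

Both surrogate roles are small tanh-hidden, linear-output perceptrons with
min–max input scaling to [−1, 1] fitted on training rows only (regressor
targets likewise). Weights start from Nguyen–Widrow-style initialization
(unit weight vectors renormalized to $0.7\,n_h^{1/n_{in}}$ with spread
biases), which distributes the hidden units' active regions across the
input cube.

* **Collision classifier** [14, 25, 1], trained by Levenberg–Marquardt
  backpropagation on squared error against 0/1 targets, thresholded at 0.5.
  The damping schedule is conventional: $\mu$ starts at $10^{-3}$, ×10 on a
  rejected step, ×0.1 on an accepted one, stop on $\mu > 10^{10}$, gradient
  below $10^{-7}$, or six consecutive validation-SSE increases (restoring
  the best-validation weights).
* **Strain regressors** [16 or 14, 10, 5, 1], trained by Bayesian
  regularization: Levenberg–Marquardt steps on
  $F = \beta E_D + \alpha E_W$, where $E_W$ penalises connection weights
  only (biases are location parameters), with MacKay evidence updates
  $\gamma = P_w - \alpha\,\mathrm{tr}_w(H^{-1})$,
  $\alpha \leftarrow \gamma / 2E_W$,
  $\beta \leftarrow (N - \gamma)/2E_D$ after each accepted step. No
  validation set is consumed; validation rows fold into training, the
  standard behaviour of the method. Tests pin the contracts: the analytic
  Jacobian matches finite differences, a linear toy is solved to machine
  precision, $0 < \gamma < P_w$ throughout, and the regulariser does not
  lose to plain Levenberg–Marquardt on held-out error over a noisy toy.

Replicate training repeats the fit from distinct seeds (the study protocol
uses 100; the package exposes `n_replicates`) and reports the best model
alongside the replicate mean. **Selection uses the external testing set**,
mirroring the study's reporting; that is optimistic — the selected model's
score on the same set it won is biased upward — and the documentation says
so rather than silently switching to a cleaner protocol.

## Evaluation statistics

`regression_metrics` reports $R^2$ (on residuals $\hat y - y$), the OLS
slope of predictions on observations, RMSE in μstrain, and RMSE as a
percentage of the observed range of the true values — the "% strain"
normalisation is not uniquely defined by the study's tables, so the range
convention is declared. `classification_table` reports percent true/false.
Group contrasts use Welch's unequal-variance $t$ (two-sided), the robust
default when group sizes differ by orders of magnitude, with raw p-values
against fixed thresholds (0.001 for heatmap cells, 0.05 for range
comparisons); no multiple-testing correction, deliberately matching the
reporting style the tables emulate.

The full-factorial heatmap streams the $9^7$ configurations in batches,
drops predicted-colliding ones, and accumulates exact running moments
(count, mean, centred sum of squares) per screw and tip state. Because a
Welch test needs only those moments, the per-cell tests are computed
**exactly from the accumulators** rather than from the originally planned
fixed-size reservoir subsamples — strictly more accurate and cheaper;
reservoir sampling is kept only for the optional median-centred heatmap,
whose centres are then approximate for groups larger than the reservoir.
Cells whose configurations all collide are flagged invalid rather than
silently dropped.

## Problem sizes and numerical choices

The test suite runs the full protocol at the study's data scale (1341
training rows, 91-row testing designs, best-of-20 replicate selection, 10-
and 20-seed repetition loops, the complete $9^7$ exploration) but with 2
replicates per surrogate inside the 20-seed dominance loop — sizes chosen
to keep a laptop run comfortable while leaving every statistical contrast
well-powered. Degenerate inputs fail loudly: rays that miss the joint
sphere, heads too close to it, constant regression targets, degenerate
variances, and empty splits are all errors with named causes, not NaNs.

## What passing tests do and do not show

The oracle is smooth, log-additive, and noise-controlled; real FE strain
fields have mesh effects, contact nonlinearity, density heterogeneity and
load-case sensitivity that it does not emulate. Passing recovery tests
therefore shows that *the pipeline faithfully recovers the structure it was
pointed at* — calcar dominance, effect ranges, collision structure — not
that a clinical plate behaves like the fixture. Absolute strain magnitudes,
densities and attrition counts are fixture-relative by design.

Two honest limitations deserve emphasis. First, the collision classifier
plateaus at roughly 78–89% accuracy (best-of-20 across seeds, median
~84.6%) on 91-row testing designs under the fixture's high-attrition
regime; this mirrors the accuracy ceiling the emulated study itself reports
(82.6–84.4%, improving little with training-set size), and appears to be
an information limit of ~1341 Latin-Hypercube rows against a 21-pair
collision boundary rather than a trainer defect — a 400-tree random forest
does no better. Second, best-model selection on the testing set inflates
the reported best scores; the replicate means printed alongside are the
honest central estimates.
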