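# screwscape

Surrogate-model exploration of how locking-plate screw orientations affect
peri-screw bone strain in the proximal humerus.

Variable-angle locking plates let each of the seven proximal screws tilt up
to ±10° in 5° steps in two planes, giving (5×5)⁷ ≈ 6.1 × 10⁹ possible
configurations — far beyond any finite-element (FE) budget, even though the
compressive strain around the screws predicts cut-out failure. The package
implements the surrogate strategy for this problem, aimed at computational
biomechanics researchers who want the whole pipeline testable on a desk:

* a parametric capsule model of the seven screws — fixed head points,
  tangent-offset tip tilts `normalize(n + tan(δ_dp)·u_dp + tan(δ_ap)·u_ap)`,
  screw lengths solved so every tip stops 8 mm short of the spherical joint
  surface (tip-to-joint distance), and exact segment–segment collision
  detection;
* a synthetic strain oracle standing in for the FE solver: a log-additive
  response surface over the 14 tilt angles with a dominant calcar screw
  (screw 6), a collision term, the Morgan density–modulus law
  `E = 6850·ρ_app^1.49`, and unit-median lognormal noise;
* design-of-experiments tools: grid-snapped Latin Hypercube training
  designs, random testing designs, 80/10/10 splits, and a memory-bounded
  full-factorial enumerator over 9⁷ = 4 782 969 configurations;
* from-scratch multilayer-perceptron surrogates in the classic R modelling
  idiom (`mlp_fit()` returning an S3 object with `predict`, `print`,
  `summary`, `coef`, `residuals`, `plot` methods): a [14, 25, 1] collision
  classifier trained by Levenberg–Marquardt backpropagation
  (Δw = −(JᵀJ + μI)⁻¹Jᵀe with adaptive damping), and [16, 10, 5, 1] strain
  regressors trained by Bayesian regularization (MacKay evidence updates of
  α, β via the effective parameter count γ);
* the evaluation statistics of the study design: accuracy tables, R²/slope/
  RMSE, Welch t-tests, streamed per-screw strain-variation heatmaps over
  the full factorial with significance versus neutral, and strain-range
  comparisons between designs.

## Worked example

```r
library(screwscape)

geom <- default_geometry()                      # documented synthetic plate
cfg <- setNames(rep(0, 14), config_names())
cfg["s6_dp"] <- -10                             # calcar screw tilted distally
real <- realize_configuration(geom, cfg)

base <- strain_response(setNames(rep(0, 14), config_names()), 0, oracle_params())
tilt <- strain_response(cfg, 0, oracle_params())

train <- generate_dataset(lhs_design(400, design_grid(), seed = 1),
                          geom, oracle_params())
x   <- strain16_inputs(train[, config_names()], train$collision)
fit <- mlp_fit(x, train$e90_all, hidden = c(10, 5), seed = 1)

test <- generate_dataset(random_design(100, seed = 2), geom,
                         oracle_params(), draw_offset = 400)
regression_metrics(test$e90_all,
                   predict(fit, strain16_inputs(test[, config_names()],
                                                test$collision)))
```

which prints

```
collision: FALSE; screw 6 length: 70.9 mm
e90_all neutral: 2998 ustrain; calcar tilted distal: 4091 ustrain (+36.4%)
331 of 400 configurations collide
Feed-forward surrogate (regressor, Bayesian regularization)
  architecture: 16-10-5-1 (231 parameters)
  epochs run: 19   final objective: 200
  effective parameters gamma: 15.06 of 215 weights
held-out R2 0.872, slope 0.814, RMSE 361 ustrain (8.3% of range)
```

Reading it: tilting the calcar screw distally raises the pooled
90th-percentile strain magnitude by ~36% over neutral — the dominant-screw
effect the oracle embeds. About 83% of random tilt combinations collide
(the high-attrition regime of the emulated study design), and a single
400-row fit already tracks the surface at R² ≈ 0.87; at study scale (1341
rows, best of 20 replicates) the regressors reach R² ≈ 0.985 with slope
≈ 0.98. `run_pipeline()` chains all stages — designs, oracle simulation,
replicate training, evaluation, the 9⁷ exploration heatmap and range
comparison — into one reproducible, manifest-tracked run.

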