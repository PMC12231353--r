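test_that("the Morgan power law is exact and monotone", {
  expect_equal(density_to_modulus(1), 6850)
  expect_equal(density_to_modulus(0), 0)
  expect_equal(density_to_modulus(0.5), exp(log(6850) + 1.49 * log(0.5)),
               tolerance = 1e-12)
  expect_error(density_to_modulus(-0.1), "non-negative")
  rho <- seq(0, 2, length.out = 1000)
  expect_true(all(diff(density_to_modulus(rho)) > 0))
})

test_that("the neutral configuration returns the baseline strains exactly", {
  p <- oracle_params()
  r <- strain_response(neutral_config(), 0, p)
  for (k in 1:7)
    expect_equal(r[[paste0("e50_s", k + 5)]], unname(p$baseline_strain[k]))
  expect_equal(r$e90_s6, unname(p$baseline_strain[1] * p$gamma[1]))
})

test_that("the response is log-additive: scaling a baseline scales its outputs", {
  p <- oracle_params()
  p2 <- p; p2$baseline_strain["s8"] <- 2 * p$baseline_strain["s8"]
  cfg <- neutral_config(); cfg["s6_dp"] <- -10; cfg["s10_ap"] <- 5
  r1 <- strain_response(cfg, 0, p)
  r2 <- strain_response(cfg, 0, p2)
  expect_equal(r2$e50_s8, 2 * r1$e50_s8, tolerance = 1e-12)
  expect_equal(r2$e90_s8, 2 * r1$e90_s8, tolerance = 1e-12)
  expect_equal(r2$e50_s7, r1$e50_s7)    # other screws untouched
})

test_that("e90 dominates e50 for every key on random configurations", {
  p <- oracle_params()
  set.seed(1)
  A <- matrix(sample(c(-10, -5, 0, 5, 10), 14 * 200, TRUE), ncol = 200 / 200 * 14)
  colnames(A) <- config_names()
  r <- strain_response(A, rep(c(0, 1), length.out = nrow(A)), p)
  expect_true(all(r[, 9:16] >= r[, 1:8]))
  expect_true(all(r > 0))
})

test_that("the calcar screw marginal spans the calibrated variation ranges", {
  p <- oracle_params()
  r0 <- strain_response(neutral_config(), 0, p)
  grid <- expand.grid(dp = c(-10, -5, 0, 5, 10), ap = c(-10, -5, 0, 5, 10))
  A <- matrix(0, nrow(grid), 14, dimnames = list(NULL, config_names()))
  A[, "s6_dp"] <- grid$dp; A[, "s6_ap"] <- grid$ap
  r <- strain_response(A, 0, p)
  v_all <- 100 * (r$e90_all / r0$e90_all - 1)
  expect_equal(max(v_all), 36.45, tolerance = 0.01)
  expect_equal(min(v_all), -12.78, tolerance = 0.01)
  v_self <- 100 * (r$e90_s6 / r0$e90_s6 - 1)
  expect_equal(max(v_self), 45.06, tolerance = 0.01)
  expect_equal(min(v_self), -22.49, tolerance = 0.01)
  # the distal tilt is the strain-raising direction
  cfg <- neutral_config(); cfg["s6_dp"] <- -10
  expect_equal(strain_response(cfg, 0, p)$e90_all / r0$e90_all - 1, 0.3645,
               tolerance = 1e-3)
})

test_that("screw 6's marginal log-effect exceeds every other screw's by the calcar gain", {
  p <- oracle_params()
  base <- log(strain_response(neutral_config(), 0, p)$e50_all)
  eff <- vapply(6:12, function(id) {
    cfg <- neutral_config(); cfg[paste0("s", id, "_dp")] <- -10
    abs(log(strain_response(cfg, 0, p)$e50_all) - base)
  }, numeric(1))
  ratios <- eff[1] / eff[-1]
  expect_equal(unname(ratios), rep(p$calcar_gain, 6), tolerance = 1e-9)
})

test_that("raising local density (stiffer bone) strictly lowers peri-screw strain", {
  p <- oracle_params()
  p2 <- p; p2$rho_app["s9"] <- p$rho_app["s9"] * 1.3
  r1 <- strain_response(neutral_config(), 0, p)
  r2 <- strain_response(neutral_config(), 0, p2)
  expect_lt(r2$e50_s9, r1$e50_s9)
  expect_equal(r2$e50_s7, r1$e50_s7)
})

test_that("collision inflates every strain output by the configured log bump", {
  p <- oracle_params()
  cfg <- neutral_config()
  r0 <- strain_response(cfg, 0, p); r1 <- strain_response(cfg, 1, p)
  expect_equal(unlist(r1) / unlist(r0),
               setNames(rep(exp(p$collision_inflation), 16), names(unlist(r0))),
               tolerance = 1e-12)
})

test_that("noise draws are reproducible, order-independent and unit-median", {
  p <- oracle_params(noise_cv = 0.1)
  cfg <- neutral_config(); cfg["s7_dp"] <- 5
  r1 <- sample_record(cfg, 0, p, draw_index = 3)
  r2 <- sample_record(cfg, 0, p, draw_index = 3)
  expect_identical(r1, r2)
  expect_false(identical(r1, sample_record(cfg, 0, p, draw_index = 4)))
  # cv = 0 degenerates to the noise-free response
  p0 <- oracle_params(noise_cv = 0)
  expect_identical(sample_record(cfg, 0, p0, 1), strain_response(cfg, 0, p0))
  # unit median over many draws
  draws <- vapply(1:4000, function(i) sample_record(cfg, 0, p, i)$e50_all,
                  numeric(1))
  truth <- strain_response(cfg, 0, p)$e50_all
  expect_equal(median(draws) / truth, 1, tolerance = 0.01)
  # e90 >= e50 survives noise (shared factor per key)
  r <- sample_record(cfg, 0, p, 17)
  expect_true(all(r[, 9:16] >= r[, 1:8]))
})

test_that("generate_dataset labels rows with the true geometric collision flag", {
  g <- default_geometry()
  p <- oracle_params(noise_cv = 0)
  d <- lhs_design(60, design_grid(), seed = 5)
  dat <- generate_dataset(d, g, p)
  expect_equal(dim(dat), c(60, 14 + 1 + 16))
  expect_named(dat, c(config_names(), "collision", strain_columns()))
  slow <- vapply(seq_len(60), function(i)
    realize_configuration(g, d[i, ])$flag, logical(1))
  expect_equal(dat$collision, as.integer(slow))
  # noise-free duplicates give duplicate strain rows
  dat2 <- generate_dataset(d[c(1, 1), ], g, p)
  expect_identical(unlist(dat2[1, -(1:15)], use.names = FALSE),
                   unlist(dat2[2, -(1:15)], use.names = FALSE))
})

test_that("oracle parameters round-trip through JSON", {
  p <- oracle_params(calcar_gain = 4, noise_cv = 0.05, seed = 77L)
  path <- withr::local_tempfile(fileext = ".json")
  write_oracle_params(p, path)
  p2 <- read_oracle_params(path)
  for (f in names(p)) expect_equal(p2[[f]], p[[f]], tolerance = 1e-12)
})
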