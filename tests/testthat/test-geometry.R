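test_that("tilt_direction composes tangent offsets and is exact on single axes", {
  a <- unit_anchor()
  expect_identical(tilt_direction(a, 0, 0), a$neutral_axis)
  # single-axis tilt is an exact rotation by the stated angle
  d10 <- tilt_direction(a, 10, 0)
  expect_equal(vnorm_test(d10), 1, tolerance = 1e-12)
  ang <- acos(sum(d10 * a$neutral_axis)) * 180 / pi
  expect_equal(ang, 10, tolerance = 1e-9)
  # simultaneous tilts combine as atan(sqrt(tan^2 + tan^2))
  d2 <- tilt_direction(a, 10, 10)
  ang2 <- acos(sum(d2 * a$neutral_axis)) * 180 / pi
  expect_equal(ang2, atan(sqrt(2 * tan(10 * pi / 180)^2)) * 180 / pi,
               tolerance = 1e-9)
})

test_that("tilt_direction is inverse-symmetric about neutral", {
  a <- unit_anchor()
  for (dp in c(-10, -5, 5, 10)) for (ap in c(-10, 0, 10)) {
    ang_pos <- acos(sum(tilt_direction(a, dp, ap) * a$neutral_axis))
    ang_neg <- acos(sum(tilt_direction(a, -dp, -ap) * a$neutral_axis))
    expect_equal(ang_pos, ang_neg, tolerance = 1e-12)
  }
})

test_that("solve_length returns far intersection minus the tip-to-joint distance", {
  sph <- list(center = c(0, 0, 0), radius = 25)
  # head at the sphere center: t* = R by symmetry
  expect_equal(solve_length(c(0, 0, 0), c(0, 0, -1), sph, 8), 17)
  # head on the surface pointing at the center: full chord
  expect_equal(solve_length(c(0, 0, 25), c(0, 0, -1), sph, 8), 42)
  # head 10 mm off-center, direction perpendicular to the center-head line
  expect_equal(solve_length(c(10, 0, 0), c(0, 0, 1), sph, 8),
               sqrt(25^2 - 10^2) - 8, tolerance = 1e-12)
})

test_that("solve_length shifts exactly with the head along a fixed direction", {
  sph <- list(center = c(1, 2, 3), radius = 30)
  dir <- normalize_test(c(0.2, -0.4, -1))
  head <- c(2, 1, 40)
  l0 <- solve_length(head, dir, sph, 8)
  l1 <- solve_length(head - dir, dir, sph, 8)   # 1 mm backward
  expect_equal(l1 - l0, 1, tolerance = 1e-9)
})

test_that("solve_length rejects rays that miss the joint or start too deep", {
  sph <- list(center = c(0, 0, 0), radius = 25)
  expect_error(solve_length(c(30, 0, 0), c(0, 0, 1), sph, 8),
               "misses joint surface")
  expect_error(solve_length(c(0, 0, 24), c(0, 0, -1), sph, 60),
               "too close to joint")
})

test_that("segment_distance handles parallel, touching and skew cases", {
  expect_equal(segment_distance(c(0, 0, 0), c(1, 0, 0),
                                c(0, 2.9, 0), c(1, 2.9, 0)), 2.9)
  expect_equal(segment_distance(c(0, 0, 0), c(1, 1, 1),
                                c(1, 1, 1), c(2, 0, 5)), 0)
  # skew pair with a known closest approach
  expect_equal(segment_distance(c(0, 0, 0), c(10, 0, 0),
                                c(5, 3, 4), c(5, 3, -4)), 3)
  # degenerate: point vs segment
  expect_equal(segment_distance(c(0, 5, 0), c(0, 5, 0),
                                c(-1, 0, 0), c(1, 0, 0)), 5)
  # symmetry in arguments
  p <- random_capsule_pair(7)
  expect_identical(segment_distance(p$p1, p$q1, p$p2, p$q2),
                   segment_distance(p$p2, p$q2, p$p1, p$q1))
})

test_that("segment_distance matches a brute-force refinement oracle", {
  for (s in 1:200) {
    p <- random_capsule_pair(s)
    expect_equal(segment_distance(p$p1, p$q1, p$p2, p$q2),
                 brute_segment_distance(p$p1, p$q1, p$p2, p$q2),
                 tolerance = 1e-3)
  }
})

test_that("detect_collision flags overlapping capsules and is order-invariant", {
  mk <- function(id, head, tip, r = 1.5)
    list(screw_id = id, head = head, tip = tip, radius = r)
  apart <- list(mk(6, c(0, 0, 0), c(0, 0, 10)), mk(7, c(5, 0, 0), c(5, 0, 10)))
  expect_false(detect_collision(apart)$flag)
  coaxial <- list(mk(6, c(0, 0, 0), c(0, 0, 10)), mk(7, c(0, 0, 5), c(0, 0, 15)))
  res <- detect_collision(coaxial)
  expect_true(res$flag)
  expect_equal(unname(res$pairs[1, ]), c(6, 7))
  # permutation invariance
  three <- list(mk(8, c(9, 0, 0), c(9, 0, 10)), coaxial[[2]], coaxial[[1]])
  res2 <- detect_collision(three)
  expect_equal(res2$pairs, res$pairs)
})

test_that("inflating radii never clears a collision", {
  for (s in 1:50) {
    p <- random_capsule_pair(s + 500)
    mk <- function(id, head, tip, r) list(screw_id = id, head = head,
                                          tip = tip, radius = r)
    small <- detect_collision(list(mk(6, p$p1, p$q1, p$r1), mk(7, p$p2, p$q2, p$r2)))
    big <- detect_collision(list(mk(6, p$p1, p$q1, p$r1 * 2), mk(7, p$p2, p$q2, p$r2 * 2)))
    if (small$flag) expect_true(big$flag)
  }
})

test_that("the default fixture is collision-free at neutral and collides on convergence", {
  g <- default_geometry()
  r <- realize_configuration(g, neutral_config())
  expect_length(r$poses, 7)
  expect_false(r$flag)
  # tip-to-joint constraint holds along each screw's trajectory
  for (p in r$poses) {
    t_exit <- solve_length(p$head, p$direction, g$sphere, 0)
    expect_equal(t_exit - p$length, g$tjd, tolerance = 1e-6)
    expect_equal(p$tip, p$head + p$length * p$direction, tolerance = 1e-9)
    expect_lt(vnorm_test(p$tip - g$sphere$center), g$sphere$radius)
  }
  # screws 7 and 8 tilted towards one another collide
  cfg <- neutral_config()
  cfg["s7_ap"] <- 10; cfg["s8_ap"] <- -10
  r2 <- realize_configuration(g, cfg)
  expect_true(r2$flag)
  expect_true(any(r2$pairs[, 1] == 7 & r2$pairs[, 2] == 8))
})

test_that("changing one screw leaves the other six poses bit-identical", {
  g <- default_geometry()
  r0 <- realize_configuration(g, neutral_config())
  cfg <- neutral_config(); cfg["s9_ap"] <- 5
  r1 <- realize_configuration(g, cfg)
  for (i in which(6:12 != 9))
    expect_identical(r0$poses[[i]], r1$poses[[i]])
  expect_false(identical(r0$poses[[4]], r1$poses[[4]]))
})

test_that("grid collision tables reproduce the reference pairwise test", {
  g <- default_geometry()
  tabs <- collision_tables(g, c(-10, 0, 10))
  set.seed(42)
  A <- matrix(sample(c(-10, 0, 10), 14 * 40, replace = TRUE), ncol = 14)
  colnames(A) <- config_names()
  fast <- config_collides(tabs, A)
  slow <- vapply(seq_len(nrow(A)), function(i)
    realize_configuration(g, A[i, ])$flag, logical(1))
  expect_identical(fast, slow)
})

test_that("geometry round-trips through its JSON schema", {
  g <- default_geometry()
  path <- withr::local_tempfile(fileext = ".json")
  write_geometry(g, path)
  g2 <- read_geometry(path)
  expect_equal(g2$sphere, g$sphere)
  expect_equal(g2$tjd, g$tjd)
  for (i in 1:7) expect_equal(g2$screws[[i]], g$screws[[i]], tolerance = 1e-12)
})
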