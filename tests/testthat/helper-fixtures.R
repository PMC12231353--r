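# Shared fixtures built in code.

vnorm_test <- function(v) sqrt(sum(v * v))
normalize_test <- function(v) v / vnorm_test(v)

# deterministic per-stage seeds for multi-seed protocol tests
child_seed_test <- function(seed, stage) screwscape:::child_seed(seed, stage)

# An anchor with the canonical axis frame, head at the origin.
unit_anchor <- function(id = 6, head = c(0, 0, 0), radius = 1.5) {
  screw_anchor(id, head,
               neutral_axis = c(0, 0, -1),
               u_dp = c(0, 1, 0),
               u_ap = c(1, 0, 0),
               radius = radius)
}

# The neutral 14-angle configuration.
neutral_config <- function() setNames(rep(0, 14), config_names())

# Brute-force minimum distance between two segments by nested grid
# refinement down to `res` parameter resolution: an oracle independent of
# the closed-form path.
brute_segment_distance <- function(p1, q1, p2, q2, res = 1e-4, levels = 5) {
  d1 <- q1 - p1; d2 <- q2 - p2
  lo_s <- 0; hi_s <- 1; lo_t <- 0; hi_t <- 1
  n <- 41
  for (lev in seq_len(levels)) {
    s <- seq(lo_s, hi_s, length.out = n)
    t <- seq(lo_t, hi_t, length.out = n)
    P1 <- outer(s, d1[1]) + p1[1]; P2 <- outer(s, d1[2]) + p1[2]
    P3 <- outer(s, d1[3]) + p1[3]
    Q1 <- outer(t, d2[1]) + p2[1]; Q2 <- outer(t, d2[2]) + p2[2]
    Q3 <- outer(t, d2[3]) + p2[3]
    D2 <- outer(P1[, 1], Q1[, 1], `-`)^2 + outer(P2[, 1], Q2[, 1], `-`)^2 +
      outer(P3[, 1], Q3[, 1], `-`)^2
    ij <- which(D2 == min(D2), arr.ind = TRUE)[1, ]
    step_s <- (hi_s - lo_s) / (n - 1); step_t <- (hi_t - lo_t) / (n - 1)
    lo_s <- max(0, s[ij[1]] - step_s); hi_s <- min(1, s[ij[1]] + step_s)
    lo_t <- max(0, t[ij[2]] - step_t); hi_t <- min(1, t[ij[2]] + step_t)
    if (step_s <= res && step_t <= res) break
  }
  sqrt(min(D2))
}

# Random capsule-pair generator for collision property tests.
random_capsule_pair <- function(seed) {
  set.seed(seed)
  p1 <- runif(3, -10, 10); q1 <- p1 + runif(3, -15, 15)
  p2 <- runif(3, -10, 10); q2 <- p2 + runif(3, -15, 15)
  list(p1 = p1, q1 = q1, p2 = p2, q2 = q2,
       r1 = runif(1, 0.5, 3), r2 = runif(1, 0.5, 3))
}
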