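# Parametric 3-D model of the seven proximal screws: capsules anchored at
# fixed head points on the plate, tips tiltable on a discrete angle grid,
# lengths solved so every tip sits a fixed tip-to-joint distance (TJD) short
# of the humeral-head joint sphere, plus exact screw-screw collision
# detection.
#
# Coordinate convention (right-handed, mm): x = anterior, y = proximal,
# z = lateral. The joint surface is modelled as a sphere.

SCREW_IDS <- 6:12

#' Column names of the 14-dimensional screw-orientation configuration
#'
#' Two tilt angles per proximal screw, in fixed order: `s6_dp, s6_ap, ...,
#' s12_dp, s12_ap`. `dp` is the distal (-) to proximal (+) tip tilt, `ap`
#' posterior (-) to anterior (+), both in degrees.
#'
#' @return Character vector of length 14.
#' @export
config_names <- function() {
  as.vector(t(outer(SCREW_IDS, c("dp", "ap"), function(i, a) sprintf("s%d_%s", i, a))))
}

#' Construct a screw anchor
#'
#' An anchor fixes a screw's head point on the plate together with the
#' orthonormal frame `(neutral_axis, u_dp, u_ap)` that parameterises tip
#' tilts, and the screw radius.
#'
#' @param screw_id Integer label in 6..12 (screw 6 is the calcar screw).
#' @param head Numeric length-3, head point (mm).
#' @param neutral_axis Unit length-3 direction of the 0-0 screw.
#' @param u_dp Unit length-3 tilt axis: tip motion for positive (proximal) dp.
#' @param u_ap Unit length-3 tilt axis: tip motion for positive (anterior) ap.
#' @param radius Screw radius in mm (default 1.5, a 3 mm diameter cylinder).
#' @return An object of class `screw_anchor`.
#' @export
screw_anchor <- function(screw_id, head, neutral_axis, u_dp, u_ap, radius = 1.5) {
  screw_id <- as.integer(screw_id)
  head <- as.numeric(head); neutral_axis <- as.numeric(neutral_axis)
  u_dp <- as.numeric(u_dp); u_ap <- as.numeric(u_ap)
  stopifnot(length(head) == 3, length(neutral_axis) == 3,
            length(u_dp) == 3, length(u_ap) == 3)
  stopifnot_finite(c(head, neutral_axis, u_dp, u_ap, radius), "anchor geometry")
  tol <- 1e-9
  if (abs(vnorm(neutral_axis) - 1) > tol || abs(vnorm(u_dp) - 1) > tol ||
      abs(vnorm(u_ap) - 1) > tol)
    stop("neutral_axis, u_dp and u_ap must be unit vectors")
  if (abs(sum(neutral_axis * u_dp)) > tol || abs(sum(neutral_axis * u_ap)) > tol ||
      abs(sum(u_dp * u_ap)) > tol)
    stop("neutral_axis, u_dp and u_ap must be mutually orthogonal")
  if (radius <= 0) stop("radius must be positive")
  structure(list(screw_id = screw_id, head = head, neutral_axis = neutral_axis,
                 u_dp = u_dp, u_ap = u_ap, radius = radius),
            class = "screw_anchor")
}

# Build an anchor whose neutral axis points from `head` towards `target`,
# with u_dp chosen in the proximal (+y) half-plane and u_ap anterior (+x).
anchor_towards <- function(screw_id, head, target, radius = 1.5) {
  n <- normalize(target - head)
  ey <- c(0, 1, 0); ex <- c(1, 0, 0)
  u_dp <- ey - sum(ey * n) * n
  if (vnorm(u_dp) < 1e-8) u_dp <- ex - sum(ex * n) * n  # axis nearly proximal
  u_dp <- normalize(u_dp)
  u_ap <- vcross(n, u_dp)
  if (sum(u_ap * ex) < 0) u_ap <- -u_ap
  # re-orthogonalise u_dp so the frame is exactly right for any u_ap flip
  u_dp <- normalize(vcross(u_ap, n))
  if (sum(u_dp * ey) < 0) u_dp <- -u_dp
  screw_anchor(screw_id, head, n, u_dp, u_ap, radius)
}

#' Default plate-and-humerus fixture geometry
#'
#' A documented synthetic stand-in for a proximal-humerus locking plate: the
#' humeral head is a 40 mm-radius sphere at the origin, and the seven screw
#' heads sit on the lateral cortex (z = +44 mm) in a plate-like two-column
#' layout, with neutral axes funnelled convergently into the head. Screw 6
#' (calcar) is the inferior-medial screw. The neutral configuration is
#' collision-free and adjacent screws tilted towards one another collide;
#' the convergent funnel puts random tilt combinations in a high-attrition
#' regime (roughly four of five Latin-Hypercube draws collide), the regime
#' the study's design attrition reflects.
#'
#' @param radius Screw radius in mm.
#' @return A `screw_geometry` list with elements `sphere` (center, radius),
#'   `tjd` (mm) and `screws` (list of [screw_anchor()]).
#' @export
default_geometry <- function(radius = 1.5) {
  heads <- list(
    `6`  = c( 0.0, -14, 44),
    `7`  = c(-3.5,  -7, 44),
    `8`  = c( 3.5,  -7, 44),
    `9`  = c(-3.5,   2, 44),
    `10` = c( 3.5,   2, 44),
    `11` = c(-3.5,  10, 44),
    `12` = c( 3.5,  10, 44))
  targets <- list(
    `6`  = c( 0.0, -9.6, 0),
    `7`  = c(-4.2, -4.2, 0),
    `8`  = c( 4.2, -4.2, 0),
    `9`  = c(-5.4,  1.8, 0),
    `10` = c( 5.4,  1.8, 0),
    `11` = c(-4.2,  8.4, 0),
    `12` = c( 4.2,  8.4, 0))
  screws <- lapply(SCREW_IDS, function(id) {
    k <- as.character(id)
    anchor_towards(id, heads[[k]], targets[[k]], radius)
  })
  structure(list(sphere = list(center = c(0, 0, 0), radius = 40),
                 tjd = 8, screws = screws),
            class = "screw_geometry")
}

#' Read / write a geometry configuration as JSON
#'
#' The schema stores the sphere (`center`, `radius_mm`), `tjd_mm` and one
#' record per screw (`id`, `head`, `neutral_axis`, `u_dp`, `u_ap`,
#' `radius_mm`), all coordinates in mm.
#'
#' @param path File path.
#' @return `read_geometry` returns a `screw_geometry`; `write_geometry`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  screws <- lapply(seq_len(nrow(j$screws)), function(i) {
    s <- j$screws[i, ]
    screw_anchor(s$id, unlist(s$head), unlist(s$neutral_axis),
                 unlist(s$u_dp), unlist(s$u_ap), s$radius_mm)
  })
  structure(list(sphere = list(center = as.numeric(unlist(j$sphere$center)),
                               radius = as.numeric(j$sphere$radius_mm)),
                 tjd = as.numeric(j$tjd_mm), screws = screws),
            class = "screw_geometry")
}

#' @rdname read_geometry
#' @param geometry A `screw_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  out <- list(
    sphere = list(center = geometry$sphere$center, radius_mm = geometry$sphere$radius),
    tjd_mm = geometry$tjd,
    screws = lapply(geometry$screws, function(s) list(
      id = s$screw_id, head = s$head, neutral_axis = s$neutral_axis,
      u_dp = s$u_dp, u_ap = s$u_ap, radius_mm = s$radius)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tilted screw direction
#'
#' Composes distal-proximal and anterior-posterior tip tilts by tangent
#' offsets along the anchor's tilt axes:
#' `normalize(neutral_axis + tan(dp) * u_dp + tan(ap) * u_ap)`. Single-axis
#' tilts are exact rotations by the stated angle; the composition is
#' order-free. `(0, 0)` returns the neutral axis exactly.
#'
#' @param anchor A [screw_anchor()].
#' @param dp_deg,ap_deg Tilt angles in degrees, |angle| well below 90.
#' @return Unit length-3 direction.
#' @export
tilt_direction <- function(anchor, dp_deg, ap_deg) {
  if (dp_deg == 0 && ap_deg == 0) return(anchor$neutral_axis)
  normalize(anchor$neutral_axis +
            tan(deg2rad(dp_deg)) * anchor$u_dp +
            tan(deg2rad(ap_deg)) * anchor$u_ap)
}

#' Solve screw length under the tip-to-joint-distance constraint
#'
#' Intersects the ray `head + t * direction` with the joint sphere and
#' returns `t* - tjd`, where `t*` is the far (exit) intersection, so the tip
#' stops `tjd` mm short of the joint surface along the screw axis.
#'
#' @param head Numeric length-3 head point (mm).
#' @param direction Unit length-3 screw direction.
#' @param sphere List with `center` (length-3) and `radius` (mm).
#' @param tjd Tip-to-joint distance in mm (>= 0).
#' @return Screw length in mm (> 0).
#' @export
solve_length <- function(head, direction, sphere, tjd = 8) {
  stopifnot(tjd >= 0)
  m <- head - sphere$center
  b <- sum(m * direction)
  cc <- sum(m * m) - sphere$radius^2
  disc <- b * b - cc
  if (disc < 0) stop("trajectory misses joint surface", call. = FALSE)
  tstar <- -b + sqrt(disc)
  if (tstar <= 0) stop("trajectory misses joint surface", call. = FALSE)
  len <- tstar - tjd
  if (len <= 0) stop("screw head too close to joint", call. = FALSE)
  len
}

#' Minimum distance between two 3-D segments
#'
#' Exact closed-form minimum Euclidean distance between the closed segments
#' `p1-q1` and `p2-q2`, handling degenerate (point) and parallel cases.
#'
#' @param p1,q1,p2,q2 Numeric length-3 segment endpoints (mm).
#' @return Distance in mm.
#' @export
segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(vnorm(p1 - p2))
  if (a <= eps) {              # first segment degenerate
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    cc <- sum(d1 * r)
    if (e <= eps) {            # second segment degenerate
      t <- 0; s <- min(max(-cc / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > eps * a * e) min(max((b * f - cc * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  vnorm((p1 + s * d1) - (p2 + t * d2))
}

#' Detect screw-screw collisions among realized poses
#'
#' Screws are modelled as capsules (their axis segment plus radius); a
#' collision is any pair whose axis distance is strictly below the sum of the
#' radii (grazing contact at exactly the sum is not a collision).
#'
#' @param poses List of poses as returned by [realize_configuration()], each
#'   with `screw_id`, `head`, `tip`, `radius`.
#' @return List with `flag` (logical) and `pairs` (2-column integer matrix of
#'   colliding screw-id pairs, 0 rows if none).
#' @export
detect_collision <- function(poses) {
  stopifnot(length(poses) >= 2)
  ids <- vapply(poses, function(p) as.integer(p$screw_id), integer(1))
  ord <- order(ids)  # permutation-invariant output
  poses <- poses[ord]; ids <- ids[ord]
  n <- length(poses)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("id_a", "id_b")))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- segment_distance(poses[[i]]$head, poses[[i]]$tip,
                          poses[[j]]$head, poses[[j]]$tip)
    if (d < poses[[i]]$radius + poses[[j]]$radius)
      pairs <- rbind(pairs, c(ids[i], ids[j]))
  }
  list(flag = nrow(pairs) > 0, pairs = pairs)
}

#' Realize a configuration: poses, lengths and collision state
#'
#' Applies [tilt_direction()] and [solve_length()] to every screw of a
#' 14-angle configuration, then runs [detect_collision()] on the resulting
#' capsules.
#'
#' @param geometry A `screw_geometry` (see [default_geometry()]).
#' @param config Named numeric vector of the 14 angles ([config_names()]),
#'   or an unnamed length-14 vector in that order.
#' @param tjd Tip-to-joint distance in mm; defaults to the geometry's.
#' @return List with `poses` (one per screw: `screw_id`, `head`, `direction`,
#'   `length`, `tip`, `radius`), `flag` and `pairs`.
#' @export
realize_configuration <- function(geometry, config, tjd = geometry$tjd) {
  config <- as_config(config)
  poses <- lapply(geometry$screws, function(a) {
    dp <- config[[sprintf("s%d_dp", a$screw_id)]]
    ap <- config[[sprintf("s%d_ap", a$screw_id)]]
    dir <- tilt_direction(a, dp, ap)
    len <- tryCatch(solve_length(a$head, dir, geometry$sphere, tjd),
                    error = function(e) stop(sprintf("screw %d: %s", a$screw_id,
                                                     conditionMessage(e)), call. = FALSE))
    list(screw_id = a$screw_id, head = a$head, direction = dir,
         length = len, tip = a$head + len * dir, radius = a$radius)
  })
  col <- detect_collision(poses)
  list(poses = poses, flag = col$flag, pairs = col$pairs)
}

as_config <- function(config) {
  nm <- config_names()
  x <- as.numeric(config)
  if (length(x) != 14) stop("a configuration has exactly 14 angles")
  if (!is.null(names(config))) {
    if (!all(nm %in% names(config))) stop("configuration names must match config_names()")
    x <- as.numeric(config[nm])
  }
  names(x) <- nm
  x
}

# --- fast exact collision flags on discrete grids -------------------------
#
# On a grid each screw has only L^2 possible poses, so pair (i, j) collision
# is a boolean lookup keyed by the two screws' states. Tables are built with
# the reference segment_distance path (exact memoisation).

#' Precompute collision lookup tables for a discrete angle grid
#'
#' @param geometry A `screw_geometry`.
#' @param levels Allowed angle levels (degrees) per axis.
#' @param tjd Tip-to-joint distance in mm.
#' @return Opaque object for [config_collides()].
#' @export
collision_tables <- function(geometry, levels = c(-10, -5, 0, 5, 10),
                             tjd = geometry$tjd) {
  L <- length(levels)
  states <- expand.grid(dp = levels, ap = levels)  # state index: dp fast
  n <- length(geometry$screws)
  # tips per screw per state
  tips <- lapply(geometry$screws, function(a) {
    t(vapply(seq_len(nrow(states)), function(k) {
      dir <- tilt_direction(a, states$dp[k], states$ap[k])
      len <- solve_length(a$head, dir, geometry$sphere, tjd)
      a$head + len * dir
    }, numeric(3)))
  })
  ids <- vapply(geometry$screws, `[[`, integer(1), "screw_id")
  tabs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tab <- matrix(FALSE, nrow(states), nrow(states))
    rsum <- geometry$screws[[i]]$radius + geometry$screws[[j]]$radius
    for (ki in seq_len(nrow(states))) for (kj in seq_len(nrow(states))) {
      d <- segment_distance(geometry$screws[[i]]$head, tips[[i]][ki, ],
                            geometry$screws[[j]]$head, tips[[j]][kj, ])
      tab[ki, kj] <- d < rsum
    }
    tabs[[sprintf("%d_%d", ids[i], ids[j])]] <- tab
  }
  structure(list(levels = levels, ids = ids, tables = tabs), class = "collision_tables")
}

#' Vectorized exact collision flags for a matrix of configurations
#'
#' @param tables From [collision_tables()].
#' @param angles Numeric matrix, one row per configuration, 14 columns in
#'   [config_names()] order; all values must lie on the table's grid.
#' @return Logical vector, one flag per row.
#' @export
config_collides <- function(tables, angles) {
  angles <- as.matrix(angles)
  L <- length(tables$levels)
  lev <- tables$levels
  # per-screw state index (dp fast within ap blocks, matching collision_tables)
  state_idx <- function(dp, ap) {
    i_dp <- match(dp, lev); i_ap <- match(ap, lev)
    if (anyNA(i_dp) || anyNA(i_ap)) stop("angle off the table grid")
    (i_ap - 1L) * L + i_dp
  }
  ids <- tables$ids
  st <- sapply(seq_along(ids), function(k)
    state_idx(angles[, 2 * k - 1], angles[, 2 * k]))
  if (is.null(dim(st))) st <- matrix(st, nrow = 1)
  flag <- rep(FALSE, nrow(angles))
  for (nmp in names(tables$tables)) {
    ij <- as.integer(strsplit(nmp, "_", fixed = TRUE)[[1]])
    i <- match(ij[1], ids); j <- match(ij[2], ids)
    tab <- tables$tables[[nmp]]
    flag <- flag | tab[cbind(st[, i], st[, j])]
  }
  flag
}
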