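# Design of experiments over the discrete tilt-angle grid: configuration
# counting, snapped Latin Hypercube training designs, random testing designs,
# 80/10/10 splits and a memory-bounded full-factorial enumerator.

#' Discrete angle grid
#'
#' @param levels_deg Allowed tilt angles per axis, degrees. The training grid
#'   is `c(-10, -5, 0, 5, 10)`; the reduced full-factorial grid
#'   `c(-10, 0, 10)`.
#' @param n_screws Number of tiltable screws (7).
#' @param axes_per_screw Tilt axes per screw (2).
#' @return A `design_grid` list.
#' @export
design_grid <- function(levels_deg = c(-10, -5, 0, 5, 10), n_screws = 7,
                        axes_per_screw = 2) {
  levels_deg <- sort(unique(as.numeric(levels_deg)))
  if (!0 %in% levels_deg) stop("grid must contain 0")
  if (any(levels_deg + rev(levels_deg) != 0))
    stop("grid must be symmetric about 0")
  structure(list(levels = levels_deg, n_screws = as.integer(n_screws),
                 axes_per_screw = as.integer(axes_per_screw)),
            class = "design_grid")
}

#' Count the configurations of a grid
#'
#' `(levels^axes)^screws`; with 5 levels, 2 axes and 7 screws this is
#' `(5 x 5)^7 = 6 103 515 625`, with 3 levels `9^7 = 4 782 969`. Exact in
#' double precision for all practical grids (< 2^53).
#'
#' @param grid A [design_grid()].
#' @return Numeric count.
#' @export
count_configs <- function(grid) {
  (length(grid$levels)^grid$axes_per_screw)^grid$n_screws
}

n_axes <- function(grid) grid$n_screws * grid$axes_per_screw

grid_colnames <- function(grid) {
  if (n_axes(grid) == 14) return(config_names())
  as.vector(t(outer(SCREW_IDS[seq_len(grid$n_screws)], c("dp", "ap"),
                    function(i, a) sprintf("s%d_%s", i, a))))
}

# Snap unit-cube coordinates to grid levels by equal-probability binning.
snap_to_grid <- function(u, levels) {
  L <- length(levels)
  idx <- pmin(pmax(ceiling(u * L), 1L), L)
  matrix(levels[idx], nrow = nrow(u), dimnames = list(NULL, NULL))
}

#' Latin Hypercube design snapped to the angle grid
#'
#' Draws an n-point Latin Hypercube in the 14-dimensional unit cube
#' (`lhs::randomLHS`), maps each coordinate to a grid level by
#' equal-probability binning, and removes exact duplicate rows, drawing
#' replacements until `n` unique rows are found (capped at 100 n attempts).
#'
#' @param n Number of configurations (1 <= n <= [count_configs()]).
#' @param grid A [design_grid()].
#' @param seed Integer seed; the design is reproducible from it.
#' @return Integer matrix, `n` rows, 14 columns named [config_names()].
#' @export
lhs_design <- function(n, grid = design_grid(), seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (n > count_configs(grid)) stop("n exceeds the number of configurations")
  k <- n_axes(grid)
  with_seed(seed, {
    X <- snap_to_grid(lhs::randomLHS(n, k), grid$levels)
    X <- unique(X)
    attempts <- 0
    while (nrow(X) < n) {
      need <- n - nrow(X)
      attempts <- attempts + need
      if (attempts > 100 * n) stop("could not draw n unique configurations")
      X <- unique(rbind(X, snap_to_grid(lhs::randomLHS(max(need, 2L), k),
                                        grid$levels)))
    }
    X <- X[seq_len(n), , drop = FALSE]
    colnames(X) <- grid_colnames(grid)
    X
  })
}

#' Random testing design on a (typically 3-level) grid
#'
#' Same snapped-Latin-Hypercube machinery as [lhs_design()], intended for the
#' testing designs whose angles take randomly distributed values on the
#' reduced grid.
#'
#' @inheritParams lhs_design
#' @export
random_design <- function(n, grid = design_grid(c(-10, 0, 10)), seed = 1L) {
  lhs_design(n, grid, seed)
}

#' Random 80/10/10 split of a dataset
#'
#' Partitions the rows of `table` into train/validation/test. Validation and
#' test sizes are `round(n * f)`; the remainder goes to train. The split is a
#' disjoint, exhaustive random partition, reproducible from `seed`.
#'
#' @param table Data.frame (or matrix) of rows to split.
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` (same type as `table`) and
#'   attribute `indices` (the row indices of each part).
#' @export
split_dataset <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- nrow(table)
  if (is.null(n) || n < 1) stop("table must be non-empty")
  n_val <- round(n * fractions[2]); n_test <- round(n * fractions[3])
  n_train <- n - n_val - n_test
  sizes <- c(train = n_train, val = n_val, test = n_test)
  if (n >= 10 && any(sizes == 0 & fractions > 0))
    stop("a split with positive fraction is empty")
  perm <- with_seed(seed, sample.int(n))
  idx <- list(train = sort(perm[seq_len(n_train)]),
              val   = sort(perm[n_train + seq_len(n_val)]),
              test  = sort(perm[n_train + n_val + seq_len(n_test)]))
  out <- lapply(idx, function(i) table[i, , drop = FALSE])
  attr(out, "indices") <- idx
  out
}

#' Memory-bounded full-factorial enumerator
#'
#' Yields every configuration of the grid exactly once, in lexicographic
#' order over `(s6_dp, s6_ap, ..., s12_ap)` (first column slowest; the first
#' row is all angles at the lowest level, the last all at the highest).
#' Memory is bounded by `batch_size` rows.
#'
#' @param grid A [design_grid()].
#' @param batch_size Rows per batch (>= 1).
#' @return A list with `next_batch()` (returns a matrix of up to
#'   `batch_size` rows, or `NULL` when exhausted), `reset()`, and `total`.
#' @export
full_factorial <- function(grid = design_grid(c(-10, 0, 10)), batch_size = 1e5) {
  stopifnot(batch_size >= 1)
  total <- count_configs(grid)
  k <- n_axes(grid)
  L <- length(grid$levels)
  pos <- 0
  cn <- grid_colnames(grid)
  decode <- function(idx0) {
    # idx0: 0-based global indices; column j has place value L^(k - j)
    out <- matrix(0, length(idx0), k, dimnames = list(NULL, cn))
    rem <- idx0
    for (j in k:1) {
      out[, j] <- grid$levels[rem %% L + 1]
      rem <- rem %/% L
    }
    out
  }
  list(
    next_batch = function() {
      if (pos >= total) return(NULL)
      m <- min(batch_size, total - pos)
      idx <- pos + seq_len(m) - 1
      pos <<- pos + m
      decode(idx)
    },
    reset = function() pos <<- 0,
    total = total
  )
}
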