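# Full-factorial exploration statistics: per-screw strain-variation heatmaps
# with significance against the neutral tip state, and strain-range
# comparisons between designs. Both operate on streamed predictions so the
# 9^7 design space never has to be materialized.

#' Per-screw strain-variation heatmap over a full factorial
#'
#' Streams every configuration of `grid` through `predict_fn`, drops
#' colliding configurations, and for each screw and tip state `(dp, ap)`
#' summarises the predicted strain over all configurations with that state
#' (all other screws free). Each cell reports the percentage change of the
#' group mean from the neutral-state group and a Welch p-value against the
#' neutral group; the neutral cell is 0 with p = 1 by construction.
#'
#' Group means, variances and counts are held in exact streaming
#' accumulators, so the Welch tests use the full groups, not subsamples.
#' `center = "median"` instead contrasts medians of fixed-size seeded
#' reservoir samples per group (approximate for groups larger than
#' `reservoir`).
#'
#' @param predict_fn Function taking an n x 14 angle matrix and returning
#'   `list(value = numeric(n), collide = logical(n))` — typically built from
#'   a strain surrogate plus a collision classifier, or from the oracle.
#' @param grid A [design_grid()] (default the reduced 3-level grid).
#' @param screw_ids Screws to tabulate (default all seven).
#' @param alpha Significance threshold (default 0.001).
#' @param batch_size Streaming batch size (memory bound).
#' @param center `"mean"` or `"median"`.
#' @param reservoir Per-group reservoir size for `center = "median"`.
#' @param seed Seed for the reservoir sampler.
#' @return A `strain_heatmap` data.frame with columns `screw_id`, `dp_deg`,
#'   `ap_deg`, `pct_variation`, `p_value`, `significant`, `n`. Cells whose
#'   group is empty (all configurations colliding) have `NA` statistics.
#' @export
heatmap_variation <- function(predict_fn, grid = design_grid(c(-10, 0, 10)),
                              screw_ids = SCREW_IDS, alpha = 0.001,
                              batch_size = 2e5, center = c("mean", "median"),
                              reservoir = 1e4, seed = 1L) {
  center <- match.arg(center)
  lev <- grid$levels; L <- length(lev)
  G <- L * L                             # states per screw, dp fast
  ns <- length(screw_ids)
  kpos <- match(screw_ids, SCREW_IDS)
  if (anyNA(kpos)) stop("screw_ids must be in 6..12")
  cnt <- matrix(0, ns, G); s1 <- matrix(0, ns, G); s2 <- matrix(0, ns, G)
  res <- if (center == "median")
    replicate(ns, replicate(G, numeric(0), simplify = FALSE), simplify = FALSE)
  seen <- if (center == "median") matrix(0, ns, G)
  offset <- NULL
  ff <- full_factorial(grid, batch_size)
  rng_seed <- child_seed(seed, 777L)
  repeat {
    batch <- ff$next_batch()
    if (is.null(batch)) break
    pred <- predict_fn(batch)
    keep <- !pred$collide
    if (!any(keep)) next
    v <- pred$value[keep]
    if (is.null(offset)) offset <- mean(v)   # numerical centring for sumsq
    vc <- v - offset
    for (si in seq_len(ns)) {
      k <- kpos[si]
      g <- (match(batch[keep, 2 * k], lev) - 1L) * L +
        match(batch[keep, 2 * k - 1], lev)
      cnt[si, ] <- cnt[si, ] + tabulate(g, G)
      rs1 <- rowsum(vc, g); rs2 <- rowsum(vc^2, g)
      gi <- as.integer(rownames(rs1))
      s1[si, gi] <- s1[si, gi] + rs1[, 1]
      s2[si, gi] <- s2[si, gi] + rs2[, 1]
      if (center == "median") {
        for (gg in unique(g)) {
          vals <- v[g == gg]
          res[[si]][[gg]] <- reservoir_update(res[[si]][[gg]], vals,
                                              seen[si, gg], reservoir,
                                              child_seed(rng_seed, si * 1000L + gg))
          seen[si, gg] <- seen[si, gg] + length(vals)
        }
      }
    }
  }
  neutral_g <- (match(0, lev) - 1L) * L + match(0, lev)
  rows <- list()
  for (si in seq_len(ns)) {
    n0 <- cnt[si, neutral_g]
    m0 <- s1[si, neutral_g] / n0 + offset
    v0 <- (s2[si, neutral_g] - s1[si, neutral_g]^2 / n0) / (n0 - 1)
    c0 <- if (center == "median") median(res[[si]][[neutral_g]]) else m0
    for (ia in seq_len(L)) for (id in seq_len(L)) {
      g <- (ia - 1L) * L + id
      n1 <- cnt[si, g]
      if (n1 == 0 || n0 == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          screw_id = screw_ids[si], dp_deg = lev[id], ap_deg = lev[ia],
          pct_variation = NA_real_, p_value = NA_real_,
          significant = NA, n = n1)
        next
      }
      if (g == neutral_g) {
        pct <- 0; p <- 1
      } else {
        m1 <- s1[si, g] / n1 + offset
        v1 <- (s2[si, g] - s1[si, g]^2 / n1) / (n1 - 1)
        c1 <- if (center == "median") median(res[[si]][[g]]) else m1
        pct <- 100 * (c1 - c0) / c0
        p <- welch_from_stats(m1, v1, n1, m0, v0, n0)$p
      }
      rows[[length(rows) + 1]] <- data.frame(
        screw_id = screw_ids[si], dp_deg = lev[id], ap_deg = lev[ia],
        pct_variation = pct, p_value = p, significant = !is.na(p) & p < alpha,
        n = n1)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "levels") <- lev
  class(out) <- c("strain_heatmap", "data.frame")
  out
}

# Reservoir sampling update: keep a uniform sample of size <= cap from a
# stream, having already seen `seen` items before this chunk.
reservoir_update <- function(res, vals, seen, cap, seed) {
  with_seed(seed, {
    for (v in vals) {
      seen <- seen + 1
      if (length(res) < cap) res <- c(res, v)
      else {
        j <- sample.int(seen, 1)
        if (j <= cap) res[j] <- v
      }
    }
    res
  })
}

#' Plot a strain-variation heatmap
#'
#' One panel per screw: tip states on the axes, cell colour the percentage
#' strain variation from neutral, stars marking cells significant at the
#' heatmap's alpha.
#'
#' @param x A `strain_heatmap`.
#' @param ... Unused.
#' @export
plot.strain_heatmap <- function(x, ...) {
  lev <- attr(x, "levels")
  ids <- unique(x$screw_id)
  L <- length(lev)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(ids)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lim <- max(abs(x$pct_variation), na.rm = TRUE)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  for (id in ids) {
    d <- x[x$screw_id == id, ]
    z <- matrix(NA_real_, L, L)
    z[cbind(match(d$dp_deg, lev), match(d$ap_deg, lev))] <- d$pct_variation
    graphics::image(lev, lev, z, zlim = c(-lim, lim), col = pal,
                    xlab = "dp tilt (deg)", ylab = "ap tilt (deg)",
                    main = sprintf("Screw %d", id))
    sig <- d[!is.na(d$significant) & d$significant, ]
    if (nrow(sig)) graphics::text(sig$dp_deg, sig$ap_deg, "*", cex = 1.4)
  }
  invisible(x)
}

#' Compare strain ranges across designs
#'
#' Summarises an output across several named tables (min, quartiles, max,
#' range) and Welch-tests each against a reference table — in the study
#' design, the training sets against the full-factorial predictions.
#'
#' @param tables Named list (>= 2) of data.frames carrying `output_key`, or
#'   of numeric vectors.
#' @param output_key Strain column name (see [strain_columns()]); ignored
#'   for numeric-vector input.
#' @param reference Name of the reference table (default the first).
#' @param alpha Significance threshold for the pairwise tests (default 0.05).
#' @return Data.frame, one row per table: `name`, `n`, `min`, `q25`,
#'   `median`, `q75`, `max`, `range`, `t`, `df`, `p_vs_reference`,
#'   `significant` (NA for the reference row).
#' @export
strain_range_comparison <- function(tables, output_key = "e90_all",
                                    reference = names(tables)[1],
                                    alpha = 0.05) {
  if (length(tables) < 2 || is.null(names(tables)))
    stop("tables must be a named list of at least two tables")
  vals <- lapply(tables, function(tb) {
    if (is.data.frame(tb)) {
      if (!output_key %in% names(tb))
        stop(sprintf("missing output column '%s'", output_key), call. = FALSE)
      tb[[output_key]]
    } else as.numeric(tb)
  })
  if (!reference %in% names(vals)) stop("unknown reference table")
  ref <- vals[[reference]]
  rows <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    tt <- if (nm == reference) list(t = NA_real_, df = NA_real_, p = NA_real_)
          else welch_ttest(v, ref)
    data.frame(name = nm, n = length(v), min = min(v), q25 = q[1],
               median = q[2], q75 = q[3], max = max(v),
               range = max(v) - min(v), t = tt$t, df = tt$df,
               p_vs_reference = tt$p,
               significant = if (nm == reference) NA else tt$p < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  out
}
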