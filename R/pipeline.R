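# Dataset / design / model readers and writers, surrogate composition, and
# the end-to-end pipeline reproducing the study design on the synthetic
# oracle.

#' Write / read a design or dataset CSV
#'
#' Designs carry the 14 angle columns ([config_names()], integer degrees);
#' datasets additionally carry `collision` (0/1) and the 16 strain columns
#' ([strain_columns()], mu-strain). Headers are mandatory and validated.
#'
#' @param x Data.frame or matrix.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   validated data.frame.
#' @export
write_dataset <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param kind `"design"` (angles only) or `"dataset"` (angles + collision +
#'   strain).
#' @export
read_dataset <- function(path, kind = c("dataset", "design")) {
  kind <- match.arg(kind)
  x <- utils::read.csv(path, check.names = FALSE)
  need <- config_names()
  if (kind == "dataset") need <- c(need, "collision", strain_columns())
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop(sprintf("%s is missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  x[, need, drop = FALSE]
}

#' Serialize / restore a fitted network as JSON
#'
#' Stores layer sizes, weights (row-major per layer), biases, normalization
#' and metadata under a format-version field. Round-tripping preserves
#' predictions exactly (numbers are written at full precision).
#'
#' @param model An `mlp`.
#' @param path File path.
#' @return `write_mlp` returns `path` invisibly; `read_mlp` an `mlp`.
#' @export
write_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp"))
  out <- list(
    format_version = 1L,
    layer_sizes = model$layer_sizes,
    role = model$role, algorithm = model$algorithm,
    weights = lapply(model$W, function(w) list(dim = dim(w),
                                               values = as.vector(t(w)))),
    biases = model$b,
    input_norm = model$input_norm,
    output_norm = model$output_norm,
    seed = model$seed, epochs_run = model$epochs_run,
    final_objective = model$final_objective)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$format_version) || j$format_version != 1)
    stop("unsupported model format version")
  W <- lapply(j$weights, function(w)
    matrix(unlist(w$values), unlist(w$dim)[1], unlist(w$dim)[2], byrow = TRUE))
  b <- lapply(j$biases, function(bb) as.numeric(unlist(bb)))
  j$input_norm <- lapply(j$input_norm, function(v) as.numeric(unlist(v)))
  if (!is.null(j$output_norm))
    j$output_norm <- lapply(j$output_norm, function(v) as.numeric(unlist(v)))
  j$layer_sizes <- unlist(j$layer_sizes)
  structure(list(
    layer_sizes = as.integer(j$layer_sizes), W = W, b = b,
    hidden_activation = "tanh", output_activation = "linear",
    role = j$role, algorithm = j$algorithm,
    input_norm = list(min = as.numeric(j$input_norm$min),
                      max = as.numeric(j$input_norm$max)),
    output_norm = if (!is.null(j$output_norm))
      list(min = as.numeric(j$output_norm$min),
           max = as.numeric(j$output_norm$max)),
    seed = j$seed, epochs_run = j$epochs_run,
    final_objective = j$final_objective,
    alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
    history = data.frame(), fitted_values = NULL, y = NULL,
    call = NULL), class = "mlp")
}

#' Build the 16-input design matrix of the collision-aware strain regressor
#'
#' The collision-aware regressor takes the 14 tilt angles plus the collision
#' state encoded as a complementary indicator pair (`collide`, `clear`),
#' giving the architecture's 16 inputs and letting the binary state carry a
#' full-swing signal on both levels.
#'
#' @param angles n x 14 angle matrix in [config_names()] order.
#' @param flag 0/1 collision flags (true labels at training time, the
#'   classifier's predictions at exploration time).
#' @return n x 16 numeric matrix.
#' @export
strain16_inputs <- function(angles, flag) {
  angles <- as.matrix(angles)
  flag <- as.numeric(flag)
  cbind(angles, collide = flag, clear = 1 - flag)
}

#' Compose surrogates into a heatmap prediction function
#'
#' Builds the `predict_fn` consumed by [heatmap_variation()]: the collision
#' classifier labels each configuration, its 0/1 label optionally feeds the
#' strain regressor's 16th input (the trained composition of the study), and
#' predicted-colliding configurations are flagged for exclusion.
#'
#' @param strain_model `mlp` regressor with 14 or 16 inputs.
#' @param collision_model Optional `mlp` classifier (14 inputs). Required
#'   when `strain_model` takes 16 inputs.
#' @return Function: n x 14 angle matrix -> `list(value, collide)`.
#' @export
surrogate_predict_fn <- function(strain_model, collision_model = NULL) {
  n_in <- strain_model$layer_sizes[1]
  if (n_in == 16 && is.null(collision_model))
    stop("a 16-input strain model needs a collision classifier")
  function(angles) {
    angles <- as.matrix(angles)
    flag <- if (!is.null(collision_model))
      predict(collision_model, angles, type = "class") else integer(nrow(angles))
    keep <- flag == 0L
    value <- rep(NA_real_, nrow(angles))
    if (any(keep)) {   # strain is only consumed for non-colliding rows
      x <- if (n_in == 16) strain16_inputs(angles[keep, , drop = FALSE], 0)
           else angles[keep, , drop = FALSE]
      value[keep] <- predict(strain_model, x)
    }
    list(value = value, collide = !keep)
  }
}

#' Exact oracle prediction function (ground truth)
#'
#' The noise-free response surface with exact geometric collision flags, for
#' cross-checking surrogate-based heatmaps.
#'
#' @param params An [oracle_params()].
#' @param geometry A `screw_geometry`.
#' @param levels Grid levels the configurations will lie on.
#' @param output_key Strain column to report.
#' @return Function: n x 14 angle matrix -> `list(value, collide)`.
#' @export
oracle_predict_fn <- function(params = oracle_params(),
                              geometry = default_geometry(),
                              levels = c(-10, 0, 10),
                              output_key = "e90_all") {
  tabs <- collision_tables(geometry, levels)
  function(angles) {
    angles <- as.matrix(angles)
    flag <- config_collides(tabs, angles)
    list(value = strain_response(angles, as.numeric(flag), params)[[output_key]],
         collide = flag)
  }
}

#' Pipeline configuration
#'
#' Defaults mirror the study protocol: Latin Hypercube training designs of
#' 500/2000/5000 on the 5-level grid plus their 7500-row concatenation, a
#' 500-row testing design on the 3-level grid, 80/10/10 splits, 100 training
#' replicates, a reduced 3-level full factorial, alpha 0.001 for heatmap
#' cells and 0.05 for range comparisons. Scale the sizes down for smoke
#' runs.
#'
#' @param train_sizes Training design sizes (concatenated for the final set).
#' @param n_test Testing design size before collision attrition.
#' @param n_replicates Replicates per architecture.
#' @param outputs Strain columns to fit regressors for.
#' @param train_grid,test_grid [design_grid()]s.
#' @param geometry,params Geometry and oracle parameters.
#' @param control A [mlp_control()].
#' @param alpha_heatmap,alpha_ranges Significance thresholds.
#' @param batch_size Full-factorial streaming batch size.
#' @param seed Master seed; every stage derives child seeds from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(train_sizes = c(500, 2000, 5000), n_test = 500,
                            n_replicates = 100, outputs = "e90_all",
                            train_grid = design_grid(),
                            test_grid = design_grid(c(-10, 0, 10)),
                            geometry = default_geometry(),
                            params = oracle_params(),
                            control = mlp_control(),
                            alpha_heatmap = 0.001, alpha_ranges = 0.05,
                            batch_size = 2e5, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full surrogate-modeling pipeline
#'
#' Executes design generation, oracle simulation, replicate surrogate
#' training (collision classifier, 16-input and 14-input strain regressors),
#' evaluation on the held-out testing design, the full-factorial heatmap
#' from the best composed surrogates, and the strain-range comparison of the
#' training sets against the full factorial. All artifacts are written under
#' `out_dir` along with a manifest recording seeds, sizes and file hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly; see `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("designs", "data", "models", "reports"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # designs ---------------------------------------------------------------
  designs <- stage("design", {
    ds <- lapply(seq_along(config$train_sizes), function(i)
      lhs_design(config$train_sizes[i], config$train_grid, child_seed(seed, i)))
    names(ds) <- paste0("train_", config$train_sizes)
    ds[[paste0("train_", sum(config$train_sizes))]] <- do.call(rbind, ds)
    ds$test <- random_design(config$n_test, config$test_grid, child_seed(seed, 90L))
    ds
  })
  for (nm in names(designs))
    write_dataset(designs[[nm]], file.path(out_dir, "designs", paste0(nm, ".csv")))

  # simulate --------------------------------------------------------------
  datasets <- stage("simulate", {
    offs <- 0L
    lapply(designs, function(d) {
      out <- generate_dataset(d, config$geometry, config$params, draw_offset = offs)
      offs <<- offs + nrow(d)
      out
    })
  })
  for (nm in names(datasets))
    write_dataset(datasets[[nm]], file.path(out_dir, "data", paste0(nm, ".csv")))

  final_nm <- paste0("train_", sum(config$train_sizes))
  train_tab <- datasets[[final_nm]]
  test_tab <- datasets$test
  test_ok <- test_tab[test_tab$collision == 0, ]   # surviving testing rows
  ang <- config_names()

  # train -----------------------------------------------------------------
  split <- split_dataset(train_tab, seed = child_seed(seed, 91L))
  models <- stage("train", {
    out <- list()
    out$collision <- mlp_replicates(
      x = as.matrix(split$train[, ang]), y = split$train$collision,
      eval_x = as.matrix(test_tab[, ang]), eval_y = test_tab$collision,
      hidden = 25, role = "classifier",
      validation = list(x = as.matrix(split$val[, ang]), y = split$val$collision),
      n_replicates = config$n_replicates, control = config$control,
      seed = child_seed(seed, 92L))
    for (key in config$outputs) {
      x16 <- strain16_inputs(train_tab[, ang], train_tab$collision)
      sp16 <- split_dataset(cbind(as.data.frame(x16), y = train_tab[[key]]),
                            seed = child_seed(seed, 93L))
      out[[paste0("strain16_", key)]] <- mlp_replicates(
        x = as.matrix(sp16$train[, 1:16]), y = sp16$train[, "y"],
        eval_x = strain16_inputs(test_ok[, ang], test_ok$collision),
        eval_y = test_ok[[key]],
        hidden = c(10, 5), role = "regressor",
        validation = list(x = as.matrix(sp16$val[, 1:16]), y = sp16$val[, "y"]),
        n_replicates = config$n_replicates, control = config$control,
        seed = child_seed(seed, 94L))
      out[[paste0("strain14_", key)]] <- mlp_replicates(
        x = as.matrix(split$train[, ang]), y = split$train[[key]],
        eval_x = as.matrix(test_ok[, ang]), eval_y = test_ok[[key]],
        hidden = c(10, 5), role = "regressor",
        validation = list(x = as.matrix(split$val[, ang]), y = split$val[[key]]),
        n_replicates = config$n_replicates, control = config$control,
        seed = child_seed(seed, 95L))
    }
    out
  })
  for (nm in names(models))
    write_mlp(select_best(models[[nm]]),
              file.path(out_dir, "models", paste0(nm, ".json")))

  # evaluate --------------------------------------------------------------
  evaluation <- stage("evaluate", {
    best_cls <- select_best(models$collision)
    ev <- list(collision = c(
      as.list(classification_table(test_tab$collision,
                                   predict(best_cls, as.matrix(test_tab[, ang]),
                                           type = "class"))),
      list(replicate_accuracy = unname(ensemble_report(models$collision)))))
    for (key in config$outputs) {
      for (role in c("strain16", "strain14")) {
        ens <- models[[paste0(role, "_", key)]]
        best <- select_best(ens)
        xe <- if (role == "strain16")
          strain16_inputs(test_ok[, ang], test_ok$collision)
        else as.matrix(test_ok[, ang])
        ev[[paste0(role, "_", key)]] <- c(
          regression_metrics(test_ok[[key]], predict(best, xe)),
          list(replicate_rmse = unname(ensemble_report(ens))))
      }
    }
    ev
  })
  jsonlite::write_json(evaluation, file.path(out_dir, "reports", "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)

  # full factorial: heatmap + predicted values for ranges -------------------
  key0 <- config$outputs[1]
  pfn <- surrogate_predict_fn(select_best(models[[paste0("strain16_", key0)]]),
                              select_best(models$collision))
  heat <- stage("heatmap", heatmap_variation(
    pfn, config$test_grid, alpha = config$alpha_heatmap,
    batch_size = config$batch_size, seed = child_seed(seed, 96L)))
  utils::write.csv(heat, file.path(out_dir, "reports", "heatmap.csv"),
                   row.names = FALSE)

  ranges <- stage("ranges", {
    ff <- full_factorial(config$test_grid, config$batch_size)
    vals <- numeric(0)
    repeat {
      b <- ff$next_batch(); if (is.null(b)) break
      p <- pfn(b)
      vals <- c(vals, p$value[!p$collide])
    }
    tabs <- c(list(full_factorial = vals),
              lapply(datasets[names(datasets) != "test"], function(d)
                d[d$collision == 0, key0]))
    strain_range_comparison(tabs, output_key = key0,
                            reference = "full_factorial",
                            alpha = config$alpha_ranges)
  })
  utils::write.csv(ranges, file.path(out_dir, "reports", "ranges.csv"),
                   row.names = FALSE)

  # manifest ----------------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("screwscape")),
    seed = seed,
    train_sizes = config$train_sizes, n_test = config$n_test,
    n_replicates = config$n_replicates, outputs = config$outputs,
    train_levels = config$train_grid$levels, test_levels = config$test_grid$levels,
    alpha_heatmap = config$alpha_heatmap, alpha_ranges = config$alpha_ranges,
    files = lapply(files, function(f) list(
      path = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
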