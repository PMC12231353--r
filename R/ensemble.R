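# Replicate training and best-model selection. The study protocol trains
# each architecture many times from different random initializations and
# reports the best model alongside the replicate average.

#' Train an ensemble of replicate networks
#'
#' Fits `n_replicates` copies of the same architecture on the same split,
#' from distinct seeds, and scores each on an evaluation table. Individual
#' training failures are recorded, not fatal, unless more than half fail.
#'
#' @inheritParams mlp_fit
#' @param eval_x,eval_y Evaluation rows used to score each replicate
#'   (typically the external testing design).
#' @param metric `"accuracy"` (classifier, maximized) or `"rmse"`
#'   (regressor, minimized).
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Base seed; replicate `i` trains from seed
#'   `child_seed(seed, i)`.
#' @return An object of class `mlp_ensemble`: `models` (list, `NULL` where a
#'   replicate failed), `metric`, `scores`, `best` (index), `seeds`.
#' @export
mlp_replicates <- function(x, y, eval_x, eval_y, hidden = c(10, 5),
                           role = c("regressor", "classifier"),
                           algorithm = NULL, validation = NULL,
                           metric = NULL, n_replicates = 100,
                           control = mlp_control(), seed = 1L) {
  role <- match.arg(role)
  metric <- metric %||% if (role == "classifier") "accuracy" else "rmse"
  metric <- match.arg(metric, c("accuracy", "rmse"))
  stopifnot(n_replicates >= 1)
  seeds <- vapply(seq_len(n_replicates), function(i) child_seed(seed, i), integer(1))
  eval_x <- as.matrix(eval_x); eval_y <- as.numeric(eval_y)
  models <- vector("list", n_replicates)
  scores <- rep(NA_real_, n_replicates)
  failures <- character(0)
  for (i in seq_len(n_replicates)) {
    fit <- tryCatch(
      mlp_fit(x, y, hidden = hidden, role = role, algorithm = algorithm,
              validation = validation, control = control, seed = seeds[i]),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", i, conditionMessage(fit)))
      next
    }
    models[[i]] <- fit
    scores[i] <- if (metric == "accuracy") {
      classification_table(eval_y, predict(fit, eval_x, type = "class"))$pct_true
    } else {
      sqrt(mean((eval_y - predict(fit, eval_x))^2))
    }
  }
  if (sum(!vapply(models, is.null, logical(1))) < n_replicates / 2)
    stop("more than half of the replicate trainings failed:\n",
         paste(failures, collapse = "\n"))
  best <- if (metric == "accuracy") which.max(scores) else which.min(scores)
  structure(list(models = models, metric = metric, scores = scores,
                 best = best, seeds = seeds, failures = failures,
                 hidden = hidden, role = role),
            class = "mlp_ensemble")
}

#' Select the best replicate of an ensemble
#'
#' Argmax accuracy (classifier) or argmin RMSE (regressor) on the ensemble's
#' evaluation table; ties break to the lowest replicate index (which.max /
#' which.min semantics).
#'
#' @param ensemble An [mlp_replicates()] result.
#' @return The winning `mlp`.
#' @export
select_best <- function(ensemble) {
  stopifnot(inherits(ensemble, "mlp_ensemble"))
  if (!length(ensemble$models) || all(vapply(ensemble$models, is.null, logical(1))))
    stop("empty ensemble")
  ensemble$models[[ensemble$best]]
}

#' @export
print.mlp_ensemble <- function(x, ...) {
  ok <- !is.na(x$scores)
  best_fmt <- if (x$metric == "accuracy") "%.1f%%" else "%.4g"
  cat(sprintf("Replicate ensemble: %d trained (%d failed), metric = %s\n",
              sum(ok), sum(!ok), x$metric))
  cat(sprintf(paste0("  best: ", best_fmt, " (replicate %d)   mean: ", best_fmt, "\n"),
              x$scores[x$best], x$best, mean(x$scores[ok])))
  invisible(x)
}

#' Best and replicate-mean score of an ensemble
#'
#' The study's tables report the best model's score with the replicate
#' average in brackets; this helper returns both.
#'
#' @param ensemble An `mlp_ensemble`.
#' @return Named numeric vector `c(best =, mean =)`.
#' @export
ensemble_report <- function(ensemble) {
  ok <- !is.na(ensemble$scores)
  c(best = ensemble$scores[ensemble$best], mean = mean(ensemble$scores[ok]))
}
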