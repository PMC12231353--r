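# Small feed-forward surrogates trained from scratch. Two roles mirror the
# study design: a collision classifier ([14, 25, 1], Levenberg-Marquardt)
# and strain regressors ([16 or 14, 10, 5, 1], Bayesian regularization).
# Hidden layers are tanh, the output layer linear; inputs (and regressor
# outputs) are min-max scaled to [-1, 1] on the training rows only.

#' Training control parameters
#'
#' @param max_epochs Maximum LM / Bayesian-regularization epochs.
#' @param mu_init,mu_increase,mu_decrease,mu_max Levenberg-Marquardt damping
#'   schedule: `mu` is multiplied by `mu_increase` on a rejected step and by
#'   `mu_decrease` on an accepted one; training stops if `mu > mu_max`.
#' @param val_patience Consecutive validation-SSE increases tolerated before
#'   early stopping (LM only; best-validation weights are restored).
#' @param grad_tol Stop when the gradient infinity-norm falls below this.
#' @param sse_tol Stop when the training SSE falls below this.
#' @param alpha_init,beta_init Initial Bayesian-regularization
#'   hyperparameters (weight-decay and data precision).
#' @param evidence_tol Relative stabilization tolerance on the effective
#'   number of parameters gamma (Bayesian regularization stop rule).
#' @return A `mlp_control` list.
#' @export
mlp_control <- function(max_epochs = 200, mu_init = 1e-3, mu_increase = 10,
                        mu_decrease = 0.1, mu_max = 1e10, val_patience = 6,
                        grad_tol = 1e-7, sse_tol = 1e-12,
                        alpha_init = 0.01, beta_init = 1, evidence_tol = 1e-4) {
  stopifnot(max_epochs >= 0, mu_increase > 1, mu_decrease > 0, mu_decrease < 1)
  structure(as.list(environment()), class = "mlp_control")
}

# ---- weight packing -------------------------------------------------------

layer_shapes <- function(layer_sizes) {
  L <- length(layer_sizes) - 1
  lapply(seq_len(L), function(l)
    c(n_in = layer_sizes[l], n_out = layer_sizes[l + 1]))
}

n_params <- function(layer_sizes) {
  sum(vapply(layer_shapes(layer_sizes), function(s) s[1] * s[2] + s[2], numeric(1)))
}

# 1 for connection-weight entries of the packed vector, 0 for biases.
weight_mask <- function(layer_sizes) {
  shapes <- layer_shapes(layer_sizes)
  unlist(lapply(shapes, function(s) c(rep(1, s[1] * s[2]), rep(0, s[2]))))
}

pack_weights <- function(W, b) {
  unlist(c(mapply(function(w, bb) c(as.vector(w), bb), W, b, SIMPLIFY = FALSE)),
         use.names = FALSE)
}

unpack_weights <- function(theta, layer_sizes) {
  shapes <- layer_shapes(layer_sizes)
  W <- list(); b <- list(); pos <- 0
  for (l in seq_along(shapes)) {
    ni <- shapes[[l]][1]; no <- shapes[[l]][2]
    W[[l]] <- matrix(theta[pos + seq_len(ni * no)], ni, no); pos <- pos + ni * no
    b[[l]] <- theta[pos + seq_len(no)]; pos <- pos + no
  }
  list(W = W, b = b)
}

# ---- initialization and normalization ------------------------------------

# Nguyen-Widrow initialization for tanh layers (inputs scaled to [-1, 1]):
# unit weight vectors are renormalized to magnitude 0.7 * no^(1/ni) and the
# biases spread the units' active regions across the input cube. The linear
# output layer uses a small scaled-uniform draw.
init_weights <- function(layer_sizes, seed) {
  shapes <- layer_shapes(layer_sizes)
  L <- length(shapes)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_along(shapes)) {
      ni <- shapes[[l]][1]; no <- shapes[[l]][2]
      if (l < L) {
        beta <- 0.7 * no^(1 / ni)
        Wl <- matrix(runif(ni * no, -1, 1), ni, no)
        nrm <- sqrt(colSums(Wl^2)); nrm[nrm == 0] <- 1
        W[[l]] <- sweep(Wl, 2, beta / nrm, `*`)
        bl <- if (no == 1) 0 else beta * seq(-1, 1, length.out = no)
        b[[l]] <- bl * sign(runif(no, -1, 1))
      } else {
        a <- sqrt(6 / (ni + no))
        W[[l]] <- matrix(runif(ni * no, -a, a), ni, no)
        b[[l]] <- runif(no, -a, a)
      }
    }
    list(W = W, b = b)
  })
}

fit_norm <- function(x) {
  mn <- apply(x, 2, min); mx <- apply(x, 2, max)
  list(min = mn, max = mx)
}

apply_norm <- function(x, norm) {
  rng <- norm$max - norm$min
  rng[rng == 0] <- 1                    # constant feature -> mapped to -1.. keep 0
  ctr <- (norm$max + norm$min) / 2
  sweep(sweep(x, 2, ctr), 2, rng / 2, `/`)
}

invert_norm <- function(z, norm) {
  rng <- norm$max - norm$min
  z * rng / 2 + (norm$max + norm$min) / 2
}

# ---- forward pass and Jacobian -------------------------------------------

# Forward on the normalized scale. Returns output column and per-layer
# activations (A[[1]] = normalized input) for Jacobian assembly.
forward_norm <- function(W, b, X) {
  L <- length(W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], `+`)
    A[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  list(out = A[[L + 1]][, 1], A = A)
}

# N x P Jacobian d out / d theta for a single-output net, by backprop.
# Column order matches pack_weights.
mlp_jacobian <- function(W, b, A) {
  L <- length(W); N <- nrow(A[[1]])
  delta <- vector("list", L)
  delta[[L]] <- matrix(1, N, 1)
  for (l in rev(seq_len(L - 1)))
    delta[[l]] <- (delta[[l + 1]] %*% t(W[[l + 1]])) * (1 - A[[l + 1]]^2)
  blocks <- vector("list", 2 * L)
  for (l in seq_len(L)) {
    ni <- nrow(W[[l]]); no <- ncol(W[[l]])
    # column (j,k), j fast: A[[l]][, j] * delta[[l]][, k]
    blocks[[2 * l - 1]] <- A[[l]][, rep(seq_len(ni), no), drop = FALSE] *
      delta[[l]][, rep(seq_len(no), each = ni), drop = FALSE]
    blocks[[2 * l]] <- delta[[l]]
  }
  do.call(cbind, blocks)
}

# ---- trainers -------------------------------------------------------------

# Levenberg-Marquardt on SSE = sum (t - out)^2, on the normalized scale.
# Early stopping on validation SSE with patience; best-val weights restored.
train_lm <- function(theta, layer_sizes, X, t, Xval = NULL, tval = NULL, control) {
  mu <- control$mu_init
  wb <- unpack_weights(theta, layer_sizes)
  fw <- forward_norm(wb$W, wb$b, X)
  r <- t - fw$out
  sse <- sum(r^2)
  best_val <- Inf; best_theta <- theta; val_up <- 0
  hist <- list()
  epochs <- 0
  for (epoch in seq_len(control$max_epochs)) {
    J <- mlp_jacobian(wb$W, wb$b, fw$A)
    g <- crossprod(J, r)
    if (max(abs(g)) < control$grad_tol) break
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted && mu <= control$mu_max) {
      H <- JtJ; diag(H) <- diag(H) + mu
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta + as.vector(step)
        wb_new <- unpack_weights(theta_new, layer_sizes)
        fw_new <- forward_norm(wb_new$W, wb_new$b, X)
        sse_new <- sum((t - fw_new$out)^2)
        if (!is.finite(sse_new))
          stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
        if (sse_new < sse) {
          theta <- theta_new; wb <- wb_new; fw <- fw_new
          r <- t - fw$out; sse <- sse_new
          mu <- max(mu * control$mu_decrease, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) mu <- mu * control$mu_increase
    }
    epochs <- epoch
    val_sse <- NA_real_
    if (!is.null(Xval) && length(tval)) {
      val_sse <- sum((tval - forward_norm(wb$W, wb$b, Xval)$out)^2)
      if (val_sse < best_val) { best_val <- val_sse; best_theta <- theta; val_up <- 0 }
      else val_up <- val_up + 1
    }
    hist[[epoch]] <- c(epoch = epoch, sse = sse, val_sse = val_sse, mu = mu)
    if (!accepted) break                               # mu overflow
    if (sse < control$sse_tol) break
    if (val_up >= control$val_patience) break
  }
  if (!is.null(Xval) && length(tval) && is.finite(best_val)) theta <- best_theta
  wb <- unpack_weights(theta, layer_sizes)
  final_sse <- sum((t - forward_norm(wb$W, wb$b, X)$out)^2)
  list(theta = theta, epochs = epochs, final_objective = final_sse,
       history = if (length(hist)) as.data.frame(do.call(rbind, hist)) else
         data.frame(epoch = numeric(0), sse = numeric(0),
                    val_sse = numeric(0), mu = numeric(0)))
}

# Bayesian regularization: LM steps on F = beta E_D + alpha E_W with
# E_D = 0.5 sum r^2 and E_W = 0.5 sum w^2 over connection weights only
# (biases are unpenalized location parameters), plus MacKay evidence updates
# gamma = P_w - alpha tr_w(H^-1), alpha = gamma / (2 E_W),
# beta = (N - gamma) / (2 E_D) after each accepted step.
train_bayes_reg <- function(theta, layer_sizes, X, t, control) {
  N <- length(t)
  wmask <- weight_mask(layer_sizes)      # 1 for weights, 0 for biases
  Pw <- sum(wmask)
  alpha <- control$alpha_init; beta <- control$beta_init
  mu <- control$mu_init
  wb <- unpack_weights(theta, layer_sizes)
  fw <- forward_norm(wb$W, wb$b, X)
  r <- t - fw$out
  ED <- 0.5 * sum(r^2); EW <- 0.5 * sum((wmask * theta)^2)
  Fobj <- beta * ED + alpha * EW
  gamma <- Pw
  hist <- list(); epochs <- 0
  for (epoch in seq_len(control$max_epochs)) {
    J <- mlp_jacobian(wb$W, wb$b, fw$A)
    g <- beta * crossprod(J, r) - alpha * (wmask * theta)
    if (max(abs(g)) < control$grad_tol) break
    bJtJ <- beta * crossprod(J)
    accepted <- FALSE
    while (!accepted && mu <= control$mu_max) {
      H <- bJtJ; diag(H) <- diag(H) + alpha * wmask + mu
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta + as.vector(step)
        wb_new <- unpack_weights(theta_new, layer_sizes)
        fw_new <- forward_norm(wb_new$W, wb_new$b, X)
        r_new <- t - fw_new$out
        ED_new <- 0.5 * sum(r_new^2)
        EW_new <- 0.5 * sum((wmask * theta_new)^2)
        F_new <- beta * ED_new + alpha * EW_new
        if (!is.finite(F_new))
          stop(sprintf("non-finite loss at epoch %d", epoch), call. = FALSE)
        if (F_new < Fobj) {
          theta <- theta_new; wb <- wb_new; fw <- fw_new; r <- r_new
          ED <- ED_new; EW <- EW_new
          mu <- max(mu * control$mu_decrease, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) mu <- mu * control$mu_increase
    }
    epochs <- epoch
    if (!accepted) break
    # evidence update at the accepted point (Gauss-Newton Hessian of F)
    Hgn <- beta * crossprod(mlp_jacobian(wb$W, wb$b, fw$A))
    diag(Hgn) <- diag(Hgn) + alpha * wmask + 1e-12
    trHinv_w <- tryCatch(sum(wmask * diag(chol2inv(chol(Hgn)))),
                         error = function(e) sum(wmask / diag(Hgn)))
    gamma_new <- Pw - alpha * trHinv_w
    gamma_new <- min(max(gamma_new, 1e-6), Pw - 1e-6)
    alpha <- gamma_new / max(2 * EW, 1e-12)
    beta <- max(N - gamma_new, 1e-6) / max(2 * ED, 1e-12)
    stable <- abs(gamma_new - gamma) < control$evidence_tol * Pw
    gamma <- gamma_new
    Fobj <- beta * ED + alpha * EW
    hist[[epoch]] <- c(epoch = epoch, sse = 2 * ED, alpha = alpha,
                       beta = beta, gamma = gamma, mu = mu)
    if (stable && epoch > 10) break
  }
  list(theta = theta, epochs = epochs, final_objective = Fobj,
       alpha = alpha, beta = beta, gamma = gamma,
       history = if (length(hist)) as.data.frame(do.call(rbind, hist)) else
         data.frame(epoch = numeric(0), sse = numeric(0), alpha = numeric(0),
                    beta = numeric(0), gamma = numeric(0), mu = numeric(0)))
}

# ---- the fitting function -------------------------------------------------

#' Fit a small feed-forward surrogate network
#'
#' The central fitting function. Builds a tanh-hidden, linear-output
#' multilayer perceptron and trains it with Levenberg-Marquardt
#' backpropagation (`algorithm = "lm"`, the classifier default) or
#' Bayesian-regularization backpropagation (`algorithm = "bayes"`, the
#' regressor default). Inputs are min-max scaled to [-1, 1] on the training
#' rows; regressor targets likewise. A classifier is trained against raw
#' 0/1 targets and thresholds its linear output at 0.5.
#'
#' `hidden = integer(0)` gives a pure affine model (no hidden layer), for
#' which a Levenberg-Marquardt step with vanishing damping solves the linear
#' least-squares problem exactly.
#'
#' @param x Numeric matrix of predictors (rows = observations).
#' @param y Numeric response vector (0/1 for classifiers).
#' @param hidden Integer vector of hidden-layer sizes.
#' @param role `"regressor"` or `"classifier"`.
#' @param algorithm `"bayes"` or `"lm"`; defaults by role.
#' @param validation Optional `list(x =, y =)` held-out rows for LM early
#'   stopping. Bayesian regularization uses no validation set: such rows are
#'   folded into training, the standard behavior of the method.
#' @param control A [mlp_control()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mlp` with `predict`, `print`, `summary`,
#'   `coef`, `fitted`, `residuals` and `plot` methods.
#' @examples
#' x <- matrix(runif(60, -1, 1), ncol = 2)
#' y <- x[, 1]^2 + x[, 2]
#' fit <- mlp_fit(x, y, hidden = c(4), seed = 1,
#'                control = mlp_control(max_epochs = 50))
#' cor(predict(fit, x), y)
#' @export
mlp_fit <- function(x, y, hidden = c(10, 5),
                    role = c("regressor", "classifier"),
                    algorithm = NULL, validation = NULL,
                    control = mlp_control(), seed = 1L) {
  role <- match.arg(role)
  algorithm <- algorithm %||% if (role == "classifier") "lm" else "bayes"
  algorithm <- match.arg(algorithm, c("lm", "bayes"))
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (nrow(x) == 0) stop("empty training set")
  layer_sizes <- c(ncol(x), as.integer(hidden), 1L)

  if (algorithm == "bayes" && !is.null(validation)) {
    x <- rbind(x, as.matrix(validation$x))
    y <- c(y, as.numeric(validation$y))
    validation <- NULL
  }
  input_norm <- fit_norm(x)
  Xn <- apply_norm(x, input_norm)
  output_norm <- NULL
  tn <- y
  if (role == "regressor") {
    output_norm <- list(min = min(y), max = max(y))
    tn <- as.vector(apply_norm(matrix(y, ncol = 1),
                               list(min = output_norm$min, max = output_norm$max)))
  }
  Xv <- NULL; tv <- NULL
  if (!is.null(validation)) {
    Xv <- apply_norm(as.matrix(validation$x), input_norm)
    tv <- as.numeric(validation$y)
    if (role == "regressor")
      tv <- as.vector(apply_norm(matrix(tv, ncol = 1),
                                 list(min = output_norm$min, max = output_norm$max)))
  }

  wb0 <- init_weights(layer_sizes, seed)
  theta0 <- pack_weights(wb0$W, wb0$b)
  res <- if (algorithm == "lm")
    train_lm(theta0, layer_sizes, Xn, tn, Xv, tv, control)
  else
    train_bayes_reg(theta0, layer_sizes, Xn, tn, control)

  wb <- unpack_weights(res$theta, layer_sizes)
  fitted_vals <- forward_norm(wb$W, wb$b, Xn)$out
  if (role == "regressor")
    fitted_vals <- as.vector(invert_norm(matrix(fitted_vals, ncol = 1),
                                         list(min = output_norm$min,
                                              max = output_norm$max)))
  structure(list(
    layer_sizes = layer_sizes, W = wb$W, b = wb$b,
    hidden_activation = "tanh", output_activation = "linear",
    role = role, algorithm = algorithm,
    input_norm = input_norm, output_norm = output_norm,
    seed = as.integer(seed), epochs_run = res$epochs,
    final_objective = res$final_objective,
    alpha = res$alpha %||% NA_real_, beta = res$beta %||% NA_real_,
    gamma = res$gamma %||% NA_real_,
    history = res$history,
    fitted_values = fitted_vals, y = y, call = match.call()),
    class = "mlp")
}

#' Predict from a fitted surrogate network
#'
#' Vectorized batch prediction; each row's output is independent of the rest
#' of the batch.
#'
#' @param object An `mlp`.
#' @param newdata Matrix with `layer_sizes[1]` columns.
#' @param type `"response"` (denormalized regressor output / raw linear
#'   classifier output) or `"class"` (classifier only: 0/1 at threshold 0.5).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.mlp <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$layer_sizes[1])
    stop(sprintf("newdata must have %d columns", object$layer_sizes[1]))
  out <- forward_norm(object$W, object$b, apply_norm(newdata, object$input_norm))$out
  if (type == "class") {
    if (object$role != "classifier") stop("type = 'class' requires a classifier")
    return(as.integer(out >= 0.5))
  }
  if (object$role == "regressor")
    out <- as.vector(invert_norm(matrix(out, ncol = 1),
                                 list(min = object$output_norm$min,
                                      max = object$output_norm$max)))
  out
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("Feed-forward surrogate (%s, %s)\n", x$role,
              if (x$algorithm == "lm") "Levenberg-Marquardt"
              else "Bayesian regularization"))
  cat("  architecture:", paste(x$layer_sizes, collapse = "-"),
      sprintf("(%d parameters)\n", n_params(x$layer_sizes)))
  cat(sprintf("  epochs run: %d   final objective: %.6g\n",
              x$epochs_run, x$final_objective))
  if (is.finite(x$gamma))
    cat(sprintf("  effective parameters gamma: %.2f of %d weights\n",
                x$gamma, sum(weight_mask(x$layer_sizes))))
  invisible(x)
}

#' @export
summary.mlp <- function(object, ...) {
  r <- residuals(object)
  structure(list(model = object, n = length(object$y),
                 rmse = sqrt(mean(r^2)),
                 resid_summary = summary(r)), class = "summary.mlp")
}

#' @export
print.summary.mlp <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training rows: %d   training RMSE: %.6g\n", x$n, x$rmse))
  cat("  residuals:\n"); print(x$resid_summary)
  invisible(x)
}

#' @export
coef.mlp <- function(object, ...) {
  th <- pack_weights(object$W, object$b)
  names(th) <- param_names(object$layer_sizes)
  th
}

param_names <- function(layer_sizes) {
  shapes <- layer_shapes(layer_sizes)
  unlist(lapply(seq_along(shapes), function(l) {
    ni <- shapes[[l]][1]; no <- shapes[[l]][2]
    c(sprintf("W%d[%d,%d]", l, rep(seq_len(ni), no), rep(seq_len(no), each = ni)),
      sprintf("b%d[%d]", l, seq_len(no)))
  }))
}

#' @export
fitted.mlp <- function(object, ...) object$fitted_values

#' @export
residuals.mlp <- function(object, ...) object$y - object$fitted_values

#' Plot the training history of a fitted network
#'
#' @param x An `mlp`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mlp <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("no training history"); return(invisible(x)) }
  graphics::plot(h$epoch, h$sse, type = "l", log = "y",
                 xlab = "epoch", ylab = "training SSE (normalized scale)",
                 main = paste("Training history,",
                              paste(x$layer_sizes, collapse = "-")), ...)
  if ("val_sse" %in% names(h) && any(is.finite(h$val_sse)))
    graphics::lines(h$epoch, h$val_sse, lty = 2)
  invisible(x)
}
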