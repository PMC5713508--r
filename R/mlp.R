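#' MLP training configuration
#'
#' Hyperparameters for the one-hidden-layer perceptron regression of stem
#' water potential on canopy band reflectances.  Training is full-batch
#' back-propagation (gradient descent on the mean squared error) for
#' exactly `iterations` epochs, repeated over `restarts` independent
#' seeded initializations; the restart with the lowest training RMSE is
#' kept.
#'
#' @param band_subset wavelengths (nm) used as input features.
#' @param hidden_nodes hidden-layer size, 2..20.
#' @param iterations training epochs; a multiple of 100 in 100..5000.
#' @param restarts independent re-initializations (>= 1, default 20).
#' @param learning_rate positive step size for the mean-gradient update
#'   (default 0.5; inputs and target are standardized internally, for
#'   which this is a stable, fast-converging choice).
#' @param activation hidden-layer activation: `"sigmoid"` or `"tanh"`
#'   (output is linear).
#' @param seed integer seed; restart `r` uses a seed derived
#'   deterministically from `seed` and `r`.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(band_subset = c(530, 550, 570, 670, 700, 800),
                       hidden_nodes = 5,
                       iterations = 500,
                       restarts = 20,
                       learning_rate = 0.5,
                       activation = c("sigmoid", "tanh"),
                       seed = 1L) {
  activation <- match.arg(activation)
  if (hidden_nodes < 2 || hidden_nodes > 20)
    stop("hidden_nodes must lie in [2, 20]")
  if (iterations %% 100 != 0 || iterations < 100 || iterations > 5000)
    stop("iterations must be a multiple of 100 in [100, 5000]")
  if (restarts < 1) stop("restarts must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(band_subset = sort(band_subset),
                 hidden_nodes = as.integer(hidden_nodes),
                 iterations = as.integer(iterations),
                 restarts = as.integer(restarts),
                 learning_rate = learning_rate,
                 activation = activation,
                 seed = as.integer(seed)),
            class = "ann_config")
}

# deterministic seed for restart r of a config (pure function, 32-bit safe)
restart_seed <- function(seed, r) {
  as.integer((abs(as.numeric(seed)) + 104729 * as.numeric(r)) %% 2147483647)
}

act_fun <- function(activation) {
  switch(activation,
         sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                        df = function(a) a * (1 - a)),
         tanh = list(f = tanh,
                     df = function(a) 1 - a^2))
}

#' Fit a one-hidden-layer perceptron for stem water potential
#'
#' The central fitting function of the package.  Regresses psi (MPa) on
#' the selected mean canopy band reflectances with a single-hidden-layer
#' perceptron trained by full-batch back-propagation.  Inputs and target
#' are standardized to zero mean and unit variance before training and
#' predictions are mapped back to MPa.  The network is trained
#' `config$restarts` times from independent seeded uniform(-0.5, 0.5)
#' initializations for exactly `config$iterations` epochs each, and the
#' restart attaining the lowest training RMSE is returned.
#'
#' @param table feature table: a data frame with one column per band
#'   (named `R530`, `R550`, ... after the wavelengths in
#'   `config$band_subset`) and the target column `psi_mpa` (MPa,
#'   negative).
#' @param config an [ann_config()].
#' @return An object of class `psi_mlp` with components `config`,
#'   `weights` (`W1`, `b1`, `w2`, `b2` on the standardized scale),
#'   `input_scaling`, `target_scaling`, `restart_rmse` (MPa, one per
#'   restart), `selected_restart`, `fitted_values`, `residuals`,
#'   `training_rmse`, `training_r2` (`NA` with a flag for a constant
#'   target), and `data` (the training table).
#' @seealso [predict.psi_mlp()], [grid_search()], [ablation_study()]
#' @export
#' @examples
#' set.seed(1)
#' tab <- data.frame(R800 = runif(40, 0.3, 0.5))
#' tab$psi_mpa <- 0.5 * tab$R800 - 1.5
#' fit <- train_mlp(tab, ann_config(band_subset = 800, hidden_nodes = 2,
#'                                  iterations = 2000, restarts = 3))
#' fit$training_r2
train_mlp <- function(table, config) {
  stopifnot(inherits(config, "ann_config"))
  feat_names <- paste0("R", config$band_subset)
  missing <- setdiff(feat_names, names(table))
  if (length(missing))
    stop("feature table lacks column(s) ", paste(missing, collapse = ", "))
  if (!"psi_mpa" %in% names(table)) stop("feature table needs a psi_mpa column")
  X <- as.matrix(table[, feat_names, drop = FALSE])
  y <- table$psi_mpa
  n <- nrow(X)
  if (n < 2 * config$hidden_nodes)
    stop("need at least ", 2 * config$hidden_nodes,
         " observations for ", config$hidden_nodes, " hidden nodes (have ",
         n, ")")
  if (anyNA(X) || anyNA(y)) stop("feature table contains missing values")

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  y_sd <- stats::sd(y)
  constant_target <- !is.finite(y_sd) || y_sd == 0
  y_scale <- if (constant_target) 1 else y_sd
  ys <- (y - y_center) / y_scale

  act <- act_fun(config$activation)
  p <- ncol(Xs); h <- config$hidden_nodes; lr <- config$learning_rate

  best <- NULL
  restart_rmse <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    set.seed(restart_seed(config$seed, r))
    W1 <- matrix(stats::runif(p * h, -0.5, 0.5), p, h)
    b1 <- stats::runif(h, -0.5, 0.5)
    w2 <- stats::runif(h, -0.5, 0.5)
    b2 <- stats::runif(1, -0.5, 0.5)
    for (it in seq_len(config$iterations)) {
      A <- act$f(sweep(Xs %*% W1, 2, b1, "+"))
      yhat <- drop(A %*% w2) + b2
      d <- (yhat - ys) / n
      gw2 <- drop(crossprod(A, d)); gb2 <- sum(d)
      dA <- tcrossprod(d, w2) * act$df(A)
      gW1 <- crossprod(Xs, dA); gb1 <- colSums(dA)
      W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
      w2 <- w2 - lr * gw2; b2 <- b2 - lr * gb2
    }
    if (!all(is.finite(W1)) || !all(is.finite(w2)) ||
        !all(is.finite(b1)) || !is.finite(b2))
      stop("non-finite weights after training (restart ", r,
           "): learning rate too large for this data")
    A <- act$f(sweep(Xs %*% W1, 2, b1, "+"))
    yhat <- drop(A %*% w2) + b2
    rmse <- sqrt(mean((yhat - ys)^2)) * y_scale
    restart_rmse[r] <- rmse
    if (is.null(best) || rmse < best$rmse) {
      best <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                   rmse = rmse, restart = r, fitted_std = yhat)
    }
  }

  fitted <- best$fitted_std * y_scale + y_center
  res <- y - fitted
  r2 <- if (constant_target || stats::sd(fitted) == 0) NA_real_ else
    stats::cor(fitted, y)^2
  structure(list(
    config = config,
    weights = best[c("W1", "b1", "w2", "b2")],
    input_scaling = list(center = x_center, scale = x_scale),
    target_scaling = list(center = y_center, scale = y_scale),
    restart_rmse = restart_rmse,
    selected_restart = best$restart,
    fitted_values = fitted,
    residuals = res,
    training_rmse = best$rmse,
    training_r2 = r2,
    constant_target = constant_target,
    feature_names = feat_names,
    n_obs = n,
    data = table
  ), class = "psi_mlp")
}

#' Predict stem water potential from a fitted perceptron
#'
#' Deterministic forward pass; features are bound by column name, so the
#' column order of `newdata` is irrelevant.
#'
#' @param object a `psi_mlp` from [train_mlp()].
#' @param newdata data frame (or named-column matrix) containing the
#'   model's feature columns; defaults to the training data.
#' @param ... unused.
#' @return Numeric vector of psi estimates in MPa.
#' @export
predict.psi_mlp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    stop("newdata lacks feature column(s) ", paste(missing, collapse = ", "))
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$input_scaling$center),
              2, object$input_scaling$scale, "/")
  act <- act_fun(object$config$activation)
  A <- act$f(sweep(Xs %*% object$weights$W1, 2, object$weights$b1, "+"))
  yhat <- drop(A %*% object$weights$w2) + object$weights$b2
  yhat * object$target_scaling$scale + object$target_scaling$center
}

#' @export
fitted.psi_mlp <- function(object, ...) object$fitted_values

#' @export
residuals.psi_mlp <- function(object, ...) object$residuals

#' @export
coef.psi_mlp <- function(object, ...) object$weights

#' @export
print.psi_mlp <- function(x, ...) {
  cat(sprintf(
    "<psi_mlp> %d-%d-1 %s MLP on bands %s nm\n",
    length(x$feature_names), x$config$hidden_nodes, x$config$activation,
    paste(x$config$band_subset, collapse = "/")))
  cat(sprintf(
    "  %d obs, %d epochs x %d restarts; training RMSE %.4f MPa (restart %d), R2 %s\n",
    x$n_obs, x$config$iterations, x$config$restarts, x$training_rmse,
    x$selected_restart,
    if (is.na(x$training_r2)) "undefined (constant target)" else
      sprintf("%.3f", x$training_r2)))
  invisible(x)
}

#' @export
summary.psi_mlp <- function(object, ...) {
  structure(list(model = object), class = "summary.psi_mlp")
}

#' @export
print.summary.psi_mlp <- function(x, ...) {
  m <- x$model
  print(m)
  cat("  restart RMSE (MPa): ")
  cat(paste(sprintf("%.4f", m$restart_rmse), collapse = " "), "\n")
  cat("  residual quartiles (MPa):\n")
  print(signif(stats::quantile(m$residuals), 4))
  invisible(x)
}

#' @export
plot.psi_mlp <- function(x, ...) {
  obs <- x$data$psi_mpa
  graphics::plot(obs, x$fitted_values,
                 xlab = "observed psi (MPa)", ylab = "fitted psi (MPa)",
                 main = "MLP fit: observed vs fitted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize a fitted perceptron to YAML
#'
#' Writes weights, scalings and config in a portable, human-inspectable
#' form readable by [load_mlp()].
#'
#' @param model a `psi_mlp`.
#' @param path output YAML file.
#' @return Invisibly, `path`.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "psi_mlp"))
  obj <- list(
    config = unclass(model$config),
    feature_names = model$feature_names,
    input_scaling = lapply(model$input_scaling, as.numeric),
    target_scaling = model$target_scaling,
    weights = list(W1 = as.numeric(model$weights$W1),
                   W1_dim = dim(model$weights$W1),
                   b1 = as.numeric(model$weights$b1),
                   w2 = as.numeric(model$weights$w2),
                   b2 = as.numeric(model$weights$b2)),
    restart_rmse = model$restart_rmse,
    selected_restart = model$selected_restart,
    training_rmse = model$training_rmse,
    training_r2 = model$training_r2
  )
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' Load a serialized perceptron
#'
#' @param path YAML file written by [save_mlp()].
#' @return A `psi_mlp` (without training data; `fitted_values`,
#'   `residuals` are absent).
#' @export
load_mlp <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- obj$config
  config <- ann_config(band_subset = cfg$band_subset,
                       hidden_nodes = cfg$hidden_nodes,
                       iterations = cfg$iterations,
                       restarts = cfg$restarts,
                       learning_rate = cfg$learning_rate,
                       activation = cfg$activation,
                       seed = cfg$seed)
  structure(list(
    config = config,
    weights = list(
      W1 = matrix(obj$weights$W1, obj$weights$W1_dim[1], obj$weights$W1_dim[2]),
      b1 = obj$weights$b1, w2 = obj$weights$w2, b2 = obj$weights$b2),
    input_scaling = list(
      center = stats::setNames(as.numeric(obj$input_scaling$center),
                               obj$feature_names),
      scale = stats::setNames(as.numeric(obj$input_scaling$scale),
                              obj$feature_names)),
    target_scaling = obj$target_scaling,
    restart_rmse = obj$restart_rmse,
    selected_restart = obj$selected_restart,
    training_rmse = obj$training_rmse,
    training_r2 = obj$training_r2,
    feature_names = obj$feature_names,
    n_obs = NA_integer_
  ), class = "psi_mlp")
}
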