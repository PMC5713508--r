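#' Hyperparameter grid search with restarts
#'
#' The trial-and-error protocol for choosing the MLP architecture: every
#' combination of hidden-node count and iteration count is trained
#' `restarts` times from independent seeded initializations, and the
#' combination with the lowest mean training RMSE across restarts is
#' selected (ties broken by fewer hidden nodes, then fewer iterations).
#' The full protocol spans nodes 2..20 and iterations 100..5000 in steps
#' of 100 with 20 restarts (950 combinations); reduced ranges are accepted
#' for desk-scale work.
#'
#' The whole search is deterministic given `seed`: each combination trains
#' under a seed derived by [grid_combo_seed()], so any combination can be
#' reproduced in isolation.
#'
#' @param table feature table (see [train_mlp()]).
#' @param band_subset wavelengths (nm) used as inputs.
#' @param node_range integer vector of hidden-node counts (subset of
#'   2..20).
#' @param iter_range integer vector of epoch counts (multiples of 100 in
#'   100..5000).
#' @param restarts restarts per combination (default 20).
#' @param seed integer seed for the whole search.
#' @param learning_rate,activation passed to [ann_config()].
#' @return An object of class `psi_grid_search`: `record` (data frame:
#'   `hidden_nodes`, `iterations`, `mean_rmse`, `sd_rmse`, `best_rmse`),
#'   `selected` (row of the chosen combination), and `model` (the selected
#'   combination's best `psi_mlp`).
#' @export
grid_search <- function(table, band_subset,
                        node_range = 2:20,
                        iter_range = seq(100, 5000, by = 100),
                        restarts = 20,
                        seed = 1L,
                        learning_rate = 0.5,
                        activation = "sigmoid") {
  if (!length(node_range) || !length(iter_range))
    stop("empty hyperparameter grid")
  grid <- expand.grid(iterations = sort(iter_range),
                      hidden_nodes = sort(node_range))[, 2:1]
  # ordered nodes-then-iterations ascending so that keeping the first
  # strict minimum realizes the tie-break (fewer nodes, then fewer epochs)
  grid <- grid[order(grid$hidden_nodes, grid$iterations), ]
  grid$hidden_nodes <- as.integer(grid$hidden_nodes)
  grid$iterations <- as.integer(grid$iterations)
  best_i <- NA_integer_
  best_model <- NULL
  rec <- cbind(grid, mean_rmse = NA_real_, sd_rmse = NA_real_,
               best_rmse = NA_real_)
  for (i in seq_len(nrow(grid))) {
    cfg <- ann_config(band_subset = band_subset,
                      hidden_nodes = grid$hidden_nodes[i],
                      iterations = grid$iterations[i],
                      restarts = restarts,
                      learning_rate = learning_rate,
                      activation = activation,
                      seed = grid_combo_seed(seed, grid$hidden_nodes[i],
                                             grid$iterations[i]))
    fit <- train_mlp(table, cfg)
    rec$mean_rmse[i] <- mean(fit$restart_rmse)
    rec$sd_rmse[i] <- stats::sd(fit$restart_rmse)
    rec$best_rmse[i] <- min(fit$restart_rmse)
    if (is.na(best_i) || rec$mean_rmse[i] < rec$mean_rmse[best_i]) {
      best_i <- i
      best_model <- fit
    }
  }
  rownames(rec) <- NULL
  structure(list(record = rec,
                 selected = rec[best_i, c("hidden_nodes", "iterations",
                                          "mean_rmse", "sd_rmse",
                                          "best_rmse")],
                 model = best_model,
                 seed = as.integer(seed)),
            class = "psi_grid_search")
}

#' Deterministic per-combination seed for [grid_search()]
#'
#' Pure function of the search seed and the combination, so a single
#' combination can be replayed independently of the loop.
#'
#' @param seed grid-search seed.
#' @param hidden_nodes,iterations the combination.
#' @return Integer seed for [ann_config()].
#' @export
grid_combo_seed <- function(seed, hidden_nodes, iterations) {
  as.integer((abs(as.numeric(seed)) %% 1e6 * 131 +
                as.numeric(hidden_nodes) * 523 +
                as.numeric(iterations) / 100 * 7919) %% 2147483647)
}

#' @export
print.psi_grid_search <- function(x, ...) {
  cat(sprintf("<psi_grid_search> %d combinations x %d restarts\n",
              nrow(x$record), x$model$config$restarts))
  cat(sprintf("  selected: %d nodes, %d epochs (mean RMSE %.4f MPa, best %.4f)\n",
              x$selected$hidden_nodes, x$selected$iterations,
              x$selected$mean_rmse, x$selected$best_rmse))
  invisible(x)
}

# the seven band subsets of the ablation protocol: the full six-band model
# first, then each model omitting exactly one wavelength in ascending order
ablation_subsets <- function() {
  all6 <- c(530, 550, 570, 670, 700, 800)
  subsets <- c(list(all6), lapply(all6, function(wl) setdiff(all6, wl)))
  names(subsets) <- paste0("ANN-", seq_along(subsets))
  subsets
}

#' Band-ablation study
#'
#' Trains seven MLP models — the full six-band model (ANN-1) and one model
#' per omitted wavelength (ANN-2 drops 530 nm, ..., ANN-7 drops 800 nm) —
#' each through its own [grid_search()] on the calibration rows of a
#' treatment-stratified split, then scores each selected model on the
#' held-out validation rows.
#'
#' @param table feature table with all six band columns and `psi_mpa`
#'   (see [build_feature_table()]).
#' @param seed integer seed driving the split and all searches.
#' @param node_range,iter_range,restarts grid passed to [grid_search()]
#'   (defaults are the desk-scale reduced grid: nodes 2..8, epochs
#'   100..1000 by 100, 5 restarts).
#' @param learning_rate,activation passed through to [grid_search()].
#' @return An object of class `psi_ablation`: `summary` (data frame with
#'   one row per model: `model`, `bands`, `n_bands`, `hidden_nodes`,
#'   `iterations`, `training_r2`, and the validation statistics `r2`,
#'   `mae`, `rmse`, `re_pct`, `d`), `models` (named list of `psi_mlp`),
#'   `searches` (named list of `psi_grid_search`), `split` (the
#'   `split_plan` used), and `reports` (named list of `eval_report`).
#' @export
ablation_study <- function(table, seed = 1L,
                           node_range = 2:8,
                           iter_range = seq(100, 1000, by = 100),
                           restarts = 5,
                           learning_rate = 0.5,
                           activation = "sigmoid") {
  all6 <- c(530, 550, 570, 670, 700, 800)
  missing <- setdiff(paste0("R", all6), names(table))
  if (length(missing))
    stop("feature table lacks band column(s) ",
         paste(missing, collapse = ", "))
  split <- split_calibration_validation(table, seed)
  cal <- table[split$calibration_rows, , drop = FALSE]
  val <- table[split$validation_rows, , drop = FALSE]
  subsets <- ablation_subsets()
  models <- list(); searches <- list(); reports <- list()
  rows <- list()
  for (nm in names(subsets)) {
    gs <- grid_search(cal, subsets[[nm]],
                      node_range = node_range, iter_range = iter_range,
                      restarts = restarts, seed = seed,
                      learning_rate = learning_rate,
                      activation = activation)
    pred <- predict(gs$model, val)
    rep <- evaluate(val$psi_mpa, pred, model_id = nm)
    models[[nm]] <- gs$model
    searches[[nm]] <- gs
    reports[[nm]] <- rep
    rows[[nm]] <- data.frame(
      model = nm,
      bands = paste(subsets[[nm]], collapse = "/"),
      n_bands = length(subsets[[nm]]),
      hidden_nodes = gs$selected$hidden_nodes,
      iterations = gs$selected$iterations,
      training_r2 = gs$model$training_r2,
      r2 = rep$r_squared, mae = rep$mae, rmse = rep$rmse,
      re_pct = rep$re_pct, d = rep$d,
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 models = models, searches = searches,
                 split = split, reports = reports),
            class = "psi_ablation")
}

#' @export
print.psi_ablation <- function(x, ...) {
  cat("<psi_ablation> band-ablation study\n")
  s <- x$summary
  s$training_r2 <- round(s$training_r2, 3)
  for (cl in c("r2", "mae", "rmse", "re_pct", "d"))
    s[[cl]] <- round(s[[cl]], 3)
  print(s, row.names = FALSE)
  invisible(x)
}
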