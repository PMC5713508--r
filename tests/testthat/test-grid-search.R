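noisy_table <- function(n = 40, seed = 13) {
  set.seed(seed)
  tab <- data.frame(R670 = runif(n, 0.05, 0.10), R800 = runif(n, 0.30, 0.50))
  tab$psi_mpa <- -2 + 2.5 * tab$R800 - 6 * tab$R670 +
    4 * (tab$R800 - 0.4)^2 + rnorm(n, 0, 0.03)
  tab
}

test_that("a single-combination grid selects that combination", {
  tab <- noisy_table()
  gs <- grid_search(tab, c(670, 800), node_range = 3, iter_range = 200,
                    restarts = 2, seed = 1)
  expect_identical(nrow(gs$record), 1L)
  expect_identical(gs$selected$hidden_nodes, 3L)
  expect_identical(gs$selected$iterations, 200L)
  expect_error(grid_search(tab, 800, node_range = integer(0),
                           iter_range = 100), "empty")
})

test_that("grid selection equals an exhaustive independent replay", {
  tab <- noisy_table()
  nodes <- c(2, 4); iters <- c(100, 300)
  gs <- grid_search(tab, c(670, 800), node_range = nodes,
                    iter_range = iters, restarts = 3, seed = 7)
  # oracle replay: re-run every combination in isolation
  replay <- expand.grid(hidden_nodes = nodes, iterations = iters)
  replay$mean_rmse <- NA_real_; replay$best_rmse <- NA_real_
  for (i in seq_len(nrow(replay))) {
    fit <- train_mlp(tab, ann_config(
      band_subset = c(670, 800),
      hidden_nodes = replay$hidden_nodes[i],
      iterations = replay$iterations[i], restarts = 3,
      seed = grid_combo_seed(7, replay$hidden_nodes[i],
                             replay$iterations[i])))
    replay$mean_rmse[i] <- mean(fit$restart_rmse)
    replay$best_rmse[i] <- min(fit$restart_rmse)
  }
  best <- replay[order(replay$mean_rmse, replay$hidden_nodes,
                       replay$iterations), ][1, ]
  expect_identical(gs$selected$hidden_nodes, as.integer(best$hidden_nodes))
  expect_identical(gs$selected$iterations, as.integer(best$iterations))
  expect_equal(gs$selected$mean_rmse, best$mean_rmse)
  # reported per-combination RMSE is the min over restarts
  expect_equal(gs$selected$best_rmse, best$best_rmse)
  # argmin property holds over the whole record
  expect_true(all(gs$selected$mean_rmse <= gs$record$mean_rmse))
  # determinism of the whole record
  gs2 <- grid_search(tab, c(670, 800), node_range = nodes,
                     iter_range = iters, restarts = 3, seed = 7)
  expect_identical(gs$record, gs2$record)
  expect_identical(gs$model$weights, gs2$model$weights)
})

test_that("the ablation subsets follow the one-band-out protocol", {
  subsets <- vinepsi:::ablation_subsets()
  expect_length(subsets, 7L)
  expect_identical(subsets[["ANN-1"]], c(530, 550, 570, 670, 700, 800))
  expect_identical(subsets[["ANN-2"]], c(550, 570, 670, 700, 800))
  expect_identical(subsets[["ANN-7"]], c(530, 550, 570, 670, 700))
  expect_identical(vapply(subsets, length, 1L),
                   c("ANN-1" = 6L, "ANN-2" = 5L, "ANN-3" = 5L, "ANN-4" = 5L,
                     "ANN-5" = 5L, "ANN-6" = 5L, "ANN-7" = 5L))
})

test_that("removing the NIR band degrades a NIR-driven target", {
  cfg <- scene_config(seed = 23, noise_cv = 0.02,
                      stress_response = red_nir_only_response())
  tab <- build_feature_table(cfg, n_flights = 2, mask_source = "true")
  split <- split_calibration_validation(tab, 23)
  cal <- tab[split$calibration_rows, ]
  val <- tab[split$validation_rows, ]
  rmse_of <- function(bands) {
    gs <- grid_search(cal, bands, node_range = 2:4,
                      iter_range = c(200, 400), restarts = 2, seed = 23)
    evaluate(val$psi_mpa, predict(gs$model, val))$rmse
  }
  full <- rmse_of(c(530, 550, 570, 670, 700, 800))
  no_nir <- rmse_of(c(530, 550, 570, 670, 700))
  expect_lt(full, no_nir)
})

test_that("the ablation study reports seven scored models", {
  cfg <- scene_config(seed = 29, n_repetitions = 2, plants_per_plot = 2)
  tab <- build_feature_table(cfg, n_flights = 3, mask_source = "true")
  abl <- ablation_study(tab, seed = 29, node_range = 2:3,
                        iter_range = c(100, 200), restarts = 2)
  expect_identical(nrow(abl$summary), 7L)
  expect_identical(abl$summary$model, paste0("ANN-", 1:7))
  expect_identical(abl$summary$n_bands, c(6L, rep(5L, 6)))
  expect_true(all(is.finite(abl$summary$rmse)))
  expect_true(all(abl$summary$d >= 0 & abl$summary$d <= 1))
  # training R2 recorded from each selected model
  expect_equal(abl$summary$training_r2[1], abl$models[["ANN-1"]]$training_r2)
})
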