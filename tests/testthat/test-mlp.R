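linear_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  tab <- data.frame(R800 = runif(n, 0.30, 0.55))
  tab$psi_mpa <- 0.5 * tab$R800 - 1.5
  tab
}

test_that("a noiseless linear target is fitted almost exactly", {
  tab <- linear_table()
  fit <- train_mlp(tab, ann_config(band_subset = 800, hidden_nodes = 2,
                                   iterations = 5000, restarts = 3, seed = 1))
  expect_gte(fit$training_r2, 0.999)
  expect_lt(max(abs(predict(fit, tab) - tab$psi_mpa)), 1e-2)
})

test_that("a constant target is flagged and predicted as the constant", {
  tab <- linear_table()
  tab$psi_mpa <- -1.1
  fit <- train_mlp(tab, ann_config(band_subset = 800, hidden_nodes = 2,
                                   iterations = 500, restarts = 2, seed = 1))
  expect_true(fit$constant_target)
  expect_true(is.na(fit$training_r2))
  expect_lt(mean(abs(fit$fitted_values - (-1.1))), 1e-3)
})

test_that("features bind by name, not by column position", {
  set.seed(2)
  tab <- data.frame(R670 = runif(30, 0.05, 0.1), R800 = runif(30, 0.3, 0.5))
  tab$psi_mpa <- -1 + 2 * tab$R800 - 5 * tab$R670
  fit <- train_mlp(tab, ann_config(band_subset = c(670, 800),
                                   hidden_nodes = 3, iterations = 1000,
                                   restarts = 2, seed = 4))
  permuted <- tab[, c("R800", "psi_mpa", "R670")]
  expect_identical(predict(fit, permuted), predict(fit, tab))
  expect_error(predict(fit, tab[, "R800", drop = FALSE]), "R670")
})

test_that("the forward pass matches hand-computed matrix arithmetic", {
  W1 <- matrix(c(0.3, -0.2, 0.1, 0.5), 2, 2)
  b1 <- c(0.1, -0.4); w2 <- c(1.2, -0.7); b2 <- 0.05
  model <- structure(list(
    config = ann_config(band_subset = c(670, 800), hidden_nodes = 2,
                        iterations = 100, restarts = 1),
    weights = list(W1 = W1, b1 = b1, w2 = w2, b2 = b2),
    input_scaling = list(center = c(R670 = 0.07, R800 = 0.4),
                         scale = c(R670 = 0.01, R800 = 0.05)),
    target_scaling = list(center = -1.1, scale = 0.3),
    feature_names = c("R670", "R800")), class = "psi_mlp")
  new <- data.frame(R670 = c(0.06, 0.08), R800 = c(0.35, 0.45))
  xs <- cbind((new$R670 - 0.07) / 0.01, (new$R800 - 0.4) / 0.05)
  hidden <- 1 / (1 + exp(-(xs %*% W1 + rep(1, 2) %o% b1)))
  manual <- drop(hidden %*% w2) + b2
  manual <- manual * 0.3 - 1.1
  expect_equal(predict(model, new), manual, tolerance = 1e-12)
})

test_that("training is deterministic and selects the best restart", {
  tab <- linear_table(seed = 3)
  tab$psi_mpa <- tab$psi_mpa + rnorm(nrow(tab), 0, 0.05)
  cfg <- ann_config(band_subset = 800, hidden_nodes = 3, iterations = 400,
                    restarts = 4, seed = 11)
  f1 <- train_mlp(tab, cfg)
  f2 <- train_mlp(tab, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$restart_rmse, f2$restart_rmse)
  expect_equal(f1$training_rmse, min(f1$restart_rmse))
  expect_identical(f1$selected_restart, which.min(f1$restart_rmse))
  # restart seeds form a prefix sequence: adding restarts never raises the
  # selected RMSE
  f3 <- train_mlp(tab, ann_config(band_subset = 800, hidden_nodes = 3,
                                  iterations = 400, restarts = 8, seed = 11))
  expect_identical(f3$restart_rmse[1:4], f1$restart_rmse)
  expect_lte(f3$training_rmse, f1$training_rmse)
})

test_that("undersized tables and exploding training are rejected", {
  tab <- linear_table(n = 5)
  expect_error(train_mlp(tab, ann_config(band_subset = 800, hidden_nodes = 4,
                                         iterations = 100, restarts = 1)),
               "at least 8 observations")
  tab2 <- linear_table(n = 30)
  expect_error(
    train_mlp(tab2, ann_config(band_subset = 800, hidden_nodes = 5,
                               iterations = 2000, restarts = 1,
                               learning_rate = 1e4, seed = 2)),
    "learning rate")
  expect_error(ann_config(hidden_nodes = 25), "hidden_nodes")
  expect_error(ann_config(iterations = 150), "iterations")
})

test_that("an independently trained nnet reaches a comparable fit", {
  skip_if_not_installed("nnet")
  set.seed(8)
  tab <- data.frame(R670 = runif(60, 0.05, 0.10), R800 = runif(60, 0.3, 0.5))
  tab$psi_mpa <- -2 + 3 * tab$R800^2 - 6 * tab$R670
  fit <- train_mlp(tab, ann_config(band_subset = c(670, 800),
                                   hidden_nodes = 4, iterations = 2000,
                                   restarts = 5, seed = 6))
  xs <- scale(as.matrix(tab[, c("R670", "R800")]))
  ys <- scale(tab$psi_mpa)
  nn <- nnet::nnet(xs, ys, size = 4, linout = TRUE, trace = FALSE,
                   maxit = 500)
  r2_nnet <- cor(predict(nn, xs)[, 1], ys[, 1])^2
  expect_gte(fit$training_r2, 0.99)
  expect_gte(r2_nnet, 0.99)
  expect_lt(abs(fit$training_r2 - r2_nnet), 0.01)
})

test_that("serialization round-trips predictions through YAML", {
  tab <- linear_table(seed = 5)
  fit <- train_mlp(tab, ann_config(band_subset = 800, hidden_nodes = 2,
                                   iterations = 1000, restarts = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".yaml")
  save_mlp(fit, path)
  back <- load_mlp(path)
  expect_equal(predict(back, tab), predict(fit, tab), tolerance = 1e-12)
})
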