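trained_toy_model <- function() {
  set.seed(40)
  tab <- data.frame(R670 = runif(60, 0.04, 0.10),
                    R800 = runif(60, 0.30, 0.52))
  tab$psi_mpa <- -2.2 + 2.5 * tab$R800 - 4 * tab$R670
  train_mlp(tab, ann_config(band_subset = c(670, 800), hidden_nodes = 3,
                            iterations = 1500, restarts = 2, seed = 40))
}

test_that("stress classes follow the treatment thresholds and gap rule", {
  expect_identical(classify_stress(-0.5), "T0")
  expect_identical(classify_stress(-1.0), "T1")
  expect_identical(classify_stress(-1.3), "T2")
  expect_identical(classify_stress(-1.6), "T3")
  # gap midpoints tie to the more stressed class
  expect_identical(classify_stress(-0.85), "T1")
  expect_identical(classify_stress(-1.15), "T2")
  # gap values go to the nearer boundary
  expect_identical(classify_stress(-0.82), "T0")
  expect_identical(classify_stress(-0.88), "T1")
  expect_identical(classify_stress(-1.12), "T1")
  expect_identical(classify_stress(-1.18), "T2")
  # boundary values belong to their stated ranges
  expect_identical(classify_stress(c(-0.9, -1.1, -1.2, -1.4)),
                   c("T1", "T1", "T2", "T2"))
  # monotone: more negative psi never yields a less stressed class
  grid <- seq(-0.1, -2.3, by = -0.01)
  cls <- as.integer(sub("T", "", classify_stress(grid)))
  expect_true(all(diff(cls) >= 0))
  expect_error(classify_stress(NA_real_), "finite")
})

test_that("map prediction equals looped scalar prediction", {
  model <- trained_toy_model()
  sc <- generate_scene(small_scene_config(seed = 41))
  mask <- sc$truth$canopy_mask
  smap <- predict_map(model, sc$stack, mask)
  expect_true(all(is.na(smap$psi_map[!mask])))
  idx <- which(mask)[seq(1, sum(mask), length.out = 50)]
  r670 <- get_band(sc$stack, 670); r800 <- get_band(sc$stack, 800)
  for (i in idx) {
    scalar <- predict(model, data.frame(R670 = r670[i], R800 = r800[i]))
    scalar <- min(max(scalar, -2.5), 0)
    expect_equal(smap$psi_map[i], scalar, tolerance = 1e-12)
  }
})

test_that("an all-false mask and a uniform stack behave as expected", {
  model <- trained_toy_model()
  sc <- generate_scene(small_scene_config(seed = 42, noise_cv = 0))
  empty <- matrix(FALSE, dim(sc$stack)[1], dim(sc$stack)[2])
  smap0 <- predict_map(model, sc$stack, empty)
  expect_true(all(is.na(smap0$psi_map)))
  uni <- band_stack(array(rep(c(0.06, 0.1, 0.08, 0.05, 0.15, 0.45),
                              each = 36), c(6, 6, 6)))
  m <- matrix(TRUE, 6, 6)
  smap1 <- predict_map(model, uni, m)
  expect_equal(length(unique(as.vector(smap1$psi_map))), 1L)
})

test_that("implausible predictions are clamped and counted", {
  model <- trained_toy_model()
  # reflectances far outside the training range force wild extrapolation
  wild <- band_stack(array(rep(c(0.06, 0.1, 0.08, 1.1, 0.15, 0.01),
                               each = 16), c(4, 4, 6)))
  smap <- predict_map(model, wild, matrix(TRUE, 4, 4),
                      clamp_range = c(-1.05, -0.95))
  expect_true(all(smap$psi_map >= -1.05 & smap$psi_map <= -0.95))
  expect_gt(smap$n_clamped, 0)
})

test_that("plot aggregation averages core canopy pixels and classifies", {
  model <- trained_toy_model()
  sc <- generate_scene(small_scene_config(seed = 43))
  smap <- predict_map(model, sc$stack, sc$truth$canopy_mask)
  agg <- aggregate_plots(smap, sc$layout)
  expect_identical(nrow(agg), nrow(sc$layout))
  # independent masked averaging oracle for each plot core
  for (i in seq_len(nrow(agg))) {
    l <- sc$layout[i, ]
    sub <- smap$psi_map[(l$cy0 + 1):l$cy1, (l$cx0 + 1):l$cx1]
    v <- sub[is.finite(sub)]
    expect_equal(agg$mean_psi[i], mean(v))
    expect_identical(agg$class[i], classify_stress(mean(v)))
  }
  # constant-psi plot classifies by its value
  flat <- smap
  flat$psi_map[is.finite(flat$psi_map)] <- -1.0
  agg_flat <- aggregate_plots(flat, sc$layout)
  expect_true(all(agg_flat$class == "T1"))
  # a layout whose core is empty reports zero pixels, without failing
  l2 <- sc$layout
  l2$cy1[1] <- l2$cy0[1]
  expect_warning(agg2 <- aggregate_plots(smap, l2), "zero canopy")
  expect_identical(agg2$n_pixels[1], 0L)
  expect_true(is.na(agg2$mean_psi[1]))
})

test_that("plot-mean predictions recover ground truth on the default scene", {
  cfg <- scene_config(seed = 47)  # noise_cv 0.05 default
  tab <- build_feature_table(cfg, n_flights = 3)
  sp <- split_calibration_validation(tab, 47)
  gs <- grid_search(tab[sp$calibration_rows, ], c(530, 550, 570, 670, 700, 800),
                    node_range = 2:5, iter_range = seq(200, 600, 200),
                    restarts = 3, seed = 47)
  sc <- generate_scene(cfg, flight = 1)
  seg <- segment_canopy(sc$stack)
  smap <- predict_map(gs$model, sc$stack, seg$mask)
  agg <- aggregate_plots(smap, sc$layout)
  truth <- sc$truth$psi_per_plot
  mae <- mean(abs(agg$mean_psi - truth$psi_mpa[match(agg$plot_id,
                                                     truth$plot_id)]))
  expect_lte(mae, 0.15)
})
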