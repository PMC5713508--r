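test_that("NDVI histogram frequencies sum to 100 and match direct counts", {
  m <- matrix(0.5, 10, 10)
  h <- ndvi_histogram(m, 50)
  expect_equal(sum(h$frequencies), 100)
  expect_identical(sum(h$frequencies > 0), 1L)
  expect_equal(max(h$frequencies), 100)

  m2 <- matrix(c(rep(0.2, 60), rep(0.7, 40)), 10, 10)
  h2 <- ndvi_histogram(m2, 100)
  expect_setequal(h2$frequencies[h2$frequencies > 0], c(60, 40))

  set.seed(9)
  m3 <- matrix(runif(500, -1, 1), 25, 20)
  h3 <- ndvi_histogram(m3, 40)
  # brute-force bin counting oracle
  counts <- vapply(seq_len(40), function(i) {
    lo <- h3$bin_edges[i]; hi <- h3$bin_edges[i + 1]
    sum(if (i == 40) m3 >= lo & m3 <= hi else m3 >= lo & m3 < hi)
  }, numeric(1))
  expect_equal(h3$frequencies, 100 * counts / 500)

  m4 <- matrix(NA_real_, 3, 3)
  expect_error(ndvi_histogram(m4), "valid NDVI")
})

test_that("double-normal fit recovers generating parameters", {
  set.seed(101)
  n <- 1e5
  x <- c(rnorm(n / 2, 0.2, 0.05), rnorm(n / 2, 0.7, 0.05))
  h <- ndvi_histogram(matrix(x, ncol = 1), 100)
  fit <- fit_double_normal(h$bin_edges, h$frequencies)
  expect_lt(abs(fit$mu1 - 0.2), 0.01)
  expect_lt(abs(fit$mu2 - 0.7), 0.01)
  expect_lt(abs(fit$sigma1 - 0.05), 0.01)
  expect_lt(abs(fit$sigma2 - 0.05), 0.01)
  expect_lt(abs(fit$w1 - 0.5), 0.05)
  expect_true(fit$mu1 < fit$mu2)
})

test_that("unimodal input yields a degenerate-fit error", {
  set.seed(7)
  x <- rnorm(5e4, 0.5, 0.05)
  h <- ndvi_histogram(matrix(x, ncol = 1), 100)
  expect_error(fit_double_normal(h$bin_edges, h$frequencies),
               "degenerate|unimodal")
})

test_that("valley threshold sits at the mixture-density minimum", {
  model <- structure(list(w1 = 0.5, mu1 = 0.2, sigma1 = 0.05,
                          w2 = 0.5, mu2 = 0.7, sigma2 = 0.05,
                          bin_edges = seq(-1, 1, by = 0.02),
                          frequencies = rep(1, 100)),
                     class = "ndvi_mixture")
  v <- find_valley(model)
  expect_equal(v$valley_ndvi, 0.45, tolerance = 1e-3)

  # asymmetric weights: valley moves above the midpoint; check against an
  # independent dense evaluation of the mixture density
  model$w1 <- 0.7; model$w2 <- 0.3
  v2 <- find_valley(model)
  expect_gt(v2$valley_ndvi, 0.45)
  grid <- seq(0.2, 0.7, by = 1e-5)
  dens <- 0.7 * dnorm(grid, 0.2, 0.05) + 0.3 * dnorm(grid, 0.7, 0.05)
  expect_equal(v2$valley_ndvi, grid[which.min(dens)], tolerance = 2e-4)
})

test_that("valley occurrence reports the observed histogram frequency", {
  set.seed(33)
  x <- c(rnorm(6e4, 0.2, 0.05), rnorm(4e4, 0.7, 0.05))
  h <- ndvi_histogram(matrix(x, ncol = 1), 100)
  fit <- fit_double_normal(h$bin_edges, h$frequencies)
  v <- find_valley(fit)
  bin <- findInterval(v$valley_ndvi, h$bin_edges, all.inside = TRUE)
  expect_identical(v$valley_occurrence_pct, h$frequencies[bin])
  # fitted valley close to the empirical minimum-frequency bin between the
  # two modal bins
  modal1 <- which.max(h$frequencies * (h$mids < 0.45))
  modal2 <- which.max(h$frequencies * (h$mids > 0.45))
  between <- seq(modal1, modal2)
  # low-count bins in the gap tie at the minimum; the fitted valley must
  # fall within one bin width of the set of minimal-frequency bins
  emp_min <- h$mids[between[h$frequencies[between] ==
                              min(h$frequencies[between])]]
  expect_gte(v$valley_ndvi, min(emp_min) - 0.02 - 1e-9)
  expect_lte(v$valley_ndvi, max(emp_min) + 0.02 + 1e-9)
})

test_that("mask building counts cover and nests monotonically", {
  m <- matrix(seq(-0.5, 0.9, length.out = 1000), 25, 40)
  cm <- build_mask(m, 0.9)
  expect_equal(cm$fractional_cover_pct, 0)
  # 283 of 1000 valid pixels above threshold -> 28.3%
  thr <- sort(m)[1000 - 283]
  cm2 <- build_mask(m, thr)
  expect_equal(cm2$fractional_cover_pct, 28.3)
  # nodata pixels are non-canopy and not valid
  m[1, 1] <- NA
  cm3 <- build_mask(m, 0)
  expect_false(cm3$mask[1, 1])
  # raising the threshold never adds canopy pixels
  masks <- lapply(c(-0.2, 0.1, 0.4, 0.7), function(t) build_mask(m, t)$mask)
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))
  }
  expect_error(build_mask(m, 1.5), "threshold")
})

test_that("segmentation recovers the true canopy mask on a noisy scene", {
  sc <- generate_scene(scene_config(seed = 19, noise_cv = 0.1))
  seg <- segment_canopy(sc$stack)
  agreement <- mean(seg$mask$mask == sc$truth$canopy_mask)
  expect_gte(agreement, 0.99)
  fc_true <- 100 * mean(sc$truth$canopy_mask)
  expect_lt(abs(seg$mask$fractional_cover_pct - fc_true), 1)
  # valley lies between the soil and canopy NDVI populations
  expect_gt(seg$valley$valley_ndvi, seg$model$mu1)
  expect_lt(seg$valley$valley_ndvi, seg$model$mu2)
})
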