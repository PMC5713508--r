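#' NDVI occurrence histogram
#'
#' Bins an NDVI map into percent-occurrence frequencies over the valid
#' pixels.  The default 100 bins over \[-1, 1\] give the fine-grained
#' frequency curve used for soil-canopy distinction.
#'
#' @param ndvi_map numeric matrix of NDVI values; `NA` = nodata.
#' @param n_bins number of equal-width bins (>= 10).
#' @param range NDVI range covered by the bins.
#' @return List with `bin_edges` (length `n_bins + 1`), `mids` and
#'   `frequencies` (percent, summing to 100).
#' @export
ndvi_histogram <- function(ndvi_map, n_bins = 100, range = c(-1, 1)) {
  stopifnot(n_bins >= 10)
  x <- ndvi_map[is.finite(ndvi_map)]
  if (length(x) < 2) stop("need at least 2 valid NDVI pixels")
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  x <- pmin(pmax(x, range[1]), range[2])
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  list(bin_edges = edges,
       mids = (edges[-1] + edges[-length(edges)]) / 2,
       frequencies = 100 * counts / length(x))
}

#' Fit a double-normal distribution to an NDVI histogram
#'
#' Fits the two-component Gaussian mixture density
#' `w1 * N(mu1, sigma1) + w2 * N(mu2, sigma2)` (with `w1 + w2 = 1`) to the
#' binned NDVI density by nonlinear least squares
#' ([minpack.lm::nlsLM()]), starting from a moment-based initialization
#' obtained by a 2-means split of the binned values.  Components are
#' returned ordered so `mu1 < mu2` (component 1 = soil, 2 = canopy).
#'
#' @param bin_edges,frequencies a histogram as from [ndvi_histogram()]
#'   (frequencies in percent).
#' @return An object of class `ndvi_mixture`: `w1, mu1, sigma1, w2, mu2,
#'   sigma2`, the input histogram, and fit diagnostics (`rss`,
#'   `converged`).
#' @section Degenerate input: if the fitted component means coincide
#'   within 1e-3 or a component weight falls below 0.01, the input is
#'   effectively unimodal and an error is raised.
#' @export
fit_double_normal <- function(bin_edges, frequencies) {
  stopifnot(length(bin_edges) == length(frequencies) + 1L)
  if (sum(frequencies > 0) < 2) stop("histogram needs >= 2 nonzero bins")
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  bw <- diff(bin_edges)[1]
  dens <- frequencies / 100 / bw          # density per NDVI unit

  # moment init from a 2-means split of the binned sample
  p <- frequencies / sum(frequencies)
  mu_all <- sum(p * mids)
  left <- mids <= mu_all
  for (it in 1:20) {
    m1 <- sum(p[left] * mids[left]) / max(sum(p[left]), 1e-12)
    m2 <- sum(p[!left] * mids[!left]) / max(sum(p[!left]), 1e-12)
    new_left <- abs(mids - m1) <= abs(mids - m2)
    if (identical(new_left, left)) break
    left <- new_left
  }
  w1_0 <- max(min(sum(p[left]), 0.95), 0.05)
  s1_0 <- sqrt(max(sum(p[left] * (mids[left] - m1)^2) / max(sum(p[left]), 1e-12),
                   bw^2))
  s2_0 <- sqrt(max(sum(p[!left] * (mids[!left] - m2)^2) / max(sum(p[!left]), 1e-12),
                   bw^2))
  start <- list(w1 = w1_0, mu1 = min(m1, m2), s1 = s1_0,
                mu2 = max(m1, m2), s2 = s2_0)

  df <- data.frame(x = mids, y = dens)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ w1 * stats::dnorm(x, mu1, s1) + (1 - w1) * stats::dnorm(x, mu2, s2),
      data = df, start = start,
      lower = c(w1 = 1e-4, mu1 = bin_edges[1], s1 = bw / 10,
                mu2 = bin_edges[1], s2 = bw / 10),
      upper = c(w1 = 1 - 1e-4, mu1 = bin_edges[length(bin_edges)], s1 = 2,
                mu2 = bin_edges[length(bin_edges)], s2 = 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("double-normal fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  w1 <- unname(cf["w1"]); mu1 <- unname(cf["mu1"]); s1 <- unname(cf["s1"])
  mu2 <- unname(cf["mu2"]); s2 <- unname(cf["s2"]); w2 <- 1 - w1
  if (mu1 > mu2) {  # resolve label switching: component 1 = lower NDVI
    tmp <- c(mu1, s1, w1); mu1 <- mu2; s1 <- s2; w1 <- w2
    mu2 <- tmp[1]; s2 <- tmp[2]; w2 <- tmp[3]
  }
  if (abs(mu2 - mu1) < 1e-3 || min(w1, w2) < 0.01)
    stop("degenerate double-normal fit (means ",
         signif(mu1, 4), ", ", signif(mu2, 4), ", weights ",
         signif(w1, 3), ", ", signif(w2, 3),
         "): NDVI histogram looks unimodal")
  # a usable double-normal must show an actual inter-peak dip: the fitted
  # density minimum between the means must fall below both component peaks
  mix <- function(x) w1 * stats::dnorm(x, mu1, s1) + w2 * stats::dnorm(x, mu2, s2)
  between <- seq(mu1, mu2, length.out = 512)
  if (min(mix(between)) >= 0.99 * min(mix(mu1), mix(mu2)))
    stop("degenerate double-normal fit: no occurrence valley between the ",
         "component means; NDVI histogram looks unimodal")
  structure(list(
    w1 = w1, mu1 = mu1, sigma1 = s1,
    w2 = w2, mu2 = mu2, sigma2 = s2,
    bin_edges = bin_edges, frequencies = frequencies,
    rss = sum(stats::resid(fit)^2), converged = TRUE
  ), class = "ndvi_mixture")
}

#' Mixture density of a fitted NDVI double-normal
#'
#' @param model an `ndvi_mixture`.
#' @param x NDVI values.
#' @return density values.
#' @export
mixture_density <- function(model, x) {
  model$w1 * stats::dnorm(x, model$mu1, model$sigma1) +
    model$w2 * stats::dnorm(x, model$mu2, model$sigma2)
}

#' Locate the occurrence valley between the soil and canopy peaks
#'
#' Minimizes the fitted mixture density on `[mu1, mu2]` by dense grid
#' search (step <= 1e-4; ties broken toward the lower NDVI) and reads the
#' observed histogram frequency of the bin containing the valley.
#'
#' @param model an `ndvi_mixture` from [fit_double_normal()].
#' @param step grid step for the search (default 1e-4).
#' @return List with `valley_ndvi` and `valley_occurrence_pct`.
#' @export
find_valley <- function(model, step = 1e-4) {
  stopifnot(inherits(model, "ndvi_mixture"))
  grid <- seq(model$mu1, model$mu2, by = step)
  dens <- mixture_density(model, grid)
  valley <- grid[which.min(dens)]   # first minimum = lower NDVI on ties
  bin <- findInterval(valley, model$bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  list(valley_ndvi = valley,
       valley_occurrence_pct = model$frequencies[bin])
}

#' Binarize an NDVI map into a canopy mask
#'
#' Canopy = NDVI strictly greater than the threshold; the threshold bin
#' itself belongs to neither population and is excluded from canopy.
#' Nodata pixels are non-canopy and do not count as valid.
#'
#' @param ndvi_map numeric NDVI matrix (`NA` = nodata).
#' @param threshold NDVI threshold in (-1, 1).
#' @return An object of class `canopy_mask`: logical `mask`,
#'   `threshold_used`, `fractional_cover_pct` (canopy / valid pixels).
#' @export
build_mask <- function(ndvi_map, threshold) {
  if (!is.finite(threshold) || threshold <= -1 || threshold >= 1)
    stop("threshold must lie in (-1, 1)")
  valid <- is.finite(ndvi_map)
  mask <- valid & (ndvi_map > threshold)
  structure(list(
    mask = mask,
    threshold_used = threshold,
    fractional_cover_pct = 100 * sum(mask) / max(sum(valid), 1L)
  ), class = "canopy_mask")
}

#' Full soil-canopy segmentation of a reflectance stack
#'
#' Convenience wrapper: NDVI, histogram, double-normal fit, valley
#' threshold, mask.
#'
#' @param stack a [band_stack()] with 670 and 800 nm bands.
#' @param n_bins histogram bins (default 100 over \[-1, 1\]).
#' @return List with `ndvi`, `histogram`, `model` (`ndvi_mixture`),
#'   `valley` and `mask` (`canopy_mask`).
#' @export
segment_canopy <- function(stack, n_bins = 100) {
  ndvi <- compute_index("NDVI", stack)$values
  h <- ndvi_histogram(ndvi, n_bins)
  model <- fit_double_normal(h$bin_edges, h$frequencies)
  valley <- find_valley(model)
  mask <- build_mask(ndvi, valley$valley_ndvi)
  list(ndvi = ndvi, histogram = h, model = model,
       valley = valley, mask = mask)
}

#' @export
print.ndvi_mixture <- function(x, ...) {
  cat(sprintf(
    "<ndvi_mixture> soil: %.2f*N(%.3f, %.3f)  canopy: %.2f*N(%.3f, %.3f)\n",
    x$w1, x$mu1, x$sigma1, x$w2, x$mu2, x$sigma2))
  invisible(x)
}

#' @export
plot.ndvi_mixture <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  bw <- diff(x$bin_edges)[1]
  graphics::plot(mids, x$frequencies / 100 / bw, type = "h", col = "grey70",
                 xlab = "NDVI", ylab = "density",
                 main = "NDVI double-normal fit", ...)
  xs <- seq(x$bin_edges[1], x$bin_edges[length(x$bin_edges)], length.out = 512)
  graphics::lines(xs, mixture_density(x, xs), col = "red", lwd = 2)
  v <- find_valley(x)
  graphics::abline(v = v$valley_ndvi, col = "blue", lty = 2)
  invisible(x)
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat(sprintf("<canopy_mask> threshold NDVI > %.4f, fractional cover %.2f%%\n",
              x$threshold_used, x$fractional_cover_pct))
  invisible(x)
}
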