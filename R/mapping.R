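#' Per-pixel stem water potential map
#'
#' Applies a fitted perceptron to every canopy pixel of a reflectance
#' stack: the model's input bands are read per pixel, the forward pass is
#' evaluated, and predictions are clamped to a plausibility range (MLPs
#' extrapolate poorly outside the reflectance range they were trained on;
#' clamping is logged, not silent).
#'
#' @param model a `psi_mlp`.
#' @param stack a [band_stack()] containing the model's band subset.
#' @param mask a `canopy_mask` (or logical matrix); psi is predicted only
#'   where the mask is `TRUE` and the pixel is valid.
#' @param clamp_range numeric `c(lo, hi)` plausibility range in MPa
#'   (default `c(-2.5, 0)`).
#' @return An object of class `stress_map`: `psi_map` (matrix, MPa, `NA`
#'   off-canopy), `class_map` (character matrix of `"T0".."T3"`, `NA`
#'   off-canopy), `n_clamped`, `model_id`.
#' @export
predict_map <- function(model, stack, mask, clamp_range = c(-2.5, 0)) {
  stopifnot(inherits(model, "psi_mlp"), inherits(stack, "band_stack"))
  m <- if (inherits(mask, "canopy_mask")) mask$mask else mask
  need <- model$config$band_subset
  missing <- setdiff(need, stack$wavelengths)
  if (length(missing))
    stop("stack lacks band(s) ", paste(missing, collapse = ", "), " nm")
  H <- dim(stack$values)[1]; W <- dim(stack$values)[2]
  psi_map <- matrix(NA_real_, H, W)
  idx <- which(m & !stack$nodata)
  if (length(idx)) {
    feats <- vapply(need, function(wl) get_band(stack, wl)[idx],
                    numeric(length(idx)))
    feats <- matrix(feats, nrow = length(idx),
                    dimnames = list(NULL, paste0("R", need)))
    pred <- predict(model, as.data.frame(feats))
    n_clamped <- sum(pred < clamp_range[1] | pred > clamp_range[2])
    pred <- pmin(pmax(pred, clamp_range[1]), clamp_range[2])
    psi_map[idx] <- pred
  } else {
    n_clamped <- 0L
  }
  class_map <- matrix(NA_character_, H, W)
  class_map[idx] <- classify_stress(psi_map[idx])
  structure(list(psi_map = psi_map, class_map = class_map,
                 n_clamped = n_clamped,
                 clamp_range = clamp_range,
                 model_id = paste(need, collapse = "/")),
            class = "stress_map")
}

#' Classify psi into the four water-stress treatment classes
#'
#' Thresholds: T0 (no stress) psi > -0.8 MPa; T1 (moderate) -1.1 to -0.9;
#' T2 (strong) -1.4 to -1.2; T3 (severe) psi < -1.4.  Values in the
#' definition gaps (-0.9, -0.8) and (-1.2, -1.1) go to the nearer class
#' boundary, with ties (the gap midpoints -0.85 and -1.15) assigned to the
#' more stressed class.  The resulting rule is monotone: psi > -0.85 is
#' T0, (-1.15, -0.85\] is T1, \[-1.4, -1.15\] is T2, below -1.4 is T3.
#'
#' @param psi numeric vector of stem water potential, MPa; must be finite.
#' @return Character vector of `"T0"`, `"T1"`, `"T2"`, `"T3"`.
#' @export
#' @examples
#' classify_stress(c(-0.5, -1.0, -1.3, -1.6, -0.85))
classify_stress <- function(psi) {
  if (any(!is.finite(psi))) stop("psi must be finite")
  ifelse(psi > -0.85, "T0",
         ifelse(psi > -1.15, "T1",
                ifelse(psi >= -1.4, "T2", "T3")))
}

#' Aggregate a stress map per plot
#'
#' Summarizes predicted psi over each plot's border-eliminated core canopy
#' pixels and classifies the plot by its mean.
#'
#' @param stress_map a `stress_map` from [predict_map()].
#' @param layout plot layout data frame with core rectangles.
#' @return Data frame: `plot_id`, `treatment`, `repetition`, `mean_psi`,
#'   `sd_psi`, `n_pixels`, `class` (`NA` class for zero-pixel plots, which
#'   are reported via a warning, not an error).
#' @export
aggregate_plots <- function(stress_map, layout) {
  stopifnot(inherits(stress_map, "stress_map"))
  mask_all <- is.finite(stress_map$psi_map)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    v <- plot_core_values(stress_map$psi_map, mask_all, layout[i, ])
    data.frame(plot_id = layout$plot_id[i],
               treatment = layout$treatment[i],
               repetition = layout$repetition[i],
               mean_psi = if (length(v)) mean(v) else NA_real_,
               sd_psi = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_pixels = length(v),
               class = if (length(v)) classify_stress(mean(v))
                       else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$n_pixels == 0))
    warning("plot(s) with zero canopy pixels: ",
            paste(out$plot_id[out$n_pixels == 0], collapse = ", "))
  out
}

#' @export
print.stress_map <- function(x, ...) {
  v <- x$psi_map[is.finite(x$psi_map)]
  cat(sprintf(
    "<stress_map> model %s: %d canopy px, psi %.2f to %.2f MPa (%d clamped)\n",
    x$model_id, length(v),
    if (length(v)) max(v) else NA, if (length(v)) min(v) else NA,
    x$n_clamped))
  if (length(v)) {
    tab <- table(factor(x$class_map[is.finite(x$psi_map)],
                        levels = paste0("T", 0:3)))
    cat("  class mix: ",
        paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.stress_map <- function(x, ...) {
  v <- x$psi_map
  grDevices::dev.hold()
  on.exit(grDevices::dev.flush())
  graphics::image(t(v)[, nrow(v):1],
                  col = grDevices::hcl.colors(64, "RdYlGn"),
                  axes = FALSE, main = "predicted psi (MPa)", ...)
  invisible(x)
}

#' Write a stress map to disk
#'
#' The psi map goes to a 32-bit TIFF (via [write_band_stack()] encoding),
#' the class map to an 8-bit TIFF with classes 0..3 and nodata = 255.
#'
#' @param stress_map a `stress_map`.
#' @param psi_path,class_path output files.
#' @return Invisibly, the paths.
#' @export
write_stress_map <- function(stress_map, psi_path, class_path) {
  v <- stress_map$psi_map
  st <- band_stack(array(ifelse(is.finite(v), -v, 0), c(dim(v), 1)),
                   wavelengths = 0,
                   nodata = !is.finite(v))
  write_band_stack(st, psi_path)
  cls <- match(stress_map$class_map, paste0("T", 0:3)) - 1L
  cls[is.na(cls)] <- 255L
  tiff::writeTIFF(matrix(cls / 255, nrow(v), ncol(v)), class_path,
                  bits.per.sample = 8L)
  invisible(c(psi = psi_path, class = class_path))
}
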