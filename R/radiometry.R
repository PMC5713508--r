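#' White-panel empirical-line calibration
#'
#' Derives per-band gain factors from a white reference panel of known
#' reflectance imaged within the scene: for each band,
#' `scale = panel_reflectance / mean(DN over the panel region)`.  This is
#' a single-point (gain-only, zero-offset) empirical-line normalization.
#'
#' @param raw_stack a [band_stack()] of raw digital numbers.
#' @param panel_region integer vector `c(x0, y0, x1, y1)`: pixel rectangle
#'   of the panel, 0-based, half-open.
#' @param panel_reflectance known panel reflectance per band, each in
#'   (0, 1]; recycled if scalar.
#'
#' @return An object of class `panel_calibration`: list with
#'   `panel_region`, `panel_reflectance`, `scale_per_band`.
#' @export
#' @examples
#' dn <- band_stack(array(200, c(8, 8, 6)))
#' cal <- calibrate_panel(dn, c(0, 0, 4, 4), 0.99)
#' cal$scale_per_band  # 0.99 / 200 in every band
calibrate_panel <- function(raw_stack, panel_region, panel_reflectance) {
  stopifnot(inherits(raw_stack, "band_stack"))
  nb <- length(raw_stack$wavelengths)
  panel_reflectance <- rep_len(panel_reflectance, nb)
  if (any(panel_reflectance <= 0) || any(panel_reflectance > 1))
    stop("panel reflectance must lie in (0, 1]")
  d <- dim(raw_stack$values)
  r <- as.integer(panel_region)
  if (length(r) != 4L || r[1] < 0 || r[2] < 0 || r[3] > d[2] || r[4] > d[1] ||
      r[1] >= r[3] || r[2] >= r[4])
    stop("panel_region must be a non-empty c(x0, y0, x1, y1) rectangle inside the image")
  rows <- (r[2] + 1L):r[4]
  cols <- (r[1] + 1L):r[3]
  valid <- !raw_stack$nodata[rows, cols, drop = FALSE]
  if (!any(valid)) stop("panel region contains no valid pixels")
  scale <- vapply(seq_len(nb), function(b) {
    m <- mean(raw_stack$values[rows, cols, b][valid])
    if (!is.finite(m) || m <= 0)
      stop("mean panel DN in band ", raw_stack$wavelengths[b],
           " nm is not positive; wrong region or saturated-to-black panel?")
    panel_reflectance[b] / m
  }, numeric(1))
  structure(list(panel_region = r,
                 panel_reflectance = panel_reflectance,
                 wavelengths = raw_stack$wavelengths,
                 scale_per_band = scale),
            class = "panel_calibration")
}

#' @export
print.panel_calibration <- function(x, ...) {
  cat("<panel_calibration> per-band gains:\n")
  print(stats::setNames(signif(x$scale_per_band, 5),
                        paste0(x$wavelengths, "nm")))
  invisible(x)
}

#' Apply a panel calibration to a raw stack
#'
#' Multiplies each band by its gain; nodata propagates unchanged.
#' Reflectances above 1.2 are reported with a warning (count per band) but
#' not clipped, as they usually indicate a mis-located panel rather than a
#' pixel problem.
#'
#' @param raw_stack a [band_stack()] of digital numbers.
#' @param calibration a `panel_calibration` from [calibrate_panel()].
#' @return A [band_stack()] of reflectance.
#' @export
apply_calibration <- function(raw_stack, calibration) {
  stopifnot(inherits(raw_stack, "band_stack"),
            inherits(calibration, "panel_calibration"))
  nb <- dim(raw_stack$values)[3]
  if (nb != length(calibration$scale_per_band))
    stop("band count mismatch: stack has ", nb, " bands, calibration has ",
         length(calibration$scale_per_band))
  v <- raw_stack$values
  n_high <- integer(nb)
  for (b in seq_len(nb)) {
    v[, , b] <- v[, , b] * calibration$scale_per_band[b]
    n_high[b] <- sum(v[, , b][!raw_stack$nodata] > 1.2, na.rm = TRUE)
  }
  if (any(n_high > 0))
    warning("reflectance > 1.2 at ",
            paste0(n_high[n_high > 0], " px (",
                   raw_stack$wavelengths[n_high > 0], " nm)",
                   collapse = ", "),
            "; values kept unclipped")
  band_stack(v, raw_stack$wavelengths, raw_stack$nodata)
}
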