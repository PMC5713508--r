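#' Extract per-plot mean canopy reflectances
#'
#' Averages each band over the border-eliminated core canopy pixels of
#' every plot — the "pure canopy" plot signature used as MLP input.
#'
#' @param stack a [band_stack()] of reflectance.
#' @param mask a `canopy_mask` (or logical matrix).
#' @param layout plot layout data frame with core rectangles
#'   (`cx0`, `cy0`, `cx1`, `cy1`; 0-based, half-open).
#' @param psi_per_plot optional ground-truth data frame (`plot_id`,
#'   `psi_mpa`) merged in as the target column.
#' @param flight flight identifier recorded per row.
#' @return Data frame: `plot_id`, `treatment`, `repetition`, `flight`,
#'   `n_pixels`, one `R<wavelength>` column per band, and `psi_mpa` if
#'   ground truth was supplied.  Plots with zero core canopy pixels get
#'   `NA` features and are reported via a warning.
#' @export
extract_features <- function(stack, mask, layout, psi_per_plot = NULL,
                             flight = 1L) {
  stopifnot(inherits(stack, "band_stack"))
  m <- if (inherits(mask, "canopy_mask")) mask$mask else mask
  bands <- lapply(stack$wavelengths, function(wl) get_band(stack, wl))
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    lrow <- layout[i, ]
    means <- vapply(bands, function(bm) {
      v <- plot_core_values(bm, m, lrow)
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    n_px <- length(plot_core_values(bands[[1]], m, lrow))
    out <- data.frame(plot_id = lrow$plot_id,
                      treatment = lrow$treatment,
                      repetition = lrow$repetition,
                      flight = flight, n_pixels = n_px,
                      stringsAsFactors = FALSE)
    out[paste0("R", stack$wavelengths)] <- as.list(means)
    out
  })
  tab <- do.call(rbind, rows)
  if (any(tab$n_pixels == 0))
    warning("plot(s) with zero core canopy pixels: ",
            paste(tab$plot_id[tab$n_pixels == 0], collapse = ", "))
  if (!is.null(psi_per_plot)) {
    tab$psi_mpa <- psi_per_plot$psi_mpa[match(tab$plot_id,
                                              psi_per_plot$plot_id)]
  }
  tab
}

#' Build a multi-flight feature table from the synthetic generator
#'
#' Simulates `n_flights` flights over the configured trial (shared field
#' layout, fresh psi draws and noise per flight), segments each flight's
#' imagery, and extracts per-plot mean canopy reflectances paired with the
#' ground-truth psi.  This reproduces the observation structure of a
#' multi-date UAV campaign: one row per plot and flight.
#'
#' @param config a [scene_config()].
#' @param n_flights number of flights (default 5).
#' @param mask_source `"segmented"` (default; the NDVI valley-threshold
#'   mask, i.e. the full pipeline) or `"true"` (the generator's mask).
#' @return A feature-table data frame (see [extract_features()]) with a
#'   `psi_mpa` target column.
#' @export
build_feature_table <- function(config, n_flights = 5,
                                mask_source = c("segmented", "true")) {
  mask_source <- match.arg(mask_source)
  tabs <- lapply(seq_len(n_flights), function(f) {
    scene <- generate_scene(config, flight = f)
    mask <- if (mask_source == "segmented") {
      segment_canopy(scene$stack)$mask
    } else {
      scene$truth$canopy_mask
    }
    extract_features(scene$stack, mask, scene$layout,
                     psi_per_plot = scene$truth$psi_per_plot, flight = f)
  })
  tab <- do.call(rbind, tabs)
  tab$row_id <- seq_len(nrow(tab))
  tab
}
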