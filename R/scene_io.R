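#' Export a scene to disk
#'
#' Writes the reflectance stack as a multi-page 32-bit TIFF (one page per
#' band, ascending wavelength, plus a trailing validity page; see
#' [write_band_stack()] for the encoding), the plot layout and
#' ground-truth psi as CSV, and the true canopy mask as a single-band 0/1
#' TIFF.  The files round-trip losslessly (well within float32 precision)
#' through [read_scene()].
#'
#' @param scene a `vineyard_scene` from [generate_scene()].
#' @param directory output directory, created if missing.
#' @return Invisibly, a named character vector of the files written.
#' @export
export_scene <- function(scene, directory) {
  stopifnot(inherits(scene, "vineyard_scene"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", directory)
  }
  files <- c(
    stack = file.path(directory, "reflectance.tif"),
    layout = file.path(directory, "layout.csv"),
    psi = file.path(directory, "ground_truth_psi.csv"),
    mask = file.path(directory, "canopy_mask_true.tif")
  )
  write_band_stack(scene$stack, files[["stack"]])
  utils::write.csv(scene$layout, files[["layout"]], row.names = FALSE)
  utils::write.csv(scene$truth$psi_per_plot, files[["psi"]], row.names = FALSE)
  tiff::writeTIFF(scene$truth$canopy_mask * 1, files[["mask"]],
                  bits.per.sample = 8L)
  invisible(files)
}

#' Read an exported scene back
#'
#' @param directory a directory written by [export_scene()].
#' @return A list with `stack` ([band_stack()]), `layout`, `psi_per_plot`
#'   and `canopy_mask` as in the exported scene.
#' @export
read_scene <- function(directory) {
  stack <- read_band_stack(file.path(directory, "reflectance.tif"))
  layout <- utils::read.csv(file.path(directory, "layout.csv"),
                            stringsAsFactors = FALSE)
  psi <- utils::read.csv(file.path(directory, "ground_truth_psi.csv"),
                         stringsAsFactors = FALSE)
  mask_file <- file.path(directory, "canopy_mask_true.tif")
  canopy_mask <- NULL
  if (file.exists(mask_file)) {
    canopy_mask <- tiff::readTIFF(mask_file) > 0.5
  }
  list(stack = stack, layout = layout, psi_per_plot = psi,
       canopy_mask = canopy_mask)
}

#' Write a band stack as a multi-page 32-bit TIFF
#'
#' libtiff 32-bit samples are stored normalized to \code{[0, 1]}, so values
#' are divided by a scale factor recorded in a `<path>.meta.csv` sidecar
#' (one row per band: `wavelength_nm`, `scale`).  Nodata pixels are
#' written as 0 and flagged in a trailing validity page (1 = valid).
#' Quantization error is ~2e-10 of the scale, far below float32
#' resolution.
#'
#' @param stack a [band_stack()].
#' @param path output file; the sidecar is written next to it.
#' @return Invisibly, `path`.
#' @export
write_band_stack <- function(stack, path) {
  stopifnot(inherits(stack, "band_stack"))
  v <- stack$values
  vmax <- max(v[is.finite(v)], 0)
  scale <- max(1.2, vmax)
  pages <- lapply(seq_len(dim(v)[3]), function(b) {
    pl <- v[, , b] / scale
    pl[stack$nodata | !is.finite(pl)] <- 0
    pl
  })
  pages[[length(pages) + 1L]] <- (!stack$nodata) * 1
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  utils::write.csv(
    data.frame(wavelength_nm = stack$wavelengths, scale = scale),
    paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a band stack written by [write_band_stack()]
#'
#' @param path TIFF file with its `<path>.meta.csv` sidecar.
#' @return A [band_stack()].
#' @export
read_band_stack <- function(path) {
  meta <- utils::read.csv(paste0(path, ".meta.csv"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nb <- nrow(meta)
  if (length(pages) != nb + 1L)
    stop("expected ", nb + 1L, " TIFF pages, found ", length(pages))
  nodata <- pages[[nb + 1L]] < 0.5
  v <- array(0, c(dim(pages[[1]]), nb))
  for (b in seq_len(nb)) {
    pl <- pages[[b]] * meta$scale[b]
    pl[nodata] <- NA_real_
    v[, , b] <- pl
  }
  band_stack(v, meta$wavelength_nm, nodata)
}
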