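#' Six-band reflectance stack
#'
#' A `band_stack` is the package's in-memory container for multi-band
#' imagery: a numeric `H x W x B` array of reflectance (or raw digital
#' numbers before calibration), a vector of band-centre wavelengths in nm,
#' and a logical `H x W` nodata mask.  Band order always follows ascending
#' wavelength.
#'
#' @param values numeric array, `H x W x B`.
#' @param wavelengths numeric vector of length `B`, band centres in nm.
#' @param nodata logical `H x W` matrix, `TRUE` where the pixel is invalid.
#'   Defaults to all-valid.
#'
#' @return An object of class `band_stack`.
#' @export
#' @examples
#' r <- band_stack(array(runif(4 * 3 * 6), c(4, 3, 6)))
#' dim(r$values)
band_stack <- function(values,
                       wavelengths = c(530, 550, 570, 670, 700, 800),
                       nodata = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an H x W x B array")
  if (dim(values)[3] != length(wavelengths))
    stop("third dimension of `values` must match `wavelengths`")
  if (is.unsorted(wavelengths))
    stop("bands must be in ascending wavelength order")
  if (is.null(nodata)) {
    nodata <- matrix(FALSE, dim(values)[1], dim(values)[2])
  }
  if (!identical(dim(nodata), dim(values)[1:2]))
    stop("`nodata` must be an H x W logical matrix")
  structure(
    list(values = values,
         wavelengths = as.numeric(wavelengths),
         nodata = nodata),
    class = "band_stack"
  )
}

#' Extract one band from a stack as a matrix
#'
#' @param stack a [band_stack()].
#' @param wavelength band centre in nm; must be one of `stack$wavelengths`.
#' @return `H x W` numeric matrix with `NA` at nodata pixels.
#' @export
get_band <- function(stack, wavelength) {
  stopifnot(inherits(stack, "band_stack"))
  i <- match(wavelength, stack$wavelengths)
  if (is.na(i))
    stop("stack has no band at ", wavelength,
         " nm (has: ", paste(stack$wavelengths, collapse = ", "), ")")
  m <- stack$values[, , i]
  m[stack$nodata] <- NA_real_
  m
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<band_stack> %d x %d px, %d bands (%s nm), %d nodata px\n",
              d[1], d[2], d[3],
              paste(x$wavelengths, collapse = "/"),
              sum(x$nodata)))
  invisible(x)
}

#' @export
dim.band_stack <- function(x) dim(x$values)
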