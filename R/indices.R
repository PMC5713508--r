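#' Spectral index catalogue
#'
#' The thirteen conventional multispectral indices computable from the six
#' camera bands (R530, R550, R570, R670, R700, R800).  Two dialects are
#' supported:
#'
#' * `"printed"` (default) follows the index table exactly as printed in
#'   the source literature compilation, including its quirks: RDVI is
#'   rendered identically to NDVI, and MSR's denominator carries no square
#'   root.
#' * `"canonical"` switches RDVI to `(R800 - R670) / sqrt(R800 + R670)`
#'   and MSR's denominator to `sqrt(R800 / R670) + 1`, the forms of the
#'   original index definitions.
#'
#' MCARI2's denominator is read as
#' `sqrt((2 R800 + 1)^2 - 6 (R800 - 5 R670) - 0.5)` (the -0.5 inside the
#' root).  Divisions by zero and negative square-root arguments yield
#' nodata.
#'
#' @param dialect `"printed"` or `"canonical"`.
#' @return Named list of scalar formula functions (used internally by
#'   [compute_index()]); names are the available index identifiers.
#' @export
index_catalogue <- function(dialect = c("printed", "canonical")) {
  dialect <- match.arg(dialect)
  div <- function(a, b) ifelse(is.na(b) | b == 0, NA_real_, a / b)
  rt <- function(x) ifelse(is.na(x) | x < 0, NA_real_, sqrt(x))
  msr <- if (dialect == "printed") {
    function(R530, R550, R570, R670, R700, R800) {
      r <- div(R800, R670); div(r - 1, r + 1)
    }
  } else {
    function(R530, R550, R570, R670, R700, R800) {
      r <- div(R800, R670); div(r - 1, rt(r) + 1)
    }
  }
  rdvi <- if (dialect == "printed") {
    function(R530, R550, R570, R670, R700, R800)
      div(R800 - R670, R800 + R670)
  } else {
    function(R530, R550, R570, R670, R700, R800)
      div(R800 - R670, rt(R800 + R670))
  }
  list(
    GI = function(R530, R550, R570, R670, R700, R800) div(R550, R670),
    GNDVI = function(R530, R550, R570, R670, R700, R800)
      div(R800 - R550, R800 + R550),
    MCARI = function(R530, R550, R570, R670, R700, R800)
      ((R700 - R670) - 0.2 * (R700 - R550)) * div(R700, R670),
    MCARI1 = function(R530, R550, R570, R670, R700, R800)
      1.2 * (2.5 * (R800 - R670) - 1.3 * (R800 - R550)),
    MCARI2 = function(R530, R550, R570, R670, R700, R800)
      div(1.2 * (2.5 * (R800 - R670) - 1.3 * (R800 - R550)),
          rt((2 * R800 + 1)^2 - 6 * (R800 - 5 * R670) - 0.5)),
    MSAVI = function(R530, R550, R570, R670, R700, R800)
      (2 * R800 + 1 - rt((2 * R800 + 1)^2 - 8 * (R800 - R670))) / 2,
    MSR = msr,
    MTVI3 = function(R530, R550, R570, R670, R700, R800)
      1.2 * (1.2 * (R800 - R550) - 2.5 * (R670 - R550)),
    NDVI = function(R530, R550, R570, R670, R700, R800)
      div(R800 - R670, R800 + R670),
    TCARI_OSAVI = function(R530, R550, R570, R670, R700, R800)
      div(3 * ((R700 - R670) - 0.2 * (R700 - R550) * div(R700, R670)),
          (1 + 0.16) * div(R800 - R670, R800 + R670 + 0.16)),
    SRI = function(R530, R550, R570, R670, R700, R800) div(R800, R550),
    PRI = function(R530, R550, R570, R670, R700, R800)
      div(R530 - R550, R530 + R550),
    RDVI = rdvi
  )
}

# wavelengths each index formula actually reads
index_bands <- list(
  GI = c(550, 670), GNDVI = c(550, 800), MCARI = c(550, 670, 700),
  MCARI1 = c(550, 670, 800), MCARI2 = c(550, 670, 800),
  MSAVI = c(670, 800), MSR = c(670, 800), MTVI3 = c(550, 670, 800),
  NDVI = c(670, 800), TCARI_OSAVI = c(550, 670, 700, 800),
  SRI = c(550, 800), PRI = c(530, 550), RDVI = c(670, 800)
)

normalize_index_name <- function(name) {
  n <- toupper(gsub("[/-]", "_", name))
  if (n == "TCARI_OSAVI" || n == "TCARIOSAVI") n <- "TCARI_OSAVI"
  n
}

#' Compute one spectral index per pixel
#'
#' Evaluates the named index formula element-wise over a six-band stack.
#' Nodata in any band the formula uses, division by zero, and negative
#' square-root arguments all propagate to nodata in the result.
#'
#' @param name index identifier (see [index_catalogue()]); `"TCARI/OSAVI"`
#'   is accepted as an alias of `"TCARI_OSAVI"`.
#' @param stack a [band_stack()] carrying every wavelength the formula
#'   references.
#' @param dialect formula dialect, see [index_catalogue()].
#' @return An object of class `index_map`: `name`, `values` (matrix, `NA`
#'   = nodata), `bands_used`, `dialect`.
#' @export
#' @examples
#' st <- band_stack(array(c(0.06, 0.08, 0.07, 0.10, 0.15, 0.50),
#'                        c(1, 1, 6)))
#' compute_index("NDVI", st)$values  # (0.5 - 0.1) / (0.5 + 0.1)
compute_index <- function(name, stack, dialect = c("printed", "canonical")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(stack, "band_stack"))
  key <- normalize_index_name(name)
  cat_ <- index_catalogue(dialect)
  if (!key %in% names(cat_))
    stop("unknown index '", name, "'; available: ",
         paste(names(cat_), collapse = ", "))
  need <- index_bands[[key]]
  missing <- setdiff(need, stack$wavelengths)
  if (length(missing))
    stop(key, " requires band(s) ", paste(missing, collapse = ", "),
         " nm, absent from the stack")
  bands <- lapply(c(530, 550, 570, 670, 700, 800), function(wl) {
    if (wl %in% stack$wavelengths) get_band(stack, wl) else NULL
  })
  names(bands) <- paste0("R", c(530, 550, 570, 670, 700, 800))
  # unused bands may be absent; pass NA placeholders of the right shape
  shape <- dim(stack$values)[1:2]
  for (nm in names(bands)) {
    if (is.null(bands[[nm]]))
      bands[[nm]] <- matrix(NA_real_, shape[1], shape[2])
  }
  vals <- do.call(cat_[[key]], bands)
  vals <- matrix(ifelse(is.finite(vals), vals, NA_real_), shape[1], shape[2])
  structure(list(name = key, values = vals, bands_used = need,
                 dialect = dialect),
            class = "index_map")
}

#' Compute all thirteen indices
#'
#' @param stack a [band_stack()] with all six bands.
#' @param dialect formula dialect, see [index_catalogue()].
#' @return Named list of `index_map` objects (one per catalogue entry).
#' @export
compute_all_indices <- function(stack, dialect = c("printed", "canonical")) {
  dialect <- match.arg(dialect)
  need <- c(530, 550, 570, 670, 700, 800)
  missing <- setdiff(need, stack$wavelengths)
  if (length(missing))
    stop("stack is missing band(s) ", paste(missing, collapse = ", "), " nm")
  nms <- names(index_catalogue(dialect))
  stats::setNames(lapply(nms, compute_index, stack = stack,
                         dialect = dialect), nms)
}

#' @export
print.index_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<index_map> %s (%s dialect), %d valid px, range [%.4g, %.4g]\n",
              x$name, x$dialect, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Per-plot index summary table
#'
#' Mean, sd and pixel count of an index over the border-eliminated core
#' canopy pixels of each plot.
#'
#' @param index_map an `index_map` (or bare matrix).
#' @param mask a `canopy_mask` (or logical matrix).
#' @param layout plot layout data frame (see [generate_scene()]).
#' @return Data frame: `plot_id`, `index`, `mean`, `sd`, `n_pixels`.
#' @export
summarize_index_by_plot <- function(index_map, mask, layout) {
  vals <- if (inherits(index_map, "index_map")) index_map$values else index_map
  nm <- if (inherits(index_map, "index_map")) index_map$name else "index"
  m <- if (inherits(mask, "canopy_mask")) mask$mask else mask
  out <- lapply(seq_len(nrow(layout)), function(i) {
    px <- plot_core_values(vals, m, layout[i, ])
    data.frame(plot_id = layout$plot_id[i], index = nm,
               mean = if (length(px)) mean(px) else NA_real_,
               sd = if (length(px) > 1) stats::sd(px) else NA_real_,
               n_pixels = length(px), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# values of `vals` over the core (border-eliminated) canopy pixels of one
# layout row; coordinates are 0-based half-open
plot_core_values <- function(vals, mask, lrow) {
  if (lrow$cy1 <= lrow$cy0 || lrow$cx1 <= lrow$cx0) return(numeric(0))
  rr <- (lrow$cy0 + 1L):lrow$cy1
  cc <- (lrow$cx0 + 1L):lrow$cx1
  sub <- vals[rr, cc, drop = FALSE]
  msk <- mask[rr, cc, drop = FALSE]
  v <- sub[msk]
  v[is.finite(v)]
}
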