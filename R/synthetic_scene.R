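#' Configuration for the synthetic vineyard-scene generator
#'
#' Describes a row-structured vineyard trial: vertical canopy stripes on a
#' soil background, tiled into `n_treatments * n_repetitions` rectangular
#' plots under a completely randomized irrigation-treatment assignment.
#' Each treatment holds midday stem water potential (psi, MPa) within a
#' fixed range; canopy reflectance in each band responds to psi through a
#' per-band scaled-logistic curve (see [stress_response_default()]), and
#' both soil and canopy carry multiplicative Gaussian noise truncated at
#' +/- 3 sd.
#'
#' The default treatment ranges follow the usual water-status classes for
#' deficit-irrigated vines: T0 (no stress) psi > -0.8 MPa, T1 (moderate)
#' -1.1 to -0.9, T2 (strong) -1.4 to -1.2, T3 (severe) below -1.4 with a
#' floor of -2.0 MPa.  Default geometry is 2.5 m row spacing and 1.5 m
#' vine spacing at a 6 cm ground sample distance, giving a ~28% canopy
#' cover for the default 12-px stripe width.
#'
#' @param pixel_size_m ground sample distance in metres (default 0.06).
#' @param row_spacing_m distance between vine rows in metres.
#' @param vine_spacing_m distance between plants along the row in metres.
#' @param canopy_width_px width of each canopy stripe in pixels; must be
#'   smaller than the row period `round(row_spacing_m / pixel_size_m)`.
#' @param n_treatments,n_repetitions trial dimensions (plots =
#'   `n_treatments * n_repetitions`, tiled `n_treatments` rows of plots by
#'   `n_repetitions` columns).
#' @param plants_per_plot vines per plot along the row direction.
#' @param rows_per_plot vine rows spanned by each plot.
#' @param treatment_psi_ranges named list `T0..T{k-1}` of `c(min, max)` psi
#'   ranges in MPa, disjoint and ordered from least to most negative.
#' @param soil_spectrum,canopy_base_spectrum length-6 reflectance vectors
#'   (530, 550, 570, 670, 700, 800 nm), each in (0, 1.2].
#' @param stress_response data frame of per-band response-curve parameters
#'   (`wavelength`, `amp`, `mid`, `width`); see [stress_response_default()].
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (unitless, >= 0).
#' @param margin_px soil-only margin around the plot block, in pixels.
#' @param border_px thickness, in pixels, of the plot border excluded from
#'   "core" (pure-canopy) averaging along the vine-row direction; default
#'   one vine spacing (the first and last plant of each plot).
#' @param seed integer seed controlling treatment assignment, psi draws
#'   and noise.
#'
#' @return An object of class `scene_config` (a validated list, with
#'   derived fields `row_period_px`, `plot_height_px`, `plot_width_px`,
#'   `image_height_px`, `image_width_px`).
#' @seealso [generate_scene()]
#' @export
scene_config <- function(pixel_size_m = 0.06,
                         row_spacing_m = 2.5,
                         vine_spacing_m = 1.5,
                         canopy_width_px = 12,
                         n_treatments = 4,
                         n_repetitions = 4,
                         plants_per_plot = 6,
                         rows_per_plot = 2,
                         treatment_psi_ranges = NULL,
                         soil_spectrum = c(0.15, 0.17, 0.18, 0.22, 0.24, 0.28),
                         canopy_base_spectrum = c(0.06, 0.10, 0.08, 0.05, 0.15, 0.50),
                         stress_response = stress_response_default(),
                         noise_cv = 0.05,
                         margin_px = 12,
                         border_px = NULL,
                         seed = 1L) {
  if (is.null(treatment_psi_ranges)) {
    treatment_psi_ranges <- default_psi_ranges(n_treatments)
  }
  stopifnot(pixel_size_m > 0, row_spacing_m > 0, vine_spacing_m > 0,
            noise_cv >= 0, n_treatments >= 1, n_repetitions >= 1,
            plants_per_plot >= 1, rows_per_plot >= 1, margin_px >= 0)
  if (length(soil_spectrum) != 6L || length(canopy_base_spectrum) != 6L)
    stop("spectra must have 6 bands")
  if (any(soil_spectrum <= 0) || any(soil_spectrum > 1.2) ||
      any(canopy_base_spectrum <= 0) || any(canopy_base_spectrum > 1.2))
    stop("reflectances must lie in (0, 1.2]")
  if (length(treatment_psi_ranges) != n_treatments)
    stop("need one psi range per treatment")
  rng <- do.call(rbind, treatment_psi_ranges)
  if (any(rng >= 0)) stop("psi ranges must be negative (MPa)")
  if (any(rng[, 1] >= rng[, 2])) stop("each psi range must be c(min, max) with min < max")
  if (n_treatments > 1) {
    # ordered least to most negative, disjoint
    if (any(diff(rng[, 1]) >= 0) || any(rng[-1, 2] > rng[-n_treatments, 1]))
      stop("treatment psi ranges must be disjoint and ordered T0 > T1 > ... (less to more negative)")
  }
  row_period_px <- round(row_spacing_m / pixel_size_m)
  if (canopy_width_px >= row_period_px)
    stop("canopy_width_px must be smaller than the row period (",
         row_period_px, " px)")
  if (canopy_width_px < 1) stop("canopy_width_px must be >= 1")
  vine_px <- round(vine_spacing_m / pixel_size_m)
  if (is.null(border_px)) border_px <- vine_px
  plot_height_px <- plants_per_plot * vine_px
  plot_width_px <- rows_per_plot * row_period_px
  cfg <- list(
    pixel_size_m = pixel_size_m, row_spacing_m = row_spacing_m,
    vine_spacing_m = vine_spacing_m, canopy_width_px = as.integer(canopy_width_px),
    n_treatments = as.integer(n_treatments),
    n_repetitions = as.integer(n_repetitions),
    plants_per_plot = as.integer(plants_per_plot),
    rows_per_plot = as.integer(rows_per_plot),
    treatment_psi_ranges = treatment_psi_ranges,
    soil_spectrum = soil_spectrum,
    canopy_base_spectrum = canopy_base_spectrum,
    stress_response = stress_response,
    noise_cv = noise_cv,
    margin_px = as.integer(margin_px),
    border_px = as.integer(border_px),
    seed = as.integer(seed),
    row_period_px = as.integer(row_period_px),
    vine_px = as.integer(vine_px),
    plot_height_px = as.integer(plot_height_px),
    plot_width_px = as.integer(plot_width_px),
    image_height_px = as.integer(2 * margin_px + n_treatments * plot_height_px),
    image_width_px = as.integer(2 * margin_px + n_repetitions * plot_width_px)
  )
  structure(cfg, class = "scene_config")
}

default_psi_ranges <- function(n_treatments) {
  all <- list(T0 = c(-0.8, -0.3), T1 = c(-1.1, -0.9),
              T2 = c(-1.4, -1.2), T3 = c(-2.0, -1.4))
  if (n_treatments > 4) stop("default psi ranges exist for up to 4 treatments")
  all[seq_len(n_treatments)]
}

#' Default per-band spectral response to water stress
#'
#' Each band's canopy reflectance is `base * g_b(psi)` with
#' `g_b(psi) = 1 + amp * plogis((s - mid) / width)` where `s = -psi` is
#' stress in MPa.  Amplitudes are signed: near-infrared (800 nm)
#' reflectance falls with stress while red (670 nm) rises, the classic
#' canopy-stress signature; the green/red-edge bands (550, 570, 700 nm)
#' respond with distinct midpoints and widths so that the joint
#' band-to-psi map is nonlinear and no single two-band ratio index is a
#' sufficient statistic for psi.
#'
#' @return data frame with columns `wavelength`, `amp`, `mid`, `width`.
#' @export
stress_response_default <- function() {
  data.frame(
    wavelength = c(530, 550, 570, 670, 700, 800),
    amp   = c(0.10, 0.25, 0.20, 0.60, 0.30, -0.35),
    mid   = c(1.20, 0.80, 1.40, 1.00, 1.50, 1.00),
    width = c(0.25, 0.20, 0.15, 0.30, 0.20, 0.35)
  )
}

#' Evaluate the per-band stress response factor g_b(psi)
#'
#' @param psi stem water potential, MPa (negative).
#' @param response response-parameter data frame
#'   (see [stress_response_default()]).
#' @return matrix `length(psi) x nbands` of multiplicative factors.
#' @export
stress_response_eval <- function(psi, response) {
  s <- -psi
  vapply(seq_len(nrow(response)), function(b) {
    1 + response$amp[b] * stats::plogis((s - response$mid[b]) / response$width[b])
  }, numeric(length(psi)))
}

#' Generate a synthetic vineyard scene
#'
#' Builds one flight over the configured trial: a [band_stack()] of
#' six-band reflectance, the plot layout, and the ground truth (per-plot
#' psi, the true canopy mask, and per-pixel true psi).  The treatment
#' assignment is a seeded random permutation fixed by `config$seed`;
#' per-plot psi draws and pixel noise are controlled by the flight seed so
#' that repeated flights over the same field share the layout but not the
#' water status.
#'
#' @param config a [scene_config()].
#' @param flight integer flight number (>= 1); flight 1 with the default
#'   seed reproduces the config's own seed stream.
#'
#' @return A list of class `vineyard_scene` with elements `stack`
#'   ([band_stack()]), `layout` (data frame: `plot_id`, `treatment`,
#'   `repetition`, `x0`, `y0`, `x1`, `y1`, `cx0`, `cy0`, `cx1`, `cy1`;
#'   pixel coordinates 0-based, half-open, `c*` = border-eliminated core),
#'   `truth` (list: `psi_per_plot` data frame, `canopy_mask` logical
#'   matrix, `psi_map` numeric matrix with `NA` off-canopy), and `config`.
#' @export
#' @examples
#' sc <- generate_scene(scene_config(n_repetitions = 2, plants_per_plot = 2))
#' sc$truth$psi_per_plot
generate_scene <- function(config, flight = 1L) {
  stopifnot(inherits(config, "scene_config"), flight >= 1)
  H <- config$image_height_px
  W <- config$image_width_px
  nb <- 6L

  # treatment assignment: seeded permutation, fixed across flights
  set.seed(config$seed)
  n_plots <- config$n_treatments * config$n_repetitions
  # completely randomized design: permute plot cells, then chunk by treatment
  treat_of_plot <- integer(n_plots)
  perm <- sample.int(n_plots)
  treat_of_plot[perm] <- rep(seq_len(config$n_treatments) - 1L,
                             each = config$n_repetitions)
  rep_of_plot <- integer(n_plots)
  for (tr in unique(treat_of_plot)) {
    idx <- which(treat_of_plot == tr)
    rep_of_plot[idx] <- seq_along(idx)
  }

  # flight-specific stream: psi draws + noise
  set.seed(flight_seed(config$seed, flight))

  # plot rectangles (0-based, half-open), tiled row-major
  m <- config$margin_px
  ph <- config$plot_height_px; pw <- config$plot_width_px
  cell_row <- (seq_len(n_plots) - 1L) %/% config$n_repetitions
  cell_col <- (seq_len(n_plots) - 1L) %% config$n_repetitions
  x0 <- m + cell_col * pw; x1 <- x0 + pw
  y0 <- m + cell_row * ph; y1 <- y0 + ph
  bpx <- min(config$border_px, (ph - 1L) %/% 2L)
  layout <- data.frame(
    plot_id = sprintf("P%02d", seq_len(n_plots)),
    treatment = paste0("T", treat_of_plot),
    repetition = rep_of_plot,
    x0 = x0, y0 = y0, x1 = x1, y1 = y1,
    cx0 = x0, cy0 = y0 + bpx, cx1 = x1, cy1 = y1 - bpx,
    stringsAsFactors = FALSE
  )

  # per-plot psi, uniform in the treatment range
  rngs <- do.call(rbind, config$treatment_psi_ranges)
  lo <- rngs[treat_of_plot + 1L, 1]; hi <- rngs[treat_of_plot + 1L, 2]
  psi <- stats::runif(n_plots, lo, hi)
  psi_per_plot <- data.frame(plot_id = layout$plot_id,
                             treatment = layout$treatment,
                             repetition = layout$repetition,
                             psi_mpa = psi, stringsAsFactors = FALSE)

  # canopy stripes: within the plot block only, one stripe centred in
  # each row period
  canopy_cols <- logical(W)
  field_x0 <- m; field_x1 <- m + config$n_repetitions * pw
  off <- (config$row_period_px - config$canopy_width_px) %/% 2L
  col0 <- seq.int(field_x0, field_x1 - 1L, by = config$row_period_px)
  for (c0 in col0) {
    canopy_cols[(c0 + off + 1L):(c0 + off + config$canopy_width_px)] <- TRUE
  }
  field_rows <- (m + 1L):(m + config$n_treatments * ph)
  canopy_mask <- matrix(FALSE, H, W)
  canopy_mask[field_rows, canopy_cols] <- TRUE

  # per-pixel true psi and plot membership
  psi_map <- matrix(NA_real_, H, W)
  plot_of_px <- matrix(NA_integer_, H, W)
  for (i in seq_len(n_plots)) {
    rr <- (layout$y0[i] + 1L):layout$y1[i]
    cc <- (layout$x0[i] + 1L):layout$x1[i]
    plot_of_px[rr, cc] <- i
  }
  psi_map[canopy_mask] <- psi[plot_of_px[canopy_mask]]

  # reflectance: soil everywhere, canopy on stripes, multiplicative noise
  g <- stress_response_eval(psi, config$stress_response)  # n_plots x 6
  values <- array(NA_real_, c(H, W, nb))
  can_idx <- which(canopy_mask)
  soil_idx <- which(!canopy_mask)
  can_plot <- plot_of_px[can_idx]
  npx_can <- length(can_idx); npx_soil <- length(soil_idx)
  for (b in seq_len(nb)) {
    band <- matrix(0, H, W)
    band[soil_idx] <- config$soil_spectrum[b]
    band[can_idx] <- config$canopy_base_spectrum[b] * g[can_plot, b]
    if (config$noise_cv > 0) {
      eps <- pmax(pmin(stats::rnorm(H * W), 3), -3) * config$noise_cv
      band <- band * (1 + eps)
    }
    values[, , b] <- band
  }

  structure(list(
    stack = band_stack(values),
    layout = layout,
    truth = list(psi_per_plot = psi_per_plot,
                 canopy_mask = canopy_mask,
                 psi_map = psi_map),
    config = config,
    flight = as.integer(flight)
  ), class = "vineyard_scene")
}

# deterministic per-flight seed, kept inside 32-bit integer range
flight_seed <- function(seed, flight) {
  as.integer((as.numeric(seed) + 77003 * (as.numeric(flight) - 1)) %% 2147483647)
}

#' @export
print.vineyard_scene <- function(x, ...) {
  cat(sprintf("<vineyard_scene> flight %d: %d x %d px, %d plots (%d treatments x %d reps)\n",
              x$flight, dim(x$stack)[1], dim(x$stack)[2], nrow(x$layout),
              x$config$n_treatments, x$config$n_repetitions))
  cat(sprintf("  true canopy cover %.1f%%, psi %.2f to %.2f MPa\n",
              100 * mean(x$truth$canopy_mask),
              max(x$truth$psi_per_plot$psi_mpa),
              min(x$truth$psi_per_plot$psi_mpa)))
  invisible(x)
}
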