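# shared fixtures: small scenes, toy stacks, independent index oracle

small_scene_config <- function(seed = 1L, noise_cv = 0.05, ...) {
  scene_config(n_repetitions = 2, plants_per_plot = 2, seed = seed,
               noise_cv = noise_cv, ...)
}

# a 1x1 six-band stack from named reflectances (530..800 order)
pixel_stack <- function(R530, R550, R570, R670, R700, R800) {
  band_stack(array(c(R530, R550, R570, R670, R700, R800), c(1, 1, 6)))
}

# Independent scalar evaluation of every index formula, written from the
# printed table without reference to the package implementation.
oracle_index <- function(name, r, dialect = "printed") {
  R530 <- r[1]; R550 <- r[2]; R570 <- r[3]
  R670 <- r[4]; R700 <- r[5]; R800 <- r[6]
  val <- switch(name,
    GI = R550 / R670,
    GNDVI = (R800 - R550) / (R800 + R550),
    MCARI = ((R700 - R670) - 0.2 * (R700 - R550)) * (R700 / R670),
    MCARI1 = 1.2 * (2.5 * (R800 - R670) - 1.3 * (R800 - R550)),
    MCARI2 = {
      disc <- (2 * R800 + 1)^2 - 6 * (R800 - 5 * R670) - 0.5
      if (disc < 0) NA_real_ else
        1.2 * (2.5 * (R800 - R670) - 1.3 * (R800 - R550)) / sqrt(disc)
    },
    MSAVI = {
      disc <- (2 * R800 + 1)^2 - 8 * (R800 - R670)
      if (disc < 0) NA_real_ else (2 * R800 + 1 - sqrt(disc)) / 2
    },
    MSR = {
      ratio <- R800 / R670
      if (dialect == "printed") (ratio - 1) / (ratio + 1)
      else (ratio - 1) / (sqrt(ratio) + 1)
    },
    MTVI3 = 1.2 * (1.2 * (R800 - R550) - 2.5 * (R670 - R550)),
    NDVI = (R800 - R670) / (R800 + R670),
    TCARI_OSAVI = {
      tcari <- 3 * ((R700 - R670) - 0.2 * (R700 - R550) * (R700 / R670))
      osavi <- (1 + 0.16) * (R800 - R670) / (R800 + R670 + 0.16)
      tcari / osavi
    },
    SRI = R800 / R550,
    PRI = (R530 - R550) / (R530 + R550),
    RDVI = {
      if (dialect == "printed") (R800 - R670) / (R800 + R670)
      else (R800 - R670) / sqrt(R800 + R670)
    },
    stop("unknown index ", name))
  if (!is.finite(val)) NA_real_ else val
}

# independent modified index of agreement (absolute-value form)
oracle_d <- function(obs, pred) {
  ob <- mean(obs)
  1 - sum(abs(obs - pred)) / sum(abs(pred - ob) + abs(obs - ob))
}

# a stress-response table where psi affects only the 670 and 800 nm bands
red_nir_only_response <- function() {
  r <- stress_response_default()
  r$amp[!r$wavelength %in% c(670, 800)] <- 0
  r
}
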