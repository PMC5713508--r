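#' Simulate a raw digital-number stack from a reflectance scene
#'
#' Converts reflectance to sensor digital numbers with per-band gains and
#' embeds a white reference panel patch of known reflectance, producing
#' the raw input the radiometric-calibration stage expects.
#'
#' @param stack a [band_stack()] of reflectance.
#' @param gains per-band DN per unit reflectance (recycled if scalar).
#' @param panel_region `c(x0, y0, x1, y1)` rectangle (0-based, half-open)
#'   overwritten with the panel.
#' @param panel_reflectance the panel's reflectance (default 0.99).
#' @return List with `dn_stack` ([band_stack()] of DN), `panel_region`,
#'   `panel_reflectance`.
#' @export
simulate_dn_stack <- function(stack, gains = 1000,
                              panel_region = c(1, 1, 9, 9),
                              panel_reflectance = 0.99) {
  stopifnot(inherits(stack, "band_stack"))
  nb <- dim(stack$values)[3]
  gains <- rep_len(gains, nb)
  v <- stack$values
  r <- as.integer(panel_region)
  rows <- (r[2] + 1L):r[4]; cols <- (r[1] + 1L):r[3]
  for (b in seq_len(nb)) {
    pl <- v[, , b]
    pl[rows, cols] <- panel_reflectance
    v[, , b] <- pl * gains[b]
  }
  list(dn_stack = band_stack(v, stack$wavelengths, stack$nodata),
       panel_region = r, panel_reflectance = panel_reflectance)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].  Can
#' also be loaded from a YAML file via `pipeline_config_from_yaml()`.
#'
#' @param seed master seed for the run (scene generation, split, grid
#'   search).
#' @param outdir artifact directory.
#' @param scene named list of [scene_config()] arguments (seed is taken
#'   from `seed`).
#' @param n_flights flights to simulate (default 5).
#' @param grid `"reduced"` (nodes 2..8, epochs 100..1000 by 100, 5
#'   restarts), `"full"` (nodes 2..20, epochs 100..5000 by 100, 20
#'   restarts), or a list with `node_range`, `iter_range`, `restarts`.
#' @param index_dialect `"printed"` or `"canonical"` (see
#'   [index_catalogue()]).
#' @param dn_gains per-band gains for the simulated raw imagery.
#' @param panel_reflectance white-panel reflectance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("vinepsi_run_"),
                            scene = list(), n_flights = 5,
                            grid = "reduced",
                            index_dialect = c("printed", "canonical"),
                            dn_gains = c(900, 950, 1000, 1050, 1100, 800),
                            panel_reflectance = 0.99) {
  index_dialect <- match.arg(index_dialect)
  if (is.character(grid)) {
    grid <- switch(match.arg(grid, c("reduced", "full")),
      reduced = list(node_range = 2:8,
                     iter_range = seq(100, 1000, by = 100), restarts = 5),
      full = list(node_range = 2:20,
                  iter_range = seq(100, 5000, by = 100), restarts = 20))
  }
  stopifnot(is.list(grid),
            all(c("node_range", "iter_range", "restarts") %in% names(grid)))
  structure(list(seed = as.integer(seed), outdir = outdir, scene = scene,
                 n_flights = as.integer(n_flights), grid = grid,
                 index_dialect = index_dialect, dn_gains = dn_gains,
                 panel_reflectance = panel_reflectance),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments.
#' @export
pipeline_config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$grid) && is.list(args$grid)) {
    args$grid$node_range <- as.integer(unlist(args$grid$node_range))
    args$grid$iter_range <- as.integer(unlist(args$grid$iter_range))
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: scene simulation (all flights), simulated
#' raw-to-reflectance radiometric calibration, soil-canopy segmentation,
#' per-pixel index computation with per-plot summaries, linear index
#' baselines, the MLP band-ablation study (grid search per band subset),
#' validation, and per-pixel stress mapping of the first flight with the
#' best ANN model.  All tables, maps, a run manifest and a log are written
#' under `config$outdir`.  Identical config and seed reproduce the run
#' byte-for-byte (CSV outputs).
#'
#' A stage failure aborts with an error naming the stage.
#'
#' @param config a [pipeline_config()], a YAML path, or a named list of
#'   [pipeline_config()] arguments.
#' @return Invisibly, a list with the key result objects (`ablation`,
#'   `baselines`, `segmentation`, `stress_map`, `plot_predictions`) and
#'   `files` (named artifact paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config_from_yaml(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_path <- file.path(outdir, "log.txt")
  cat("", file = log_path)
  t_all <- proc.time()[3]
  logline <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logline(sprintf("[stage %s] done in %.1f s", name,
                    proc.time()[3] - t0))
    res
  }
  wcsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  files <- list()

  scene_args <- config$scene
  scene_args$seed <- config$seed
  scfg <- do.call(scene_config, scene_args)

  scenes <- stage("simulate", lapply(seq_len(config$n_flights),
                                     function(f) generate_scene(scfg, f)))
  files$scene <- file.path(outdir, "scene")
  export_scene(scenes[[1]], files$scene)

  # raw DN -> reflectance through the white panel, per flight
  stacks <- stage("normalize", lapply(scenes, function(sc) {
    sim <- simulate_dn_stack(sc$stack, gains = config$dn_gains,
                             panel_reflectance = config$panel_reflectance)
    cal <- calibrate_panel(sim$dn_stack, sim$panel_region,
                           sim$panel_reflectance)
    apply_calibration(sim$dn_stack, cal)
  }))

  segs <- stage("segment", lapply(stacks, segment_canopy))
  seg_tab <- data.frame(
    flight = seq_along(segs),
    valley_ndvi = vapply(segs, function(s) s$valley$valley_ndvi, 1),
    valley_occurrence_pct =
      vapply(segs, function(s) s$valley$valley_occurrence_pct, 1),
    soil_mu = vapply(segs, function(s) s$model$mu1, 1),
    canopy_mu = vapply(segs, function(s) s$model$mu2, 1),
    fractional_cover_pct =
      vapply(segs, function(s) s$mask$fractional_cover_pct, 1),
    true_cover_pct =
      vapply(scenes, function(sc) 100 * mean(sc$truth$canopy_mask), 1))
  files$segmentation <- wcsv(seg_tab, "segmentation.csv")

  # per-plot features + per-plot mean index values, all flights
  feat_idx <- stage("indices", {
    feats <- list(); idx_rows <- list()
    for (f in seq_along(stacks)) {
      sc <- scenes[[f]]
      feats[[f]] <- extract_features(stacks[[f]], segs[[f]]$mask, sc$layout,
                                     psi_per_plot = sc$truth$psi_per_plot,
                                     flight = f)
      maps <- compute_all_indices(stacks[[f]], dialect = config$index_dialect)
      per_plot <- do.call(rbind, lapply(maps, summarize_index_by_plot,
                                        mask = segs[[f]]$mask,
                                        layout = sc$layout))
      per_plot$flight <- f
      idx_rows[[f]] <- per_plot
    }
    tab <- do.call(rbind, feats)
    tab$row_id <- seq_len(nrow(tab))
    list(features = tab, index_values = do.call(rbind, idx_rows))
  })
  files$features <- wcsv(feat_idx$features, "features.csv")
  files$index_values <- wcsv(feat_idx$index_values, "index_values_per_plot.csv")

  table <- feat_idx$features
  split <- split_calibration_validation(table, config$seed)
  files$split <- wcsv(
    data.frame(row_id = table$row_id,
               set = ifelse(seq_len(nrow(table)) %in% split$validation_rows,
                            "validation", "calibration")),
    "split.csv")

  # Linear baselines for all 13 indices on the calibration rows
  baselines <- stage("baselines", {
    iv <- feat_idx$index_values
    idx_names <- unique(iv$index)
    rows <- lapply(idx_names, function(nm) {
      sub <- iv[iv$index == nm, ]
      x <- sub$mean[match(paste(table$plot_id, table$flight),
                          paste(sub$plot_id, sub$flight))]
      cal_fit <- linear_baseline(table[split$calibration_rows, ],
                                 x[split$calibration_rows])
      data.frame(index = nm, a = cal_fit$a, b = cal_fit$b,
                 r_squared = cal_fit$r_squared, p_value = cal_fit$p_value,
                 stringsAsFactors = FALSE)
    })
    list(table3 = do.call(rbind, rows), index_values = iv)
  })
  files$table3 <- wcsv(baselines$table3, "table3_index_baselines.csv")

  abl <- stage("ablation", ablation_study(
    table, seed = config$seed,
    node_range = config$grid$node_range,
    iter_range = config$grid$iter_range,
    restarts = config$grid$restarts))
  files$table4 <- wcsv(
    abl$summary[, c("model", "bands", "hidden_nodes", "iterations",
                    "training_r2")],
    "table4_training.csv")
  grid_rec <- do.call(rbind, lapply(names(abl$searches), function(nm) {
    r <- abl$searches[[nm]]$record; r$model <- nm; r
  }))
  files$grid_records <- wcsv(grid_rec, "grid_search_records.csv")

  # Table-5-shaped validation: significant indices + the seven ANN models
  table5 <- stage("evaluate", {
    iv <- baselines$index_values
    val <- table[split$validation_rows, ]
    idx_rows <- lapply(c("NDVI", "GNDVI", "MSR"), function(nm) {
      sub <- iv[iv$index == nm, ]
      x <- sub$mean[match(paste(table$plot_id, table$flight),
                          paste(sub$plot_id, sub$flight))]
      fit <- linear_baseline(table[split$calibration_rows, ],
                             x[split$calibration_rows])
      pred <- fit$a + fit$b * x[split$validation_rows]
      as.data.frame(evaluate(val$psi_mpa, pred, model_id = nm))
    })
    ann_rows <- lapply(abl$reports, as.data.frame)
    out <- do.call(rbind, c(idx_rows, ann_rows, make.row.names = FALSE))
    out
  })
  files$table5 <- wcsv(table5, "table5_validation.csv")

  # map the first flight with the ANN model of lowest validation RMSE
  best_nm <- abl$summary$model[which.min(abl$summary$rmse)]
  best_model <- abl$models[[best_nm]]
  smap <- stage("map", predict_map(best_model, stacks[[1]], segs[[1]]$mask))
  files$psi_map <- file.path(outdir, "psi_map.tif")
  files$class_map <- file.path(outdir, "class_map.tif")
  write_stress_map(smap, files$psi_map, files$class_map)
  plot_pred <- aggregate_plots(smap, scenes[[1]]$layout)
  truth1 <- scenes[[1]]$truth$psi_per_plot
  plot_pred$true_psi <- truth1$psi_mpa[match(plot_pred$plot_id,
                                             truth1$plot_id)]
  files$plot_predictions <- wcsv(plot_pred, "plot_predictions.csv")
  files$model <- file.path(outdir, "model_best.yaml")
  save_mlp(best_model, files$model)

  manifest <- list(
    package = "vinepsi",
    version = as.character(utils::packageVersion("vinepsi")),
    seed = config$seed,
    n_flights = config$n_flights,
    grid = config$grid,
    index_dialect = config$index_dialect,
    scene = scene_args,
    best_model = best_nm,
    selected = list(hidden_nodes = abl$summary$hidden_nodes[
                      abl$summary$model == best_nm],
                    iterations = abl$summary$iterations[
                      abl$summary$model == best_nm])
  )
  files$manifest <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, files$manifest)
  logline(sprintf("pipeline complete in %.1f s; best model %s",
                  proc.time()[3] - t_all, best_nm))

  invisible(list(ablation = abl, baselines = baselines$table3,
                 segmentation = seg_tab, stress_map = smap,
                 plot_predictions = plot_pred, table5 = table5,
                 split = split, config = config,
                 files = lapply(files, identity)))
}
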