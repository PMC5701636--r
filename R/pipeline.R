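#' Default (reference) pipeline configuration
#'
#' The shipped synthetic reference configuration: a 100 x 100 equal-area
#' lattice of 10-km cells with seven correlated bioclimatic surfaces (one
#' designated collinear pair at r = 0.9, exercising the 0.70 pruning rule),
#' a water mask covering a quarter of the landscape, a unimodal suitability
#' truth on bio1 with a weak secondary effect of bio3, an eight-decade
#' warming trend applied along the x axis, 200 occurrence records, the
#' "clubrush" kernel archetype, and 10 replicates of an 80-year simulation
#' under all four dispersal scenarios.
#'
#' @param seed global base seed; every stage derives its own stream from it.
#' @return nested configuration list (YAML-serializable).
#' @export
default_config <- function(seed = 1L) {
  list(
    mode = "synthetic",
    seed = as.integer(seed),
    landscape = list(
      n_rows = 100, n_cols = 100, cell_size = 10, n_variables = 7,
      spatial_correlation_range = 100, inter_variable_correlation = 0.9,
      collinear_pairs = list(c(1L, 2L)), water_fraction = 0.25
    ),
    trend = list(increments = list(bio1 = 0.25), n_decades = 8,
                 direction = c(1, 0)),
    truth = list(intercept = -12, linear = list(bio1 = 16, bio3 = 0.5),
                 quadratic = list(bio1 = -4)),
    n_presences = 200,
    sdm = list(n_background = 10000, regularization = 1, quadratic = TRUE,
               k_folds = 5, select_threshold = 0.70),
    kernel = list(archetype = "clubrush", n_samples = 1e5),
    simulation = list(n_years = 80, climate_interval = 10,
                      n_replicates = 10, maturity_age1 = 0.5),
    scenarios = c("no_dispersal", "local", "full_ldd", "unlimited"),
    benchmark_km_yr = 0.42
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return the configuration list (read) or \code{path} (write).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks that exactly one input mode is configured and, in real-data mode,
#' that every referenced path resolves before any computation starts.
#'
#' @param config configuration list.
#' @return the config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config) {
  if (is.null(config$mode) ||
      !config$mode %in% c("synthetic", "real"))
    stop("config$mode must be 'synthetic' or 'real'", call. = FALSE)
  if (config$mode == "synthetic") {
    if (!is.null(config$inputs))
      stop("synthetic mode must not carry real-mode `inputs`",
           call. = FALSE)
    for (f in c("landscape", "trend", "truth"))
      if (is.null(config[[f]]))
        stop("synthetic mode requires config$", f, call. = FALSE)
  } else {
    inp <- config$inputs
    if (is.null(inp))
      stop("real mode requires config$inputs", call. = FALSE)
    paths <- c(unlist(inp$baseline), unlist(inp$future), inp$water,
               inp$occurrences)
    missing_paths <- paths[!file.exists(paths)]
    if (length(missing_paths))
      stop("missing input file(s): ",
           paste(missing_paths, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unlist(config$scenarios),
                 c("no_dispersal", "local", "full_ldd", "unlimited"))
  if (length(bad))
    stop("unknown scenario(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(config)
}

#' Read an occurrence CSV (columns lon, lat)
#'
#' @param path CSV path.
#' @return data.frame with \code{lon}, \code{lat}.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("occurrence file must have columns lon,lat: ", path,
         call. = FALSE)
  df[, c("lon", "lat")]
}

# Assemble inputs: synthetic generation or real rasters from disk.
assemble_inputs <- function(config) {
  if (config$mode == "synthetic") {
    ls_cfg <- config$landscape
    spec <- landscape_spec(
      n_rows = ls_cfg$n_rows, n_cols = ls_cfg$n_cols,
      cell_size = ls_cfg$cell_size, n_variables = ls_cfg$n_variables,
      spatial_correlation_range = ls_cfg$spatial_correlation_range,
      inter_variable_correlation = ls_cfg$inter_variable_correlation,
      collinear_pairs = ls_cfg$collinear_pairs,
      water_fraction = ls_cfg$water_fraction,
      seed = config$seed
    )
    land <- gen_landscape(spec)
    trend <- trend_spec(unlist(config$trend$increments),
                        n_decades = config$trend$n_decades,
                        direction = unlist(config$trend$direction))
    series <- gen_climate_series(land$climate, trend)
    truth <- truth_model(intercept = config$truth$intercept,
                         linear = unlist(config$truth$linear),
                         quadratic = unlist(config$truth$quadratic))
    occ <- gen_occurrences(truth, land$climate, land$water,
                           n_presences = config$n_presences,
                           seed = config$seed + 1L)
    list(climate = land$climate, water = land$water, series = series,
         occurrences = occ, truth = truth)
  } else {
    inp <- config$inputs
    baseline <- climate_stack(lapply(inp$baseline, read_ascii_grid))
    series <- c(list(baseline),
                lapply(inp$future, function(slice)
                  climate_stack(lapply(slice, read_ascii_grid))))
    list(climate = baseline, water = read_ascii_grid(inp$water),
         series = series, occurrences = read_occurrences(inp$occurrences),
         truth = NULL)
  }
}

#' Run the full pipeline
#'
#' Chains landscape/climate assembly, collinearity pruning, SDM fit and
#' cross-validated evaluation, kernel construction (full LDD kernel plus its
#' 100-km local truncation), the range-shift simulation for every configured
#' scenario, and the rate summary. All artifacts are written to
#' \code{out_dir} (ASCII-grid rasters, CSV tables, JSON model and manifest);
#' a rerun with the same config produces identical outputs.
#'
#' @param config configuration list (see \code{\link{default_config}}).
#' @param out_dir output directory (created if needed).
#' @param write_rasters also write the baseline climate rasters (ASCII grid).
#' @return invisibly, a list with all in-memory stage outputs.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile(),
                         write_rasters = TRUE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  message("stage 1/5: inputs (", config$mode, " mode)")
  inputs <- assemble_inputs(config)
  n_water <- sum(inputs$water$values > 0)
  message(sprintf("  %d x %d grid, %d water cells, %d occurrences",
                  nrow(inputs$water$values), ncol(inputs$water$values),
                  n_water, nrow(inputs$occurrences)))

  message("stage 2/5: species distribution model")
  sdm_cfg <- config$sdm
  vars <- select_variables(inputs$climate, inputs$occurrences, inputs$water,
                           threshold = sdm_cfg$select_threshold,
                           n_background = sdm_cfg$n_background,
                           quadratic = isTRUE(sdm_cfg$quadratic),
                           seed = seed + 2L)
  model <- fit_sdm(inputs$climate, inputs$occurrences, inputs$water,
                   variables = vars, n_background = sdm_cfg$n_background,
                   regularization = sdm_cfg$regularization,
                   quadratic = isTRUE(sdm_cfg$quadratic), seed = seed + 2L)
  eval <- evaluate_sdm(model, inputs$climate, inputs$occurrences,
                       inputs$water, k_folds = sdm_cfg$k_folds,
                       seed = seed + 3L)
  message(sprintf("  retained %s; CV AUC %.3f (Dxy %.3f), theta %.3f",
                  paste(vars, collapse = ","), eval$auc_mean, eval$dxy,
                  model$theta))

  message("stage 3/5: dispersal kernels")
  kp <- if (!is.null(config$kernel$archetype))
    reference_kernel_params(config$kernel$archetype)
  else
    list(movement = do.call(movement_spec, config$kernel$movement),
         retention = do.call(retention_spec, config$kernel$retention))
  cs <- inputs$water$cell_size
  kern_full <- build_kernel(kp$movement, kp$retention, cell_size = cs,
                            n_samples = config$kernel$n_samples,
                            seed = seed + 4L)
  kern_local <- truncate_kernel(kern_full, 100)
  message(sprintf("  full kernel: max %.0f km, LDD>100km %.3f%%",
                  kern_full$max_distance_km,
                  100 * kern_full$p_over_100km))

  message("stage 4/5: range-shift simulation")
  sim_cfg <- config$simulation
  results <- lapply(unlist(config$scenarios), function(sc) {
    cfg <- scenario_config(sc, n_years = sim_cfg$n_years,
                           climate_interval = sim_cfg$climate_interval,
                           n_replicates = sim_cfg$n_replicates,
                           base_seed = seed + 10L,
                           maturity_age1 = sim_cfg$maturity_age1)
    kern <- switch(sc, local = kern_local, full_ldd = kern_full, NULL)
    res <- run_scenario(cfg, model, inputs$series, kern,
                        inputs$occurrences, inputs$water)
    fin <- res$records[res$records$year == sim_cfg$n_years, "occupied_km2"]
    message(sprintf("  %-12s final occupied %.0f +/- %.0f km^2", sc,
                    mean(fin), stats::sd(fin)))
    res
  })
  names(results) <- unlist(config$scenarios)

  message("stage 5/5: rates")
  rates <- summarize_rates(results,
                           benchmark_km_yr = config$benchmark_km_yr)

  # ---- artifacts ----
  write_config(config, file.path(out_dir, "config.yaml"))
  utils::write.csv(inputs$occurrences,
                   file.path(out_dir, "occurrences.csv"),
                   row.names = FALSE)
  write_ascii_grid(inputs$water, file.path(out_dir, "water.asc"))
  if (write_rasters)
    for (v in names(inputs$climate))
      write_ascii_grid(inputs$climate[[v]],
                       file.path(out_dir, paste0(v, ".asc")))
  write_sdm_json(model, file.path(out_dir, "model.json"))
  jsonlite::write_json(
    list(auc_folds = eval$auc_folds, auc_mean = eval$auc_mean,
         dxy = eval$dxy, k_folds = eval$k_folds),
    file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)
  write_kernel_csv(kern_full, file.path(out_dir, "kernel_full.csv"))
  write_kernel_csv(kern_local, file.path(out_dir, "kernel_local.csv"))
  all_records <- do.call(rbind, lapply(results, function(r) r$records))
  utils::write.csv(all_records, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  write_rates_csv(rates, file.path(out_dir, "rates.csv"))

  outputs <- c("config.yaml", "occurrences.csv", "water.asc", "model.json",
               "eval.json", "kernel_full.csv", "kernel_local.csv",
               "results.csv", "rates.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("aquashift")),
    seed = seed,
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
    output_md5 = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(config = config, inputs = inputs, variables = vars,
                 model = model, eval = eval, kernel_full = kern_full,
                 kernel_local = kern_local, results = results,
                 rates = rates, out_dir = out_dir))
}

#' Plot occupied-area trajectories per scenario
#'
#' One line per replicate per scenario (occupied area against simulation
#' year), with the habitat-available area overlaid as a dashed reference
#' line — the standard way to visualize how far each dispersal scenario lags
#' behind the moving habitat.
#'
#' @param results list of \code{range_shift_result} (or a single one).
#' @param file optional PNG path; NULL plots to the active device.
#' @return invisibly, the combined records data.frame.
#' @export
plot_trajectories <- function(results, file = NULL) {
  if (inherits(results, "range_shift_result")) results <- list(results)
  rec <- do.call(rbind, lapply(results, function(r) r$records))
  scen <- unique(rec$scenario)
  cols <- stats::setNames(grDevices::hcl.colors(max(4, length(scen)),
                                                "Dark 3")[seq_along(scen)],
                          scen)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NULL, xlim = range(rec$year),
                 ylim = c(0, max(rec$occupied_km2, rec$habitat_km2)),
                 xlab = "year", ylab = expression(area ~ (km^2)),
                 main = "Occupied area by dispersal scenario")
  for (sc in scen)
    for (r in unique(rec$replicate[rec$scenario == sc])) {
      sub <- rec[rec$scenario == sc & rec$replicate == r, ]
      graphics::lines(sub$year, sub$occupied_km2, col = cols[sc])
    }
  hab <- rec[rec$scenario == scen[1] & rec$replicate == 1, ]
  graphics::lines(hab$year, hab$habitat_km2, lty = 2, col = "black")
  graphics::legend("topleft", legend = c(scen, "available habitat"),
                   col = c(cols, "black"),
                   lty = c(rep(1, length(scen)), 2), bty = "n")
  invisible(rec)
}
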