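# Shared fixtures, built in code. The reference pipeline run and the
# 500-presence recovery fit are computed lazily once and reused across
# test files.

uniform_water <- function(n_rows = 4, n_cols = n_rows, cell_size = 10) {
  raster_grid(matrix(1, n_rows, n_cols), cell_size = cell_size)
}

flat_suitability <- function(water, p = 1, theta = 0.1) {
  suitability_map(
    raster_grid(matrix(p, nrow(water$values), ncol(water$values)),
                cell_size = water$cell_size),
    water, theta = theta
  )
}

occurrences_at <- function(water, rows, cols) {
  cc <- cell_centers(water, rows, cols)
  data.frame(lon = cc$lon, lat = cc$lat)
}

# Hand-built range-shift result from per-year colonized / decolonized areas.
fake_result <- function(colonized, decolonized = rep(0, length(colonized)),
                        scenario = "local", replicate = 1L,
                        start_km2 = 100, habitat_km2 = 1e6,
                        n_replicates = 1L) {
  occ <- start_km2 + cumsum(colonized - decolonized)
  records <- data.frame(
    scenario = scenario, replicate = replicate,
    year = 0:length(colonized),
    occupied_km2 = c(start_km2, occ),
    colonized_km2 = c(0, colonized),
    decolonized_km2 = c(0, decolonized),
    habitat_km2 = habitat_km2
  )
  cfg <- scenario_config(scenario, n_years = length(colonized),
                         climate_interval = length(colonized),
                         n_replicates = n_replicates)
  structure(list(records = records, scenario = scenario, config = cfg),
            class = "range_shift_result")
}

local({
  cache <- new.env(parent = emptyenv())

  # Shipped reference pipeline run (100x100, 10 replicates, 80 years,
  # all four scenarios).
  reference_run <<- function() {
    if (is.null(cache$ref))
      cache$ref <- suppressMessages(
        run_pipeline(default_config(seed = 1),
                     out_dir = file.path(tempdir(), "aquashift-ref"),
                     write_rasters = FALSE))
    cache$ref
  }

  # Synthetic landscape plus a 500-presence sample from the reference truth.
  recovery_fixture <<- function() {
    if (is.null(cache$rec)) {
      cfg <- default_config(seed = 1)
      inp <- assemble_reference_inputs(cfg)
      truth <- truth_model(intercept = cfg$truth$intercept,
                           linear = unlist(cfg$truth$linear),
                           quadratic = unlist(cfg$truth$quadratic))
      occ <- gen_occurrences(truth, inp$climate, inp$water,
                             n_presences = 500, seed = 11)
      cache$rec <- list(climate = inp$climate, water = inp$water,
                        truth = truth, occurrences = occ)
    }
    cache$rec
  }
})

assemble_reference_inputs <- function(cfg) {
  spec <- landscape_spec(
    n_rows = cfg$landscape$n_rows, n_cols = cfg$landscape$n_cols,
    cell_size = cfg$landscape$cell_size,
    n_variables = cfg$landscape$n_variables,
    spatial_correlation_range = cfg$landscape$spatial_correlation_range,
    inter_variable_correlation = cfg$landscape$inter_variable_correlation,
    collinear_pairs = cfg$landscape$collinear_pairs,
    water_fraction = cfg$landscape$water_fraction,
    seed = cfg$seed
  )
  gen_landscape(spec)
}
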