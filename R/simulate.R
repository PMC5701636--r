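#' Scenario configuration for the range-shift simulation
#'
#' Four dispersal scenarios are supported: \code{no_dispersal} (occupied
#' cells can only go extinct), \code{local} (seed dispersal by local bird
#' movements, kernel truncated at 100 km), \code{full_ldd} (local plus
#' migratory movements, untruncated kernel), and \code{unlimited} (the
#' species occupies all suitable habitat every year).
#'
#' @param scenario one of "no_dispersal", "local", "full_ldd", "unlimited".
#' @param n_years simulation horizon in years (default 80).
#' @param climate_interval years between suitability updates (default 10;
#'   suitability is held constant within each interval).
#' @param n_replicates stochastic replicates (default 10); replicate r runs
#'   on its own RNG stream seeded from \code{base_seed + r}.
#' @param base_seed base RNG seed.
#' @param maturity_age1 propagule-production weight of a cell in its first
#'   year after colonization, in [0, 1] (default 0.5); cells aged >= 2 years
#'   produce at full weight 1.
#' @return an object of class \code{scenario_config}.
#' @export
scenario_config <- function(scenario = c("no_dispersal", "local", "full_ldd",
                                         "unlimited"),
                            n_years = 80, climate_interval = 10,
                            n_replicates = 10, base_seed = 1L,
                            maturity_age1 = 0.5) {
  scenario <- match.arg(scenario)
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  if (climate_interval < 1 || n_years %% climate_interval != 0)
    stop("climate_interval must divide n_years", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (maturity_age1 < 0 || maturity_age1 > 1)
    stop("maturity_age1 must lie in [0, 1]", call. = FALSE)
  structure(
    list(scenario = scenario, n_years = as.integer(n_years),
         climate_interval = as.integer(climate_interval),
         n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed),
         maturity_age1 = maturity_age1),
    class = "scenario_config"
  )
}

#' Initialize the simulation state from occurrence records
#'
#' Cells containing at least one occurrence start occupied at age 2 (fully
#' mature). Records outside the grid or on non-water cells are rejected; if
#' nothing remains, initialization fails with a diagnostic count.
#'
#' @param occurrences data.frame with \code{lon}, \code{lat}.
#' @param suit_map a \code{suitability_map} for the baseline climate.
#' @param water 0/1 water-mask \code{raster_grid}.
#' @return an object of class \code{sim_state}.
#' @export
initialize_state <- function(occurrences, suit_map, water) {
  stopifnot(inherits(suit_map, "suitability_map"),
            inherits(water, "raster_grid"))
  cells <- cells_from_coords(water, occurrences$lon, occurrences$lat)
  outside <- is.na(cells$row)
  wmask <- water$values > 0
  on_water <- !outside & wmask[cbind(
    ifelse(outside, 1L, cells$row), ifelse(outside, 1L, cells$col))]
  if (!any(on_water))
    stop(sprintf(
      "no occurrence initializes the grid (%d outside the grid, %d on ",
      sum(outside), sum(!outside & !on_water)),
      "non-water cells)", call. = FALSE)
  age <- matrix(0L, nrow(water$values), ncol(water$values))
  age[unique(cbind(cells$row[on_water], cells$col[on_water]))] <- 2L
  structure(
    list(age = age, year = 0L,
         suitability = suit_map$suitability$values,
         habitat = suit_map$habitat$values > 0 & wmask,
         theta = suit_map$theta,
         water = wmask, cell_size = water$cell_size),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "<sim_state> year %d: %d occupied cells (%.0f km^2), %d habitat cells\n",
    x$year, sum(x$age > 0), sum(x$age > 0) * x$cell_size^2,
    sum(x$habitat)))
  invisible(x)
}

# ---- dispersal machinery ----------------------------------------------------

#' Precompute dispersal operators for a kernel on a grid
#'
#' Expands the kernel to a per-cell stamp capped at the grid diagonal (mass
#' beyond the landscape is lost, not wrapped) and prepares the log-survival
#' stamps for the two maturity classes, plus their FFTs for the convolution
#' path.
#'
#' @param kernel a \code{dispersal_kernel}.
#' @param grid_dim c(n_rows, n_cols) of the simulation grid.
#' @param maturity_age1 production weight of age-1 cells.
#' @return an internal dispersal-operator object.
#' @export
prepare_dispersal <- function(kernel, grid_dim, maturity_age1 = 0.5) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  diag_cells <- ceiling(sqrt(sum(grid_dim^2)))
  stamp <- kernel_stamp(kernel, max_radius = diag_cells)
  R <- (nrow(stamp) - 1L) %/% 2L
  L1 <- log1p(-maturity_age1 * stamp)
  L2 <- log1p(-stamp)
  P1 <- stats::nextn(grid_dim[1] + 2L * R)
  P2 <- stats::nextn(grid_dim[2] + 2L * R)
  pad <- function(m) {
    out <- matrix(0, P1, P2)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  list(stamp = stamp, R = R, L1 = L1, L2 = L2,
       P = c(P1, P2),
       F_L1 = stats::fft(pad(L1)), F_L2 = stats::fft(pad(L2)),
       pad = pad, stamp_cells = length(stamp))
}

# Sum over sources of the log-survival stamp: direct per-source accumulation
# (cheap when few sources or a small stamp) or zero-padded FFT convolution.
# Both give the same field up to floating-point error; the method is chosen
# deterministically from the problem size.
accumulate_log_survival <- function(ind1, ind2, disp) {
  n_src <- sum(ind1) + sum(ind2)
  nr <- nrow(ind1); nc <- ncol(ind1)
  if (n_src == 0) return(matrix(0, nr, nc))
  if (as.numeric(n_src) * as.numeric(disp$stamp_cells) <= 2e6) {
    acc <- matrix(0, nr, nc)
    R <- disp$R
    add_sources <- function(ind, L) {
      src <- which(ind, arr.ind = TRUE)
      for (k in seq_len(nrow(src))) {
        i <- src[k, 1]; j <- src[k, 2]
        r1 <- max(1L, i - R); r2 <- min(nr, i + R)
        c1 <- max(1L, j - R); c2 <- min(nc, j + R)
        acc[r1:r2, c1:c2] <<- acc[r1:r2, c1:c2] +
          L[(r1 - i + R + 1L):(r2 - i + R + 1L),
            (c1 - j + R + 1L):(c2 - j + R + 1L)]
      }
    }
    add_sources(ind1, disp$L1)
    add_sources(ind2, disp$L2)
    acc
  } else {
    FA <- stats::fft(disp$pad(ind1 * 1)) * disp$F_L1 +
          stats::fft(disp$pad(ind2 * 1)) * disp$F_L2
    full <- Re(stats::fft(FA, inverse = TRUE)) / prod(disp$P)
    full[disp$R + seq_len(nr), disp$R + seq_len(nc)]
  }
}

#' Cell-wise arrival probability for one annual step
#'
#' For every cell, q = 1 - prod over occupied sources of
#' (1 - m(age_source) * K(distance)), with K the per-cell kernel stamp and
#' m the maturity weight (\code{maturity_age1} at age 1, 1 at age >= 2).
#'
#' @param state a \code{sim_state}.
#' @param disp operators from \code{\link{prepare_dispersal}}.
#' @return matrix of arrival probabilities in [0, 1].
#' @export
arrival_probability <- function(state, disp) {
  A <- accumulate_log_survival(state$age == 1L, state$age >= 2L, disp)
  q <- -expm1(pmin(A, 0))
  q[q < 1e-12] <- 0
  q
}

# ---- annual step ------------------------------------------------------------

#' Advance the simulation by one year
#'
#' Phase order: propagule production (maturity-weighted) -> dispersal ->
#' establishment -> extinction -> aging. A habitat cell that is currently
#' unoccupied becomes colonized (age 1) with probability
#' q * suitability(cell); occupied cells whose habitat became unsuitable go
#' extinct; survivors age by one year (capped at 2, full maturity).
#' Establishment draws one uniform variate per unoccupied habitat cell in a
#' fixed (column-major) order, so trajectories are reproducible given the
#' replicate RNG state.
#'
#' @param state a \code{sim_state}.
#' @param kernel a \code{dispersal_kernel} (ignored for the no_dispersal and
#'   unlimited scenarios); its cell size must match the grid.
#' @param config a \code{scenario_config}.
#' @param disp optional precomputed \code{\link{prepare_dispersal}} object
#'   (built from the kernel if missing).
#' @return the updated \code{sim_state}, with an attribute \code{step_stats}
#'   holding the colonized / decolonized cell counts of this step.
#' @export
sim_step <- function(state, kernel = NULL, config, disp = NULL) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "scenario_config"))
  scen <- config$scenario
  if (scen %in% c("local", "full_ldd")) {
    if (is.null(disp)) {
      if (is.null(kernel))
        stop("a dispersal kernel is required for scenario ", scen,
             call. = FALSE)
      if (!isTRUE(all.equal(kernel$cell_size, state$cell_size)))
        stop("kernel cell size does not match the simulation grid",
             call. = FALSE)
      disp <- prepare_dispersal(kernel, dim(state$age), config$maturity_age1)
    }
  }
  prev_occ <- state$age > 0L
  new_age <- state$age
  hab <- state$habitat

  colonized <- matrix(FALSE, nrow(new_age), ncol(new_age))
  if (scen == "unlimited") {
    colonized <- hab & !prev_occ
  } else if (scen %in% c("local", "full_ldd")) {
    q <- arrival_probability(state, disp)
    cand <- which(hab & !prev_occ)
    if (length(cand)) {
      u <- stats::runif(length(cand))
      hit <- cand[u < q[cand] * state$suitability[cand]]
      colonized[hit] <- TRUE
    }
  }

  extinct <- prev_occ & !hab
  survivors <- prev_occ & hab
  new_age[extinct] <- 0L
  new_age[survivors] <- pmin(state$age[survivors] + 1L, 2L)
  new_age[colonized] <- 1L

  state$age <- new_age
  state$year <- state$year + 1L
  attr(state, "step_stats") <- list(colonized = sum(colonized),
                                    decolonized = sum(extinct))
  state
}

# ---- scenario runner --------------------------------------------------------

#' Run one dispersal scenario with replicates
#'
#' Simulates \code{n_years} annual steps, re-predicting habitat suitability
#' from the fitted model at every climate-update boundary (years 1, 1 +
#' interval, ...; years within an interval share the slice projected for
#' that decade). Replicate r uses an independent reproducible RNG stream
#' seeded from \code{base_seed + r}, so reruns are bit-identical.
#'
#' @param config a \code{scenario_config}.
#' @param model a fitted \code{sdm_model}.
#' @param climate_series list of \code{climate_stack} (baseline first), at
#'   least \code{1 + n_years / climate_interval} slices.
#' @param kernel a \code{dispersal_kernel} (may be NULL for no_dispersal /
#'   unlimited).
#' @param occurrences data.frame with \code{lon}, \code{lat} (initial
#'   distribution).
#' @param water 0/1 water-mask \code{raster_grid}.
#' @return an object of class \code{range_shift_result}: a tidy records
#'   data.frame (scenario, replicate, year, occupied_km2, colonized_km2,
#'   decolonized_km2, habitat_km2) plus the config.
#' @export
run_scenario <- function(config, model, climate_series, kernel = NULL,
                         occurrences, water) {
  stopifnot(inherits(config, "scenario_config"))
  n_slices <- config$n_years %/% config$climate_interval
  if (length(climate_series) < n_slices + 1L)
    stop(sprintf(
      "climate series too short: %d slices for %d decadal updates",
      length(climate_series), n_slices), call. = FALSE)
  maps <- lapply(climate_series[seq_len(n_slices + 1L)], function(cs)
    predict_suitability(model, cs, water))
  cell_area <- water$cell_size^2
  needs_kernel <- config$scenario %in% c("local", "full_ldd")
  disp <- if (needs_kernel) {
    if (is.null(kernel))
      stop("scenario ", config$scenario, " requires a kernel", call. = FALSE)
    if (!isTRUE(all.equal(kernel$cell_size, water$cell_size)))
      stop("kernel cell size does not match the grid", call. = FALSE)
    prepare_dispersal(kernel, dim(water$values), config$maturity_age1)
  } else NULL

  rows <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed((config$base_seed + r) %% 2147483647L)
    state <- initialize_state(occurrences, maps[[1]], water)
    rec <- matrix(0, nrow = config$n_years + 1L, ncol = 4L)
    rec[1, ] <- c(sum(state$age > 0) * cell_area, 0, 0,
                  sum(state$habitat) * cell_area)
    for (t in seq_len(config$n_years)) {
      if ((t - 1L) %% config$climate_interval == 0L) {
        slice <- 1L + ceiling(t / config$climate_interval)
        state$suitability <- maps[[slice]]$suitability$values
        state$habitat <- maps[[slice]]$habitat$values > 0 & state$water
      }
      state <- sim_step(state, kernel, config, disp)
      st <- attr(state, "step_stats")
      rec[t + 1L, ] <- c(sum(state$age > 0) * cell_area,
                         st$colonized * cell_area,
                         st$decolonized * cell_area,
                         sum(state$habitat) * cell_area)
    }
    rows[[r]] <- data.frame(
      scenario = config$scenario, replicate = r,
      year = 0:config$n_years,
      occupied_km2 = rec[, 1], colonized_km2 = rec[, 2],
      decolonized_km2 = rec[, 3], habitat_km2 = rec[, 4]
    )
  }
  structure(
    list(records = do.call(rbind, rows), scenario = config$scenario,
         config = config),
    class = "range_shift_result"
  )
}

#' @export
print.range_shift_result <- function(x, ...) {
  fin <- x$records[x$records$year == max(x$records$year), ]
  cat(sprintf(
    "<range_shift_result> scenario %s: %d replicates x %d years\n",
    x$scenario, x$config$n_replicates, x$config$n_years))
  cat(sprintf(
    "  final occupied area %.0f +/- %.0f km^2 (habitat %.0f km^2)\n",
    mean(fin$occupied_km2), stats::sd(fin$occupied_km2),
    fin$habitat_km2[1]))
  invisible(x)
}
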