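#' Specification of a synthetic landscape
#'
#' Describes the synthetic stand-in for a stack of bioclimatic rasters plus a
#' water-presence mask: smooth correlated Gaussian random fields on an
#' equal-area lattice, with designated variable pairs forced to a target
#' collinearity (to exercise the |r| >= 0.70 pruning rule downstream), and a
#' binary water mask covering a set fraction of cells.
#'
#' @param n_rows,n_cols grid dimensions (>= 4).
#' @param cell_size cell edge in km (default 10, the scale of a 10-arc-minute
#'   grid in mid-latitudes).
#' @param n_variables number of bioclimatic surfaces, named bio1..bioK.
#' @param spatial_correlation_range autocorrelation range of the random
#'   fields, km.
#' @param inter_variable_correlation target Pearson r induced between each
#'   designated collinear pair.
#' @param collinear_pairs list of 2-vectors of variable indices (or names);
#'   each pair (a, b) rebuilds b as a mixture of a and independent noise.
#' @param water_fraction proportion of cells flagged as water, in (0, 1].
#' @param seed RNG seed for the generator.
#' @return an object of class \code{landscape_spec}.
#' @export
landscape_spec <- function(n_rows = 100, n_cols = 100, cell_size = 10,
                           n_variables = 7, spatial_correlation_range = 100,
                           inter_variable_correlation = 0.9,
                           collinear_pairs = list(c(1L, 2L)),
                           water_fraction = 0.25, seed = 1L) {
  if (n_rows < 4 || n_cols < 4)
    stop("grid must be at least 4 x 4", call. = FALSE)
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (water_fraction <= 0 || water_fraction > 1)
    stop("water_fraction must be in (0, 1]", call. = FALSE)
  if (n_variables < 1) stop("need at least one variable", call. = FALSE)
  if (abs(inter_variable_correlation) > 1)
    stop("inter_variable_correlation must lie in [-1, 1]", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, n_variables = as.integer(n_variables),
         spatial_correlation_range = spatial_correlation_range,
         inter_variable_correlation = inter_variable_correlation,
         collinear_pairs = collinear_pairs,
         water_fraction = water_fraction, seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

# Gaussian random field: white noise smoothed by a circular (FFT) Gaussian
# filter, then standardized to mean 0, sd 1. The wrap-around from circular
# convolution is acceptable for synthetic landscapes.
grf_surface <- function(n_rows, n_cols, sigma_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma_cells <= 0) return((z - mean(z)) / stats::sd(z))
  fx <- c(0:(floor(n_rows / 2)), -(ceiling(n_rows / 2) - 1):-1) / n_rows
  fy <- c(0:(floor(n_cols / 2)), -(ceiling(n_cols / 2) - 1):-1) / n_cols
  # Fourier transform of a Gaussian kernel with spatial sd sigma_cells
  gr <- exp(-2 * pi^2 * sigma_cells^2 * fx^2)
  gc <- exp(-2 * pi^2 * sigma_cells^2 * fy^2)
  filt <- outer(gr, gc)
  s <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / length(z)
  (s - mean(s)) / stats::sd(s)
}

#' Generate a synthetic landscape
#'
#' Builds \code{n_variables} smooth standardized climate surfaces and a binary
#' water mask. Collinear pairs are induced by linear mixing:
#' bio_b = r * bio_a + sqrt(1 - r^2) * independent field, so the empirical
#' correlation matches the target up to sampling error of the smoothed field.
#' The water mask is a smooth field thresholded at the (1 - water_fraction)
#' quantile, giving the requested coverage to within one cell.
#'
#' @param spec a \code{landscape_spec}.
#' @return list with elements \code{climate} (a \code{climate_stack}),
#'   \code{water} (a 0/1 \code{raster_grid}) and \code{spec}.
#' @export
gen_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  sigma <- spec$spatial_correlation_range / spec$cell_size / 2
  vars <- paste0("bio", seq_len(spec$n_variables))
  fields <- lapply(vars, function(v)
    grf_surface(spec$n_rows, spec$n_cols, sigma))
  names(fields) <- vars
  r <- spec$inter_variable_correlation
  for (pr in spec$collinear_pairs) {
    a <- if (is.character(pr)) pr[1] else vars[pr[1]]
    b <- if (is.character(pr)) pr[2] else vars[pr[2]]
    if (!a %in% vars || !b %in% vars)
      stop("collinear pair references unknown variable", call. = FALSE)
    mixed <- r * fields[[a]] + sqrt(1 - r^2) * fields[[b]]
    fields[[b]] <- (mixed - mean(mixed)) / stats::sd(mixed)
  }
  wf <- grf_surface(spec$n_rows, spec$n_cols, sigma)
  thr <- stats::quantile(wf, 1 - spec$water_fraction, names = FALSE)
  water <- (wf >= thr) * 1
  mk <- function(m) raster_grid(m, cell_size = spec$cell_size)
  list(
    climate = climate_stack(lapply(fields, mk)),
    water = mk(water),
    spec = spec
  )
}

#' Specification of a decadal climate trend
#'
#' Decadal increments applied along a spatial gradient: cells furthest along
#' \code{direction} warm at twice the stated increment and cells at the
#' trailing edge not at all, so the landscape mean changes by exactly
#' \code{increment} per decade while suitable habitat shifts directionally.
#'
#' @param increments named numeric vector of per-decade changes, one entry
#'   per trending variable (units of the variable per decade). Variables not
#'   named are held constant.
#' @param n_decades number of future decades (>= 1); the generated series has
#'   \code{n_decades + 1} slices including the baseline.
#' @param direction length-2 vector (x, y) giving the gradient direction;
#'   normalized internally.
#' @return an object of class \code{trend_spec}.
#' @export
trend_spec <- function(increments, n_decades = 8, direction = c(1, 0)) {
  if (n_decades < 1) stop("n_decades must be >= 1", call. = FALSE)
  if (is.null(names(increments)) || any(!nzchar(names(increments))))
    stop("`increments` must be a named vector", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero", call. = FALSE)
  structure(
    list(increments = increments, n_decades = as.integer(n_decades),
         direction = direction / nrm),
    class = "trend_spec"
  )
}

# Spatial ramp in [0, 2] (mean 1) along the trend direction, evaluated at
# cell centers.
trend_ramp <- function(grid, direction) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cc <- cell_centers(grid, rep(seq_len(nr), nc),
                     rep(seq_len(nc), each = nr))
  proj <- cc$lon * direction[1] + cc$lat * direction[2]
  rng <- range(proj)
  ramp <- if (diff(rng) == 0) rep(1, length(proj))
          else 2 * (proj - rng[1]) / diff(rng)
  matrix(ramp, nr, nc)
}

#' Generate a decadal climate series
#'
#' Slice d equals baseline + d * increment field, exactly (affine in d, no
#' accumulation drift). The increment field for each trending variable is the
#' stated per-decade increment times the spatial ramp.
#'
#' @param base a \code{climate_stack} (the baseline slice).
#' @param trend a \code{trend_spec}; all trending variables must exist in
#'   \code{base}.
#' @return list of \code{climate_stack} of length \code{n_decades + 1};
#'   element 1 is the baseline.
#' @export
gen_climate_series <- function(base, trend) {
  stopifnot(inherits(base, "climate_stack"), inherits(trend, "trend_spec"))
  missing_vars <- setdiff(names(trend$increments), names(base))
  if (length(missing_vars))
    stop("trend references variables absent from the baseline stack: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  ramp <- trend_ramp(base$layers[[1]], trend$direction)
  lapply(0:trend$n_decades, function(d) {
    layers <- base$layers
    for (v in names(trend$increments)) {
      g <- layers[[v]]
      g$values <- g$values + d * trend$increments[[v]] * ramp
      layers[[v]] <- g
    }
    climate_stack(layers)
  })
}

#' Ground-truth occurrence model
#'
#' The true occurrence probability is the inverse logit of a linear-plus-
#' quadratic predictor in the climate variables, multiplied by the water mask
#' (exactly zero off water). It is the known truth against which the fitted
#' habitat-suitability model can be checked.
#'
#' @param intercept scalar intercept of the linear predictor.
#' @param linear named numeric vector of linear coefficients.
#' @param quadratic optional named numeric vector of coefficients on squared
#'   variables.
#' @return an object of class \code{truth_model}.
#' @export
truth_model <- function(intercept = -12, linear = c(bio1 = 16),
                        quadratic = c(bio1 = -4)) {
  if (length(linear) && is.null(names(linear)))
    stop("`linear` must be named", call. = FALSE)
  if (length(quadratic) && is.null(names(quadratic)))
    stop("`quadratic` must be named", call. = FALSE)
  structure(list(intercept = intercept, linear = linear,
                 quadratic = quadratic),
            class = "truth_model")
}

#' True suitability surface implied by a truth model
#'
#' @param truth a \code{truth_model}.
#' @param climate a \code{climate_stack} containing every variable the truth
#'   references.
#' @param water 0/1 water-mask \code{raster_grid}.
#' @return \code{raster_grid} of probabilities in [0, 1], zero off water.
#' @export
true_suitability <- function(truth, climate, water) {
  stopifnot(inherits(truth, "truth_model"), inherits(climate, "climate_stack"))
  need <- union(names(truth$linear), names(truth$quadratic))
  missing_vars <- setdiff(need, names(climate))
  if (length(missing_vars))
    stop("truth references variables absent from the stack: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  eta <- matrix(truth$intercept, nrow(water$values), ncol(water$values))
  for (v in names(truth$linear))
    eta <- eta + truth$linear[[v]] * climate[[v]]$values
  for (v in names(truth$quadratic))
    eta <- eta + truth$quadratic[[v]] * climate[[v]]$values^2
  p <- stats::plogis(eta) * (water$values > 0)
  raster_grid(p, cell_size = water$cell_size, xll = water$xll,
              yll = water$yll)
}

#' Sample occurrence records from the truth
#'
#' Presence cells are drawn (with replacement) with probability proportional
#' to the true occurrence probability; only water cells have positive mass.
#' Records are returned at cell-center coordinates, emulating a cleaned
#' occurrence download.
#'
#' @param truth a \code{truth_model}.
#' @param climate baseline \code{climate_stack}.
#' @param water 0/1 water mask.
#' @param n_presences number of records (>= 1).
#' @param seed RNG seed.
#' @return data.frame with columns \code{lon}, \code{lat}.
#' @export
gen_occurrences <- function(truth, climate, water, n_presences = 200,
                            seed = 1L) {
  if (n_presences < 1) stop("n_presences must be >= 1", call. = FALSE)
  p <- true_suitability(truth, climate, water)$values
  if (all(p <= 0))
    stop("degenerate landscape: no water cell has positive occurrence ",
         "probability", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(length(p), n_presences, replace = TRUE,
                    prob = as.vector(p))
  nr <- nrow(p)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  cell_centers(water, rows, cols)
}
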