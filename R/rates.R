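#' Colonization, extinction and expansion rates (km per year)
#'
#' The colonization rate of a replicate is the square root of its mean
#' annual colonized area; the extinction rate is defined symmetrically on
#' decolonized area. The expansion rate is the signed square root of the
#' mean annual net change (colonized minus decolonized): the sign carries
#' the direction of net range change. All three average over every simulated
#' year (including post-saturation years with little change), which is why
#' expansion is typically well below colonization minus extinction on the
#' km/yr scale. The formula behind the expansion rate is a package
#' definition; treat cross-study comparisons of that one statistic with
#' care.
#'
#' @param result a \code{range_shift_result}.
#' @param replicate replicate index.
#' @return rate in km per year.
#' @export
colonization_rate <- function(result, replicate = 1L) {
  sqrt(mean(annual_series(result, replicate)$colonized_km2))
}

#' @rdname colonization_rate
#' @export
extinction_rate <- function(result, replicate = 1L) {
  sqrt(mean(annual_series(result, replicate)$decolonized_km2))
}

#' @rdname colonization_rate
#' @export
expansion_rate <- function(result, replicate = 1L) {
  s <- annual_series(result, replicate)
  delta <- mean(s$colonized_km2 - s$decolonized_km2)
  sign(delta) * sqrt(abs(delta))
}

# Annual rows (year >= 1) of one replicate; year 0 is the initial census.
annual_series <- function(result, replicate) {
  stopifnot(inherits(result, "range_shift_result"))
  out <- result$records[result$records$replicate == replicate &
                          result$records$year >= 1, ]
  if (nrow(out) == 0)
    stop("replicate ", replicate, " has no simulated years", call. = FALSE)
  out
}

#' Summarize rates across scenarios and replicates
#'
#' Rates are computed per replicate and then averaged (not pooled), so the
#' across-replicate standard deviation is meaningful. The colonization rate
#' of each scenario is also compared with a climate-velocity benchmark
#' (default 0.42 km/yr, the estimated mean speed of isotherm movement under
#' global warming; plausible range roughly 0.11-0.46 km/yr).
#'
#' @param results list of \code{range_shift_result} (one per scenario).
#' @param benchmark_km_yr climate-velocity benchmark in km/yr.
#' @return an object of class \code{rate_summary}: a tidy data.frame
#'   (scenario, rate, mean, sd, n_replicates) plus the benchmark and the
#'   colonization / benchmark ratio per scenario.
#' @export
summarize_rates <- function(results, benchmark_km_yr = 0.42) {
  if (inherits(results, "range_shift_result")) results <- list(results)
  if (length(results) == 0) stop("no results to summarize", call. = FALSE)
  nreps <- vapply(results, function(r) r$config$n_replicates, integer(1))
  if (length(unique(nreps)) > 1)
    warning("scenario results have differing replicate counts")
  tab <- do.call(rbind, lapply(results, function(res) {
    reps <- seq_len(res$config$n_replicates)
    per <- data.frame(
      colonization = vapply(reps, function(r) colonization_rate(res, r),
                            numeric(1)),
      extinction = vapply(reps, function(r) extinction_rate(res, r),
                          numeric(1)),
      expansion = vapply(reps, function(r) expansion_rate(res, r),
                         numeric(1))
    )
    data.frame(
      scenario = res$scenario,
      rate = names(per),
      mean = vapply(per, mean, numeric(1)),
      sd = vapply(per, function(x) if (length(x) > 1) stats::sd(x) else 0,
                  numeric(1)),
      n_replicates = length(reps),
      row.names = NULL
    )
  }))
  col_means <- tab[tab$rate == "colonization", ]
  ratio <- stats::setNames(col_means$mean / benchmark_km_yr,
                           col_means$scenario)
  structure(
    list(table = tab, benchmark_km_yr = benchmark_km_yr,
         colonization_vs_benchmark = ratio),
    class = "rate_summary"
  )
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("<rate_summary> rates in km/yr (mean +/- sd across replicates)\n")
  for (sc in unique(x$table$scenario)) {
    sub <- x$table[x$table$scenario == sc, ]
    cat(sprintf("  %-13s", sc))
    cat(paste(sprintf("%s %.2f+/-%.2f", sub$rate, sub$mean, sub$sd),
              collapse = "  "), "\n")
  }
  cat(sprintf(
    "  climate-velocity benchmark %.2f km/yr; colonization/benchmark: %s\n",
    x$benchmark_km_yr,
    paste(sprintf("%s %.1fx", names(x$colonization_vs_benchmark),
                  x$colonization_vs_benchmark), collapse = ", ")))
  cat("  note: the expansion-rate formula (signed sqrt of mean net annual",
      "change) is a\n  package definition; compare across studies with",
      "care.\n")
  invisible(x)
}

#' Write the rate summary as a tidy CSV
#'
#' @param summary a \code{rate_summary}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_rates_csv <- function(summary, path) {
  stopifnot(inherits(summary, "rate_summary"))
  utils::write.csv(summary$table, path, row.names = FALSE)
  invisible(path)
}
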