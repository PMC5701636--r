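test_that("initialization rasterizes occurrences at full maturity", {
  water <- uniform_water(4)
  sm <- flat_suitability(water)
  occ <- occurrences_at(water, c(2, 2, 3), c(2, 2, 4))  # 3 records, 2 cells
  st <- initialize_state(occ, sm, water)
  expect_identical(sum(st$age > 0), 2L)
  expect_true(all(st$age[st$age > 0] == 2L))
  expect_identical(st$year, 0L)
})

test_that("initialization fails off water and outside the grid", {
  water <- raster_grid(matrix(c(1, rep(0, 15)), 4, 4), cell_size = 10)
  sm <- flat_suitability(water)
  dry_occ <- occurrences_at(water, 3, 3)
  expect_error(initialize_state(dry_occ, sm, water), "non-water")
  outside <- data.frame(lon = -500, lat = -500)
  expect_error(initialize_state(outside, sm, water), "outside")
})

test_that("no-dispersal steps change nothing but ages in stable habitat", {
  water <- uniform_water(5)
  sm <- flat_suitability(water, p = 0.9, theta = 0.5)
  st <- initialize_state(occurrences_at(water, c(2, 4), c(2, 3)), sm, water)
  cfg <- scenario_config("no_dispersal", n_years = 1, climate_interval = 1,
                         n_replicates = 1)
  st1 <- sim_step(st, NULL, cfg)
  expect_identical(st1$age > 0, st$age > 0)
  expect_identical(attr(st1, "step_stats"),
                   list(colonized = 0L, decolonized = 0L))
})

test_that("a unit kernel colonizes the whole first ring with certainty", {
  water <- uniform_water(5)
  sm <- flat_suitability(water, p = 1, theta = 0.5)
  st <- initialize_state(occurrences_at(water, 3, 3), sm, water)
  # ring 1 holds the 8 adjacent cells; mass 8 puts per-cell probability 1
  kern <- dispersal_kernel(c(0, 8), cell_size = 10)
  cfg <- scenario_config("local", n_years = 1, climate_interval = 1,
                         n_replicates = 1)
  set.seed(1)
  st1 <- sim_step(st, kern, cfg)
  expect_identical(sum(st1$age == 1L), 8L)
  expect_true(all(st1$age[2:4, 2:4] > 0))
})

test_that("single-step colonization frequencies match the closed-form
           product formula", {
  set.seed(99)
  water <- uniform_water(4)
  suit <- raster_grid(matrix(runif(16, 0.3, 1), 4, 4), cell_size = 10)
  sm <- suitability_map(suit, water, theta = 0.1)
  st0 <- initialize_state(occurrences_at(water, 2, 2), sm, water)
  kern <- dispersal_kernel(c(0.3, 0.4, 0.2), cell_size = 10)
  cfg <- scenario_config("local", n_years = 1, climate_interval = 1,
                         n_replicates = 1)
  disp <- prepare_dispersal(kern, c(4, 4), cfg$maturity_age1)
  # one mature source: q at a cell is just its per-cell stamp value
  stamp <- kernel_stamp(kern)
  R <- (nrow(stamp) - 1) / 2
  q_exp <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    if (abs(i - 2) <= R && abs(j - 2) <= R)
      q_exp[i, j] <- stamp[i - 2 + R + 1, j - 2 + R + 1]
  expect_equal(arrival_probability(st0, disp), q_exp, tolerance = 1e-12)
  n <- 5000
  hits <- matrix(0, 4, 4)
  set.seed(7)
  for (k in seq_len(n)) hits <- hits + (sim_step(st0, kern, cfg,
                                                 disp)$age == 1L)
  p_exp <- q_exp * sm$suitability$values
  p_exp[2, 2] <- 0
  idx <- p_exp > 0
  z <- (hits[idx] / n - p_exp[idx]) /
    sqrt(p_exp[idx] * (1 - p_exp[idx]) / n)
  expect_lt(max(abs(z)), 3)
})

test_that("multi-source arrival uses the full survival product", {
  water <- uniform_water(4)
  sm <- flat_suitability(water, p = 1, theta = 0.5)
  st <- initialize_state(occurrences_at(water, c(1, 1), c(1, 3)), sm, water)
  st$age[1, 1] <- 1L  # one immature source (weight 0.5), one mature
  kern <- dispersal_kernel(c(0, 0.8), cell_size = 10)
  disp <- prepare_dispersal(kern, c(4, 4), maturity_age1 = 0.5)
  q <- arrival_probability(st, disp)
  kcell <- kernel_stamp(kern)[1, 2]  # per-cell ring-1 probability
  # cell (1,2) is a ring-1 neighbour of both sources
  expect_equal(q[1, 2], 1 - (1 - 0.5 * kcell) * (1 - kcell),
               tolerance = 1e-12)
})

test_that("direct and FFT accumulation agree", {
  set.seed(12)
  water <- uniform_water(30)
  sm <- flat_suitability(water, p = 1, theta = 0.5)
  pts <- occurrences_at(water, sample(30, 40, TRUE), sample(30, 40, TRUE))
  st <- initialize_state(pts, sm, water)
  kp <- reference_kernel_params("clubrush")
  kern <- build_kernel(kp$movement, kp$retention, truncation_km = 100,
                       n_samples = 1e4, seed = 5)
  disp <- prepare_dispersal(kern, c(30, 30), 0.5)
  d_direct <- disp; d_direct$stamp_cells <- 0  # force direct path
  d_fft <- disp; d_fft$stamp_cells <- Inf      # force convolution path
  a1 <- arrival_probability(st, d_direct)
  a2 <- arrival_probability(st, d_fft)
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("unlimited dispersal occupies exactly the habitat set", {
  fx <- recovery_fixture()
  m <- fit_sdm(fx$climate, fx$occurrences, fx$water, seed = 2)
  series <- gen_climate_series(fx$climate,
                               trend_spec(c(bio1 = 0.25), n_decades = 2))
  cfg <- scenario_config("unlimited", n_years = 20, climate_interval = 10,
                         n_replicates = 1, base_seed = 3)
  res <- run_scenario(cfg, m, series, NULL, fx$occurrences, fx$water)
  rec <- res$records[res$records$year >= 1, ]
  expect_identical(rec$occupied_km2, rec$habitat_km2)
})

test_that("no dispersal in shrinking habitat is monotonically
           non-increasing", {
  fx <- recovery_fixture()
  m <- fit_sdm(fx$climate, fx$occurrences, fx$water, seed = 2)
  series <- gen_climate_series(fx$climate,
                               trend_spec(c(bio1 = 0.25), n_decades = 3))
  cfg <- scenario_config("no_dispersal", n_years = 30,
                         climate_interval = 10, n_replicates = 1,
                         base_seed = 3)
  res <- run_scenario(cfg, m, series, NULL, fx$occurrences, fx$water)
  expect_true(all(diff(res$records$occupied_km2) <= 0))
  expect_true(all(res$records$colonized_km2 == 0))
})

test_that("runs are bit-identical under the same base seed and the
           bookkeeping identity holds", {
  fx <- recovery_fixture()
  m <- fit_sdm(fx$climate, fx$occurrences, fx$water, seed = 2)
  series <- gen_climate_series(fx$climate,
                               trend_spec(c(bio1 = 0.25), n_decades = 2))
  kp <- reference_kernel_params("clubrush")
  kern <- build_kernel(kp$movement, kp$retention, truncation_km = 100,
                       n_samples = 1e4, seed = 5)
  cfg <- scenario_config("local", n_years = 20, climate_interval = 10,
                         n_replicates = 3, base_seed = 7)
  r1 <- run_scenario(cfg, m, series, kern, fx$occurrences, fx$water)
  r2 <- run_scenario(cfg, m, series, kern, fx$occurrences, fx$water)
  expect_identical(r1$records, r2$records)
  for (r in 1:3) {
    rec <- r1$records[r1$records$replicate == r, ]
    expect_equal(diff(rec$occupied_km2),
                 (rec$colonized_km2 - rec$decolonized_km2)[-1])
  }
  # distinct replicate substreams give distinct trajectories
  traj <- split(r1$records$occupied_km2, r1$records$replicate)
  expect_false(identical(traj[[1]], traj[[2]]))
})

test_that("a short climate series is rejected before simulating", {
  fx <- recovery_fixture()
  m <- fit_sdm(fx$climate, fx$occurrences, fx$water, seed = 2)
  series <- gen_climate_series(fx$climate,
                               trend_spec(c(bio1 = 0.25), n_decades = 2))
  cfg <- scenario_config("no_dispersal", n_years = 80,
                         climate_interval = 10, n_replicates = 1)
  expect_error(run_scenario(cfg, m, series, NULL, fx$occurrences,
                            fx$water), "too short")
})

test_that("kernel cell size must match the grid", {
  water <- uniform_water(5)
  sm <- flat_suitability(water)
  st <- initialize_state(occurrences_at(water, 3, 3), sm, water)
  kern <- dispersal_kernel(c(0, 1), cell_size = 7)
  cfg <- scenario_config("local", n_years = 1, climate_interval = 1,
                         n_replicates = 1)
  expect_error(sim_step(st, kern, cfg), "cell size")
})
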