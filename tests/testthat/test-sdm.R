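# Small landscape with a collinear pair (bio1 ~ bio2) and an independent
# bio3; the truth loads on bio1 and bio3 only, so bio2 is the redundant,
# less-important member of the correlated pair.
collinear_fixture <- function(r = 0.95, seed = 21) {
  land <- gen_landscape(landscape_spec(
    n_rows = 50, n_cols = 50, n_variables = 3,
    inter_variable_correlation = r, collinear_pairs = list(c(1L, 2L)),
    water_fraction = 1, seed = seed))
  truth <- truth_model(intercept = -1, linear = c(bio1 = 3, bio3 = 1.5),
                       quadratic = NULL)
  occ <- gen_occurrences(truth, land$climate, land$water,
                         n_presences = 300, seed = seed + 1)
  list(land = land, occ = occ)
}

test_that("selection is a no-op when all correlations are below 0.70", {
  fx <- collinear_fixture(r = 0.3)
  kept <- select_variables(fx$land$climate, fx$occ, fx$land$water, seed = 1)
  expect_identical(kept, c("bio1", "bio2", "bio3"))
})

test_that("selection drops the less important member of a collinear pair", {
  fx <- collinear_fixture(r = 0.95)
  V <- stack_values(fx$land$climate)
  expect_gt(abs(cor(V[, "bio1"], V[, "bio2"])), 0.90)
  kept <- select_variables(fx$land$climate, fx$occ, fx$land$water, seed = 1)
  expect_identical(kept, c("bio1", "bio3"))
})

test_that("retained variables always satisfy the 0.70 correlation bound", {
  for (s in c(21, 22, 23)) {
    fx <- collinear_fixture(r = 0.95, seed = s)
    kept <- select_variables(fx$land$climate, fx$occ, fx$land$water,
                             seed = 1)
    tc <- stack_values(fx$land$climate)[, kept, drop = FALSE]
    C <- abs(cor(tc)); diag(C) <- 0
    expect_lt(max(C), 0.70)
  }
})

test_that("duplicated variables collapse to a single retained one", {
  land <- gen_landscape(landscape_spec(n_rows = 20, n_cols = 20,
                                       n_variables = 1,
                                       collinear_pairs = list(),
                                       water_fraction = 1, seed = 9))
  dup <- climate_stack(list(bio1 = land$climate[["bio1"]],
                            bio2 = land$climate[["bio1"]]))
  truth <- truth_model(0, c(bio1 = 2), NULL)
  occ <- gen_occurrences(truth, dup, land$water, 100, seed = 2)
  kept <- select_variables(dup, occ, land$water, seed = 1)
  expect_length(kept, 1)
})

test_that("fitting recovers the sign of a strong positive effect", {
  land <- gen_landscape(landscape_spec(n_rows = 40, n_cols = 40,
                                       n_variables = 2,
                                       collinear_pairs = list(),
                                       water_fraction = 1, seed = 31))
  truth <- truth_model(-1, c(bio1 = 3), NULL)
  occ <- gen_occurrences(truth, land$climate, land$water, 300, seed = 32)
  m <- fit_sdm(land$climate, occ, land$water, seed = 5)
  expect_gt(m$coef[["bio1"]], 0)
})

test_that("fits are deterministic given the seed and refuse tiny samples", {
  land <- gen_landscape(landscape_spec(n_rows = 20, n_cols = 20,
                                       n_variables = 2,
                                       collinear_pairs = list(),
                                       water_fraction = 1, seed = 33))
  truth <- truth_model(0, c(bio1 = 2), NULL)
  occ <- gen_occurrences(truth, land$climate, land$water, 100, seed = 3)
  m1 <- fit_sdm(land$climate, occ, land$water, seed = 8)
  m2 <- fit_sdm(land$climate, occ, land$water, seed = 8)
  expect_identical(m1$coef, m2$coef)
  expect_error(fit_sdm(land$climate, occ[1:5, ], land$water, seed = 8),
               "at least 10")
})

test_that("rank AUC matches pROC and is monotone-transform invariant", {
  set.seed(41)
  pos <- rnorm(80, mean = 1); neg <- rnorm(120)
  a <- auc_rank(pos, neg)
  expect_equal(a, as.numeric(pROC::auc(
    pROC::roc(response = c(rep(1, 80), rep(0, 120)),
              predictor = c(pos, neg), quiet = TRUE))))
  expect_identical(auc_rank(exp(pos), exp(neg)), a)
  expect_identical(auc_rank(1000 + 2 * pos, 1000 + 2 * neg), a)
  expect_identical(auc_rank(neg, neg), 0.5)
  expect_identical(auc_rank(rep(2, 5), rep(1, 7)), 1)
})

test_that("evaluation reports Dxy = 2*AUC - 1 and detects no-signal data", {
  fx <- recovery_fixture()
  # real signal
  m <- fit_sdm(fx$climate, fx$occurrences, fx$water, seed = 2)
  ev <- evaluate_sdm(m, fx$climate, fx$occurrences, fx$water,
                     k_folds = 5, seed = 3)
  expect_identical(ev$dxy, 2 * ev$auc_mean - 1)
  expect_length(ev$auc_folds, 5)
  # presences indistinguishable from background
  null_truth <- truth_model(0, c(bio1 = 0), NULL)
  nocc <- gen_occurrences(null_truth, fx$climate, fx$water, 500, seed = 12)
  mn <- fit_sdm(fx$climate, nocc, fx$water, n_background = 500, seed = 2)
  evn <- evaluate_sdm(mn, fx$climate, nocc, fx$water, k_folds = 5,
                      seed = 3)
  expect_gte(evn$auc_mean, 0.4)
  expect_lte(evn$auc_mean, 0.6)
})

test_that("prediction honors masking and degenerate coefficients", {
  land <- gen_landscape(landscape_spec(n_rows = 10, n_cols = 10,
                                       n_variables = 2,
                                       collinear_pairs = list(),
                                       water_fraction = 0.5, seed = 51))
  truth <- truth_model(0, c(bio1 = 2), NULL)
  occ <- gen_occurrences(truth, land$climate, land$water, 50, seed = 52)
  m <- fit_sdm(land$climate, occ, land$water, seed = 5)
  m$coef[] <- 0
  sm <- predict_suitability(m, land$climate, land$water)
  w <- land$water$values > 0
  expect_true(all(sm$suitability$values[w] == 0.5))
  expect_true(all(sm$suitability$values[!w] == 0))
  # all-dry mask
  dry <- raster_grid(matrix(0, 10, 10), cell_size = 10)
  expect_true(all(predict_suitability(m, land$climate,
                                      dry)$suitability$values == 0))
  # schema error on a missing variable
  partial <- climate_stack(land$climate$layers["bio1"])
  expect_error(predict_suitability(m, partial, land$water), "bio2")
})

test_that("projected habitat shifts along the warming gradient", {
  land <- gen_landscape(landscape_spec(n_rows = 40, n_cols = 40,
                                       n_variables = 2,
                                       collinear_pairs = list(),
                                       water_fraction = 1, seed = 61))
  # band-shaped truth with its optimum in the warm tail: warming along +x
  # moves the habitat band onto the leading edge by decade 8
  truth <- truth_model(-12, c(bio1 = 16), c(bio1 = -4))
  occ <- gen_occurrences(truth, land$climate, land$water, 300, seed = 62)
  m <- fit_sdm(land$climate, occ, land$water, seed = 6)
  series <- gen_climate_series(land$climate,
                               trend_spec(c(bio1 = 0.125), n_decades = 8,
                                          direction = c(1, 0)))
  centroid_x <- function(sm) {
    hab <- which(sm$habitat$values > 0, arr.ind = TRUE)
    mean(cell_centers(sm$habitat, hab[, 1], hab[, 2])$lon)
  }
  x0 <- centroid_x(predict_suitability(m, series[[1]], land$water))
  x8 <- centroid_x(predict_suitability(m, series[[9]], land$water))
  expect_gt(x8, x0)
})

test_that("models survive a JSON round trip", {
  fx <- recovery_fixture()
  m <- fit_sdm(fx$climate, fx$occurrences, fx$water, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_sdm_json(m, path)
  m2 <- read_sdm_json(path)
  expect_equal(m2$coef, m$coef)
  expect_equal(m2$theta, m$theta)
  sm1 <- predict_suitability(m, fx$climate, fx$water)
  sm2 <- predict_suitability(m2, fx$climate, fx$water)
  expect_equal(sm2$suitability$values, sm1$suitability$values)
})
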