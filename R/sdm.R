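#' @importFrom stats plogis quantile sd cor predict coef
NULL

# ---- internal helpers -------------------------------------------------------

# Linear (+ quadratic) feature expansion of a variable matrix.
expand_features <- function(X, quadratic = TRUE) {
  if (quadratic) {
    Xq <- X^2
    colnames(Xq) <- paste0(colnames(X), "_sq")
    cbind(X, Xq)
  } else X
}

standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# Penalized presence-background logistic fit on an already-expanded,
# standardized design matrix. Returns the named coefficient vector
# (intercept first) and the lambda used. With lambda = NULL the value is
# chosen by seeded k-fold cross-validated deviance, scaled by the
# `regularization` multiplier.
fit_pb_glmnet <- function(Xs, y, lambda = NULL, regularization = 1,
                          seed = 1L) {
  if (regularization <= 0)
    stop("regularization must be positive", call. = FALSE)
  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep_len(1:5, length(y)))
    cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = FALSE)
    lambda <- cv$lambda.min * regularization
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 1,
                          standardize = FALSE)
  }
  b <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  names(b) <- c("(Intercept)", colnames(Xs))
  list(coef = b, lambda = lambda)
}

pb_linear_predictor <- function(coefs, Xs) {
  drop(cbind(1, Xs[, names(coefs)[-1], drop = FALSE]) %*% coefs)
}

# Assemble presence + background training cells for a climate stack.
training_cells <- function(climate, presences, water, n_background, seed) {
  g <- water
  cells <- cells_from_coords(g, presences$lon, presences$lat)
  if (anyNA(cells$row))
    stop("some presences fall outside the grid", call. = FALSE)
  on_water <- g$values[cbind(cells$row, cells$col)] > 0
  if (!all(on_water))
    stop(sum(!on_water), " presence record(s) fall on non-water cells",
         call. = FALSE)
  water_idx <- which(g$values > 0)
  k <- min(n_background, length(water_idx))
  set.seed(seed)
  bg <- sample(water_idx, k)
  nr <- nrow(g$values)
  bg_rows <- ((bg - 1L) %% nr) + 1L
  bg_cols <- ((bg - 1L) %/% nr) + 1L
  list(
    rows = c(cells$row, bg_rows), cols = c(cells$col, bg_cols),
    y = c(rep(1L, nrow(cells)), rep(0L, k))
  )
}

# ---- AUC --------------------------------------------------------------------

#' Rank-based ROC area (Mann-Whitney with midranks)
#'
#' AUC computed from the rank statistic: the probability that a randomly
#' chosen presence scores higher than a randomly chosen background point,
#' with ties handled by midranks. Invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores_pos scores of the positive (presence) class.
#' @param scores_neg scores of the negative (background) class.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty",
                               call. = FALSE)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- variable selection -----------------------------------------------------

#' Backward collinearity pruning with importance tie-breaking
#'
#' Iteratively finds the variable pair with the largest pairwise |Pearson r|
#' at or above the threshold among the training cells (presences plus
#' background), drops the member that is less important to the model, and
#' repeats until all pairwise correlations are below the threshold.
#' Importance is permutation importance: the drop in training AUC when the
#' variable's columns (linear and quadratic) are permuted under a seeded
#' permutation, with the model refitted on the currently retained set each
#' iteration.
#'
#' @param climate baseline \code{climate_stack}.
#' @param presences data.frame with \code{lon}, \code{lat}.
#' @param water 0/1 water-mask \code{raster_grid}; background cells are
#'   sampled uniformly from it.
#' @param threshold correlation threshold (default 0.70).
#' @param n_background number of background cells (capped at the number of
#'   water cells).
#' @param quadratic include squared features in the importance model.
#' @param seed RNG seed for background sampling and permutations.
#' @return character vector of retained variable names in original order;
#'   a fully collinear input collapses to a single variable.
#' @export
select_variables <- function(climate, presences, water, threshold = 0.70,
                             n_background = 10000, quadratic = TRUE,
                             seed = 1L) {
  stopifnot(inherits(climate, "climate_stack"))
  if (length(names(climate)) < 2)
    stop("need at least two variables to select among", call. = FALSE)
  if (nrow(presences) == 0) stop("presences are empty", call. = FALSE)
  tc <- training_cells(climate, presences, water, n_background, seed)
  V <- stack_values(climate, tc$rows, tc$cols)
  y <- tc$y
  retained <- colnames(V)
  iter <- 0L
  repeat {
    if (length(retained) == 1L) break
    C <- stats::cor(V[, retained, drop = FALSE])
    diag(C) <- 0
    mx <- max(abs(C))
    if (mx < threshold) break
    hit <- which(abs(C) == mx, arr.ind = TRUE)[1, ]
    pair <- retained[c(hit[["row"]], hit[["col"]])]
    iter <- iter + 1L
    imp <- permutation_importance(V[, retained, drop = FALSE], y, pair,
                                  quadratic = quadratic,
                                  seed = seed + iter)
    drop_var <- pair[which.min(imp)]
    retained <- setdiff(retained, drop_var)
  }
  intersect(colnames(V), retained)
}

# Training-AUC drop when each of `vars` is permuted. A fast fixed-lambda fit
# is used: selection needs a ranking, not a tuned model.
permutation_importance <- function(V, y, vars, quadratic = TRUE,
                                   lambda = 1e-3, seed = 1L) {
  Xf <- expand_features(V, quadratic)
  st <- standardize(Xf)
  fit <- fit_pb_glmnet(st$X, y, lambda = lambda)
  base_auc <- auc_rank(pb_linear_predictor(fit$coef, st$X)[y == 1],
                       pb_linear_predictor(fit$coef, st$X)[y == 0])
  set.seed(seed)
  perm <- sample(length(y))
  vapply(vars, function(v) {
    Vp <- V
    Vp[, v] <- Vp[, v][perm]
    Xp <- standardize(expand_features(Vp, quadratic), st$center, st$scale)$X
    eta <- pb_linear_predictor(fit$coef, Xp)
    base_auc - auc_rank(eta[y == 1], eta[y == 0])
  }, numeric(1))
}

# ---- model fit --------------------------------------------------------------

#' Fit a presence-background habitat-suitability model
#'
#' A maximum-entropy-equivalent penalized logistic model: presences against
#' background cells sampled uniformly from water, on standardized linear plus
#' quadratic climate features with an L1 penalty. The binary-habitat
#' threshold theta is chosen to maximize sensitivity + specificity (TSS) on
#' the training data.
#'
#' @param climate baseline \code{climate_stack}.
#' @param presences data.frame with \code{lon}, \code{lat}; at least 10
#'   records, all on water cells.
#' @param water 0/1 water-mask \code{raster_grid}.
#' @param variables variables to use; default all layers of \code{climate}
#'   (typically the output of \code{\link{select_variables}}).
#' @param n_background background sample size (default 10000, capped at the
#'   number of water cells; sampled uniformly without replacement).
#' @param regularization multiplier on the cross-validated L1 penalty
#'   (1 = the CV-deviance optimum; larger = smoother model).
#' @param quadratic include squared features.
#' @param lambda fixed penalty, bypassing the internal cross-validation
#'   (mainly for speed in repeated refits).
#' @param seed RNG seed (background sampling, CV folds).
#' @return an object of class \code{sdm_model}.
#' @export
fit_sdm <- function(climate, presences, water, variables = NULL,
                    n_background = 10000, regularization = 1,
                    quadratic = TRUE, lambda = NULL, seed = 1L) {
  stopifnot(inherits(climate, "climate_stack"),
            inherits(water, "raster_grid"))
  if (nrow(presences) < 10)
    stop("need at least 10 presence records to fit", call. = FALSE)
  if (is.null(variables)) variables <- names(climate)
  missing_vars <- setdiff(variables, names(climate))
  if (length(missing_vars))
    stop("variables not in stack: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  tc <- training_cells(climate, presences, water, n_background, seed)
  V <- stack_values(climate, tc$rows, tc$cols)[, variables, drop = FALSE]
  if (any(!is.finite(V)))
    stop("non-finite climate values among training cells", call. = FALSE)
  Xf <- expand_features(V, quadratic)
  st <- standardize(Xf)
  fit <- fit_pb_glmnet(st$X, tc$y, lambda = lambda,
                       regularization = regularization, seed = seed)
  p <- stats::plogis(pb_linear_predictor(fit$coef, st$X))
  theta <- tss_threshold(p[tc$y == 1], p[tc$y == 0])
  structure(
    list(variables = variables, quadratic = quadratic,
         coef = fit$coef, lambda = fit$lambda,
         regularization = regularization,
         center = st$center, scale = st$scale, theta = theta,
         n_presences = sum(tc$y == 1), n_background = sum(tc$y == 0),
         seed = as.integer(seed)),
    class = "sdm_model"
  )
}

# Threshold maximizing sensitivity + specificity over observed scores.
tss_threshold <- function(p_pos, p_neg) {
  cand <- sort(unique(c(p_pos, p_neg)))
  tss <- vapply(cand, function(t)
    mean(p_pos >= t) + mean(p_neg < t), numeric(1))
  cand[which.max(tss)]
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf(
    "<sdm_model> %d variables (%s), %s features, lambda %.4g, theta %.3f\n",
    length(x$variables), paste(x$variables, collapse = ", "),
    if (x$quadratic) "linear+quadratic" else "linear", x$lambda, x$theta))
  cat(sprintf("  fitted on %d presences vs %d background cells\n",
              x$n_presences, x$n_background))
  invisible(x)
}

#' Construct a suitability map from explicit layers
#'
#' Bundles a continuous suitability raster with its binary habitat map
#' (suitability >= theta on water). \code{\link{predict_suitability}}
#' produces these from a fitted model; this constructor serves custom or
#' known-truth surfaces.
#'
#' @param suitability \code{raster_grid} of values in [0, 1].
#' @param water 0/1 water-mask \code{raster_grid}.
#' @param theta binary-habitat threshold.
#' @return an object of class \code{suitability_map}.
#' @export
suitability_map <- function(suitability, water, theta = 0.5) {
  stopifnot(inherits(suitability, "raster_grid"),
            inherits(water, "raster_grid"))
  v <- suitability$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability must lie in [0, 1]", call. = FALSE)
  pm <- v * (water$values > 0)
  suit <- raster_grid(pm, cell_size = water$cell_size, xll = water$xll,
                      yll = water$yll)
  hab <- raster_grid((pm >= theta & water$values > 0) * 1,
                     cell_size = water$cell_size, xll = water$xll,
                     yll = water$yll)
  structure(list(suitability = suit, habitat = hab, theta = theta),
            class = "suitability_map")
}

#' Project habitat suitability onto a climate slice
#'
#' Continuous suitability (inverse-logit of the fitted linear predictor) on
#' water cells, exactly zero elsewhere, plus the binary habitat map
#' (suitability >= theta on water).
#'
#' @param model an \code{sdm_model}.
#' @param climate a \code{climate_stack} containing all model variables.
#' @param water 0/1 water-mask \code{raster_grid}.
#' @return an object of class \code{suitability_map}: list with
#'   \code{suitability} and \code{habitat} rasters and \code{theta}.
#' @export
predict_suitability <- function(model, climate, water) {
  stopifnot(inherits(model, "sdm_model"), inherits(climate, "climate_stack"))
  missing_vars <- setdiff(model$variables, names(climate))
  if (length(missing_vars))
    stop("stack lacks model variables: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  V <- stack_values(climate)[, model$variables, drop = FALSE]
  Xs <- standardize(expand_features(V, model$quadratic),
                    model$center, model$scale)$X
  p <- stats::plogis(pb_linear_predictor(model$coef, Xs))
  d <- dim(climate)
  pm <- raster_grid(matrix(p, d[1], d[2]), cell_size = water$cell_size,
                    xll = water$xll, yll = water$yll)
  suitability_map(pm, water, model$theta)
}

# ---- evaluation -------------------------------------------------------------

#' Cross-validated model evaluation
#'
#' Stratified k-fold cross-validation: presences and background are split
#' into folds separately, the model is refitted on each training split with
#' the fitted model's settings, and the ROC area is computed over held-out
#' presences vs held-out background by the rank statistic. Somers' Dxy is
#' reported as 2 * AUC - 1.
#'
#' @param model an \code{sdm_model}.
#' @param climate baseline \code{climate_stack}.
#' @param presences data.frame with \code{lon}, \code{lat}.
#' @param water 0/1 water-mask \code{raster_grid}.
#' @param k_folds number of folds (>= 2, <= number of presences).
#' @param seed RNG seed for fold assignment.
#' @return an object of class \code{sdm_eval}: per-fold AUC, mean AUC, Dxy.
#' @export
evaluate_sdm <- function(model, climate, presences, water, k_folds = 5,
                         seed = 1L) {
  stopifnot(inherits(model, "sdm_model"))
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  tc <- training_cells(climate, presences, water, model$n_background,
                       model$seed)
  V <- stack_values(climate, tc$rows, tc$cols)[, model$variables,
                                               drop = FALSE]
  y <- tc$y
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (k_folds > n1)
    stop("cannot build ", k_folds, " folds from ", n1, " presences",
         call. = FALSE)
  set.seed(seed)
  fold <- integer(length(y))
  fold[y == 1] <- sample(rep_len(seq_len(k_folds), n1))
  fold[y == 0] <- sample(rep_len(seq_len(k_folds), n0))
  aucs <- vapply(seq_len(k_folds), function(k) {
    tr <- fold != k
    if (!any(y[!tr] == 1) || !any(y[!tr] == 0))
      stop("fold ", k, " has an empty class", call. = FALSE)
    Xf <- expand_features(V[tr, , drop = FALSE], model$quadratic)
    st <- standardize(Xf)
    fit <- fit_pb_glmnet(st$X, y[tr], lambda = model$lambda)
    Xt <- standardize(expand_features(V[!tr, , drop = FALSE],
                                      model$quadratic),
                      st$center, st$scale)$X
    eta <- pb_linear_predictor(fit$coef, Xt)
    auc_rank(eta[y[!tr] == 1], eta[y[!tr] == 0])
  }, numeric(1))
  structure(
    list(auc_folds = aucs, auc_mean = mean(aucs),
         dxy = 2 * mean(aucs) - 1, k_folds = as.integer(k_folds)),
    class = "sdm_eval"
  )
}

#' @export
print.sdm_eval <- function(x, ...) {
  cat(sprintf("<sdm_eval> %d-fold CV: mean AUC %.3f (Somers' Dxy %.3f)\n",
              x$k_folds, x$auc_mean, x$dxy))
  cat("  per-fold AUC:", paste(sprintf("%.3f", x$auc_folds),
                               collapse = ", "), "\n")
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Serialize / restore a fitted model as JSON
#'
#' @param model an \code{sdm_model}.
#' @param path file path.
#' @return \code{path} (write) or an \code{sdm_model} (read).
#' @export
write_sdm_json <- function(model, path) {
  stopifnot(inherits(model, "sdm_model"))
  obj <- unclass(model)
  # named numeric vectors must become JSON objects, not bare arrays
  for (f in c("coef", "center", "scale")) obj[[f]] <- as.list(obj[[f]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sdm_json
#' @export
read_sdm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coef <- unlist(obj$coef)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  structure(obj, class = "sdm_model")
}
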