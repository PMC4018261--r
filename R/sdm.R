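#' SDM engine configuration
#'
#' The package's suitability engine is a MaxEnt-style presence/background
#' discriminative model: an L1-penalized logistic regression
#' (fitted with \pkg{glmnet}) on standardized continuous predictors, their
#' squares (quadratic features), and one-hot encoded categorical levels.
#' Its logistic output is a per-cell suitability in \[0, 1\]. The engine is
#' deliberately pluggable: corrections and evaluation touch it only through
#' [sample_background()], [fit_sdm()] and [predict_sdm()], so a different
#' engine honoring the same contracts can be swapped in.
#'
#' @param n_background number of background (pseudo-absence) points
#'   (default 10000).
#' @param feature_set `"linear"` or `"linear+quadratic"` (default).
#' @param regularization_strength positive multiplier of the base L1
#'   penalty (lambda = 0.01 * strength; default 1).
#' @param seed RNG seed for background sampling.
#' @param background_weights optional [grid_raster()] of relative sampling
#'   weights (the bias-file mechanism).
#' @param background_mask optional \{0, 1\} [grid_raster()] restricting
#'   background sampling (the restricted-background mechanism).
#' @return an `sdm_config` list.
#' @export
sdm_config <- function(n_background = 10000,
                       feature_set = c("linear+quadratic", "linear"),
                       regularization_strength = 1.0, seed = 1,
                       background_weights = NULL, background_mask = NULL) {
  feature_set <- match.arg(feature_set)
  if (n_background < 100) stop("n_background must be >= 100", call. = FALSE)
  if (regularization_strength <= 0) {
    stop("regularization_strength must be positive", call. = FALSE)
  }
  structure(list(n_background = as.integer(n_background),
                 feature_set = feature_set,
                 regularization_strength = regularization_strength,
                 seed = as.integer(seed),
                 background_weights = background_weights,
                 background_mask = background_mask),
            class = "sdm_config")
}

#' Sample background (pseudo-absence) points
#'
#' Selects `n_background` cells with replacement from the valid study area
#' - optionally restricted to a \{0, 1\} mask and/or weighted by a
#' bias-file raster (selection probability proportional to weight) - and
#' places one point at each chosen cell's center.
#'
#' @param stack an [env_stack()].
#' @param config an [sdm_config()].
#' @return data.frame with `lon`, `lat` and one predictor column per layer.
#' @export
sample_background <- function(stack, config = sdm_config()) {
  ref <- stack_ref(stack)
  ok <- stack_valid_mask(stack)
  if (!is.null(config$background_mask)) {
    bm <- config$background_mask
    if (!raster_same_grid(ref, bm)) {
      stop("background_mask is not co-registered with the stack",
           call. = FALSE)
    }
    ok <- ok & !is.na(bm$values) & bm$values == 1
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty background domain", call. = FALSE)
  w <- NULL
  if (!is.null(config$background_weights)) {
    bw <- config$background_weights
    if (!raster_same_grid(ref, bw)) {
      stop("background_weights raster is not co-registered with the stack",
           call. = FALSE)
    }
    w <- bw$values[idx]
    if (anyNA(w) || any(w < 0)) {
      stop("background weights must be non-negative and defined on valid cells",
           call. = FALSE)
    }
    if (sum(w) <= 0) stop("background weights sum to zero over the domain",
                          call. = FALSE)
  }
  set.seed(config$seed)
  pick <- idx[sample.int(nrow(idx), config$n_background, replace = TRUE,
                         prob = w), , drop = FALSE]
  ctr <- cell_center(ref, pick[, 1], pick[, 2])
  out <- data.frame(lon = ctr$lon, lat = ctr$lat)
  flat <- cbind(pick[, 1], pick[, 2])
  for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]]$values[flat]
  out
}

# build the design matrix; `scheme` (returned on first call) freezes
# standardization constants and categorical levels for prediction
build_features <- function(env, cont_names, cat_names, feature_set,
                           scheme = NULL) {
  if (is.null(scheme)) {
    scheme <- list(
      center = vapply(cont_names, function(nm) mean(env[[nm]]), 0),
      scale = vapply(cont_names, function(nm) {
        s <- stats::sd(env[[nm]]); if (is.na(s) || s == 0) 1 else s
      }, 0),
      levels = lapply(stats::setNames(cat_names, cat_names),
                      function(nm) sort(unique(env[[nm]]))),
      feature_set = feature_set)
  }
  cols <- list()
  for (nm in cont_names) {
    z <- (env[[nm]] - scheme$center[[nm]]) / scheme$scale[[nm]]
    cols[[nm]] <- z
    if (scheme$feature_set == "linear+quadratic") cols[[paste0(nm, "^2")]] <- z^2
  }
  for (nm in cat_names) {
    for (lv in scheme$levels[[nm]]) {
      cols[[paste0(nm, "=", format(lv))]] <- as.numeric(env[[nm]] == lv)
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = x, scheme = scheme)
}

#' Fit the presence/background suitability model
#'
#' L1-penalized logistic discrimination of presences (label 1) against
#' background (label 0) at a fixed penalty
#' `lambda = 0.01 * regularization_strength`. Constant predictors are
#' dropped with a warning; a fit with all predictors constant is an error.
#'
#' @param presence_env predictor table for presences ([extract_env()]
#'   output; incomplete rows are dropped).
#' @param background_env predictor table for background points
#'   ([sample_background()] output).
#' @param stack the [env_stack()] the tables came from (supplies the
#'   continuous/categorical split).
#' @param config an [sdm_config()].
#' @return an object of class `sdm_model`.
#' @export
fit_sdm <- function(presence_env, background_env, stack,
                    config = sdm_config()) {
  layer_names <- names(stack$layers)
  if ("incomplete" %in% names(presence_env)) {
    presence_env <- presence_env[!presence_env$incomplete, , drop = FALSE]
  }
  if (nrow(presence_env) < 5L) {
    stop("need at least 5 complete presence rows", call. = FALSE)
  }
  env <- rbind(presence_env[, layer_names, drop = FALSE],
               background_env[, layer_names, drop = FALSE])
  y <- c(rep(1, nrow(presence_env)), rep(0, nrow(background_env)))

  cont <- continuous_names(stack)
  cats <- intersect(stack$categorical, layer_names)
  constant <- cont[vapply(cont, function(nm) {
    s <- stats::sd(env[[nm]]); is.na(s) || s == 0
  }, logical(1))]
  if (length(constant)) {
    warning("dropping constant predictor(s): ",
            paste(constant, collapse = ", "), call. = FALSE)
    cont <- setdiff(cont, constant)
  }
  cats <- cats[vapply(cats, function(nm) length(unique(env[[nm]])) > 1,
                      logical(1))]
  if (length(cont) + length(cats) == 0L) {
    stop("degenerate model: all predictors constant", call. = FALSE)
  }

  fb <- build_features(env, cont, cats, config$feature_set)
  x <- fb$x
  lambda <- 0.01 * config$regularization_strength
  if (ncol(x) < 2L) x <- cbind(x, `.pad` = 0)  # glmnet needs >= 2 columns
  # class-balanced weights: presences and background contribute equal total
  # weight, so the fitted surface depends on the environmental distribution
  # of the presences, not on how many there are (thinning a sample must not
  # change the effective regularization)
  w <- ifelse(y == 1, 0.5 / sum(y == 1), 0.5 / sum(y == 0)) * length(y)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        weights = w, lambda = lambda, standardize = FALSE)
  structure(list(fit = fit, scheme = fb$scheme,
                 cont = cont, cats = cats,
                 layer_names = layer_names,
                 feature_names = colnames(x),
                 lambda = lambda, config = config),
            class = "sdm_model")
}

# score a predictor table with a fitted model
sdm_score <- function(model, env) {
  fb <- build_features(env, model$cont, model$cats,
                       model$scheme$feature_set, scheme = model$scheme)
  x <- fb$x
  if (ncol(x) < length(model$feature_names)) x <- cbind(x, `.pad` = 0)
  p <- as.numeric(stats::predict(model$fit, newx = x, type = "response"))
  pmin(pmax(p, 0), 1)
}

#' Predict a suitability map
#'
#' Applies a fitted model to every valid cell of a stack; nodata cells are
#' propagated, output clamped to \[0, 1\].
#'
#' @param model an [fit_sdm()] result.
#' @param stack an [env_stack()] holding (at least) the model's training
#'   layers.
#' @param training_presences occurrence data.frame the model was trained on
#'   (carried for threshold-based binarization).
#' @return a `suitability_map`: list with `raster` ([grid_raster()] in
#'   \[0, 1\]) and `training_presences`.
#' @export
predict_sdm <- function(model, stack, training_presences = NULL) {
  missing <- setdiff(model$layer_names, names(stack$layers))
  if (length(missing)) {
    stop("stack is missing model layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref <- stack_ref(stack)
  ok <- stack_valid_mask(stack)
  idx <- which(ok, arr.ind = TRUE)
  env <- data.frame(row.names = seq_len(nrow(idx)))
  flat <- cbind(idx[, 1], idx[, 2])
  for (nm in model$layer_names) env[[nm]] <- stack$layers[[nm]]$values[flat]
  p <- sdm_score(model, env)
  m <- matrix(NA_real_, ref$nrows, ref$ncols)
  m[flat] <- p
  suitability_map(grid_raster(m, xll = ref$xll, yll = ref$yll,
                              cellsize = ref$cellsize),
                  training_presences)
}

#' Suitability maps
#'
#' A suitability map pairs a \[0, 1\] raster (the model's logistic output)
#' with the presence records the model was trained on, which later supply
#' the 10th-percentile training-presence threshold.
#'
#' @param raster a [grid_raster()] with all non-nodata values in \[0, 1\].
#' @param training_presences occurrence data.frame or `NULL`.
#' @return an object of class `suitability_map`.
#' @export
suitability_map <- function(raster, training_presences = NULL) {
  v <- raster$values[!is.na(raster$values)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(raster = raster, training_presences = training_presences),
            class = "suitability_map")
}
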