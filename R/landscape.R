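#' Synthetic landscape configuration
#'
#' Desk-scale stand-in for a continental study area: a grid of smooth
#' climate-like fields, one land-cover-like categorical layer, and an
#' accessibility surface with the "high near cities" structure that drives
#' road/city sampling bias.
#'
#' @param n_rows,n_cols grid dimensions (default 120 x 100).
#' @param cell_size cell side in degrees (default 0.25).
#' @param x_ll,y_ll lower-left corner of the extent.
#' @param n_continuous_layers number of autocorrelated continuous predictors
#'   besides the north-south gradient layer (default 4).
#' @param autocorrelation_length Gaussian smoothing scale in cells
#'   (default 10).
#' @param n_categories number of classes in the categorical layer
#'   (default 5).
#' @param n_cities number of random city cells for the accessibility layer
#'   (default 8).
#' @param city_decay_length e-folding distance of accessibility in cells
#'   (default 15).
#' @param seed RNG seed; the same seed yields a bit-identical landscape.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 120, n_cols = 100, cell_size = 0.25,
                             x_ll = -120, y_ll = 25,
                             n_continuous_layers = 4,
                             autocorrelation_length = 10,
                             n_categories = 5, n_cities = 8,
                             city_decay_length = 15, seed = 1) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_size = cell_size, x_ll = x_ll, y_ll = y_ll,
              n_continuous_layers = as.integer(n_continuous_layers),
              autocorrelation_length = autocorrelation_length,
              n_categories = as.integer(n_categories),
              n_cities = as.integer(n_cities),
              city_decay_length = city_decay_length,
              seed = as.integer(seed))
  counts <- c(cfg$n_rows, cfg$n_cols, cfg$n_continuous_layers,
              cfg$n_categories, cfg$n_cities)
  if (any(counts < 1L)) stop("all landscape counts must be >= 1",
                             call. = FALSE)
  if (cfg$autocorrelation_length >= min(cfg$n_rows, cfg$n_cols)) {
    stop("autocorrelation_length must be smaller than the grid",
         call. = FALSE)
  }
  class(cfg) <- "landscape_config"
  cfg
}

# separable Gaussian smoothing of a matrix, edge-normalized
gaussian_smooth <- function(m, scale) {
  wmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), `-`)
    w <- exp(-d^2 / (2 * scale^2))
    w / rowSums(w)
  }
  wmat(nrow(m)) %*% m %*% t(wmat(ncol(m)))
}

smoothed_field <- function(cfg) {
  z <- matrix(stats::rnorm(cfg$n_rows * cfg$n_cols), cfg$n_rows, cfg$n_cols)
  s <- gaussian_smooth(z, cfg$autocorrelation_length)
  (s - mean(s)) / stats::sd(s)
}

# equal-frequency classes via ranks (ties broken by order): quantile binning
quantile_bin <- function(v, k) {
  n <- length(v)
  as.integer(ceiling(rank(v, ties.method = "first") * k / n))
}

#' Generate the synthetic environmental stack
#'
#' Produces, on one co-registered grid: a north-south gradient layer
#' (`northing`: latitude trend plus smooth noise, standardized);
#' `n_continuous_layers` spatially autocorrelated fields (`env1`, `env2`,
#' ...; Gaussian-smoothed white noise, standardized); a categorical
#' `landcover` layer (an extra autocorrelated field quantile-binned into
#' `n_categories` equal-frequency classes, values `1..n_categories`); and a
#' continuous `accessibility` layer in \[0, 1\], the maximum over random
#' city cells of `exp(-d / city_decay_length)` with `d` the Euclidean
#' distance in cell units (1 at a city, tending to 0 far away).
#'
#' @param config a [landscape_config()].
#' @return an [env_stack()] with `landcover` flagged categorical.
#' @export
generate_landscape <- function(config = landscape_config()) {
  cfg <- config
  set.seed(cfg$seed)
  as_layer <- function(m) grid_raster(m, xll = cfg$x_ll, yll = cfg$y_ll,
                                      cellsize = cfg$cell_size)
  layers <- list()

  lat_norm <- matrix(rev(seq_len(cfg$n_rows)), cfg$n_rows, cfg$n_cols)
  lat_norm <- (lat_norm - mean(lat_norm)) / stats::sd(lat_norm)
  northing <- lat_norm + 0.5 * smoothed_field(cfg)
  layers$northing <- as_layer((northing - mean(northing)) /
                                stats::sd(northing))

  for (i in seq_len(cfg$n_continuous_layers)) {
    layers[[paste0("env", i)]] <- as_layer(smoothed_field(cfg))
  }

  lc_field <- smoothed_field(cfg)
  lc <- matrix(quantile_bin(as.vector(lc_field), cfg$n_categories),
               cfg$n_rows, cfg$n_cols)
  layers$landcover <- as_layer(lc)

  city_row <- sample.int(cfg$n_rows, cfg$n_cities, replace = TRUE)
  city_col <- sample.int(cfg$n_cols, cfg$n_cities, replace = TRUE)
  rows <- matrix(seq_len(cfg$n_rows), cfg$n_rows, cfg$n_cols)
  cols <- matrix(seq_len(cfg$n_cols), cfg$n_rows, cfg$n_cols, byrow = TRUE)
  acc <- matrix(0, cfg$n_rows, cfg$n_cols)
  for (k in seq_len(cfg$n_cities)) {
    d <- sqrt((rows - city_row[k])^2 + (cols - city_col[k])^2)
    acc <- pmax(acc, exp(-d / cfg$city_decay_length))
  }
  layers$accessibility <- as_layer(acc)

  env_stack(layers, categorical = "landcover")
}

#' Define the virtual species' true range
#'
#' The species' true occupancy is the set of cells where a categorical layer
#' equals a given class - outside the mask is a true absence.
#'
#' @param stack an [env_stack()].
#' @param layer name of a categorical layer.
#' @param category class value defining occupancy.
#' @return a list of class `true_range` with a \{0, 1\} `mask`
#'   [grid_raster()] and a `rule` description.
#' @export
define_true_range <- function(stack, layer = "landcover", category = 1) {
  if (!layer %in% names(stack$layers)) {
    stop("no layer named '", layer, "'", call. = FALSE)
  }
  if (!layer %in% stack$categorical) {
    stop("layer '", layer, "' is not categorical", call. = FALSE)
  }
  r <- stack$layers[[layer]]
  m <- ifelse(!is.na(r$values) & r$values == category, 1, 0)
  m[is.na(r$values)] <- NA
  if (sum(m, na.rm = TRUE) == 0) {
    stop(sprintf("empty range: category %s absent from layer '%s'",
                 format(category), layer), call. = FALSE)
  }
  mask <- grid_raster(m, xll = r$xll, yll = r$yll, cellsize = r$cellsize)
  structure(list(mask = mask,
                 rule = sprintf("%s == %s", layer, format(category))),
            class = "true_range")
}

#' Sample unbiased virtual-species occurrences
#'
#' Draws `n` presence records uniformly over the true range: cells with
#' mask 1 are chosen uniformly with replacement and each point is placed
#' uniformly at random within its cell.
#'
#' @param true_range a [define_true_range()] result.
#' @param n number of records (default 2000).
#' @param seed RNG seed.
#' @return an occurrence data.frame of exactly `n` records, all inside
#'   mask-1 cells.
#' @export
sample_virtual_occurrences <- function(true_range, n = 2000, seed = 1) {
  mask <- true_range$mask
  inside <- which(!is.na(mask$values) & mask$values == 1, arr.ind = TRUE)
  if (nrow(inside) == 0L) stop("true range is empty", call. = FALSE)
  set.seed(seed)
  pick <- inside[sample.int(nrow(inside), n, replace = TRUE), , drop = FALSE]
  ctr <- cell_center(mask, pick[, 1], pick[, 2])
  cs <- mask$cellsize
  lon <- ctr$lon + (stats::runif(n) - 0.5) * cs * 0.999
  lat <- ctr$lat + (stats::runif(n) - 0.5) * cs * 0.999
  occurrence_set(lon, lat)
}
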