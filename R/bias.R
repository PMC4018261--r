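#' Sampling-bias specifications
#'
#' A `bias_spec` names one of four geographic sampling-bias mechanisms and
#' one of three intensities; together with a seed it fully determines a
#' retention-probability surface and a thinned sample.
#'
#' * `two_areas` - records north of the occurrence-latitude midpoint are all
#'   kept; southern records survive with probability `p_s`.
#' * `gradient` - retention decreases linearly in latitude from 1 at the
#'   northernmost record to `p_min` at the southernmost.
#' * `center` - retention decays as a Gaussian
#'   `exp(-d^2 / (2 sigma^2))` of great-circle distance `d` to the
#'   occurrence centroid, with `sigma = s * r` and `r` the maximum
#'   centroid-to-record distance.
#' * `travel_time` - retention is `accessibility^gamma`, concentrating
#'   records near cities.
#'
#' Intensity parameters default to `p_s`/`p_min` of 0.5 / 0.2 / 0.05,
#' `s` of 0.6 / 0.4 / 0.2 and `gamma` of 1 / 2 / 4 for low / medium / high,
#' and can be recalibrated via `params`.
#'
#' @param bias_type one of `"two_areas"`, `"gradient"`, `"center"`,
#'   `"travel_time"`.
#' @param intensity one of `"low"`, `"medium"`, `"high"`.
#' @param seed RNG seed used when thinning.
#' @param params optional list overriding the intensity tables
#'   (`p_s`, `p_min`, `s`, `gamma`; each a named low/medium/high vector).
#' @return a `bias_spec` list.
#' @export
bias_spec <- function(bias_type = c("two_areas", "gradient", "center",
                                    "travel_time"),
                      intensity = c("low", "medium", "high"),
                      seed = 1, params = NULL) {
  bias_type <- match.arg(bias_type)
  intensity <- match.arg(intensity)
  defaults <- list(
    p_s    = c(low = 0.5, medium = 0.2, high = 0.05),
    p_min  = c(low = 0.5, medium = 0.2, high = 0.05),
    s      = c(low = 0.6, medium = 0.4, high = 0.2),
    gamma  = c(low = 1, medium = 2, high = 4))
  if (!is.null(params)) defaults[names(params)] <- params
  structure(list(bias_type = bias_type, intensity = intensity,
                 seed = as.integer(seed), params = defaults),
            class = "bias_spec")
}

#' Retention-probability surface for a bias specification
#'
#' @param spec a [bias_spec()].
#' @param occ the unbiased occurrence data.frame.
#' @param stack an [env_stack()]; must contain an `accessibility` layer for
#'   `travel_time` bias.
#' @param accessibility_layer name of the accessibility layer.
#' @return a [grid_raster()] of per-cell retention probabilities in
#'   \[0, 1\].
#' @export
retention_surface <- function(spec, occ, stack,
                              accessibility_layer = "accessibility") {
  if (nrow(occ) == 0L) stop("occurrence set is empty", call. = FALSE)
  ref <- stack_ref(stack)
  lats <- cell_center_lats(ref)
  lons <- cell_center_lons(ref)
  p <- spec$params
  surf <- switch(
    spec$bias_type,
    two_areas = {
      mid <- (min(occ$lat) + max(occ$lat)) / 2
      ps <- p$p_s[[spec$intensity]]
      matrix(ifelse(lats > mid, 1, ps), ref$nrows, ref$ncols)
    },
    gradient = {
      top <- max(occ$lat); bot <- min(occ$lat)
      pmin_v <- p$p_min[[spec$intensity]]
      frac <- (lats - bot) / max(top - bot, .Machine$double.eps)
      val <- pmin_v + (1 - pmin_v) * pmin(pmax(frac, 0), 1)
      matrix(val, ref$nrows, ref$ncols)
    },
    center = {
      ctr <- c(mean(occ$lon), mean(occ$lat))
      r_max <- max(haversine_km(occ$lon, occ$lat, ctr[1], ctr[2]))
      sigma <- p$s[[spec$intensity]] * max(r_max, .Machine$double.eps)
      grid <- expand.grid(lat = lats, lon = lons)  # column-major: rows vary
      d <- haversine_km(grid$lon, grid$lat, ctr[1], ctr[2])
      matrix(exp(-d^2 / (2 * sigma^2)), ref$nrows, ref$ncols)
    },
    travel_time = {
      if (!accessibility_layer %in% names(stack$layers)) {
        stop("travel_time bias needs an '", accessibility_layer,
             "' layer in the stack", call. = FALSE)
      }
      acc <- stack$layers[[accessibility_layer]]$values
      acc ^ p$gamma[[spec$intensity]]
    })
  surf <- pmin(pmax(surf, 0), 1)
  grid_raster(surf, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize)
}

#' Thin an occurrence set according to a retention surface
#'
#' Each record is kept independently with probability equal to the surface
#' value at its cell (seeded Bernoulli thinning). The retained and excluded
#' sets partition the input by id; the excluded records later serve as AUC
#' test points.
#'
#' @param occ occurrence data.frame.
#' @param surface a retention [grid_raster()] in \[0, 1\].
#' @param seed RNG seed.
#' @param min_records minimum acceptable retained count (default 20).
#' @param spec optional [bias_spec()] recorded in the output.
#' @return a `biased_sample` list with elements `retained`, `excluded`,
#'   `retention_surface`, `spec`, `seed`.
#' @export
apply_bias <- function(occ, surface, seed = 1, min_records = 20,
                       spec = NULL) {
  prob <- raster_value_at(surface, occ$lon, occ$lat)
  if (anyNA(prob)) {
    stop("retention surface has nodata at some occurrence cells",
         call. = FALSE)
  }
  set.seed(seed)
  keep <- stats::runif(nrow(occ)) < prob
  if (sum(keep) < min_records) {
    stop(sprintf(
      "insufficient sample: only %d of %d records retained (minimum %d)",
      sum(keep), nrow(occ), min_records), call. = FALSE)
  }
  structure(list(retained = occ[keep, , drop = FALSE],
                 excluded = occ[!keep, , drop = FALSE],
                 retention_surface = surface,
                 spec = spec, seed = as.integer(seed)),
            class = "biased_sample")
}

# great-circle distance in km (haversine, Earth radius 6371 km)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371)
}
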