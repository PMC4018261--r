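#' Bias-correction plans
#'
#' Each correction method reduces to a *plan*: possibly altered training
#' occurrences, an optional background weighting raster (bias file), an
#' optional background mask (restricted background), and an optional
#' post-combine rule (the split method's per-cell maximum). The plan is the
#' only thing the SDM engine sees, which keeps the methods engine-agnostic.
#'
#' @param method one of `"systematic_sampling"`, `"biasfile"`,
#'   `"restricted_background"`, `"cluster"`, `"split"`.
#' @param training_occurrences occurrence data.frame (or a list of two
#'   stratum sets for `"split"`).
#' @param background_weights,background_mask optional rasters.
#' @param combine_rule `"none"` or `"per_cell_max"`.
#' @return a `correction_plan` list.
#' @export
correction_plan <- function(method, training_occurrences,
                            background_weights = NULL,
                            background_mask = NULL,
                            combine_rule = c("none", "per_cell_max")) {
  method <- match.arg(method, c("systematic_sampling", "biasfile",
                                "restricted_background", "cluster", "split"))
  combine_rule <- match.arg(combine_rule)
  structure(list(method = method,
                 training_occurrences = training_occurrences,
                 background_weights = background_weights,
                 background_mask = background_mask,
                 combine_rule = combine_rule),
            class = "correction_plan")
}

#' Systematic sampling (spatial thinning)
#'
#' Overlays a coarse lattice anchored at the raster origin and keeps one
#' randomly chosen record per occupied lattice cell. Broad-extent datasets
#' use a 2-degree lattice by default; narrow-extent ones 0.2 degree.
#'
#' @param occ occurrence data.frame.
#' @param cell_size_deg lattice cell size in degrees (default 2).
#' @param seed RNG seed for the per-cell survivor choice.
#' @param origin `c(x, y)` lattice anchor (defaults to `c(0, 0)`; pass the
#'   raster's lower-left corner to align with a stack).
#' @return a subset of `occ` with at most one record per lattice cell.
#' @export
systematic_sample <- function(occ, cell_size_deg = 2, seed = 1,
                              origin = c(0, 0)) {
  if (cell_size_deg <= 0) stop("cell_size_deg must be positive",
                               call. = FALSE)
  cellkey <- paste(floor((occ$lon - origin[1]) / cell_size_deg),
                   floor((occ$lat - origin[2]) / cell_size_deg))
  set.seed(seed)
  shuffled <- sample.int(nrow(occ))
  keep <- shuffled[!duplicated(cellkey[shuffled])]
  occ[sort(keep), , drop = FALSE]
}

#' Gaussian kernel-density bias surface ("bias file")
#'
#' Estimates the sampling-effort surface as a Gaussian kernel density of
#' the occurrence locations evaluated at every valid cell center
#' (product kernel, Silverman's rule-of-thumb bandwidth per coordinate
#' axis), linearly rescaled to span exactly \[1, 20\]. A constant density
#' rescales to 1 everywhere.
#'
#' @param occ occurrence data.frame with >= 2 records.
#' @param stack an [env_stack()] supplying the grid and validity mask.
#' @return a [grid_raster()] with values in \[1, 20\].
#' @export
make_bias_surface <- function(occ, stack) {
  if (nrow(occ) < 2L) {
    stop("bias surface needs at least 2 records", call. = FALSE)
  }
  ref <- stack_ref(stack)
  dens <- product_kernel_density(
    px = occ$lon, py = occ$lat,
    gx = cell_center_lons(ref), gy = cell_center_lats(ref))
  ok <- stack_valid_mask(stack)
  dens[!ok] <- NA
  v <- dens[ok]
  rng <- max(v) - min(v)
  scaled <- if (rng < .Machine$double.eps) {
    ifelse(ok, 1, NA)
  } else {
    1 + 19 * (dens - min(v)) / rng
  }
  grid_raster(scaled, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize)
}

# separable Gaussian product-kernel density of points (px, py) on the
# lattice gy x gx; returns a length(gy) x length(gx) matrix (unnormalized
# in the KDE constant but proportional to the product-kernel density)
product_kernel_density <- function(px, py, gx, gy, bx = NULL, by = NULL) {
  if (is.null(bx)) bx <- silverman_bw(px)
  if (is.null(by)) by <- silverman_bw(py)
  kx <- exp(-outer(gx, px, `-`)^2 / (2 * bx^2))  # |gx| x n
  ky <- exp(-outer(gy, py, `-`)^2 / (2 * by^2))  # |gy| x n
  (ky %*% t(kx)) / (length(px) * 2 * pi * bx * by)
}

# Silverman's rule of thumb, with a floor for degenerate spreads
silverman_bw <- function(x) {
  bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) {
    spread <- diff(range(x))
    bw <- if (spread > 0) spread / 10 else 1e-3
  }
  bw
}

#' Buffered background mask (restricted background)
#'
#' Marks as available (1) every cell whose center lies within `radius_km`
#' (great-circle, haversine) of at least one occurrence; background points
#' are then drawn only from this buffer.
#'
#' @param occ occurrence data.frame.
#' @param radius_km buffer radius in kilometers (default 500; narrow-extent
#'   datasets use 100).
#' @param stack an [env_stack()].
#' @return a \{0, 1\} [grid_raster()] (nodata where the stack is nodata).
#' @export
buffer_background_mask <- function(occ, radius_km = 500, stack) {
  if (radius_km <= 0) stop("radius_km must be positive", call. = FALSE)
  ref <- stack_ref(stack)
  lons <- cell_center_lons(ref)
  lats <- cell_center_lats(ref)
  inside <- matrix(FALSE, ref$nrows, ref$ncols)
  # a latitude/longitude window prefilters candidate cells per record;
  # the haversine test on the survivors is exact
  deg_lat <- radius_km / 111.2 * 1.02
  for (i in seq_len(nrow(occ))) {
    band <- min(abs(occ$lat[i]) + deg_lat, 89)
    deg_lon <- deg_lat / max(cos(band * pi / 180), 0.01)
    rws <- which(abs(lats - occ$lat[i]) <= deg_lat)
    cls <- which(abs(lons - occ$lon[i]) <= deg_lon)
    if (!length(rws) || !length(cls)) next
    sub <- !inside[rws, cls, drop = FALSE]
    if (!any(sub)) next
    cand <- which(sub, arr.ind = TRUE)
    d <- haversine_km(lons[cls[cand[, 2]]], lats[rws[cand[, 1]]],
                      occ$lon[i], occ$lat[i])
    hit <- cand[d <= radius_km, , drop = FALSE]
    inside[cbind(rws[hit[, 1]], cls[hit[, 2]])] <- TRUE
  }
  m <- matrix(as.numeric(inside), ref$nrows, ref$ncols)
  m[!stack_valid_mask(stack)] <- NA
  grid_raster(m, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize)
}

#' Environmental-space cluster filtering
#'
#' Runs a PCA on the standardized continuous predictor values of the
#' occurrences (all axes retained), clusters the records by Ward-linkage
#' agglomerative clustering on Euclidean distances in that axis space,
#' cuts the dendrogram into `ceiling(n / 2)` classes, and keeps one
#' seeded-random record per class - thinning the sample evenly in
#' environmental rather than geographic space.
#'
#' @param occ occurrence data.frame with >= 4 complete-predictor records.
#' @param stack an [env_stack()].
#' @param seed RNG seed.
#' @return a subset of `occ` of exactly `ceiling(n / 2)` records.
#' @export
cluster_filter <- function(occ, stack, seed = 1) {
  env <- extract_env(stack, occ)
  complete <- !env$incomplete
  occ <- occ[complete, , drop = FALSE]
  env <- env[complete, , drop = FALSE]
  n <- nrow(occ)
  if (n < 4L) stop("cluster filtering needs at least 4 records",
                   call. = FALSE)
  k <- ceiling(n / 2)
  cont <- continuous_names(stack)
  m <- as.matrix(env[, cont, drop = FALSE])
  sds <- apply(m, 2, stats::sd)
  m <- scale(m[, sds > 0, drop = FALSE])
  set.seed(seed)
  if (ncol(m) == 0L) {
    # all records environmentally identical: fall back to uniform thinning
    warning("degenerate predictors: sampling k records uniformly",
            call. = FALSE)
    return(occ[sort(sample.int(n, k)), , drop = FALSE])
  }
  scores <- tryCatch(stats::prcomp(m, center = FALSE, scale. = FALSE)$x,
                     error = function(e) NULL)
  if (is.null(scores)) {
    warning("PCA degenerate: clustering on raw standardized predictors",
            call. = FALSE)
    scores <- m
  }
  cl <- stats::cutree(stats::hclust(stats::dist(scores), method = "ward.D2"),
                      k = k)
  keep <- vapply(split(seq_len(n), cl), function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1)]
  }, integer(1))
  occ[sort(keep), , drop = FALSE]
}

#' Split-and-combine composite model
#'
#' Splits the records at the median occurrence latitude into a northern and
#' a southern stratum, fits one model per stratum over the full study area,
#' and composes the final suitability map by taking the per-cell maximum of
#' the two stratum predictions. The composite map's training presences are
#' the union of the strata.
#'
#' @param occ occurrence data.frame.
#' @param stack an [env_stack()] used for modeling.
#' @param config an [sdm_config()].
#' @param engine optional engine override (see [sdm_engine()]).
#' @return a `suitability_map` with a `strata` attribute holding the two
#'   stratum maps.
#' @export
split_and_combine <- function(occ, stack, config = sdm_config(),
                              engine = sdm_engine()) {
  med <- stats::median(occ$lat)
  north <- occ[occ$lat > med, , drop = FALSE]
  south <- occ[occ$lat <= med, , drop = FALSE]
  if (nrow(north) < 5L || nrow(south) < 5L) {
    stop(sprintf(
      "stratum underflow: north %d / south %d records (need >= 5 each)",
      nrow(north), nrow(south)), call. = FALSE)
  }
  fit_one <- function(sub) {
    bg <- engine$sample_background(stack, config)
    model <- engine$fit_sdm(extract_env(stack, sub), bg, stack, config)
    engine$predict_sdm(model, stack, training_presences = sub)
  }
  map_n <- fit_one(north)
  map_s <- fit_one(south)
  comp <- pmax(map_n$raster$values, map_s$raster$values)
  ref <- stack_ref(stack)
  out <- suitability_map(
    grid_raster(comp, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize),
    training_presences = occ)
  attr(out, "strata") <- list(north = map_n, south = map_s)
  out
}

#' The pluggable suitability-model engine
#'
#' Bundles the three operations the rest of the package uses to talk to an
#' SDM implementation. The default engine is the package's penalized
#' logistic model; supplying a list with the same three functions swaps in
#' another engine without touching corrections or evaluation.
#'
#' @param sample_background,fit_sdm,predict_sdm engine operations.
#' @return a list of class `sdm_engine`.
#' @export
sdm_engine <- function(sample_background = sdmbias::sample_background,
                       fit_sdm = sdmbias::fit_sdm,
                       predict_sdm = sdmbias::predict_sdm) {
  structure(list(sample_background = sample_background,
                 fit_sdm = fit_sdm, predict_sdm = predict_sdm),
            class = "sdm_engine")
}

#' Build the correction plan for a biased sample
#'
#' Maps a method name to its [correction_plan()]: `systematic_sampling`
#' thins on a coarse lattice; `biasfile` weights background sampling with a
#' kernel-density effort surface; `restricted_background` masks background
#' to a buffer around the records; `cluster` thins in environmental space;
#' `split` fits per-stratum models combined by per-cell max.
#'
#' @param method correction method name.
#' @param occ the biased (retained) occurrence data.frame.
#' @param stack the modeling [env_stack()].
#' @param seed RNG seed for the stochastic methods.
#' @param thin_cell_deg lattice size for systematic sampling (default 2).
#' @param buffer_km buffer radius for restricted background (default 500).
#' @return a [correction_plan()].
#' @export
build_correction <- function(method, occ, stack, seed = 1,
                             thin_cell_deg = 2, buffer_km = 500) {
  ref <- stack_ref(stack)
  switch(
    match.arg(method, c("systematic_sampling", "biasfile",
                        "restricted_background", "cluster", "split")),
    systematic_sampling = correction_plan(
      "systematic_sampling",
      systematic_sample(occ, thin_cell_deg, seed = seed,
                        origin = c(ref$xll, ref$yll))),
    biasfile = correction_plan(
      "biasfile", occ, background_weights = make_bias_surface(occ, stack)),
    restricted_background = correction_plan(
      "restricted_background", occ,
      background_mask = buffer_background_mask(occ, buffer_km, stack)),
    cluster = correction_plan(
      "cluster", cluster_filter(occ, stack, seed = seed)),
    split = correction_plan("split", occ, combine_rule = "per_cell_max"))
}
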