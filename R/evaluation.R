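#' AUC of a suitability map against test points
#'
#' Mann-Whitney form of the area under the ROC curve: the probability that
#' a random test presence scores higher than a random (pseudo-)absence,
#' with ties counted one half:
#' `(#\{p > a\} + 0.5 #\{p = a\}) / (n_p * n_a)`.
#' Points on nodata cells are dropped with a message.
#'
#' @param map a `suitability_map`.
#' @param test_presences occurrence data.frame of test presences (typically
#'   the records excluded when the bias was applied).
#' @param eval_absences occurrence data.frame of evaluation absences
#'   (true absences outside the range, or background points).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(map, test_presences, eval_absences) {
  p <- raster_value_at(map$raster, test_presences$lon, test_presences$lat)
  a <- raster_value_at(map$raster, eval_absences$lon, eval_absences$lat)
  n_drop <- sum(is.na(p)) + sum(is.na(a))
  if (n_drop > 0) message(n_drop, " evaluation point(s) on nodata dropped")
  p <- p[!is.na(p)]; a <- a[!is.na(a)]
  auc_scores(p, a)
}

# Mann-Whitney AUC from score vectors (midrank formula)
auc_scores <- function(p, a) {
  np <- length(p); na_ <- length(a)
  if (np == 0L || na_ == 0L) {
    stop("undefined metric: empty presence or absence set", call. = FALSE)
  }
  r <- rank(c(p, a))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na_)
}

#' Cross-validated AUC of the unbiased model
#'
#' The unbiased model has no held-out test points, so its reference AUC is
#' the mean over `k` seeded random folds: each fold's records are held out,
#' the model is refitted on the rest, and the fold is scored against the
#' standard evaluation absences.
#'
#' @param occ unbiased occurrence data.frame.
#' @param stack modeling [env_stack()].
#' @param config an [sdm_config()].
#' @param eval_absences occurrence data.frame of evaluation absences.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param engine engine triple (see [sdm_engine()]).
#' @return mean AUC over the `k` folds.
#' @export
auc_unbiased_cv <- function(occ, stack, config, eval_absences, k = 5,
                            seed = 1, engine = sdm_engine()) {
  n <- nrow(occ)
  if (n < 5L * k) stop("fold underflow: need at least ", 5L * k, " records",
                       call. = FALSE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  aucs <- vapply(seq_len(k), function(f) {
    train <- occ[fold != f, , drop = FALSE]
    test <- occ[fold == f, , drop = FALSE]
    bg <- engine$sample_background(stack, config)
    model <- engine$fit_sdm(extract_env(stack, train), bg, stack, config)
    map <- engine$predict_sdm(model, stack, training_presences = train)
    auc(map, test, eval_absences)
  }, numeric(1))
  mean(aucs)
}

#' Schoener's D overlap between two suitability maps (geographic space)
#'
#' Each map is normalized to sum to one over the cells valid in both, and
#' `D = 1 - 0.5 * sum |p_a - p_b|`: 1 for identical maps, 0 for disjoint
#' support. Symmetric.
#'
#' @param map_a,map_b co-registered `suitability_map`s (or bare
#'   [grid_raster()]s).
#' @return D in \[0, 1\].
#' @export
schoener_d_geo <- function(map_a, map_b) {
  ra <- if (inherits(map_a, "suitability_map")) map_a$raster else map_a
  rb <- if (inherits(map_b, "suitability_map")) map_b$raster else map_b
  if (!raster_same_grid(ra, rb)) {
    stop("maps are not co-registered", call. = FALSE)
  }
  ok <- !is.na(ra$values) & !is.na(rb$values)
  va <- ra$values[ok]; vb <- rb$values[ok]
  if (sum(va) <= 0 || sum(vb) <= 0) {
    stop("undefined metric: a map sums to zero over shared cells",
         call. = FALSE)
  }
  1 - 0.5 * sum(abs(va / sum(va) - vb / sum(vb)))
}

#' Sample points from a suitability map
#'
#' Draws `n` cell centers with selection probability proportional to
#' suitability - turning a model's output into a point cloud whose density
#' mirrors its predicted distribution (used by the environmental-space
#' overlap).
#'
#' @param map a `suitability_map`.
#' @param n number of points (default 500).
#' @param seed RNG seed.
#' @return an occurrence data.frame of `n` cell-center points.
#' @export
sample_points_from_map <- function(map, n = 500, seed = 1) {
  r <- map$raster
  idx <- which(!is.na(r$values) & r$values > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("empty domain: map has no positive suitability", call. = FALSE)
  }
  w <- r$values[idx]
  set.seed(seed)
  pick <- idx[sample.int(nrow(idx), n, replace = TRUE, prob = w), ,
              drop = FALSE]
  ctr <- cell_center(r, pick[, 1], pick[, 2])
  occurrence_set(ctr$lon, ctr$lat)
}

#' PCA of the study-area environment
#'
#' Fits a principal component analysis on the standardized continuous
#' predictors of all valid cells; reused by [pca_env_overlap()] so the
#' (fixed) environmental space need only be computed once per stack.
#'
#' @param stack an [env_stack()].
#' @return a list with the standardization constants, rotation, and the
#'   cell scores on the first two axes.
#' @export
stack_pca <- function(stack) {
  cont <- continuous_names(stack)
  ok <- stack_valid_mask(stack)
  m <- vapply(cont, function(nm) stack$layers[[nm]]$values[ok],
              numeric(sum(ok)))
  center <- colMeans(m)
  scale_ <- apply(m, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  z <- sweep(sweep(m, 2, center), 2, scale_, `/`)
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  n_axes <- min(2L, ncol(pca$rotation))
  informative <- sum(pca$sdev > 1e-8)
  if (informative < 2L) {
    warning("degenerate PCA: only one informative axis", call. = FALSE)
    n_axes <- 1L
  }
  list(cont = cont, center = center, scale = scale_,
       rotation = pca$rotation[, seq_len(n_axes), drop = FALSE],
       cell_scores = pca$x[, seq_len(n_axes), drop = FALSE])
}

project_on_pca <- function(pca, stack, occ) {
  env <- extract_env(stack, occ)
  env <- env[!env$incomplete, , drop = FALSE]
  m <- as.matrix(env[, pca$cont, drop = FALSE])
  z <- sweep(sweep(m, 2, pca$center), 2, pca$scale, `/`)
  z %*% pca$rotation
}

#' Schoener's D overlap in environmental space (PCA-env)
#'
#' Projects two point sets onto the first two principal components of the
#' study area's environments, kernel-smooths each set's density (Gaussian
#' product kernel, Silverman bandwidths) on a `grid_bins` x `grid_bins`
#' lattice spanning the cell-score range, normalizes both densities to sum
#' one, and returns `D = 1 - 0.5 * sum |z_a - z_b|`.
#'
#' @param points_a,points_b occurrence data.frames (>= 5 complete records
#'   each).
#' @param stack an [env_stack()].
#' @param grid_bins lattice resolution per axis (default 100).
#' @param pca optional precomputed [stack_pca()].
#' @return D in \[0, 1\].
#' @export
pca_env_overlap <- function(points_a, points_b, stack, grid_bins = 100,
                            pca = NULL) {
  if (is.null(pca)) pca <- stack_pca(stack)
  sa <- project_on_pca(pca, stack, points_a)
  sb <- project_on_pca(pca, stack, points_b)
  if (nrow(sa) < 5L || nrow(sb) < 5L) {
    stop("need at least 5 complete-predictor points per set", call. = FALSE)
  }
  n_axes <- ncol(pca$rotation)
  gx <- seq(min(pca$cell_scores[, 1]), max(pca$cell_scores[, 1]),
            length.out = grid_bins)
  if (n_axes == 2L) {
    gy <- seq(min(pca$cell_scores[, 2]), max(pca$cell_scores[, 2]),
              length.out = grid_bins)
    da <- product_kernel_density(sa[, 1], sa[, 2], gx, gy)
    db <- product_kernel_density(sb[, 1], sb[, 2], gx, gy)
  } else {
    bwa <- silverman_bw(sa[, 1]); bwb <- silverman_bw(sb[, 1])
    da <- rowSums(exp(-outer(gx, sa[, 1], `-`)^2 / (2 * bwa^2)))
    db <- rowSums(exp(-outer(gx, sb[, 1], `-`)^2 / (2 * bwb^2)))
  }
  da <- da / sum(da)
  db <- db / sum(db)
  1 - 0.5 * sum(abs(da - db))
}

#' Binarize a suitability map at the 10th-percentile training-presence
#' threshold
#'
#' Let `v` be the sorted training-presence suitabilities and
#' `k = floor(percentile / 100 * n)`; the threshold is the `(k + 1)`-th
#' smallest value and a cell is suitable (1) iff its suitability is >= the
#' threshold, so at most `percentile` percent of training presences fall
#' below it.
#'
#' @param map a `suitability_map` with non-empty `training_presences`.
#' @param percentile training-presence percentile (default 10).
#' @return a \{0, 1\} [grid_raster()].
#' @export
binarize <- function(map, percentile = 10) {
  occ <- map$training_presences
  if (is.null(occ) || nrow(occ) == 0L) {
    stop("missing threshold: map has no training presences", call. = FALSE)
  }
  v <- raster_value_at(map$raster, occ$lon, occ$lat)
  v <- sort(v[!is.na(v)])
  if (!length(v)) stop("missing threshold: no valid training suitabilities",
                       call. = FALSE)
  k <- floor(percentile / 100 * length(v))
  t <- v[min(k + 1L, length(v))]
  r <- map$raster
  out <- ifelse(is.na(r$values), NA, as.numeric(r$values >= t))
  grid_raster(out, xll = r$xll, yll = r$yll, cellsize = r$cellsize)
}

#' Jaccard overlap between binary suitability maps
#'
#' `|A intersect B| / |A union B|` over cells valid in both maps; the
#' geographic agreement of two suitable-area delineations.
#'
#' @param bin_a,bin_b co-registered \{0, 1\} [grid_raster()]s.
#' @return overlap in \[0, 1\]; error if both maps have no suitable cell.
#' @export
binary_overlap <- function(bin_a, bin_b) {
  if (!raster_same_grid(bin_a, bin_b)) {
    stop("maps are not co-registered", call. = FALSE)
  }
  ok <- !is.na(bin_a$values) & !is.na(bin_b$values)
  a <- bin_a$values[ok] == 1
  b <- bin_b$values[ok] == 1
  uni <- sum(a | b)
  if (uni == 0L) {
    stop("undefined metric: both binary maps are empty", call. = FALSE)
  }
  sum(a & b) / uni
}

#' Delta correction-performance index
#'
#' `Delta = (m_corrected - m_biased) / (m_unbiased - m_biased)`: the
#' improvement of the corrected model over the biased one, standardized by
#' the unbiased-to-biased gap. Ranges over (-Inf, 1]; 1 is perfect
#' correction (corrected metric equals the unbiased reference), 0 is no
#' change, negative means the correction made the model worse. Returns
#' `NA` (undefined, not an error) when the unbiased and biased metrics
#' coincide within `tol` - there is then no gap to close.
#'
#' @param m_unbiased,m_biased,m_corrected metric values on a common scale
#'   (for the overlap metrics `m_unbiased` is 1 by definition: the unbiased
#'   model against itself).
#' @param tol coincidence tolerance (default 1e-9).
#' @return the Delta index, or `NA` when undefined.
#' @export
delta_index <- function(m_unbiased, m_biased, m_corrected, tol = 1e-9) {
  denom <- m_unbiased - m_biased
  ifelse(abs(denom) < tol, NA_real_, (m_corrected - m_biased) / denom)
}
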