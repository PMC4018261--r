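suit_map <- function(m, occ = NULL, cellsize = 1) {
  suitability_map(grid_raster(m, cellsize = cellsize),
                  training_presences = occ)
}

test_that("AUC reproduces the enumerated toy cases", {
  expect_equal(sdmbias:::auc_scores(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(sdmbias:::auc_scores(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  # 4 pairs: 0.9>0.5, 0.9>0.1, 0.4<0.5, 0.4>0.1 -> 3/4
  expect_equal(sdmbias:::auc_scores(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_error(sdmbias:::auc_scores(numeric(0), 1), "undefined")
})

test_that("Mann-Whitney AUC equals the trapezoidal ROC oracle", {
  set.seed(77)
  for (i in 1:200) {
    np <- sample(1:100, 1); na_ <- sample(1:100, 1)
    # mix of continuous and tied discrete scores
    if (runif(1) < 0.5) {
      p <- runif(np); a <- runif(na_)
    } else {
      p <- sample(seq(0, 1, 0.1), np, replace = TRUE)
      a <- sample(seq(0, 1, 0.1), na_, replace = TRUE)
    }
    expect_equal(sdmbias:::auc_scores(p, a), roc_auc_oracle(p, a),
                 tolerance = 1e-12)
  }
})

test_that("AUC of a map drops points on nodata and scores the rest", {
  m <- matrix(c(0.9, 0.8, NA, 0.1), 2, 2)
  map <- suit_map(m)
  pres <- occurrence_set(c(0.5, 0.5), c(1.5, 0.5))  # scores 0.9, 0.8
  abs_ <- occurrence_set(c(1.5, 1.5), c(1.5, 0.5))  # scores NA, 0.1
  expect_message(val <- auc(map, pres, abs_), "dropped")
  expect_equal(val, 1.0)
})

test_that("Schoener's D in geographic space matches hand-computed overlaps", {
  a <- suit_map(matrix(c(0.2, 0.6, 0.1, 0.1), 2, 2))
  expect_equal(schoener_d_geo(a, a), 1.0)
  # disjoint support
  b <- suit_map(matrix(c(0.5, 0, 0, 0), 2, 2))
  c_ <- suit_map(matrix(c(0, 0, 0, 0.7), 2, 2))
  expect_equal(schoener_d_geo(b, c_), 0.0)
  # 2-cell maps normalizing to (0.5, 0.5) vs (0.8, 0.2): D = 0.7
  d <- suit_map(matrix(c(0.4, 0.4), 1, 2))
  e <- suit_map(matrix(c(0.8, 0.2), 1, 2))
  expect_equal(schoener_d_geo(d, e), 0.7)
  expect_equal(schoener_d_geo(e, d), schoener_d_geo(d, e))  # symmetry
  zero <- suit_map(matrix(0, 2, 2))
  expect_error(schoener_d_geo(a, zero), "undefined")
})

test_that("map point sampling follows the suitability weights", {
  m <- matrix(0, 3, 3); m[2, 2] <- 0.4
  pts <- sample_points_from_map(suit_map(m), n = 50, seed = 1)
  expect_equal(nrow(pts), 50)
  expect_true(all(pts$lon == 1.5 & pts$lat == 1.5))

  m2 <- matrix(0, 1, 2); m2[1, 1] <- 0.9; m2[1, 2] <- 0.1
  pts2 <- sample_points_from_map(suit_map(m2), n = 5000, seed = 2)
  ratio <- sum(pts2$lon == 0.5) / sum(pts2$lon == 1.5)
  expect_lt(abs(ratio - 9), 1)
  expect_error(sample_points_from_map(suit_map(matrix(0, 2, 2))), "empty")
})

test_that("environmental-space overlap is 1 on itself and near 0 when separated", {
  vs <- small_system()
  stk <- vs$modeling_stack
  pca <- stack_pca(stk)
  # same set against itself
  occ_a <- vs$occ[1:100, ]
  expect_equal(pca_env_overlap(occ_a, occ_a, stk, pca = pca), 1.0)

  # opposite extremes of the strongest gradient, far beyond the bandwidth
  s <- pca$cell_scores[, 1]
  ref <- sdmbias:::stack_ref(stk)
  ok <- which(sdmbias:::stack_valid_mask(stk), arr.ind = TRUE)
  lo <- ok[order(s)[1:30], , drop = FALSE]
  hi <- ok[order(-s)[1:30], , drop = FALSE]
  ctr_lo <- cell_center(ref, lo[, 1], lo[, 2])
  ctr_hi <- cell_center(ref, hi[, 1], hi[, 2])
  d <- pca_env_overlap(occurrence_set(ctr_lo$lon, ctr_lo$lat),
                       occurrence_set(ctr_hi$lon, ctr_hi$lat),
                       stk, pca = pca)
  expect_lt(d, 0.05)
  # symmetry
  d2 <- pca_env_overlap(occurrence_set(ctr_hi$lon, ctr_hi$lat),
                        occurrence_set(ctr_lo$lon, ctr_lo$lat),
                        stk, pca = pca)
  expect_equal(d, d2)
})

test_that("the grid kernel density matches the MASS::kde2d oracle", {
  set.seed(12)
  px <- rnorm(40); py <- rnorm(40, sd = 2)
  gx <- seq(-3, 3, length.out = 25)
  gy <- seq(-6, 6, length.out = 30)
  bx <- 0.5; by <- 0.8
  mine <- sdmbias:::product_kernel_density(px, py, gx, gy, bx, by)
  # kde2d divides its h by 4 internally; transpose: kde2d's z is [x, y]
  oracle <- MASS::kde2d(px, py, h = c(4 * bx, 4 * by), n = c(25, 30),
                        lims = c(-3, 3, -6, 6))
  expect_equal(mine, t(oracle$z), tolerance = 1e-10)
})

test_that("binarization uses the 10th-percentile training-presence threshold", {
  # training suitabilities 0.1 ... 1.0 across ten 1-cell columns
  m <- matrix(seq(0.1, 1.0, 0.1), 1, 10)
  occ <- occurrence_set(seq(0.5, 9.5, 1), rep(0.5, 10))
  map <- suit_map(m, occ)
  bin <- binarize(map, 10)
  v <- as.vector(bin$values)
  expect_equal(v, c(0, rep(1, 9)))  # threshold 0.2: only 0.1 unsuitable
  expect_equal(sum(seq(0.1, 1, 0.1) < 0.2), 1)  # exactly 10% below

  # all-equal training values: every cell >= v suitable
  m2 <- matrix(c(0.3, 0.3, 0.2, 0.4), 1, 4)
  occ2 <- occurrence_set(c(0.5, 1.5), c(0.5, 0.5))
  bin2 <- binarize(suit_map(m2, occ2), 10)
  expect_equal(as.vector(bin2$values), c(1, 1, 0, 1))

  # percentile 0: threshold is the minimum training suitability
  bin0 <- binarize(map, 0)
  expect_equal(as.vector(bin0$values), rep(1, 10))
  expect_error(binarize(suit_map(m, NULL)), "missing threshold")
})

test_that("binary overlap is the Jaccard index over suitable cells", {
  a <- grid_raster(matrix(c(1, 1, 0, 0), 1, 4), cellsize = 1)
  b <- grid_raster(matrix(c(1, 1, 1, 1), 1, 4), cellsize = 1)
  c_ <- grid_raster(matrix(c(0, 0, 1, 1), 1, 4), cellsize = 1)
  expect_equal(binary_overlap(a, a), 1.0)
  expect_equal(binary_overlap(a, c_), 0.0)
  expect_equal(binary_overlap(a, b), 0.5)  # 2 shared of 4 in the union
  expect_equal(binary_overlap(b, a), binary_overlap(a, b))
  z <- grid_raster(matrix(0, 1, 4), cellsize = 1)
  expect_error(binary_overlap(z, z), "undefined")
})

test_that("the Delta index standardizes improvement as specified", {
  expect_equal(delta_index(0.9, 0.6, 0.9), 1.0)   # perfect correction
  expect_equal(delta_index(0.9, 0.6, 0.6), 0.0)   # no change
  expect_equal(delta_index(0.9, 0.6, 0.45), -0.5) # made it worse
  expect_true(is.na(delta_index(0.8, 0.8, 0.9)))  # undefined: no gap
  # whenever the corrected metric cannot exceed the unbiased reference
  # (true for the overlap metrics, whose reference is 1) Delta <= 1,
  # with equality exactly at perfect correction
  set.seed(10)
  for (i in 1:50) {
    mb <- runif(1, 0, 0.99)
    mc <- runif(1, 0, 1)
    d <- delta_index(1, mb, mc)
    expect_lte(d, 1)
    expect_equal(d == 1, mc == 1)
  }
})
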