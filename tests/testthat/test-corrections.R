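test_that("systematic sampling keeps one record per lattice cell", {
  # 5 records in one 2-degree cell, 1 in another
  occ <- occurrence_set(c(0.1, 0.3, 0.5, 0.7, 0.9, 3.5),
                        c(0.1, 0.3, 0.5, 0.7, 0.9, 3.5))
  thin <- systematic_sample(occ, 2, seed = 1)
  expect_equal(nrow(thin), 2)
  expect_true(all(thin$id %in% occ$id))

  # all records in distinct cells: identity
  occ2 <- occurrence_set(c(1, 3, 5, 7), c(1, 3, 5, 7))
  expect_identical(systematic_sample(occ2, 2, seed = 1), occ2)

  # idempotence: re-thinning a thinned set changes nothing
  set.seed(2)
  occ3 <- occurrence_set(runif(200, 0, 20), runif(200, 0, 20))
  t1 <- systematic_sample(occ3, 2, seed = 5)
  expect_identical(systematic_sample(t1, 2, seed = 5), t1)
  expect_error(systematic_sample(occ3, -1), "positive")
})

test_that("bias surface spans exactly [1, 20] and peaks at the record cluster", {
  vs <- small_system()
  # tight cluster in one corner plus scattered records
  set.seed(6)
  occ <- occurrence_set(c(rnorm(80, -118, 0.3), runif(20, -115, -109)),
                        c(rnorm(80, 38, 0.3), runif(20, 27, 38)))
  surf <- make_bias_surface(occ, vs$modeling_stack)
  v <- surf$values[!is.na(surf$values)]
  expect_equal(min(v), 1)
  expect_equal(max(v), 20)
  peak <- which(surf$values == 20, arr.ind = TRUE)
  pk <- cell_center(surf, peak[1, 1], peak[1, 2])
  expect_lt(abs(pk$lon - -118), 1)
  expect_lt(abs(pk$lat - 38), 1)
  expect_error(make_bias_surface(occ[1, ], vs$modeling_stack), "2 records")
})

test_that("buffered mask matches a brute-force haversine check", {
  stk <- tiny_stack()  # 12 x 10 one-degree cells at (0, 0)
  occ <- occurrence_set(c(2.3, 7.8), c(3.1, 9.4))
  radius <- 300
  mask <- buffer_background_mask(occ, radius, stk)
  ref <- stk$layers[[1]]
  for (i in seq_len(ref$nrows)) {
    for (j in seq_len(ref$ncols)) {
      ctr <- cell_center(ref, i, j)
      d <- min(geosphere::distHaversine(cbind(occ$lon, occ$lat),
                                        c(ctr$lon, ctr$lat), r = 6371))
      expect_equal(mask$values[i, j], as.numeric(d <= radius),
                   label = sprintf("cell (%d,%d)", i, j))
    }
  }
  # a cell containing a record is always inside
  expect_equal(raster_value_at(mask, occ$lon, occ$lat), c(1, 1))
  expect_error(buffer_background_mask(occ, -5, stk), "positive")
})

test_that("cluster filtering returns ceiling(n/2) spread records", {
  vs <- small_system()
  occ <- vs$occ[1:10, ]
  out <- cluster_filter(occ, vs$modeling_stack, seed = 3)
  expect_equal(nrow(out), 5)
  expect_true(all(out$id %in% occ$id))
  # odd n: ceiling
  out11 <- cluster_filter(vs$occ[1:11, ], vs$modeling_stack, seed = 3)
  expect_equal(nrow(out11), 6)
})

test_that("cluster filtering separates two well-separated predictor clouds", {
  # 2 + 2 points at opposite ends of a strong gradient, k = 2
  flat <- grid_raster(matrix(rep(seq(0, 9), each = 10), 10, 10),
                      cellsize = 1)
  noise <- grid_raster(matrix(rnorm(100, sd = 0.01), 10, 10), cellsize = 1)
  stk <- env_stack(list(grad = flat, noise = noise))
  occ <- occurrence_set(c(0.5, 0.6, 9.4, 9.5), c(5, 5.2, 5, 5.2))
  out <- cluster_filter(occ, stk, seed = 1)
  expect_equal(nrow(out), 2)
  # one survivor per cloud (clouds are ids {0,1} west and {2,3} east)
  expect_equal(sort(out$id %/% 2), c(0, 1))
})

test_that("identical-predictor records still thin to ceiling(n/2)", {
  flat1 <- grid_raster(matrix(5, 6, 6), cellsize = 1)
  flat2 <- grid_raster(matrix(2, 6, 6), cellsize = 1)
  stk <- env_stack(list(a = flat1, b = flat2))
  occ <- occurrence_set(runif(9, 0, 6), runif(9, 0, 6))
  expect_warning(out <- cluster_filter(occ, stk, seed = 2), "degenerate")
  expect_equal(nrow(out), 5)
  expect_true(all(out$id %in% occ$id))
})

test_that("split composite is the per-cell max and strata are balanced", {
  vs <- small_system()
  occ <- vs$occ[1:120, ]
  comp <- split_and_combine(occ, vs$modeling_stack,
                            sdm_config(n_background = 1000, seed = 4))
  strata <- attr(comp, "strata")
  expect_equal(comp$raster$values,
               pmax(strata$north$raster$values,
                    strata$south$raster$values))
  med <- median(occ$lat)
  n_north <- sum(occ$lat > med)
  n_south <- sum(occ$lat <= med)
  expect_lte(abs(n_north - n_south), nrow(occ) %% 2 + sum(occ$lat == med))
  expect_identical(comp$training_presences, occ)

  # stratum underflow is an error, not a silent merge
  tiny <- occ[1:8, ]
  expect_error(split_and_combine(tiny, vs$modeling_stack,
                                 sdm_config(n_background = 500)),
               "stratum")
})

test_that("correction plans populate exactly the fields their method implies", {
  vs <- small_system()
  occ <- vs$occ[1:80, ]
  stk <- vs$modeling_stack

  p1 <- build_correction("systematic_sampling", occ, stk, seed = 1)
  expect_lte(nrow(p1$training_occurrences), nrow(occ))
  expect_null(p1$background_weights); expect_null(p1$background_mask)

  p2 <- build_correction("biasfile", occ, stk)
  expect_identical(p2$training_occurrences, occ)
  expect_s3_class(p2$background_weights, "grid_raster")

  p3 <- build_correction("restricted_background", occ, stk)
  expect_identical(p3$training_occurrences, occ)
  expect_s3_class(p3$background_mask, "grid_raster")

  p4 <- build_correction("cluster", occ, stk, seed = 1)
  expect_equal(nrow(p4$training_occurrences), ceiling(nrow(occ) / 2))

  p5 <- build_correction("split", occ, stk)
  expect_equal(p5$combine_rule, "per_cell_max")
})
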