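# shared in-code fixtures: everything is generated at test time

# a tiny deterministic stack: two gradients + noise + a categorical layer,
# 12 x 10 cells of 1 degree anchored at (0, 0)
tiny_stack <- function(seed = 42, nr = 12, nc = 10) {
  set.seed(seed)
  lat_grad <- matrix(rev(seq_len(nr)), nr, nc)
  lon_grad <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  noise <- matrix(rnorm(nr * nc), nr, nc)
  cats <- matrix(rep(1:2, length.out = nr * nc), nr, nc)
  as_r <- function(m) grid_raster(m, xll = 0, yll = 0, cellsize = 1)
  env_stack(list(ns = as_r(lat_grad), ew = as_r(lon_grad),
                 noise = as_r(noise), class = as_r(cats)),
            categorical = "class")
}

# the small default study system used by the heavier tests
small_system <- function(seed = 1, n_occ = 600) {
  cfg <- landscape_config(n_rows = 60, n_cols = 50, seed = seed,
                          autocorrelation_length = 6, n_cities = 5,
                          city_decay_length = 8)
  setup_virtual_species(cfg, n_occurrences = n_occ, category = 3,
                        seed = seed)
}

# brute-force trapezoidal ROC AUC: the independent oracle for the
# Mann-Whitney implementation
roc_auc_oracle <- function(p, a) {
  thr <- sort(unique(c(p, a, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(p >= t), 0)
  fpr <- vapply(thr, function(t) mean(a >= t), 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

expect_same_raster <- function(a, b) {
  expect_equal(a$nrows, b$nrows)
  expect_equal(a$ncols, b$ncols)
  expect_equal(a$xll, b$xll)
  expect_equal(a$yll, b$yll)
  expect_equal(a$cellsize, b$cellsize)
  expect_identical(is.na(a$values), is.na(b$values))
  expect_equal(a$values, b$values)
}
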