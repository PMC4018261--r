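# a small reference fit reused by the scenario tests
local_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      vs <- small_system()
      cfg <- sdm_config(n_background = 2000, seed = 1)
      cache <<- suppressMessages(fit_reference(
        vs$occ, vs$modeling_stack, cfg, true_range = vs$true_range,
        bias_stack = vs$stack, seed = 1, n_eval_absences = 2000,
        n_env_points = 200))
    }
    cache
  }
})

test_that("the factorial design enumerates the published arithmetic", {
  d3 <- enumerate_design(c("virtual", "turtle", "salamander"),
                         replicates = 10)
  expect_equal(nrow(d3), 360)
  d1 <- enumerate_design("virtual", replicates = 2)
  expect_equal(nrow(d1), 24)
  # per species: 4 types x 3 intensities x 5 methods = 60 combinations
  n_methods <- length(sdmbias:::all_correction_methods())
  expect_equal(4 * 3 * n_methods, 60)
})

test_that("evaluation absences respect the true-range mask", {
  vs <- small_system()
  absc <- sample_eval_absences(vs$modeling_stack, n = 500, seed = 2,
                               true_range = vs$true_range)
  expect_equal(nrow(absc), 500)
  expect_true(all(raster_value_at(vs$true_range$mask,
                                  absc$lon, absc$lat) == 0))
})

test_that("a scenario yields a biased row plus one row per method", {
  ref <- local_reference()
  rows <- suppressMessages(
    run_scenario(ref, bias_spec("two_areas", "medium"),
                 scenario_seed = 11))
  expect_equal(nrow(rows), 6)
  expect_setequal(rows$method,
                  c("biased", sdmbias:::all_correction_methods()))
  expect_true(all(is.na(rows$error)))
  # metrics in range
  for (mcol in c("auc", "d_geo", "d_env", "g_over")) {
    expect_true(all(rows[[mcol]] >= 0 & rows[[mcol]] <= 1), label = mcol)
  }
  # deltas bounded above by 1 and absent for the biased baseline
  for (dcol in sdmbias:::delta_columns()) {
    expect_true(is.na(rows[[dcol]][rows$method == "biased"]))
    ok <- !is.na(rows[[dcol]])
    expect_true(all(rows[[dcol]][ok] <= 1 + 1e-9), label = dcol)
  }
  # same seeds, run twice: identical rows
  rows2 <- suppressMessages(
    run_scenario(ref, bias_spec("two_areas", "medium"),
                 scenario_seed = 11))
  expect_identical(rows, rows2)
})

test_that("the species design obeys the row-count identities", {
  ref <- local_reference()
  res <- suppressMessages(
    run_species_design(ref, replicates = 1,
                       bias_types = c("two_areas", "gradient"),
                       intensities = "high",
                       master_seed = 3, quiet = TRUE))
  # 1 unbiased + 2 scenarios x (1 biased + 5 corrected)
  expect_equal(nrow(res), 1 + 2 * 6)
  expect_equal(sum(res$method == "biased"), 2)
  expect_equal(sum(!res$method %in% c("biased", "unbiased")), 10)
  expect_equal(res$d_geo[res$method == "unbiased"], 1)
})

test_that("summaries average replicates and flag the best method per cell", {
  # hand-set fixture: 2 methods x 2 replicates in one design cell
  fx <- data.frame(
    species = "v", bias_type = "gradient", intensity = "low",
    replicate = rep(1:2, each = 2),
    method = rep(c("m1", "m2"), 2), n_train = 10,
    auc = 0.9, d_geo = 0.8, d_env = 0.8, g_over = 0.7,
    delta_auc = c(0.2, -0.1, 0.4, -0.3),
    delta_d_geo = c(0.5, 0.1, 0.7, 0.3),
    delta_d_env = c(NA, 0.2, NA, 0.4),
    delta_g_over = c(-0.2, -0.4, -0.2, -0.4),
    seed = 1, error = NA_character_, stringsAsFactors = FALSE)
  s <- summarize_results(fx)
  m1 <- s[s$method == "m1", ]; m2 <- s[s$method == "m2", ]
  expect_equal(m1$mean_delta_auc, 0.3)
  expect_equal(m2$mean_delta_auc, -0.2)
  expect_equal(m1$mean_delta_d_geo, 0.6)
  expect_true(is.na(m1$mean_delta_d_env))  # all-undefined cell
  expect_equal(m2$mean_delta_d_env, 0.3)
  expect_true(m1$corrected_delta_d_geo)
  expect_false(m2$corrected_delta_g_over)
  expect_true(m1$best_delta_d_geo)
  expect_false(m2$best_delta_d_geo)
})

test_that("single-replicate summaries equal the raw Delta values", {
  ref <- local_reference()
  res <- suppressMessages(
    run_species_design(ref, replicates = 1, bias_types = "gradient",
                       intensities = "low", master_seed = 5, quiet = TRUE))
  s <- summarize_results(res)
  raw <- res[!res$method %in% c("biased", "unbiased"), ]
  for (m in s$method) {
    expect_equal(s$mean_delta_d_geo[s$method == m],
                 raw$delta_d_geo[raw$method == m])
  }
})

test_that("method ranks conserve their sum and average over ties", {
  base <- data.frame(
    species = "v", replicate = 1, n_train = 10,
    auc = 0.9, d_geo = 0.8, d_env = 0.8, g_over = 0.7,
    delta_auc = NA_real_, delta_d_env = NA_real_,
    delta_g_over = NA_real_, seed = 1, error = NA_character_,
    stringsAsFactors = FALSE)
  cells <- expand.grid(bias_type = c("a", "b"), intensity = c("x", "y"),
                       method = paste0("m", 1:5),
                       stringsAsFactors = FALSE)
  fx <- cbind(base, cells)
  # m1 strictly best everywhere; m2 and m3 tied second in cell (a, x)
  fx$delta_d_geo <- 0.1
  fx$delta_d_geo[fx$method == "m1"] <- 0.9
  fx$delta_d_geo[fx$method %in% c("m2", "m3") &
                   fx$bias_type == "a" & fx$intensity == "x"] <- 0.5
  rk <- rank_methods(fx, indices = "delta_d_geo")
  expect_equal(rk$mean_rank[rk$method == "m1"], 1.0)
  # per-cell rank sums are 15 even with ties
  s <- summarize_results(fx)
  for (bt in c("a", "b")) {
    for (it in c("x", "y")) {
      mv <- s$mean_delta_d_geo[s$bias_type == bt & s$intensity == it]
      expect_equal(sum(rank(-mv, ties.method = "average")), 15)
    }
  }
  # the tied pair shares rank (2 + 3) / 2 = 2.5 in its cell
  m2_ranks <- rk[rk$method == "m2", ]
  expect_equal(m2_ranks$mean_rank * 4,  # 4 cells total
               2.5 + 3 * mean(rank(-c(0.9, 0.1, 0.1, 0.1, 0.1),
                                   ties.method = "average")[2]))
})

test_that("biased-model summaries report the AUC percent change", {
  fx <- data.frame(
    species = "v", bias_type = "gradient", intensity = "low",
    replicate = 1:2, method = "biased", n_train = 10,
    auc = c(0.8, 0.9), d_geo = c(0.6, 0.8), d_env = 0.7, g_over = 0.5,
    delta_auc = NA_real_, delta_d_geo = NA_real_, delta_d_env = NA_real_,
    delta_g_over = NA_real_, seed = 1, error = NA_character_,
    stringsAsFactors = FALSE)
  unb <- fx[1, ]
  unb$method <- "unbiased"; unb$auc <- 1.0
  unb[c("d_geo", "d_env", "g_over")] <- 1
  s <- summarize_biased(rbind(unb, fx))
  expect_equal(s$mean_auc, 0.85)
  expect_equal(s$sd_d_geo, sd(c(0.6, 0.8)))
  expect_equal(s$auc_pct_change, 100 * (0.85 - 1) / 1)
})
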