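#' Evaluation absences
#'
#' Samples the absence set used by the AUC: for a virtual species with a
#' known true range, `n` cell centers drawn from valid cells *outside* the
#' range mask (true absences); without a mask, `n` background cell centers
#' from the whole study area.
#'
#' @param stack an [env_stack()].
#' @param n number of absence points (default 10000).
#' @param seed RNG seed.
#' @param true_range optional [define_true_range()] result; when given,
#'   sampling is restricted to mask-0 cells.
#' @return an occurrence data.frame of `n` cell-center points.
#' @export
sample_eval_absences <- function(stack, n = 10000, seed = 1,
                                 true_range = NULL) {
  ref <- stack_ref(stack)
  ok <- stack_valid_mask(stack)
  if (!is.null(true_range)) {
    m <- true_range$mask$values
    ok <- ok & !is.na(m) & m == 0
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no cells available for evaluation absences",
                            call. = FALSE)
  set.seed(seed)
  pick <- idx[sample.int(nrow(idx), n, replace = TRUE), , drop = FALSE]
  ctr <- cell_center(ref, pick[, 1], pick[, 2])
  occurrence_set(ctr$lon, ctr$lat)
}

#' Enumerate the factorial bias design
#'
#' One row per (species x bias type x intensity x replicate): the biased
#' datasets of the full design. With 3 species and 10 replicates this is
#' the full 360-dataset factorial; each species contributes
#' `4 * 3 * length(methods) = 60` (type x intensity x method) combinations.
#'
#' @param species character vector of species ids.
#' @param replicates replicates per (type x intensity) cell (default 10).
#' @param bias_types,intensities design levels (defaults: all four types,
#'   all three intensities).
#' @return a data.frame of scenario coordinates.
#' @export
enumerate_design <- function(species = "virtual", replicates = 10,
                             bias_types = c("two_areas", "gradient",
                                            "center", "travel_time"),
                             intensities = c("low", "medium", "high")) {
  expand.grid(species = species, bias_type = bias_types,
              intensity = intensities, replicate = seq_len(replicates),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

all_correction_methods <- function() {
  c("systematic_sampling", "biasfile", "restricted_background",
    "cluster", "split")
}

# metrics of one fitted map against the unbiased reference
evaluate_model <- function(map, ref, test_presences) {
  d_env_pts <- sample_points_from_map(map, n = ref$n_env_points,
                                      seed = ref$seed_env)
  list(
    auc = auc(map, test_presences, ref$eval_absences),
    d_geo = schoener_d_geo(map, ref$unbiased_map),
    d_env = pca_env_overlap(d_env_pts, ref$unbiased_env_points, ref$stack,
                            pca = ref$pca),
    g_over = binary_overlap(binarize(map), ref$unbiased_binary))
}

#' Fit and evaluate the unbiased reference model
#'
#' Fits the model once on the full unbiased dataset and precomputes
#' everything reused across scenarios: the reference suitability map, its
#' binary version, its 500-point environmental sample, the study-area PCA,
#' the evaluation absences, and the 5-fold cross-validated reference AUC.
#'
#' @param occ unbiased occurrence data.frame.
#' @param stack modeling [env_stack()].
#' @param config an [sdm_config()].
#' @param true_range optional [define_true_range()] result (true absences).
#' @param bias_stack stack used for *bias generation* (defaults to
#'   `stack`); pass the full landscape here when the modeling stack
#'   excludes the accessibility layer.
#' @param seed RNG seed for absences / folds / map sampling.
#' @param n_eval_absences evaluation absence count (default 10000).
#' @param n_env_points points sampled from each map for the
#'   environmental-space overlap (default 500).
#' @param engine engine triple (see [sdm_engine()]).
#' @return a `reference_fit` list consumed by [run_scenario()].
#' @export
fit_reference <- function(occ, stack, config = sdm_config(),
                          true_range = NULL, bias_stack = stack, seed = 1,
                          n_eval_absences = 10000, n_env_points = 500,
                          engine = sdm_engine()) {
  eval_absences <- sample_eval_absences(stack, n_eval_absences, seed = seed,
                                        true_range = true_range)
  bg <- engine$sample_background(stack, config)
  model <- engine$fit_sdm(extract_env(stack, occ), bg, stack, config)
  unbiased_map <- engine$predict_sdm(model, stack, training_presences = occ)
  pca <- stack_pca(stack)
  ref <- list(stack = stack, bias_stack = bias_stack, config = config,
              engine = engine,
              occ = occ, eval_absences = eval_absences,
              unbiased_map = unbiased_map,
              unbiased_binary = binarize(unbiased_map),
              pca = pca, n_env_points = n_env_points,
              seed_env = seed,
              unbiased_env_points = sample_points_from_map(
                unbiased_map, n = n_env_points, seed = seed))
  ref$auc_unbiased <- auc_unbiased_cv(occ, stack, config, eval_absences,
                                      k = 5, seed = seed, engine = engine)
  class(ref) <- "reference_fit"
  ref
}

fit_plan_map <- function(plan, ref, scenario_seed) {
  cfg <- ref$config
  cfg$seed <- scenario_seed
  cfg$background_weights <- plan$background_weights
  cfg$background_mask <- plan$background_mask
  engine <- ref$engine
  if (plan$method == "split") {
    return(split_and_combine(plan$training_occurrences, ref$stack, cfg,
                             engine = engine))
  }
  occ <- plan$training_occurrences
  bg <- engine$sample_background(ref$stack, cfg)
  model <- engine$fit_sdm(extract_env(ref$stack, occ), bg, ref$stack, cfg)
  engine$predict_sdm(model, ref$stack, training_presences = occ)
}

#' Run one bias / correction scenario
#'
#' Applies one bias specification to the unbiased dataset, fits the biased
#' model, applies the requested correction methods, evaluates everything
#' against the unbiased reference, and computes the four Delta indices.
#' AUC uses the excluded records as test presences; the overlap metrics
#' compare against the unbiased reference map, for which the reference
#' value is 1 by definition.
#'
#' @param ref a [fit_reference()] result.
#' @param spec a [bias_spec()].
#' @param methods correction methods to apply (default all five).
#' @param scenario_seed seed driving the thinning, background sampling and
#'   stochastic corrections of this scenario.
#' @param thin_cell_deg,buffer_km method parameters passed to
#'   [build_correction()].
#' @return a data.frame of result rows (one `biased` row + one per method).
#' @export
run_scenario <- function(ref, spec, methods = all_correction_methods(),
                         scenario_seed = 1, thin_cell_deg = 2,
                         buffer_km = 500) {
  surface <- retention_surface(spec, ref$occ, ref$bias_stack)
  bs <- apply_bias(ref$occ, surface, seed = scenario_seed, spec = spec)
  retained <- bs$retained

  row_of <- function(method, metrics, n_train, err = NA_character_) {
    data.frame(
      bias_type = spec$bias_type, intensity = spec$intensity,
      method = method, n_train = n_train,
      auc = metrics$auc, d_geo = metrics$d_geo,
      d_env = metrics$d_env, g_over = metrics$g_over,
      delta_auc = NA_real_, delta_d_geo = NA_real_,
      delta_d_env = NA_real_, delta_g_over = NA_real_,
      seed = scenario_seed, error = err,
      stringsAsFactors = FALSE)
  }
  na_metrics <- list(auc = NA_real_, d_geo = NA_real_, d_env = NA_real_,
                     g_over = NA_real_)

  # biased baseline: retained records, default (unweighted, unmasked)
  # background
  baseline_plan <- list(method = "none", training_occurrences = retained,
                        background_weights = NULL, background_mask = NULL)
  biased_map <- fit_plan_map(baseline_plan, ref, scenario_seed)
  biased_metrics <- evaluate_model(biased_map, ref, bs$excluded)
  rows <- row_of("biased", biased_metrics, nrow(retained))

  for (method in methods) {
    res <- tryCatch({
      plan <- build_correction(method, retained, ref$stack,
                               seed = scenario_seed,
                               thin_cell_deg = thin_cell_deg,
                               buffer_km = buffer_km)
      map <- fit_plan_map(plan, ref, scenario_seed)
      m <- evaluate_model(map, ref, bs$excluded)
      r <- row_of(method, m, nrow(plan$training_occurrences))
      r$delta_auc <- delta_index(ref$auc_unbiased, biased_metrics$auc, m$auc)
      r$delta_d_geo <- delta_index(1, biased_metrics$d_geo, m$d_geo)
      r$delta_d_env <- delta_index(1, biased_metrics$d_env, m$d_env)
      r$delta_g_over <- delta_index(1, biased_metrics$g_over, m$g_over)
      r
    }, error = function(e) {
      row_of(method, na_metrics, NA_integer_, err = conditionMessage(e))
    })
    rows <- rbind(rows, res)
  }
  rows
}

#' Run the full factorial experiment for one species
#'
#' Iterates bias type x intensity x replicate, running [run_scenario()]
#' for each cell with reproducible per-scenario seeds derived from
#' `master_seed`. Scenario failures are recorded as flagged rows, not
#' aborts. Prepends one `unbiased` baseline row carrying the reference
#' metrics (overlaps 1 by definition, AUC from 5-fold cross-validation).
#'
#' @param ref a [fit_reference()] result.
#' @param species species id recorded in the rows.
#' @param replicates replicates per (type x intensity) cell.
#' @param bias_types,intensities design levels.
#' @param methods correction methods.
#' @param master_seed master seed from which scenario seeds are drawn.
#' @param thin_cell_deg,buffer_km method parameters.
#' @param quiet suppress per-scenario progress messages.
#' @return a results data.frame (`species`, scenario coordinates, method,
#'   four metrics, four Delta indices, seeds, error flags).
#' @export
run_species_design <- function(ref, species = "virtual", replicates = 10,
                               bias_types = c("two_areas", "gradient",
                                              "center", "travel_time"),
                               intensities = c("low", "medium", "high"),
                               methods = all_correction_methods(),
                               master_seed = 1, thin_cell_deg = 2,
                               buffer_km = 500, quiet = FALSE) {
  design <- enumerate_design(species, replicates, bias_types, intensities)
  set.seed(master_seed)
  design$scenario_seed <- sample.int(.Machine$integer.max - 1L, nrow(design))
  out <- vector("list", nrow(design) + 1L)
  out[[1]] <- data.frame(
    species = species, bias_type = NA_character_, intensity = NA_character_,
    replicate = NA_integer_, method = "unbiased", n_train = nrow(ref$occ),
    auc = ref$auc_unbiased, d_geo = 1, d_env = 1, g_over = 1,
    delta_auc = NA_real_, delta_d_geo = NA_real_, delta_d_env = NA_real_,
    delta_g_over = NA_real_, seed = master_seed, error = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    if (!quiet) {
      message(sprintf("[%s] %s / %s / replicate %d", species, d$bias_type,
                      d$intensity, d$replicate))
    }
    spec <- bias_spec(d$bias_type, d$intensity, seed = d$scenario_seed)
    rows <- tryCatch(
      run_scenario(ref, spec, methods, scenario_seed = d$scenario_seed,
                   thin_cell_deg = thin_cell_deg, buffer_km = buffer_km),
      error = function(e) data.frame(
        bias_type = d$bias_type, intensity = d$intensity, method = "biased",
        n_train = NA_integer_, auc = NA_real_, d_geo = NA_real_,
        d_env = NA_real_, g_over = NA_real_, delta_auc = NA_real_,
        delta_d_geo = NA_real_, delta_d_env = NA_real_,
        delta_g_over = NA_real_, seed = d$scenario_seed,
        error = conditionMessage(e), stringsAsFactors = FALSE))
    rows <- cbind(species = species, replicate = d$replicate, rows)
    out[[i + 1L]] <- rows[, names(out[[1]])]
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Set up the virtual-species study system
#'
#' Convenience wrapper: generates the synthetic landscape, defines the
#' species' true range from a land-cover class, samples the unbiased
#' occurrence set, and splits the stack into a modeling stack (without the
#' accessibility layer, which is a survey-effort surface rather than an
#' ecological predictor) and the full bias-generation stack.
#'
#' @param config a [landscape_config()].
#' @param n_occurrences unbiased record count (default 2000).
#' @param category land-cover class defining the true range (default 3).
#' @param seed RNG seed for the occurrence sample.
#' @return a list with `stack`, `modeling_stack`, `true_range`, `occ`.
#' @export
setup_virtual_species <- function(config = landscape_config(),
                                  n_occurrences = 2000, category = 3,
                                  seed = 1) {
  stack <- generate_landscape(config)
  true_range <- define_true_range(stack, "landcover", category)
  occ <- sample_virtual_occurrences(true_range, n_occurrences, seed = seed)
  modeling <- stack_subset(stack,
                           setdiff(names(stack$layers), "accessibility"))
  list(stack = stack, modeling_stack = modeling, true_range = true_range,
       occ = occ)
}

delta_columns <- function() {
  c("delta_auc", "delta_d_geo", "delta_d_env", "delta_g_over")
}

#' Aggregate replicates into the per-cell summary table
#'
#' For each (species x bias type x intensity x method) cell: the mean of
#' each Delta index across replicates, whether the cell was corrected
#' (mean Delta > 0) and whether the method is best in its cell (highest
#' mean Delta), per index. Undefined Deltas are excluded from means;
#' all-undefined cells are reported as `NA`.
#'
#' @param results a [run_species_design()] results data.frame.
#' @return a summary data.frame with `mean_<index>`, `corrected_<index>`
#'   and `best_<index>` columns.
#' @export
summarize_results <- function(results) {
  res <- results[!results$method %in% c("biased", "unbiased") &
                   is.na(results$error), , drop = FALSE]
  key <- c("species", "bias_type", "intensity", "method")
  agg <- stats::aggregate(res[, delta_columns()], by = res[key],
                          FUN = function(x) mean(x, na.rm = TRUE))
  for (dc in delta_columns()) {
    v <- agg[[dc]]
    v[is.nan(v)] <- NA
    agg[[paste0("mean_", dc)]] <- v
    agg[[dc]] <- NULL
    agg[[paste0("corrected_", dc)]] <- !is.na(v) & v > 0
  }
  cell <- interaction(agg$species, agg$bias_type, agg$intensity, drop = TRUE)
  for (dc in delta_columns()) {
    mv <- agg[[paste0("mean_", dc)]]
    best <- stats::ave(mv, cell, FUN = function(x) {
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    })
    agg[[paste0("best_", dc)]] <- !is.na(mv) & !is.na(best) & mv == best
  }
  agg[order(agg$species, agg$bias_type, agg$intensity, agg$method), ,
      drop = FALSE]
}

#' Biased-model deviation summary
#'
#' Mean and SD of each raw metric of the *biased* models per
#' (species x bias type x intensity), plus the mean percent change of AUC
#' relative to the unbiased reference.
#'
#' @param results a [run_species_design()] results data.frame.
#' @return a data.frame with one row per design cell.
#' @export
summarize_biased <- function(results) {
  unb <- results[results$method == "unbiased", , drop = FALSE]
  auc_ref <- stats::setNames(unb$auc, unb$species)
  res <- results[results$method == "biased" & is.na(results$error), ,
                 drop = FALSE]
  key <- c("species", "bias_type", "intensity")
  metrics <- c("auc", "d_geo", "d_env", "g_over")
  mean_tab <- stats::aggregate(res[, metrics], by = res[key], FUN = mean)
  sd_tab <- stats::aggregate(res[, metrics], by = res[key], FUN = stats::sd)
  names(mean_tab)[match(metrics, names(mean_tab))] <-
    paste0("mean_", metrics)
  names(sd_tab)[match(metrics, names(sd_tab))] <- paste0("sd_", metrics)
  out <- merge(mean_tab, sd_tab, by = key)
  out$auc_pct_change <- 100 * (out$mean_auc - auc_ref[out$species]) /
    auc_ref[out$species]
  out[order(out$species, out$bias_type, out$intensity), , drop = FALSE]
}

#' Mean rank of each correction method
#'
#' Within every (species x bias type x intensity) cell, methods are ranked
#' by mean Delta, descending (rank 1 = best correction, ties get the
#' average of the tied ranks); the mean and standard error of these ranks
#' across the 12 (type x intensity) cells are reported per species, method
#' and index.
#'
#' @param results a [run_species_design()] results data.frame.
#' @param indices Delta columns to rank on (default all four).
#' @return a data.frame with `species`, `index`, `method`, `mean_rank`,
#'   `se_rank`, `n_cells`.
#' @export
rank_methods <- function(results, indices = delta_columns()) {
  summ <- summarize_results(results)
  out <- list()
  for (dc in indices) {
    mv <- summ[[paste0("mean_", dc)]]
    cell <- interaction(summ$species, summ$bias_type, summ$intensity,
                        drop = TRUE)
    ranks <- rep(NA_real_, nrow(summ))
    for (cl in levels(cell)) {
      ix <- which(cell == cl)
      if (any(is.na(mv[ix]))) next  # a method missing: skip the cell
      ranks[ix] <- rank(-mv[ix], ties.method = "average")
    }
    ok <- !is.na(ranks)
    if (!any(ok)) next
    d <- data.frame(species = summ$species[ok], method = summ$method[ok],
                    rank = ranks[ok], stringsAsFactors = FALSE)
    agg <- stats::aggregate(rank ~ species + method, data = d,
                            FUN = function(x) {
                              c(mean = mean(x),
                                se = stats::sd(x) / sqrt(length(x)),
                                n = length(x))
                            })
    out[[dc]] <- data.frame(species = agg$species, index = dc,
                            method = agg$method,
                            mean_rank = agg$rank[, "mean"],
                            se_rank = agg$rank[, "se"],
                            n_cells = agg$rank[, "n"],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$index, res$species, res$mean_rank), , drop = FALSE]
}
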