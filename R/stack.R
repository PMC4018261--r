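#' Environmental predictor stacks
#'
#' An `env_stack` bundles co-registered [grid_raster()] layers, each flagged
#' continuous or categorical. All layers must share grid geometry and at
#' least one must be continuous.
#'
#' @param layers named list of [grid_raster()] objects.
#' @param categorical character vector of layer names to treat as
#'   categorical (one-hot encoded in models, exempt from the collinearity
#'   filter).
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, categorical = character()) {
  if (is.null(names(layers)) || any(!nzchar(names(layers))) ||
      anyDuplicated(names(layers))) {
    stop("layers must have unique non-empty names", call. = FALSE)
  }
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "grid_raster")) {
      stop("layer '", nm, "' is not a grid_raster", call. = FALSE)
    }
    if (!raster_same_grid(ref, layers[[nm]])) {
      stop("layer '", nm, "' is not co-registered with layer '",
           names(layers)[1], "'", call. = FALSE)
    }
  }
  bad <- setdiff(categorical, names(layers))
  if (length(bad)) stop("unknown categorical layer(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (length(setdiff(names(layers), categorical)) == 0L) {
    stop("the stack needs at least one continuous layer", call. = FALSE)
  }
  structure(list(layers = layers, categorical = categorical),
            class = "env_stack")
}

#' @method print env_stack
#' @export
print.env_stack <- function(x, ...) {
  r <- x$layers[[1]]
  cat(sprintf("<env_stack> %d layers on a %d x %d grid (cellsize %g deg)\n",
              length(x$layers), r$nrows, r$ncols, r$cellsize))
  for (nm in names(x$layers)) {
    cat(sprintf("  %-16s %s\n", nm,
                if (nm %in% x$categorical) "categorical" else "continuous"))
  }
  invisible(x)
}

stack_ref <- function(stack) stack$layers[[1]]

continuous_names <- function(stack) {
  setdiff(names(stack$layers), stack$categorical)
}

# logical matrix: cells valid (non-nodata) in every layer
stack_valid_mask <- function(stack) {
  ok <- !is.na(stack$layers[[1]]$values)
  for (l in stack$layers[-1]) ok <- ok & !is.na(l$values)
  ok
}

#' Subset the layers of a stack
#' @param stack an [env_stack()].
#' @param keep character vector of layer names to retain.
#' @return an [env_stack()] with the selected layers.
#' @export
stack_subset <- function(stack, keep) {
  missing <- setdiff(keep, names(stack$layers))
  if (length(missing)) stop("unknown layer(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  env_stack(stack$layers[keep], intersect(stack$categorical, keep))
}

#' Occurrence sets
#'
#' Presence records are a data.frame with integer `id`, `lon` and `lat`
#' columns (decimal degrees). `occurrence_set()` validates and normalizes
#' such a frame; most functions accept any conforming data.frame.
#'
#' @param lon,lat numeric coordinate vectors.
#' @param id optional integer ids; defaults to `0:(n-1)`.
#' @param species optional species label column.
#' @return a data.frame with columns `id`, `lon`, `lat` (and `species` when
#'   given).
#' @export
occurrence_set <- function(lon, lat, id = NULL, species = NULL) {
  n <- length(lon)
  if (length(lat) != n) stop("lon and lat lengths differ", call. = FALSE)
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  if (is.null(id)) id <- seq_len(n) - 1L
  if (anyDuplicated(id)) stop("occurrence ids must be unique", call. = FALSE)
  out <- data.frame(id = as.integer(id), lon = as.numeric(lon),
                    lat = as.numeric(lat))
  if (!is.null(species)) out$species <- species
  out
}

#' Read occurrence records from CSV
#'
#' Expects a header `species,lon,lat`. Ids are assigned `0..n-1` in file
#' order; a non-numeric coordinate raises an error citing the offending
#' line.
#'
#' @param path CSV path.
#' @return an occurrence data.frame (`id`, `lon`, `lat`, `species`).
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character")
  if (!all(c("species", "lon", "lat") %in% names(raw))) {
    stop("occurrence CSV must have header columns species,lon,lat",
         call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("occurrence file holds no records", call. = FALSE)
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- which(is.na(lon) | is.na(lat))
  if (length(bad)) {
    stop(sprintf("non-numeric coordinate on data line %d of %s",
                 bad[1], path), call. = FALSE)
  }
  occurrence_set(lon, lat, species = raw$species)
}

#' Write occurrence records to CSV
#' @param occ occurrence data.frame.
#' @param path output path.
#' @param species species label used when `occ` lacks a `species` column.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, species = "species") {
  sp <- if ("species" %in% names(occ)) occ$species else species
  utils::write.csv(
    data.frame(species = sp,
               lon = format(occ$lon, digits = 17, trim = TRUE),
               lat = format(occ$lat, digits = 17, trim = TRUE)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract predictor values at occurrence locations
#'
#' Nearest-cell extraction: each record gets the value of the cell containing
#' it in every layer. Records falling on a nodata cell in any layer are
#' flagged `incomplete`.
#'
#' @param stack an [env_stack()].
#' @param occ occurrence data.frame (`id`, `lon`, `lat`).
#' @return data.frame with `id`, one column per layer, and a logical
#'   `incomplete` flag.
#' @export
extract_env <- function(stack, occ) {
  ref <- stack_ref(stack)
  idx <- cell_index(ref, occ$lon, occ$lat)
  if (anyNA(idx$row)) {
    first <- which(is.na(idx$row))[1]
    stop(sprintf("record id %d falls outside the stack extent",
                 occ$id[first]), call. = FALSE)
  }
  out <- data.frame(id = occ$id)
  flat <- cbind(idx$row, idx$col)
  for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]]$values[flat]
  out$incomplete <- Reduce(`|`, lapply(names(stack$layers),
                                       function(nm) is.na(out[[nm]])))
  out
}

#' Drop highly collinear continuous layers
#'
#' Computes pairwise Pearson correlations between continuous layers over
#' cells valid in all layers, then greedily removes layers: pairs are
#' visited in decreasing `|r|`; whenever both members of a pair with
#' `|r| > threshold` are still present, the member appearing *later* in
#' stack order is dropped. Categorical layers are always retained. The
#' operation is deterministic and idempotent.
#'
#' @param stack an [env_stack()].
#' @param threshold correlation magnitude above which a pair is considered
#'   collinear (default 0.9).
#' @return a filtered [env_stack()].
#' @export
correlation_filter <- function(stack, threshold = 0.9) {
  cont <- continuous_names(stack)
  if (length(cont) < 2L) return(stack)
  ok <- stack_valid_mask(stack)
  if (sum(ok) < 2L) {
    stop("insufficient data: fewer than 2 cells valid in all layers",
         call. = FALSE)
  }
  m <- vapply(cont, function(nm) stack$layers[[nm]]$values[ok],
              numeric(sum(ok)))
  r <- suppressWarnings(stats::cor(m))
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  absr <- abs(r[pairs])
  ord <- order(absr, decreasing = TRUE)
  dropped <- character()
  for (k in ord) {
    if (is.na(absr[k]) || absr[k] <= threshold) next
    a <- cont[pairs[k, 1]]; b <- cont[pairs[k, 2]]
    if (a %in% dropped || b %in% dropped) next
    dropped <- c(dropped, b)  # b is later in stack order (upper triangle)
  }
  keep <- setdiff(names(stack$layers), dropped)
  stack_subset(stack, keep)
}
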