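#' Per-pixel trait map from a trained model
#'
#' Applies a trait model (univariate index model or LASSO+PLSR) to every
#' sunlit vegetation pixel of a calibrated scene: pixels are screened with
#' the ExG threshold, the model's required indices are computed per pixel,
#' and the model prediction becomes the pixel value. Pixels failing an index
#' guard (flagged missing) are masked. Predictions are not clipped to
#' physiological ranges; out-of-range pixels are counted in the metadata
#' instead.
#'
#' @param scene A calibrated \code{\link{scene_raster}}.
#' @param model An \code{"index_model"}, \code{"plsr_trait_model"} or
#'   \code{"trait_model"}.
#' @param exg_threshold ExG masking threshold (default 0.07).
#' @param trait Trait label for the map (defaults to the model's, if any).
#' @param range_flag Optional c(lo, hi); predictions outside it are counted
#'   (not altered) and reported in the \code{stats}.
#' @return Object of class \code{"trait_map"}: \code{values} (H×W, NA off
#'   the valid mask), \code{nodata} (superset of the scene's), \code{trait},
#'   \code{model_hash}, \code{stats} (min/max/mean/n_valid/n_out_of_range).
#' @export
map_traits <- function(scene, model, exg_threshold = 0.07, trait = NULL,
                       range_flag = NULL) {
  need <- model_indices(model)
  reg <- index_registry(include_stubs = TRUE)
  bad <- setdiff(need, reg$name[!reg$stub])
  if (length(bad)) {
    stop(sprintf("model requires unregistered index formulas: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  exg <- compute_exg(scene)
  valid <- !scene$nodata & !is.na(exg) & exg > exg_threshold
  d <- dim(scene$bands)
  values <- matrix(NA_real_, d[1], d[2])
  n_oor <- 0L
  if (any(valid)) {
    bl <- lapply(stats::setNames(BAND_NAMES, BAND_NAMES),
                 function(b) scene$bands[, , b][valid])
    Xi <- vapply(need, function(nm) compute_index(nm, bl),
                 numeric(sum(valid)))
    Xi <- matrix(Xi, nrow = sum(valid),
                 dimnames = list(NULL, need))
    ok <- rowSums(is.na(Xi)) == 0
    pred <- rep(NA_real_, sum(valid))
    if (any(ok)) {
      pred[ok] <- predict(model, Xi[ok, , drop = FALSE])
    }
    values[valid] <- pred
    if (!is.null(range_flag)) {
      n_oor <- sum(pred < range_flag[1] | pred > range_flag[2], na.rm = TRUE)
    }
  }
  nodata <- is.na(values)
  vv <- values[!nodata]
  if (is.null(trait) && !is.null(model$trait)) trait <- model$trait
  tf <- tempfile()
  saveRDS(model, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(list(values = values, nodata = nodata,
                 trait = if (is.null(trait)) NA_character_ else trait,
                 model_hash = hash,
                 stats = list(min = if (length(vv)) min(vv) else NA_real_,
                              max = if (length(vv)) max(vv) else NA_real_,
                              mean = if (length(vv)) mean(vv) else NA_real_,
                              n_valid = length(vv),
                              n_out_of_range = n_oor)),
            class = "trait_map")
}

#' @export
print.trait_map <- function(x, ...) {
  s <- x$stats
  cat(sprintf("trait_map [%s]: %d valid px, range %.2f..%.2f, mean %.2f\n",
              x$trait, s$n_valid, s$min, s$max, s$mean))
  invisible(x)
}

#' Quicklook image of a trait map
#'
#' @param x A \code{"trait_map"}.
#' @param ... Passed to \code{image()}.
#' @export
plot.trait_map <- function(x, ...) {
  v <- x$values
  image(t(v[nrow(v):1, , drop = FALSE]), useRaster = TRUE,
        col = grDevices::hcl.colors(64, "viridis"), axes = FALSE,
        main = x$trait, ...)
  invisible(x)
}

#' Per-plot statistics of a trait map
#'
#' Mean, min, max and valid-pixel count of the mapped trait over each plot
#' rectangle of the field layout. Plots with no valid pixels are reported
#' with \code{NA} statistics, never dropped.
#'
#' @param map A \code{\link{map_traits}} result.
#' @param layout A \code{\link{field_layout}}.
#' @return Data frame: \code{plot_id}, \code{treatment}, \code{mean},
#'   \code{min}, \code{max}, \code{n_valid}.
#' @export
plot_summary <- function(map, layout) {
  plots <- layout$plots
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    sub <- map$values[plots$r0[i]:plots$r1[i], plots$c0[i]:plots$c1[i]]
    v <- sub[!is.na(sub)]
    if (length(v) == 0) {
      data.frame(plot_id = plots$plot_id[i], treatment = plots$treatment[i],
                 mean = NA_real_, min = NA_real_, max = NA_real_,
                 n_valid = 0L)
    } else {
      data.frame(plot_id = plots$plot_id[i], treatment = plots$treatment[i],
                 mean = mean(v), min = min(v), max = max(v),
                 n_valid = length(v))
    }
  })
  do.call(rbind, rows)
}

#' Write a trait map as single-band TIFF
#'
#' Trait values are affinely rescaled into [0.5, 1] for storage (the TIFF
#' writer clamps samples to [0, 1]); masked pixels are stored as exactly 0.
#' The JSON sidecar records the inverse transform
#' (\code{value = offset + (sample - 0.5) / 0.5 * span}), the trait label and
#' the model hash.
#'
#' @param map A \code{"trait_map"}.
#' @param path Output path (.tif).
#' @return The path, invisibly.
#' @export
write_trait_map <- function(map, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF i/o", call. = FALSE)
  }
  v <- map$values
  lo <- map$stats$min
  span <- max(map$stats$max - lo, .Machine$double.eps)
  enc <- 0.5 + 0.5 * (v - lo) / span
  enc[is.na(v)] <- 0
  tiff::writeTIFF(enc, path, bits.per.sample = 32)
  writeLines(sprintf(
    '{"trait": "%s", "offset": %s, "span": %s, "nodata_sample": 0, "model_hash": "%s"}',
    map$trait, format(lo, digits = 10), format(span, digits = 10),
    map$model_hash),
    paste0(sub("\\.tiff?$", "", path), ".json"))
  invisible(path)
}
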