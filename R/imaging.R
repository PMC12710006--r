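#' Construct a five-band scene raster
#'
#' Container for a calibrated multispectral image: an H×W×5 reflectance array
#' in the fixed band order blue, green, red, red-edge, near-infrared, with a
#' nodata mask and the ground sample distance.
#'
#' @param bands H×W×5 numeric array (third dimension named B, G, R, RE, NIR;
#'   names are added if absent).
#' @param gsd Ground sample distance, m/pixel.
#' @param nodata H×W logical, \code{TRUE} where the pixel is invalid.
#' @param ... Extra components (truth masks, labels) stored on the object.
#' @return Object of class \code{"scene_raster"}.
#' @export
scene_raster <- function(bands, gsd = NA_real_, nodata = NULL, ...) {
  d <- dim(bands)
  if (length(d) != 3 || d[3] != 5) {
    stop("`bands` must be an H x W x 5 array", call. = FALSE)
  }
  if (is.null(dimnames(bands)[[3]])) dimnames(bands)[[3]] <- BAND_NAMES
  if (is.null(nodata)) nodata <- matrix(FALSE, d[1], d[2])
  structure(c(list(bands = bands, gsd = gsd, nodata = nodata), list(...)),
            class = "scene_raster")
}

#' @export
print.scene_raster <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("scene_raster: %d x %d px, 5 bands (B,G,R,RE,NIR), gsd = %s m\n",
              d[1], d[2], format(x$gsd)))
  cat(sprintf("  valid pixels: %d / %d\n", sum(!x$nodata), d[1] * d[2]))
  invisible(x)
}

#' @export
dim.scene_raster <- function(x) dim(x$bands)

#' Radiometric calibration against a reflectance panel
#'
#' Converts raw digital numbers to reflectance with the empirical one-point
#' (gain-only) panel method: per band, gain = nominal panel reflectance /
#' mean panel digital number, applied multiplicatively. Output is clipped to
#' [0, 1.5]; the number of clipped pixels per band is recorded in the
#' \code{clipped} attribute of the result's bands.
#'
#' @param raw H×W×5 array of digital numbers.
#' @param panel List with \code{mean_dn} (per-band mean digital number over
#'   the panel, > 0) and \code{nominal} (per-band panel reflectance, default
#'   0.5 in every band).
#' @param gsd Ground sample distance carried onto the result.
#' @return A calibrated \code{\link{scene_raster}}.
#' @examples
#' raw <- array(rep(1000, 4 * 4 * 5), c(4, 4, 5))
#' pan <- panel_observation(mean_dn = rep(2000, 5))
#' calibrate_reflectance(raw, pan)$bands[1, 1, ]  # 0.25 everywhere
#' @export
calibrate_reflectance <- function(raw, panel, gsd = NA_real_) {
  if (any(panel$mean_dn <= 0)) {
    stop("panel digital numbers must be positive", call. = FALSE)
  }
  nominal <- if (is.null(panel$nominal)) rep(0.5, 5) else panel$nominal
  gain <- nominal / panel$mean_dn
  out <- raw
  for (b in seq_len(5)) out[, , b] <- raw[, , b] * gain[b]
  clipped <- sum(out < 0 | out > 1.5, na.rm = TRUE)
  out[out < 0] <- 0
  out[out > 1.5] <- 1.5
  sc <- scene_raster(out, gsd = gsd)
  attr(sc$bands, "clipped") <- clipped
  sc
}

#' @rdname calibrate_reflectance
#' @param mean_dn Per-band mean digital number over panel pixels.
#' @export
panel_observation <- function(mean_dn, nominal = rep(0.5, 5)) {
  if (any(mean_dn <= 0)) {
    stop("panel digital numbers must be positive", call. = FALSE)
  }
  list(mean_dn = mean_dn, nominal = nominal)
}

#' Excess green index image
#'
#' ExG = 2·ρG − ρR − ρB per pixel, the standard greenness criterion used to
#' separate canopy from soil background and leaf shadow.
#'
#' @param scene A calibrated \code{\link{scene_raster}}.
#' @return H×W numeric matrix (NA on nodata pixels).
#' @export
compute_exg <- function(scene) {
  exg <- 2 * band_plane(scene, "G") - band_plane(scene, "R") -
    band_plane(scene, "B")
  exg[scene$nodata] <- NA_real_
  exg
}

# H x W matrix of one band, robust to 1-pixel edge cases
band_plane <- function(scene, b) {
  d <- dim(scene$bands)
  matrix(scene$bands[, , b], d[1], d[2])
}

#' Vegetation mask by ExG thresholding
#'
#' Marks pixels whose excess green exceeds the threshold (strictly), removing
#' soil background and leaf shadow. Optionally intersected with a manual ROI.
#'
#' @param exg ExG matrix from \code{\link{compute_exg}}, or a
#'   \code{\link{scene_raster}} (ExG is computed on the fly).
#' @param threshold Dimensionless ExG threshold; the operational default
#'   is 0.07.
#' @param roi Optional H×W logical manual ROI to intersect with.
#' @return H×W logical matrix of class \code{"roi_mask"} with attribute
#'   \code{provenance} ("exg_refined" or "manual_polygon" when intersected).
#'   An empty mask triggers a warning, not an error.
#' @export
vegetation_mask <- function(exg, threshold = 0.07, roi = NULL) {
  if (inherits(exg, "scene_raster")) exg <- compute_exg(exg)
  if (!is.finite(threshold) && threshold != -Inf) {
    stop("`threshold` must be finite (or -Inf for no thresholding)",
         call. = FALSE)
  }
  mask <- !is.na(exg) & exg > threshold
  provenance <- "exg_refined"
  if (!is.null(roi)) {
    mask <- mask & roi
    provenance <- "manual_polygon"
  }
  if (!any(mask)) warning("vegetation mask is empty", call. = FALSE)
  structure(mask, class = c("roi_mask", class(mask)),
            provenance = provenance)
}

#' Mean canopy reflectance over a region of interest
#'
#' Arithmetic mean of each band over the masked pixels, excluding nodata.
#'
#' @param scene A \code{\link{scene_raster}}.
#' @param mask H×W logical ROI (e.g. from \code{\link{vegetation_mask}}).
#' @return Named numeric vector of five band means (B, G, R, RE, NIR).
#' @export
extract_reflectance <- function(scene, mask) {
  use <- mask & !scene$nodata
  if (!any(use)) stop("ROI mask selects no valid pixels", call. = FALSE)
  vapply(BAND_NAMES, function(b) mean(band_plane(scene, b)[use]), numeric(1))
}

#' Ground sample distance from imaging geometry
#'
#' GSD = flight altitude × pixel pitch / focal length (pinhole camera).
#'
#' @param altitude Flight altitude above canopy, m.
#' @param pixel_pitch Detector pixel pitch, m (e.g. 3.75e-6).
#' @param focal_length Lens focal length, m (e.g. 5.4e-3).
#' @return GSD in m/pixel.
#' @examples
#' gsd_from_geometry(30, 3.75e-6, 5.4e-3)  # ~0.0208 m = 2 cm
#' @export
gsd_from_geometry <- function(altitude, pixel_pitch, focal_length) {
  stop_if_not_positive(altitude, "altitude")
  stop_if_not_positive(pixel_pitch, "pixel_pitch")
  stop_if_not_positive(focal_length, "focal_length")
  altitude * pixel_pitch / focal_length
}

#' Read and write five-band scenes as multi-page TIFF
#'
#' Scenes are stored as a five-page 32-bit TIFF (one page per band, in the
#' fixed B, G, R, RE, NIR order) with reflectance divided by 1.5 (the
#' calibration clip ceiling) so the stored samples sit in [0, 1]; a JSON
#' sidecar (\code{<file>.json}) records the scale factor and the ground
#' sample distance. Requires the \pkg{tiff} package.
#'
#' @param scene A \code{\link{scene_raster}}.
#' @param path Output path (.tif).
#' @return \code{write_scene_tiff}: the path, invisibly.
#'   \code{read_scene_tiff}: a \code{\link{scene_raster}}.
#' @export
write_scene_tiff <- function(scene, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF i/o", call. = FALSE)
  }
  pages <- lapply(seq_len(5), function(b) {
    plane <- band_plane(scene, BAND_NAMES[b]) / 1.5
    plane[plane < 0] <- 0
    plane[plane > 1] <- 1
    plane
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  side <- sub("\\.tiff?$", "", path)
  writeLines(sprintf(
    '{"gsd": %s, "scale": 1.5, "bands": ["B","G","R","RE","NIR"]}',
    format(scene$gsd, digits = 10)),
    paste0(side, ".json"))
  invisible(path)
}

#' @rdname write_scene_tiff
#' @param gsd Ground sample distance override when no sidecar is present.
#' @export
read_scene_tiff <- function(path, gsd = NA_real_) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF i/o", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  scale <- 1
  side <- paste0(sub("\\.tiff?$", "", path), ".json")
  if (file.exists(side) && requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- jsonlite::fromJSON(side)
    if (!is.null(meta$gsd)) gsd <- meta$gsd
    if (!is.null(meta$scale)) scale <- meta$scale
  }
  scene_raster(img * scale, gsd = gsd)
}
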