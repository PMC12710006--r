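#' Nitrogen fertilisation treatments
#'
#' The five-level nitrogen gradient the synthetic field emulates.
#'
#' @return Data frame with columns \code{label} (N0..N4) and \code{rate}
#'   (kg/hm²: 0, 130, 260, 390, 520).
#' @export
nitrogen_treatments <- function() {
  data.frame(label = paste0("N", 0:4),
             rate = c(0, 130, 260, 390, 520))
}

#' Parameters of the synthetic truth generator
#'
#' The latent driver is leaf nitrogen per area (g m⁻²), whose treatment mean
#' rises linearly with the fertilisation rate. Chlorophyll a+b, Vcmax25 and
#' LAI are proportional to nitrogen, Jmax25 proportional to Vcmax25, each with
#' multiplicative lognormal noise (mean-corrected, so expectations are exactly
#' the stated proportionalities and strictly monotone in the nitrogen rate).
#'
#' @param n_area_base,n_area_span Mean leaf N per area at rate 0 and the added
#'   mean at the maximum rate (g m⁻²): mean = base + span·rate/520.
#' @param sdlog_n_area Lognormal sdlog of plant-to-plant nitrogen variation.
#' @param cab_per_n Chlorophyll a+b per unit nitrogen, µg cm⁻² per g m⁻².
#' @param sdlog_cab Lognormal sdlog of the Cab residual.
#' @param vcmax_per_n Vcmax25 per unit nitrogen, µmol m⁻² s⁻¹ per g m⁻².
#' @param sdlog_vcmax Lognormal sdlog of the Vcmax residual.
#' @param jmax_ratio Mean Jmax25:Vcmax25 ratio (kept inside the physiological
#'   band 1.2–2.5).
#' @param sdlog_jmax Lognormal sdlog of the ratio residual.
#' @param rd_frac Mean Rd25 as a fraction of Vcmax25.
#' @param sdlog_rd Lognormal sdlog of the Rd residual.
#' @param lai_per_n Leaf area index per unit nitrogen.
#' @param sdlog_lai Lognormal sdlog of the LAI residual.
#' @return Named list of class \code{"synth_params"}.
#' @export
synth_params <- function(n_area_base = 1.0, n_area_span = 1.2,
                         sdlog_n_area = 0.08,
                         cab_per_n = 28, sdlog_cab = 0.05,
                         vcmax_per_n = 45, sdlog_vcmax = 0.07,
                         jmax_ratio = 1.9, sdlog_jmax = 0.05,
                         rd_frac = 0.015, sdlog_rd = 0.10,
                         lai_per_n = 1.2, sdlog_lai = 0.10) {
  structure(as.list(environment()), class = "synth_params")
}

# Mean-one multiplicative lognormal noise.
rlnoise <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate ground-truth plants for a synthetic nitrogen-gradient field
#'
#' Draws per-plant latent nitrogen for each treatment and derives chlorophyll,
#' LAI and the FvCB traits from it. Identical \code{seed} gives identical
#' output.
#'
#' @param n_plots_per_treatment Replicate plots per nitrogen level (≥ 1).
#' @param plants_per_plot Plants per plot (≥ 1).
#' @param seed Integer seed.
#' @param params A \code{\link{synth_params}} list.
#' @return Data frame with one row per plant: \code{plant_id}, \code{plot_id},
#'   \code{treatment}, \code{rate}, \code{n_area} (g m⁻²), \code{cab}
#'   (µg cm⁻²), \code{lai}, \code{vcmax25}, \code{jmax25}, \code{rd25}
#'   (µmol m⁻² s⁻¹).
#' @examples
#' head(generate_truth(3, 5, seed = 42))
#' @export
generate_truth <- function(n_plots_per_treatment, plants_per_plot, seed,
                           params = synth_params()) {
  stop_if_not_count(n_plots_per_treatment, "n_plots_per_treatment")
  stop_if_not_count(plants_per_plot, "plants_per_plot")
  trt <- nitrogen_treatments()
  p <- params
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(trt))) {
      mu_n <- p$n_area_base + p$n_area_span * trt$rate[i] / max(trt$rate)
      for (r in seq_len(n_plots_per_treatment)) {
        n <- plants_per_plot
        n_area <- mu_n * rlnoise(n, p$sdlog_n_area)
        cab <- p$cab_per_n * n_area * rlnoise(n, p$sdlog_cab)
        vcmax25 <- p$vcmax_per_n * n_area * rlnoise(n, p$sdlog_vcmax)
        jmax25 <- p$jmax_ratio * vcmax25 * rlnoise(n, p$sdlog_jmax)
        rd25 <- p$rd_frac * vcmax25 * rlnoise(n, p$sdlog_rd)
        lai <- p$lai_per_n * n_area * rlnoise(n, p$sdlog_lai)
        plot_id <- sprintf("%s_rep%d", trt$label[i], r)
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = sprintf("%s_p%02d", plot_id, seq_len(n)),
          plot_id = plot_id, treatment = trt$label[i], rate = trt$rate[i],
          n_area = n_area, cab = cab, lai = lai,
          vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Lay out plots and plant markers on a pixel grid
#'
#' Arranges one plot rectangle per (treatment, replicate) — treatments as
#' columns, replicates as rows — and places each plant's canopy centre on a
#' regular grid inside its plot. Rectangles are disjoint and every plant lies
#' inside its plot.
#'
#' @param truth Output of \code{\link{generate_truth}}.
#' @param plant_radius_px Canopy radius per plant, pixels.
#' @param plant_spacing_px Plant centre spacing, pixels.
#' @param plot_cols Plant columns per plot.
#' @param gutter_px Soil gap between plot rectangles, pixels.
#' @return List of class \code{"field_layout"}: \code{plots} (plot_id,
#'   treatment, r0, c0, r1, c1), \code{plants} (plant_id, plot_id, row, col),
#'   \code{dim} = c(H, W), and the geometry parameters.
#' @export
field_layout <- function(truth, plant_radius_px = 4, plant_spacing_px = 12,
                         plot_cols = 2, gutter_px = 8) {
  plots <- unique(truth[, c("plot_id", "treatment")])
  plots$rep <- as.integer(sub(".*_rep", "", plots$plot_id))
  trt_levels <- sort(unique(as.character(plots$treatment)))
  counts <- table(truth$plot_id)
  n_per_plot <- max(counts)
  rows_in_plot <- ceiling(n_per_plot / plot_cols)
  plot_h <- rows_in_plot * plant_spacing_px
  plot_w <- plot_cols * plant_spacing_px
  n_rep <- max(plots$rep)
  H <- gutter_px + n_rep * (plot_h + gutter_px)
  W <- gutter_px + length(trt_levels) * (plot_w + gutter_px)

  plot_rows <- list()
  plant_rows <- list()
  for (i in seq_len(nrow(plots))) {
    ti <- match(as.character(plots$treatment[i]), trt_levels)
    ri <- plots$rep[i]
    r0 <- gutter_px + (ri - 1) * (plot_h + gutter_px) + 1
    c0 <- gutter_px + (ti - 1) * (plot_w + gutter_px) + 1
    plot_rows[[i]] <- data.frame(plot_id = plots$plot_id[i],
                                 treatment = plots$treatment[i],
                                 r0 = r0, c0 = c0,
                                 r1 = r0 + plot_h - 1, c1 = c0 + plot_w - 1)
    ids <- truth$plant_id[truth$plot_id == plots$plot_id[i]]
    k <- seq_along(ids)
    pr <- (k - 1) %/% plot_cols
    pc <- (k - 1) %% plot_cols
    plant_rows[[i]] <- data.frame(
      plant_id = ids, plot_id = plots$plot_id[i],
      row = r0 + pr * plant_spacing_px + plant_spacing_px %/% 2,
      col = c0 + pc * plant_spacing_px + plant_spacing_px %/% 2)
  }
  structure(list(plots = do.call(rbind, plot_rows),
                 plants = do.call(rbind, plant_rows),
                 dim = c(H, W),
                 plant_radius_px = plant_radius_px),
            class = "field_layout")
}

#' Parameters of the synthetic reflectance model
#'
#' Canopy reflectance per band follows a Beer-law mixture
#' \eqn{\rho_b = \rho_{soil,b} e^{-k_b L} + \rho_{leaf,b}(Cab) (1 - e^{-k_b
#' L})} with LAI \eqn{L}; leaf reflectance in the visible and red-edge bands
#' decays exponentially with chlorophyll (red edge most sensitive), the NIR
#' leaf reflectance is pigment-insensitive, and the soil spectrum is flat
#' (so its ExG is 0 and \eqn{\rho_{NIR} \approx \rho_R}).
#'
#' @param soil Soil reflectance, one value per band (flat by default).
#' @param k_band Beer-law extinction coefficients per band (B, G, R, RE, NIR).
#' @param leaf_base,leaf_amp,leaf_scale Leaf reflectance model
#'   \eqn{base_b + amp_b e^{-Cab/scale_b}} per band.
#' @param shadow_fraction Seeded fraction of canopy pixels darkened.
#' @param shadow_factor Multiplicative, band-neutral shadow darkening.
#' @param brightness_sdlog Per-pixel band-neutral lognormal brightness sdlog.
#' @param band_noise_sd Additive per-band Gaussian noise sd (reflectance).
#' @return Named list of class \code{"scene_params"}.
#' @export
scene_params <- function(
    soil = c(B = 0.20, G = 0.20, R = 0.20, RE = 0.20, NIR = 0.20),
    k_band = c(B = 0.9, G = 0.8, R = 0.9, RE = 0.7, NIR = 0.5),
    leaf_base = c(B = 0.03, G = 0.10, R = 0.03, RE = 0.18, NIR = 0.45),
    leaf_amp = c(B = 0.04, G = 0.15, R = 0.10, RE = 0.25, NIR = 0),
    leaf_scale = c(B = 40, G = 35, R = 25, RE = 45, NIR = 1),
    shadow_fraction = 0.10, shadow_factor = 0.3,
    brightness_sdlog = 0.05, band_noise_sd = 0.004) {
  structure(as.list(environment()), class = "scene_params")
}

#' Noise-free canopy reflectance for given chlorophyll and LAI
#'
#' Evaluates the Beer-law canopy mixture of \code{\link{scene_params}}.
#'
#' @param cab Chlorophyll a+b, µg cm⁻² (vectorised).
#' @param lai Leaf area index (vectorised, recycled against \code{cab}).
#' @param params A \code{\link{scene_params}} list.
#' @return Matrix with one row per input and columns B, G, R, RE, NIR.
#' @export
canopy_reflectance <- function(cab, lai, params = scene_params()) {
  n <- max(length(cab), length(lai))
  cab <- rep_len(cab, n)
  lai <- rep_len(lai, n)
  out <- matrix(NA_real_, n, 5, dimnames = list(NULL, BAND_NAMES))
  for (b in BAND_NAMES) {
    leaf <- params$leaf_base[[b]] + params$leaf_amp[[b]] *
      exp(-cab / params$leaf_scale[[b]])
    f <- exp(-params$k_band[[b]] * lai)
    out[, b] <- params$soil[[b]] * f + leaf * (1 - f)
  }
  out
}

#' Render a synthetic five-band scene
#'
#' Paints soil everywhere, then a circular canopy per plant whose spectrum
#' follows \code{\link{canopy_reflectance}} at that plant's chlorophyll and
#' LAI, adds band-neutral per-pixel brightness variation and small per-band
#' noise, and darkens a seeded fraction of canopy pixels uniformly across
#' bands to emulate shadow. The returned vegetation mask marks sunlit canopy
#' pixels (the segmentation target); shadowed canopy is reported separately.
#'
#' @param layout A \code{\link{field_layout}}.
#' @param truth Matching \code{\link{generate_truth}} table.
#' @param gsd Ground sample distance, m/pixel (> 0).
#' @param seed Integer seed.
#' @param params A \code{\link{scene_params}} list.
#' @param dim Optional raster dimension c(H, W); layouts exceeding it are
#'   rejected.
#' @return Object of class \code{"scene_raster"}: \code{bands} (H×W×5 array,
#'   dimnames band = B,G,R,RE,NIR), \code{gsd}, \code{nodata} (H×W logical),
#'   \code{mask_vegetation} (sunlit canopy), \code{mask_shadow},
#'   \code{mask_canopy} (all canopy), \code{labels} (H×W integer row index
#'   into \code{truth}, 0 = soil).
#' @export
render_scene <- function(layout, truth, gsd = 0.02, seed = 1,
                         params = scene_params(), dim = NULL) {
  stop_if_not_positive(gsd, "gsd")
  if (is.null(dim)) dim <- layout$dim
  H <- dim[1]; W <- dim[2]
  if (any(layout$plots$r1 > H) || any(layout$plots$c1 > W) ||
      any(layout$plots$r0 < 1) || any(layout$plots$c0 < 1)) {
    stop("layout exceeds raster bounds", call. = FALSE)
  }
  p <- params
  rad <- layout$plant_radius_px
  with_seed(seed, {
    bands <- array(NA_real_, c(H, W, 5),
                   dimnames = list(NULL, NULL, BAND_NAMES))
    soil_bright <- matrix(stats::rlnorm(H * W, -p$brightness_sdlog^2 / 2,
                                        p$brightness_sdlog), H, W)
    for (b in seq_along(BAND_NAMES)) {
      bands[, , b] <- p$soil[[BAND_NAMES[b]]] * soil_bright
    }
    labels <- matrix(0L, H, W)
    for (i in seq_len(nrow(layout$plants))) {
      pr <- layout$plants$row[i]; pc <- layout$plants$col[i]
      idx <- match(layout$plants$plant_id[i], truth$plant_id)
      if (is.na(idx)) next
      rr <- max(1, pr - rad):min(H, pr + rad)
      cc <- max(1, pc - rad):min(W, pc + rad)
      for (r in rr) for (cl in cc) {
        if ((r - pr)^2 + (cl - pc)^2 <= rad^2) labels[r, cl] <- idx
      }
    }
    veg <- labels > 0L
    nveg <- sum(veg)
    if (nveg > 0) {
      rho <- canopy_reflectance(truth$cab[labels[veg]],
                                truth$lai[labels[veg]], p)
      bright <- stats::rlnorm(nveg, -p$brightness_sdlog^2 / 2,
                              p$brightness_sdlog)
      for (b in seq_len(5)) {
        plane <- bands[, , b]
        plane[veg] <- rho[, b] * bright
        bands[, , b] <- plane
      }
    }
    # additive per-band sensor noise everywhere
    bands <- bands + array(stats::rnorm(H * W * 5, 0, p$band_noise_sd),
                           c(H, W, 5))
    bands[bands < 0] <- 0
    # band-neutral shadow on a seeded fraction of canopy pixels
    shadow <- matrix(FALSE, H, W)
    if (nveg > 0 && p$shadow_fraction > 0) {
      vi <- which(veg)
      ns <- round(p$shadow_fraction * nveg)
      si <- sample(vi, ns)
      shadow[si] <- TRUE
      for (b in seq_len(5)) {
        plane <- bands[, , b]
        plane[si] <- plane[si] * p$shadow_factor
        bands[, , b] <- plane
      }
    }
    scene_raster(bands, gsd = gsd,
                 mask_vegetation = veg & !shadow,
                 mask_shadow = shadow,
                 mask_canopy = veg,
                 labels = labels)
  })
}

#' CO2 ramp protocol for rapid A-Ci measurement
#'
#' The default matches the rapid-curve program of a portable gas-exchange
#' system: reference CO2 ramped 30 → 1830 µmol mol⁻¹ at 200 µmol mol⁻¹ min⁻¹,
#' one record every 5 s — 108 records over the 9-minute ramp.
#'
#' @param start,end Ramp endpoints, µmol mol⁻¹ (start < end).
#' @param rate Ramp rate, µmol mol⁻¹ per minute (> 0).
#' @param interval Sampling interval, s (> 0).
#' @param tleaf Leaf temperature, °C.
#' @param q Irradiance, µmol m⁻² s⁻¹.
#' @return Named list of class \code{"ramp_protocol"}.
#' @export
ramp_protocol <- function(start = 30, end = 1830, rate = 200, interval = 5,
                          tleaf = 25, q = 1500) {
  if (start >= end) stop("`start` must be below `end`", call. = FALSE)
  stop_if_not_positive(rate, "rate")
  stop_if_not_positive(interval, "interval")
  structure(list(start = start, end = end, rate = rate, interval = interval,
                 tleaf = tleaf, q = q), class = "ramp_protocol")
}

#' Simulate a rapid A-Ci curve
#'
#' Runs the forward FvCB model along the CO2 ramp and adds Gaussian
#' instrument noise to the assimilation readings (the Ci grid itself is
#' noise-free). Sampling times are \code{interval, 2·interval, ...} up to the
#' ramp duration, so the default protocol yields exactly 108 records.
#'
#' @param params Named vector or list with \code{vcmax25}, \code{jmax25},
#'   \code{rd25} (µmol m⁻² s⁻¹).
#' @param protocol A \code{\link{ramp_protocol}}.
#' @param noise_sd Instrument noise sd on A, µmol m⁻² s⁻¹ (≥ 0).
#' @param seed Integer seed.
#' @param constants \code{\link{fvcb_constants}}.
#' @param plant_id Optional identifier carried on the curve.
#' @return An \code{\link{aci_curve}} with an extra column \code{t_s}.
#' @examples
#' nrow(simulate_aci(c(vcmax25 = 60, jmax25 = 120, rd25 = 1),
#'                   noise_sd = 0, seed = 1))  # 108
#' @export
simulate_aci <- function(params, protocol = ramp_protocol(), noise_sd = 0.5,
                         seed = 1, constants = fvcb_constants(),
                         plant_id = NA_character_) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  params <- as.list(params)
  duration <- (protocol$end - protocol$start) / protocol$rate * 60
  t_s <- seq(protocol$interval, duration, by = protocol$interval)
  ci <- protocol$start + protocol$rate * t_s / 60
  a0 <- fvcb_assimilation(ci, params$vcmax25, params$jmax25, params$rd25,
                          q = protocol$q, tleaf = protocol$tleaf,
                          constants = constants)
  a <- with_seed(seed, a0 + stats::rnorm(length(ci), 0, noise_sd))
  crv <- aci_curve(ci, a, tleaf = protocol$tleaf, q = protocol$q,
                   plant_id = plant_id)
  crv$t_s <- t_s
  crv
}
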