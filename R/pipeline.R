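#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic pipeline with its
#' operational default: ExG threshold 0.07, CO2 ramp 30 → 1830 µmol mol⁻¹ at
#' 200 µmol mol⁻¹ min⁻¹ sampled every 5 s, 10 CV folds, 2:1
#' calibration:validation split, instrument noise sd 0.5 µmol m⁻² s⁻¹.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param plots_per_treatment,plants_per_plot Field size (default 3 × 14 per
#'   treatment = 210 plants over the five nitrogen levels).
#' @param exg_threshold ExG vegetation threshold.
#' @param protocol \code{\link{ramp_protocol}} for A-Ci simulation.
#' @param noise_sd A-Ci instrument noise, µmol m⁻² s⁻¹.
#' @param folds CV folds for LASSO and PLSR.
#' @param ratio Calibration fraction of the split.
#' @param constants \code{\link{fvcb_constants}}.
#' @param synth \code{\link{synth_params}}.
#' @param scene \code{\link{scene_params}}.
#' @param gsd Ground sample distance of the rendered scene, m/pixel.
#' @return Named list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 42, plots_per_treatment = 3,
                            plants_per_plot = 14, exg_threshold = 0.07,
                            protocol = ramp_protocol(), noise_sd = 0.5,
                            folds = 10, ratio = 2 / 3,
                            constants = fvcb_constants(),
                            synth = synth_params(), scene = scene_params(),
                            gsd = 0.02) {
  structure(as.list(environment()), class = "pipeline_config")
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Build per-plant trait samples from a synthetic field
#'
#' Runs the measurement emulation for every plant: a rapid A-Ci curve is
#' simulated from the plant's true FvCB parameters and fitted to give the
#' "measured" Vcmax25/Jmax25; the plant's canopy ROI (its labelled pixels,
#' refined by the ExG mask) gives the mean reflectance, from which the full
#' index bank is computed.
#'
#' @param truth \code{\link{generate_truth}} table.
#' @param layout Matching \code{\link{field_layout}}.
#' @param scene Matching \code{\link{render_scene}} result.
#' @param config A \code{\link{pipeline_config}}.
#' @return Data frame: \code{plant_id}, \code{plot_id}, \code{treatment},
#'   one column per index, then \code{vcmax25}, \code{jmax25} (A-Ci-fitted)
#'   and \code{vcmax25_true}, \code{jmax25_true}.
#' @export
extract_trait_samples <- function(truth, layout, scene, config = pipeline_config()) {
  exg <- compute_exg(scene)
  veg <- !is.na(exg) & exg > config$exg_threshold
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    roi <- scene$labels == i & veg
    if (!any(roi)) next
    bands <- extract_reflectance(scene, roi)
    idx <- compute_indices(bands)
    crv <- simulate_aci(truth[i, c("vcmax25", "jmax25", "rd25")],
                        protocol = config$protocol,
                        noise_sd = config$noise_sd,
                        seed = derive_seed(config$seed, i),
                        constants = config$constants,
                        plant_id = truth$plant_id[i])
    fit <- fit_aci(crv, constants = config$constants)
    cf <- coef(fit)
    rows[[i]] <- cbind(
      data.frame(plant_id = truth$plant_id[i], plot_id = truth$plot_id[i],
                 treatment = truth$treatment[i]),
      idx,
      data.frame(vcmax25 = cf[["vcmax25"]], jmax25 = cf[["jmax25"]],
                 vcmax25_true = truth$vcmax25[i],
                 jmax25_true = truth$jmax25[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best single-index baseline
#'
#' Fits a univariate regression of the trait on every computable registered
#' index using the calibration set and returns the index with the highest
#' calibration R² together with its validation report.
#'
#' @param cal,val Calibration/validation sample tables from
#'   \code{\link{extract_trait_samples}}.
#' @param trait Column name of the response (e.g. "vcmax25").
#' @return List: \code{index}, \code{model} (\code{"index_model"}),
#'   \code{calibration_r2}, \code{validation} (eval report).
#' @export
best_univariate <- function(cal, val, trait) {
  idx_names <- index_registry(include_stubs = FALSE)$name
  idx_names <- intersect(idx_names, colnames(cal))
  best <- NULL
  best_r2 <- -Inf
  for (nm in idx_names) {
    x <- cal[[nm]]
    if (anyNA(x) || stats::sd(x) == 0) next
    m <- univariate_fit(x, cal[[trait]], index_name = nm)
    if (m$report$r2 > best_r2) {
      best_r2 <- m$report$r2
      best <- m
    }
  }
  if (is.null(best)) stop("no usable index column", call. = FALSE)
  list(index = best$index, model = best, calibration_r2 = best_r2,
       validation = evaluate_predictions(predict(best, val),
                                         val[[trait]]))
}

#' Run the full synthetic pipeline
#'
#' simulate → fit A-Ci → extract reflectance → indices → split → univariate
#' baseline → LASSO+PLSR → evaluate → map. Writes every artifact under
#' \code{workdir} and a JSON manifest with file hashes, the seed and
#' per-stage timings. Idempotent given (config, seed).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param workdir Writable output directory (created if missing).
#' @param quiet Suppress per-stage messages.
#' @return The manifest, invisibly (list with \code{files}, \code{timings},
#'   \code{seed}, \code{results}).
#' @export
run_pipeline <- function(config = pipeline_config(), workdir, quiet = FALSE) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say("stage %-12s %7.2f s", name, timings[[name]])
    out
  }

  truth <- stage("simulate", generate_truth(config$plots_per_treatment,
                                            config$plants_per_plot,
                                            seed = config$seed,
                                            params = config$synth))
  layout <- field_layout(truth)
  scene <- stage("render", render_scene(layout, truth, gsd = config$gsd,
                                        seed = derive_seed(config$seed, 7919),
                                        params = config$scene))
  samples <- stage("measure", extract_trait_samples(truth, layout, scene,
                                                    config))
  sp <- split_dataset(samples, ratio = config$ratio, seed = config$seed)
  cal <- sp$calibration
  val <- sp$validation

  idx_names <- intersect(index_registry(include_stubs = FALSE)$name,
                         colnames(samples))
  results <- list()
  models <- list()
  for (trait in c("vcmax25", "jmax25")) {
    uni <- stage(paste0("uni_", trait),
                 best_univariate(cal, val, trait))
    tm <- stage(paste0("train_", trait),
                fit_trait_model(cal[, idx_names], cal[[trait]],
                                folds = config$folds, seed = config$seed,
                                trait = trait))
    pred_val <- predict(tm, val[, idx_names])
    results[[trait]] <- list(
      best_index = uni$index,
      univariate_validation = uni$validation,
      plsr_validation = evaluate_predictions(pred_val, val[[trait]]),
      n_selected = length(tm$plsr$x_names),
      n_components = tm$plsr$ncomp)
    models[[trait]] <- list(plsr = tm, univariate = uni$model)
  }

  files <- character()
  add_file <- function(path) files <<- c(files, path)
  utils::write.csv(truth, file.path(workdir, "truth.csv"), row.names = FALSE)
  add_file(file.path(workdir, "truth.csv"))
  utils::write.csv(samples, file.path(workdir, "samples.csv"),
                   row.names = FALSE)
  add_file(file.path(workdir, "samples.csv"))
  for (trait in c("vcmax25", "jmax25")) {
    mp <- file.path(workdir, paste0("model_", trait, ".json"))
    write_trait_model(models[[trait]]$plsr, mp)
    add_file(mp)
    map <- stage(paste0("map_", trait),
                 map_traits(scene, models[[trait]]$plsr,
                            exg_threshold = config$exg_threshold))
    if (requireNamespace("tiff", quietly = TRUE)) {
      tp <- file.path(workdir, paste0(trait, "_map.tif"))
      write_trait_map(map, tp)
      add_file(tp)
    }
    ps <- plot_summary(map, layout)
    sp_path <- file.path(workdir, paste0(trait, "_plot_summary.csv"))
    utils::write.csv(ps, sp_path, row.names = FALSE)
    add_file(sp_path)
    results[[trait]]$map_stats <- map$stats
  }
  ev <- do.call(rbind, lapply(c("vcmax25", "jmax25"), function(tr) {
    cbind(data.frame(trait = tr, model = c("best_index", "lasso_plsr")),
          rbind(results[[tr]]$univariate_validation,
                results[[tr]]$plsr_validation))
  }))
  utils::write.csv(ev, file.path(workdir, "evaluation.csv"),
                   row.names = FALSE)
  add_file(file.path(workdir, "evaluation.csv"))

  manifest <- list(seed = config$seed,
                   files = as.list(tools::md5sum(files)),
                   timings = as.list(timings),
                   results = results)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(manifest)
}
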