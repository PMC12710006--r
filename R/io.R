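# Plain-text interchange: A-Ci curves as long CSV, trait models as JSON.

#' Write / read A-Ci curves as long-format CSV
#'
#' Columns: \code{plant_id}, \code{t_s}, \code{Ci}, \code{A}, \code{Tleaf},
#' \code{Q} — one row per gas-exchange record.
#'
#' @param curves A single \code{\link{aci_curve}} or a list of them.
#' @param path CSV path.
#' @return \code{write_aci_curves}: the path, invisibly;
#'   \code{read_aci_curves}: a named list of \code{\link{aci_curve}} objects.
#' @export
write_aci_curves <- function(curves, path) {
  if (inherits(curves, "aci_curve")) curves <- list(curves)
  rows <- lapply(curves, function(crv) {
    data.frame(plant_id = attr(crv, "plant_id"),
               t_s = if (!is.null(crv$t_s)) crv$t_s else seq_len(nrow(crv)),
               Ci = crv$ci, A = crv$a, Tleaf = crv$tleaf,
               Q = attr(crv, "q"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aci_curves
#' @export
read_aci_curves <- function(path) {
  df <- utils::read.csv(path)
  ids <- unique(df$plant_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$plant_id == id, ]
    crv <- aci_curve(sub$Ci, sub$A, tleaf = sub$Tleaf, q = sub$Q[1],
                     plant_id = as.character(id))
    crv$t_s <- sub$t_s
    crv
  })
  stats::setNames(out, ids)
}

#' Write / read a PLSR trait model as JSON
#'
#' Serialises everything needed to predict and to audit the fit: selected
#' index names, centring/scaling vectors, weights, loadings, component
#' count, regression coefficients, VIP scores and (when present) the LASSO
#' penalty.
#'
#' @param model A \code{"trait_model"} or \code{"plsr_trait_model"}.
#' @param path JSON path.
#' @return \code{write_trait_model}: the path, invisibly;
#'   \code{read_trait_model}: a \code{"plsr_trait_model"} usable with
#'   \code{predict()} and \code{\link{map_traits}}.
#' @export
write_trait_model <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the `jsonlite` package is required", call. = FALSE)
  }
  lambda <- NULL
  lasso_selected <- NULL
  if (inherits(model, "trait_model")) {
    lambda <- model$selection$lambda
    lasso_selected <- model$selection$selected
    model <- model$plsr
  }
  obj <- list(trait = model$trait, x_names = model$x_names,
              x_center = model$x_center, x_scale = model$x_scale,
              y_center = model$y_center, W = model$W, P = model$P,
              q = model$q, tt = model$tt, ncomp = model$ncomp,
              coefficients = model$coefficients, vip = as.numeric(model$vip),
              lasso_lambda = lambda, lasso_selected = lasso_selected)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trait_model
#' @export
read_trait_model <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the `jsonlite` package is required", call. = FALSE)
  }
  o <- jsonlite::fromJSON(path)
  W <- matrix(unlist(o$W), ncol = o$ncomp)
  P <- matrix(unlist(o$P), ncol = o$ncomp)
  cf <- unlist(o$coefficients)
  model <- structure(list(
    trait = o$trait, x_names = o$x_names,
    x_center = stats::setNames(unlist(o$x_center), o$x_names),
    x_scale = stats::setNames(unlist(o$x_scale), o$x_names),
    y_center = o$y_center, W = W, P = P, q = unlist(o$q), tt = unlist(o$tt),
    ncomp = o$ncomp,
    coefficients = stats::setNames(cf, c("(Intercept)", o$x_names)),
    lasso_lambda = o$lasso_lambda, lasso_selected = o$lasso_selected),
    class = "plsr_trait_model")
  model$vip <- stats::setNames(unlist(o$vip), o$x_names)
  model
}
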