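# Registry of broad-band spectral indices over the five reflectance bands
# B, G, R, RE, NIR. Entries are stored as expressions so the registry can be
# serialised to / extended from a plain JSON config.

.index_registry <- new.env(parent = emptyenv())

#' Register a spectral index
#'
#' Adds (or replaces) an index definition. Definitions are arithmetic
#' expressions over the band symbols \code{B}, \code{G}, \code{R}, \code{RE},
#' \code{NIR} (and previously registered index names are \emph{not} visible —
#' each formula is self-contained). Division by zero, negative square roots
#' and other guard violations evaluate to a flagged missing value (\code{NA}),
#' never an error, so batch computation is robust.
#'
#' A \code{NULL} formula registers a named stub: the index is known (e.g. it
#' appears in published index collections) but its formula is not, and
#' computing it raises an "unregistered formula" error until the user supplies
#' a definition.
#'
#' @param name Index name (unique key; may contain "/", e.g. "1/G").
#' @param formula Character expression, e.g. \code{"(NIR - R)/(NIR + R)"}, or
#'   \code{NULL} for a stub.
#' @param overwrite Replace an existing definition.
#' @return The name, invisibly.
#' @examples
#' register_index("NDVI_dup", "(NIR - R)/(NIR + R)", overwrite = TRUE)
#' @export
register_index <- function(name, formula, overwrite = FALSE) {
  if (!overwrite && !is.null(.index_registry[[name]])) {
    stop(sprintf("index '%s' already registered", name), call. = FALSE)
  }
  order <- if (!is.null(.index_registry[[name]])) {
    .index_registry[[name]]$order
  } else {
    length(ls(.index_registry)) + 1L
  }
  entry <- if (is.null(formula)) {
    list(name = name, formula = NA_character_, expr = NULL, stub = TRUE,
         order = order)
  } else {
    list(name = name, formula = formula,
         expr = parse(text = formula)[[1]], stub = FALSE, order = order)
  }
  assign(name, entry, envir = .index_registry)
  invisible(name)
}

# Main-text index set. Stubs at the end are indices whose formulas live only
# in an unavailable supplement; they are named but not computable.
DEFAULT_INDEX_FORMULAS <- list(
  NDVI     = "(NIR - R) / (NIR + R)",
  NDRE     = "(NIR - RE) / (NIR + RE)",
  SCCCI    = "((NIR - RE) / (NIR + RE)) / ((NIR - R) / (NIR + R))",
  CVI      = "NIR * R / G^2",
  CI_green = "NIR / G - 1",
  CI_RE    = "NIR / RE - 1",
  GNDVI    = "(NIR - G) / (NIR + G)",
  VIg      = "(G - R) / (G + R)",
  VARI     = "(G - R) / (G + R - B)",
  GRRI     = "G / R",
  GBRI     = "G / B",
  IKAW     = "(R - B) / (R + B)",
  MGRVI    = "(G^2 - R^2) / (G^2 + R^2)",
  RGBVI    = "(G^2 - B * R) / (G^2 + B * R)",
  GLI      = "(2 * G - R - B) / (2 * G + R + B)",
  ExG      = "2 * G - R - B",
  ExB      = "1.4 * B - G",
  SIPI     = "(NIR - B) / (NIR - R)",
  MSAVI2   = "(2 * NIR + 1 - sqrt((2 * NIR + 1)^2 - 8 * (NIR - R))) / 2",
  MCARI2   = paste("1.5 * (2.5 * (NIR - R) - 1.3 * (NIR - G)) /",
                   "sqrt((2 * NIR + 1)^2 - (6 * NIR - 5 * sqrt(R)) - 0.5)"),
  R = "R", B = "B", G = "G", RE = "RE", NIR = "NIR",
  `1/B` = "1 / B", `1/G` = "1 / G", `1/R` = "1 / R",
  `1/RE` = "1 / RE", `1/NIR` = "1 / NIR",
  g = "G / (R + G + B)",
  b = "B / (R + G + B)"
)

DEFAULT_INDEX_STUBS <- c("IPCA", "CI2", "WI", "NDI", "VIre")

reset_index_registry <- function() {
  rm(list = ls(.index_registry), envir = .index_registry)
  for (nm in names(DEFAULT_INDEX_FORMULAS)) {
    register_index(nm, DEFAULT_INDEX_FORMULAS[[nm]], overwrite = TRUE)
  }
  for (nm in DEFAULT_INDEX_STUBS) {
    register_index(nm, NULL, overwrite = TRUE)
  }
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  reset_index_registry()
}

registry_entries <- function() {
  entries <- mget(ls(.index_registry), envir = .index_registry)
  entries[order(vapply(entries, `[[`, integer(1), "order"))]
}

#' List the index registry
#'
#' @param include_stubs Include named-but-formula-less entries.
#' @return Data frame with columns \code{name}, \code{formula}, \code{stub},
#'   in registration order.
#' @export
index_registry <- function(include_stubs = TRUE) {
  entries <- registry_entries()
  out <- data.frame(
    name = vapply(entries, `[[`, character(1), "name"),
    formula = vapply(entries, `[[`, character(1), "formula"),
    stub = vapply(entries, `[[`, logical(1), "stub"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!include_stubs) out <- out[!out$stub, , drop = FALSE]
  out
}

as_band_list <- function(bands) {
  if (is.matrix(bands) || is.data.frame(bands)) {
    stopifnot(all(BAND_NAMES %in% colnames(bands)))
    lapply(stats::setNames(BAND_NAMES, BAND_NAMES),
           function(b) as.numeric(bands[, b]))
  } else {
    stopifnot(all(BAND_NAMES %in% names(bands)))
    lapply(stats::setNames(BAND_NAMES, BAND_NAMES),
           function(b) as.numeric(bands[[b]]))
  }
}

#' Compute one spectral index
#'
#' Evaluates a registered formula on band reflectance. Guard violations
#' (zero denominators, negative square-root arguments) yield \code{NA}.
#'
#' @param name Registered index name (see \code{\link{index_registry}}).
#' @param bands Named vector/list of band reflectance (\code{B}, \code{G},
#'   \code{R}, \code{RE}, \code{NIR}), or a matrix/data frame with those
#'   columns for vectorised evaluation.
#' @return Numeric value(s), dimensionless.
#' @examples
#' compute_index("SCCCI", c(B = .04, G = .1, R = .1, RE = .3, NIR = .5))
#' @export
compute_index <- function(name, bands) {
  entry <- .index_registry[[name]]
  if (is.null(entry)) {
    stop(sprintf("unknown index '%s'", name), call. = FALSE)
  }
  if (entry$stub) {
    stop(sprintf("index '%s' has an unregistered formula; supply one with register_index()", name),
         call. = FALSE)
  }
  vals <- eval(entry$expr, as_band_list(bands))
  vals[!is.finite(vals)] <- NA_real_
  vals
}

#' Compute all registered indices
#'
#' One column per computable registered index (stubs are skipped), in stable
#' registration order. \code{NA} flags from guarded formulas are propagated.
#'
#' @param bands A named 5-vector, or a matrix/data frame of samples with
#'   columns \code{B}, \code{G}, \code{R}, \code{RE}, \code{NIR}.
#' @return Data frame with one row per sample (column names are index names,
#'   kept verbatim, e.g. \code{"1/G"}).
#' @export
compute_indices <- function(bands) {
  bl <- as_band_list(bands)
  reg <- index_registry(include_stubs = FALSE)
  cols <- lapply(reg$name, function(nm) compute_index(nm, bl))
  out <- as.data.frame(cols, optional = TRUE, check.names = FALSE)
  names(out) <- reg$name
  out
}

#' Serialise or load the index registry
#'
#' Writes the registry (names and formula strings; stubs with null formulas)
#' as JSON so users can extend it to a fuller published index bank, and loads
#' such a file back, replacing the current registry.
#'
#' @param path JSON file path.
#' @return \code{write_index_registry}: the path, invisibly;
#'   \code{read_index_registry}: the number of entries loaded, invisibly.
#' @export
write_index_registry <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the `jsonlite` package is required", call. = FALSE)
  }
  reg <- index_registry(include_stubs = TRUE)
  reg$formula[reg$stub] <- NA_character_
  jsonlite::write_json(reg[, c("name", "formula")], path, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_index_registry
#' @export
read_index_registry <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the `jsonlite` package is required", call. = FALSE)
  }
  reg <- jsonlite::fromJSON(path)
  rm(list = ls(.index_registry), envir = .index_registry)
  for (i in seq_len(nrow(reg))) {
    f <- reg$formula[i]
    register_index(reg$name[i], if (is.na(f)) NULL else f, overwrite = TRUE)
  }
  invisible(nrow(reg))
}
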