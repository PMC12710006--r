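#' Default FvCB kinetic constants and activation energies
#'
#' Rubisco kinetics at 25 °C (Bernacchi-type in vivo values, the defaults of
#' the standard A-Ci fitting tools), oxygen partial pressure, activation
#' energies for Arrhenius temperature scaling, and the light-response
#' parameters of electron transport.
#'
#' @param gammastar25 CO2 compensation point in the absence of day respiration
#'   at 25 °C, µmol mol⁻¹.
#' @param kc25,ko25 Rubisco Michaelis constants for CO2 (µmol mol⁻¹) and O2
#'   (mmol mol⁻¹) at 25 °C.
#' @param o Oxygen partial pressure, mmol mol⁻¹.
#' @param ea_vcmax,ea_jmax,ea_rd,ea_gammastar,ea_kc,ea_ko Activation energies,
#'   J mol⁻¹.
#' @param theta Curvature of the electron-transport light response,
#'   dimensionless in (0, 1).
#' @param alpha Quantum yield of electron transport, dimensionless in (0, 0.5).
#' @return A named list of class \code{"fvcb_constants"}.
#' @examples
#' fvcb_constants()
#' @export
fvcb_constants <- function(gammastar25 = 42.75, kc25 = 404.9, ko25 = 278.4,
                           o = 210,
                           ea_vcmax = 65330, ea_jmax = 43540, ea_rd = 46390,
                           ea_gammastar = 37830, ea_kc = 79430, ea_ko = 36380,
                           theta = 0.85, alpha = 0.24) {
  stopifnot(gammastar25 > 0, kc25 > 0, ko25 > 0, o > 0,
            theta > 0, theta < 1, alpha > 0, alpha < 0.5)
  structure(list(gammastar25 = gammastar25, kc25 = kc25, ko25 = ko25, o = o,
                 ea_vcmax = ea_vcmax, ea_jmax = ea_jmax, ea_rd = ea_rd,
                 ea_gammastar = ea_gammastar, ea_kc = ea_kc, ea_ko = ea_ko,
                 theta = theta, alpha = alpha),
            class = "fvcb_constants")
}

GAS_CONSTANT <- 8.314  # J mol^-1 K^-1

#' Arrhenius temperature scaling of a biochemical rate
#'
#' Scales a rate referenced to 25 °C to the leaf temperature
#' \code{tleaf} via \eqn{k(T) = k_{25} \exp[E_a (T - 298.15) / (298.15 R T)]}
#' with \eqn{T} in kelvin and \eqn{R = 8.314} J mol⁻¹ K⁻¹.
#' \code{arrhenius_normalize()} is the inverse direction (a value measured at
#' \code{tleaf} divided by the same factor, i.e. referenced back to 25 °C).
#'
#' @param k25 Rate at 25 °C (any positive unit).
#' @param ea Activation energy, J mol⁻¹.
#' @param tleaf Leaf temperature, °C. Vectorised.
#' @return Scaled rate(s), same unit as \code{k25}.
#' @examples
#' arrhenius_scale(404.9, 79430, 35)
#' @export
arrhenius_scale <- function(k25, ea, tleaf) {
  stopifnot(all(k25 >= 0))
  if (any(tleaf <= -273.15)) {
    stop("`tleaf` must be above absolute zero (-273.15 °C)", call. = FALSE)
  }
  tk <- tleaf + 273.15
  k25 * exp(ea * (tk - 298.15) / (298.15 * GAS_CONSTANT * tk))
}

#' @rdname arrhenius_scale
#' @param kt Rate measured at \code{tleaf}.
#' @export
arrhenius_normalize <- function(kt, ea, tleaf) {
  kt / arrhenius_scale(1, ea, tleaf) * 1
}

# Lower root of theta*J^2 - (alpha*Q + Jmax)*J + alpha*Q*Jmax = 0:
# the realised electron transport rate at irradiance Q.
electron_transport <- function(jmax, q, theta, alpha) {
  b <- alpha * q + jmax
  (b - sqrt(b^2 - 4 * theta * alpha * q * jmax)) / (2 * theta)
}

#' Forward FvCB net assimilation
#'
#' Net CO2 assimilation of a C3 leaf as the minimum of the Rubisco-limited
#' rate \eqn{A_c = V_{cmax}(C_i - \Gamma^*)/(C_i + K_c(1 + O/K_o))} and the
#' RuBP-regeneration-limited rate \eqn{A_j = J(C_i - \Gamma^*)/(4C_i +
#' 8\Gamma^*)}, minus day respiration \eqn{R_d}. \eqn{J} is the lower root of
#' the non-rectangular hyperbola in irradiance. All parameters are referenced
#' to 25 °C and Arrhenius-scaled to \code{tleaf}.
#'
#' @param ci Intercellular CO2, µmol mol⁻¹ (vector allowed, must be ≥ 0).
#' @param vcmax25,jmax25,rd25 FvCB parameters at 25 °C, µmol m⁻² s⁻¹.
#' @param q Irradiance, µmol m⁻² s⁻¹.
#' @param tleaf Leaf temperature, °C (scalar or one per \code{ci}).
#' @param constants A \code{\link{fvcb_constants}} list.
#' @param details If \code{TRUE}, return a list with \code{a}, \code{ac},
#'   \code{aj} and the per-point \code{limitation} ("rubisco" or "rubp").
#' @return Net assimilation A (µmol m⁻² s⁻¹), or a list when
#'   \code{details = TRUE}.
#' @examples
#' fvcb_assimilation(ci = 300, vcmax25 = 60, jmax25 = 120, rd25 = 1)
#' @export
fvcb_assimilation <- function(ci, vcmax25, jmax25, rd25, q = 1500, tleaf = 25,
                              constants = fvcb_constants(), details = FALSE) {
  if (any(ci < 0)) stop("`ci` must be non-negative", call. = FALSE)
  k <- constants
  vcmax <- arrhenius_scale(vcmax25, k$ea_vcmax, tleaf)
  jmax  <- arrhenius_scale(jmax25,  k$ea_jmax,  tleaf)
  rd    <- arrhenius_scale(rd25,    k$ea_rd,    tleaf)
  gs    <- arrhenius_scale(k$gammastar25, k$ea_gammastar, tleaf)
  kc    <- arrhenius_scale(k$kc25, k$ea_kc, tleaf)
  ko    <- arrhenius_scale(k$ko25, k$ea_ko, tleaf)
  km <- kc * (1 + k$o / ko)
  j <- electron_transport(jmax, q, k$theta, k$alpha)
  ac <- vcmax * (ci - gs) / (ci + km)
  aj <- j * (ci - gs) / (4 * ci + 8 * gs)
  a <- pmin(ac, aj) - rd
  if (!details) return(a)
  list(a = a, ac = ac - rd, aj = aj - rd,
       limitation = ifelse(ac <= aj, "rubisco", "rubp"))
}

#' Construct an A-Ci curve
#'
#' Bundles paired intercellular CO2 and net assimilation measurements with
#' their leaf temperature and irradiance.
#'
#' @param ci Intercellular CO2, µmol mol⁻¹.
#' @param a Net assimilation, µmol m⁻² s⁻¹ (same length as \code{ci}).
#' @param tleaf Leaf temperature, °C (scalar or per point).
#' @param q Irradiance, µmol m⁻² s⁻¹ (positive scalar).
#' @param plant_id Optional identifier.
#' @return A data frame of class \code{"aci_curve"} with columns \code{ci},
#'   \code{a}, \code{tleaf} and attributes \code{q}, \code{plant_id}.
#' @export
aci_curve <- function(ci, a, tleaf = 25, q = 1500, plant_id = NA_character_) {
  if (length(ci) != length(a)) {
    stop("`ci` and `a` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(ci)) || !all(is.finite(a))) {
    stop("`ci` and `a` must be finite", call. = FALSE)
  }
  stop_if_not_positive(q, "q")
  tleaf <- rep_len(tleaf, length(ci))
  structure(data.frame(ci = ci, a = a, tleaf = tleaf),
            q = q, plant_id = plant_id,
            class = c("aci_curve", "data.frame"))
}

# Three documented multi-start points (vcmax25, jmax25, rd25) spanning
# low, mid and high photosynthetic capacity.
FIT_ACI_STARTS <- list(c(50, 100, 1), c(100, 190, 2), c(20, 40, 0.5))

#' Fit the FvCB model to an A-Ci curve
#'
#' Estimates (Vcmax25, Jmax25, Rd25) by bounded nonlinear least squares:
#' Levenberg-Marquardt (\code{minpack.lm::nls.lm}) minimising
#' \eqn{\sum_i (A_i - \hat A(C_{i,i}))^2} from three documented starting
#' points, keeping the best. Kinetic constants are fixed at the values in
#' \code{constants}; the curve's leaf temperature is handled inside the
#' forward model so the returned parameters are already referenced to 25 °C.
#'
#' @param curve An \code{\link{aci_curve}} (or data frame with columns
#'   \code{ci}, \code{a}, optionally \code{tleaf}) of at least 8 points that
#'   span both sides of the Ac/Aj transition.
#' @param constants Fixed kinetics, see \code{\link{fvcb_constants}}.
#' @param init Optional numeric vector \code{c(vcmax25, jmax25, rd25)} used as
#'   an additional starting point.
#' @param lower,upper Box bounds on \code{c(vcmax25, jmax25, rd25)}.
#' @return An object of class \code{"fvcb_fit"} with components
#'   \code{coefficients} (vcmax25, jmax25, rd25), \code{constants},
#'   \code{rmse_fit}, per-point \code{limitation}, \code{converged},
#'   \code{fitted.values}, \code{residuals} and the input \code{curve}.
#' @seealso \code{\link{fvcb_assimilation}}, \code{\link{trait_summary}}
#' @examples
#' truth <- c(vcmax25 = 80, jmax25 = 160, rd25 = 1.2)
#' crv <- simulate_aci(truth, noise_sd = 0, seed = 1)
#' coef(fit_aci(crv))
#' @export
fit_aci <- function(curve, constants = fvcb_constants(), init = NULL,
                    lower = c(1, 1, 0), upper = c(600, 1200, 10)) {
  ci <- curve$ci
  a <- curve$a
  if (is.null(ci) || is.null(a)) {
    stop("`curve` must have columns `ci` and `a`", call. = FALSE)
  }
  if (anyNA(ci) || anyNA(a) || !all(is.finite(ci)) || !all(is.finite(a))) {
    stop("NaN/NA in A-Ci inputs", call. = FALSE)
  }
  if (length(ci) < 8) stop("need at least 8 A-Ci points", call. = FALSE)
  if (diff(range(ci)) == 0) {
    stop("all `ci` values identical; cannot fit", call. = FALSE)
  }
  tleaf <- if (!is.null(curve$tleaf)) curve$tleaf else 25
  q <- attr(curve, "q")
  if (is.null(q)) q <- if (!is.null(curve$q)) curve$q[1] else 1500

  resid_fun <- function(p) {
    a - fvcb_assimilation(ci, p[1], p[2], p[3], q = q, tleaf = tleaf,
                          constants = constants)
  }
  starts <- FIT_ACI_STARTS
  if (!is.null(init)) starts <- c(list(as.numeric(init)), starts)

  best <- NULL
  best_sse <- Inf
  converged <- FALSE
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, lower), upper), fn = resid_fun,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
      converged <- fit$info %in% 1:4
    }
  }
  if (is.null(best)) {
    stop("FvCB optimisation failed from every start", call. = FALSE)
  }
  p <- unname(best$par)
  det <- fvcb_assimilation(ci, p[1], p[2], p[3], q = q, tleaf = tleaf,
                           constants = constants, details = TRUE)
  structure(list(
    coefficients = c(vcmax25 = p[1], jmax25 = p[2], rd25 = p[3]),
    constants = constants,
    q = q,
    rmse_fit = sqrt(best_sse / length(a)),
    limitation = det$limitation,
    converged = converged,
    fitted.values = det$a,
    residuals = a - det$a,
    curve = curve), class = "fvcb_fit")
}

#' @export
coef.fvcb_fit <- function(object, ...) object$coefficients

#' @export
fitted.fvcb_fit <- function(object, ...) object$fitted.values

#' @export
residuals.fvcb_fit <- function(object, ...) object$residuals

#' Predict net assimilation from a fitted FvCB model
#'
#' @param object A \code{"fvcb_fit"}.
#' @param newdata Optional data frame with columns \code{ci} and optionally
#'   \code{tleaf}, \code{q}; defaults to the fitting data.
#' @param ... Unused.
#' @return Predicted A, µmol m⁻² s⁻¹.
#' @export
predict.fvcb_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  p <- object$coefficients
  tleaf <- if (!is.null(newdata$tleaf)) newdata$tleaf else 25
  q <- if (!is.null(newdata$q)) newdata$q[1] else object$q
  fvcb_assimilation(newdata$ci, p[1], p[2], p[3], q = q, tleaf = tleaf,
                    constants = object$constants)
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat("FvCB A-Ci fit\n")
  cat(sprintf("  Vcmax25 = %.2f, Jmax25 = %.2f, Rd25 = %.3f umol m-2 s-1\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  RMSE = %.3f over %d points (%d Rubisco-limited), %s\n",
              x$rmse_fit, length(x$limitation),
              sum(x$limitation == "rubisco"),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.fvcb_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  Jmax:Vcmax ratio = %.2f\n",
              object$coefficients[2] / object$coefficients[1]))
  invisible(object)
}

#' Plot an A-Ci curve with its FvCB fit
#'
#' Points are coloured by the fitted limitation state (Rubisco vs RuBP
#' regeneration); the line is the fitted model over a fine Ci grid.
#'
#' @param x A \code{"fvcb_fit"}.
#' @param ... Passed to \code{plot()}.
#' @export
plot.fvcb_fit <- function(x, ...) {
  crv <- x$curve
  cols <- ifelse(x$limitation == "rubisco", "#D55E00", "#0072B2")
  plot(crv$ci, crv$a, col = cols, pch = 16,
       xlab = expression(C[i] ~ (mu * mol ~ mol^-1)),
       ylab = expression(A ~ (mu * mol ~ m^-2 ~ s^-1)), ...)
  grid_ci <- seq(min(crv$ci), max(crv$ci), length.out = 200)
  lines(grid_ci, predict(x, data.frame(ci = grid_ci,
                                       tleaf = mean(crv$tleaf))))
  legend("bottomright", pch = 16, col = c("#D55E00", "#0072B2"),
         legend = c("Rubisco-limited", "RuBP-limited"), bty = "n")
  invisible(x)
}

#' Per-plant photosynthetic trait summary
#'
#' Averages leaf-level fitted traits to one value per plant (the arithmetic
#' mean over the measured top leaves). Only converged fits contribute; a plant
#' whose fits all failed to converge is returned with \code{NA} traits and
#' \code{ok = FALSE}.
#'
#' @param fits List of \code{"fvcb_fit"} objects.
#' @param plant_ids Character/factor vector, one id per fit.
#' @return Data frame with one row per plant: \code{plant_id}, \code{vcmax25},
#'   \code{jmax25}, \code{rd25}, \code{n_leaves}, \code{n_converged},
#'   \code{ok}.
#' @export
trait_summary <- function(fits, plant_ids) {
  if (length(fits) != length(plant_ids)) {
    stop("`fits` and `plant_ids` must have the same length", call. = FALSE)
  }
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  ids <- unique(as.character(plant_ids))
  rows <- lapply(ids, function(id) {
    sel <- fits[as.character(plant_ids) == id]
    conv <- vapply(sel, function(f) isTRUE(f$converged), logical(1))
    cf <- vapply(sel[conv], coef, numeric(3))
    if (sum(conv) == 0) {
      data.frame(plant_id = id, vcmax25 = NA_real_, jmax25 = NA_real_,
                 rd25 = NA_real_, n_leaves = length(sel), n_converged = 0L,
                 ok = FALSE)
    } else {
      m <- rowMeans(matrix(cf, nrow = 3))
      data.frame(plant_id = id, vcmax25 = m[1], jmax25 = m[2], rd25 = m[3],
                 n_leaves = length(sel), n_converged = sum(conv), ok = TRUE)
    }
  })
  do.call(rbind, rows)
}
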