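#' Split samples into calibration and validation sets
#'
#' Seeded random split. The calibration set gets \code{round(N * ratio)}
#' samples, the validation set the remainder; with the default 2:1 ratio,
#' 204 samples split into 136 and 68.
#'
#' @param x A data frame of samples, or a single integer N (split indices
#'   only).
#' @param ratio Calibration fraction, strictly inside (0, 1); default 2/3.
#' @param seed Integer seed.
#' @return List with elements \code{calibration} and \code{validation}:
#'   row subsets of \code{x} (or index vectors when \code{x} is a count).
#' @examples
#' lengths(split_dataset(204, seed = 1))  # 136, 68
#' @export
split_dataset <- function(x, ratio = 2 / 3, seed = 1) {
  if (ratio <= 0 || ratio >= 1) {
    stop("`ratio` must be strictly between 0 and 1", call. = FALSE)
  }
  n <- if (is.data.frame(x)) nrow(x) else stop_if_not_count(x, "x")
  if (n < 3) stop("need at least 3 samples to split", call. = FALSE)
  n_cal <- round(n * ratio)
  idx <- with_seed(seed, sample.int(n))
  cal <- sort(idx[seq_len(n_cal)])
  val <- sort(idx[(n_cal + 1):n])
  if (is.data.frame(x)) {
    list(calibration = x[cal, , drop = FALSE],
         validation = x[val, , drop = FALSE])
  } else {
    list(calibration = cal, validation = val)
  }
}

#' Accuracy metrics for trait predictions
#'
#' Computes the standard evaluation report: coefficient of determination
#' \eqn{R^2 = 1 - \sum(o - p)^2 / \sum(o - \bar o)^2}, absolute Pearson
#' correlation r, RMSE, bias = mean(predicted − observed), and relative RMSE
#' = 100·RMSE / mean(observed) in percent.
#'
#' @param predicted,observed Equal-length numeric vectors (n ≥ 2).
#' @return One-row data frame of class \code{"eval_report"} with columns
#'   \code{r2}, \code{r}, \code{rmse}, \code{bias}, \code{rrmse_percent},
#'   \code{n}. With zero variance in \code{observed}, \code{r2} and \code{r}
#'   are \code{NA}.
#' @examples
#' evaluate_predictions(c(1, 2, 5), c(1, 2, 3))
#' @export
evaluate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 pairs", call. = FALSE)
  err <- predicted - observed
  rmse <- sqrt(mean(err^2))
  sstot <- sum((observed - mean(observed))^2)
  r2 <- if (sstot > 0) 1 - sum(err^2) / sstot else NA_real_
  r <- if (sstot > 0 && stats::sd(predicted) > 0) {
    abs(stats::cor(predicted, observed))
  } else {
    NA_real_
  }
  structure(data.frame(r2 = r2, r = r, rmse = rmse, bias = mean(err),
                       rrmse_percent = 100 * rmse / mean(observed),
                       n = length(observed)),
            class = c("eval_report", "data.frame"))
}

#' Univariate spectral-index regression
#'
#' Ordinary least squares of a trait on a single spectral index, the baseline
#' against which the multivariate model is compared.
#'
#' @param index_values Predictor vector (one index).
#' @param trait Response vector, same length (n ≥ 3).
#' @param index_name Name carried on the model (used for mapping).
#' @return Object of class \code{"index_model"}: \code{slope},
#'   \code{intercept}, \code{index}, and \code{report}
#'   (an \code{\link{evaluate_predictions}} table on the fitting set).
#' @export
univariate_fit <- function(index_values, trait, index_name = "index") {
  if (length(index_values) != length(trait)) {
    stop("lengths differ", call. = FALSE)
  }
  if (length(trait) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(index_values) == 0) {
    stop("zero-variance predictor", call. = FALSE)
  }
  fit <- stats::lm(trait ~ index_values)
  cf <- unname(stats::coef(fit))
  structure(list(slope = cf[2], intercept = cf[1], index = index_name,
                 report = evaluate_predictions(unname(stats::fitted(fit)),
                                               trait)),
            class = "index_model")
}

#' @export
predict.index_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata) || is.matrix(newdata)) {
    newdata[, object$index]
  } else {
    newdata
  }
  object$intercept + object$slope * as.numeric(x)
}

#' @export
print.index_model <- function(x, ...) {
  cat(sprintf("univariate index model: trait = %.4g + %.4g * %s (R2 = %.3f)\n",
              x$intercept, x$slope, x$index, x$report$r2))
  invisible(x)
}

seeded_folds <- function(n, folds, seed) {
  if (n <= folds) stop("need more samples than folds", call. = FALSE)
  with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

#' LASSO selection of spectral indices
#'
#' L1-penalised linear regression of a trait on the index bank (via
#' \pkg{glmnet}). Columns are standardised internally; the penalty path runs
#' geometrically from \eqn{\lambda_{max}} (the smallest penalty that zeroes
#' every coefficient) down four decades, and \eqn{\lambda^*} minimises the
#' 10-fold cross-validated mean squared error, with ties broken toward the
#' sparser model (larger \eqn{\lambda}). The selected indices are those with
#' nonzero coefficients at \eqn{\lambda^*}.
#'
#' @param X Matrix or data frame of index values (finite; column names are
#'   the index names).
#' @param y Trait vector (non-constant).
#' @param folds Number of CV folds (n must exceed it).
#' @param seed Integer seed for the fold assignment.
#' @param n_lambda Number of penalties on the path.
#' @return Object of class \code{"lasso_selection"}: \code{selected} (names),
#'   \code{lambda} (\eqn{\lambda^*}), \code{coefficients} (at \eqn{\lambda^*},
#'   on the original scale, incl. intercept), \code{cv} (path table).
#' @export
lasso_select <- function(X, y, folds = 10, seed = 1, n_lambda = 100) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  if (stats::sd(y) == 0) stop("`y` is constant", call. = FALSE)
  foldid <- seeded_folds(nrow(X), folds, seed)
  lmax <- max(glmnet::glmnet(X, y, standardize = TRUE)$lambda)
  lambda <- lmax * 10^seq(0, -4, length.out = n_lambda)
  cv <- glmnet::cv.glmnet(X, y, lambda = lambda, foldid = foldid,
                          standardize = TRUE)
  # lambda is stored in decreasing order; first minimiser = sparsest model
  best <- which(cv$cvm == min(cv$cvm))[1]
  lambda_star <- cv$lambda[best]
  cf <- as.matrix(stats::coef(cv, s = lambda_star))
  nz <- rownames(cf)[cf[, 1] != 0]
  structure(list(selected = setdiff(nz, "(Intercept)"),
                 lambda = lambda_star,
                 coefficients = cf[, 1],
                 cv = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                                 nzero = cv$nzero)),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("LASSO selection: %d indices at lambda = %.5g\n",
              length(x$selected), x$lambda))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# --- PLS1 (NIPALS) -----------------------------------------------------------

# One-response NIPALS on pre-centred/scaled X and centred y. Returns the
# weight/loading matrices and per-component explained y-variance pieces
# needed for prediction and VIP.
nipals_pls1 <- function(Xs, ys, ncomp) {
  p <- ncol(Xs)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  tt <- numeric(ncomp)
  Xd <- Xs
  yd <- ys
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    t <- drop(Xd %*% w)
    t2 <- sum(t^2)
    pl <- drop(crossprod(Xd, t)) / t2
    q <- sum(yd * t) / t2
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - q * t
    W[, a] <- w
    P[, a] <- pl
    qv[a] <- q
    tt[a] <- t2
  }
  keep <- seq_len(ncomp)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       q = qv[keep], tt = tt[keep], ncomp = ncomp)
}

pls1_coefficients <- function(fit, ncomp) {
  keep <- seq_len(ncomp)
  W <- fit$W[, keep, drop = FALSE]
  P <- fit$P[, keep, drop = FALSE]
  drop(W %*% solve(crossprod(P, W), fit$q[keep]))
}

#' Partial least squares regression of a trait on selected indices
#'
#' PLS1 by the NIPALS algorithm on centred and unit-variance-scaled
#' predictors (response centred only). The number of latent components is
#' chosen by seeded k-fold cross-validation as the RMSE minimiser over
#' 1..min(p, n−1), ties broken toward fewer components.
#'
#' @param X Matrix/data frame of selected index values (≥ 2 columns).
#' @param y Trait vector.
#' @param folds CV folds (default 10; n must exceed it).
#' @param seed Integer seed for fold assignment.
#' @param ncomp Optional fixed component count (skips CV).
#' @param trait Optional trait label carried on the model.
#' @return Object of class \code{"plsr_trait_model"} with the centring/scaling
#'   vectors, weight (\code{W}) and loading (\code{P}) matrices, per-component
#'   y-loadings \code{q} and score norms \code{tt}, the selected
#'   \code{ncomp}, regression \code{coefficients} (original scale),
#'   \code{vip} scores, CV table, fitted values and residuals.
#' @seealso \code{\link{vip_scores}}, \code{\link{fit_trait_model}}
#' @export
fit_plsr <- function(X, y, folds = 10, seed = 1, ncomp = NULL, trait = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) < 1) stop("no predictors", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale == 0)) stop("zero-variance predictor column", call. = FALSE)
  y_center <- mean(y)
  Xs <- scale(X, x_center, x_scale)
  ys <- y - y_center
  ncomp_max <- min(p, n - 1L)

  cv_rmse <- NULL
  if (is.null(ncomp)) {
    foldid <- seeded_folds(n, folds, seed)
    sse <- numeric(ncomp_max)
    cnt <- numeric(ncomp_max)
    for (k in seq_len(folds)) {
      tr <- foldid != k
      a_max <- min(p, sum(tr) - 1L)
      # fold-local centring/scaling, as in standard chemometric CV
      xc <- colMeans(X[tr, , drop = FALSE])
      xs <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      xs[xs == 0] <- 1
      fit <- nipals_pls1(scale(X[tr, , drop = FALSE], xc, xs),
                         y[tr] - mean(y[tr]), a_max)
      Xte <- scale(X[!tr, , drop = FALSE], xc, xs)
      for (a in seq_len(min(fit$ncomp, ncomp_max))) {
        pred <- drop(Xte %*% pls1_coefficients(fit, a)) + mean(y[tr])
        sse[a] <- sse[a] + sum((pred - y[!tr])^2)
        cnt[a] <- cnt[a] + sum(!tr)
      }
    }
    usable <- cnt == n
    cv_rmse <- sqrt(sse / cnt)
    cv_rmse[!usable] <- Inf
    ncomp <- which.min(cv_rmse)  # ties -> smaller model
  }
  if (ncomp > ncomp_max) stop("`ncomp` exceeds min(p, n - 1)", call. = FALSE)

  fit <- nipals_pls1(Xs, ys, ncomp)
  ncomp <- fit$ncomp
  b_scaled <- pls1_coefficients(fit, ncomp)
  b <- b_scaled / x_scale
  intercept <- y_center - sum(b * x_center)
  fitted <- drop(X %*% b) + intercept

  model <- structure(list(
    trait = trait, x_names = colnames(X),
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    W = fit$W, P = fit$P, q = fit$q, tt = fit$tt,
    ncomp = ncomp, ncomp_max = ncomp_max, cv_rmse = cv_rmse,
    coefficients = c("(Intercept)" = intercept,
                     stats::setNames(b, colnames(X))),
    fitted.values = fitted, residuals = y - fitted, y = y,
    folds = folds, seed = seed), class = "plsr_trait_model")
  model$vip <- vip_scores(model)
  model
}

#' Variable importance in projection (VIP)
#'
#' \eqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}} where
#' \eqn{SS_a = q_a^2 t_a^\top t_a} is the response variance captured by
#' component a. The mean of squared VIP scores is exactly 1; indices with
#' VIP > 1 are conventionally flagged as influential.
#'
#' @param model A fitted \code{"plsr_trait_model"}.
#' @return Named numeric vector of VIP scores (attribute
#'   \code{influential}: names with VIP > 1).
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "plsr_trait_model") || is.null(model$W)) {
    stop("`model` must be a fitted plsr_trait_model", call. = FALSE)
  }
  W <- model$W
  p <- nrow(W)
  ss <- model$q^2 * model$tt
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  vip <- sqrt(p * drop(wn^2 %*% ss) / sum(ss))
  names(vip) <- model$x_names
  attr(vip, "influential") <- names(vip)[vip > 1]
  vip
}

#' @export
predict.plsr_trait_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$x_names, drop = FALSE])
  } else {
    as.matrix(newdata)[, object$x_names, drop = FALSE]
  }
  cf <- object$coefficients
  drop(X %*% cf[-1]) + cf[1]
}

#' @export
coef.plsr_trait_model <- function(object, ...) object$coefficients

#' @export
fitted.plsr_trait_model <- function(object, ...) object$fitted.values

#' @export
residuals.plsr_trait_model <- function(object, ...) object$residuals

#' @export
print.plsr_trait_model <- function(x, ...) {
  cat(sprintf("PLSR trait model%s: %d indices, %d component(s)\n",
              if (!is.null(x$trait)) paste0(" [", x$trait, "]") else "",
              length(x$x_names), x$ncomp))
  rep <- evaluate_predictions(x$fitted.values, x$y)
  cat(sprintf("  calibration R2 = %.3f, RMSE = %.3f\n", rep$r2, rep$rmse))
  invisible(x)
}

#' @export
summary.plsr_trait_model <- function(object, ...) {
  print(object)
  vip <- sort(object$vip, decreasing = TRUE)
  cat("  VIP > 1:", paste(names(vip)[vip > 1], collapse = ", "), "\n")
  invisible(object)
}

#' LASSO + PLSR trait model
#'
#' The two-stage estimator: LASSO picks the informative spectral indices,
#' then a PLS regression with cross-validated component count is fitted on
#' the selected columns. If the LASSO keeps fewer than two indices, the
#' selection is topped up with the indices most correlated with the trait so
#' the PLS stage is well-posed.
#'
#' @param X Full index table (samples × indices).
#' @param y Trait vector.
#' @param folds CV folds for both stages.
#' @param seed Integer seed (both stages).
#' @param trait Optional label.
#' @return Object of class \code{"trait_model"}: \code{selection}
#'   (\code{"lasso_selection"}), \code{plsr} (\code{"plsr_trait_model"}),
#'   \code{trait}.
#' @export
fit_trait_model <- function(X, y, folds = 10, seed = 1, trait = NULL) {
  X <- as.data.frame(X, check.names = FALSE)
  sel <- lasso_select(X, y, folds = folds, seed = seed)
  keep <- sel$selected
  if (length(keep) < 2) {
    cors <- abs(vapply(X, function(col) {
      if (stats::sd(col) == 0) 0 else stats::cor(col, y)
    }, numeric(1)))
    extra <- names(sort(cors, decreasing = TRUE))
    keep <- unique(c(keep, extra))[seq_len(2)]
  }
  plsr <- fit_plsr(X[, keep, drop = FALSE], y, folds = folds, seed = seed,
                   trait = trait)
  structure(list(selection = sel, plsr = plsr, trait = trait),
            class = "trait_model")
}

#' @export
predict.trait_model <- function(object, newdata, ...) {
  predict(object$plsr, newdata, ...)
}

#' @export
coef.trait_model <- function(object, ...) coef(object$plsr)

#' @export
print.trait_model <- function(x, ...) {
  print(x$selection)
  print(x$plsr)
  invisible(x)
}

#' Required index columns of a prediction model
#'
#' @param model An \code{"index_model"}, \code{"plsr_trait_model"} or
#'   \code{"trait_model"}.
#' @return Character vector of index names the model needs.
#' @export
model_indices <- function(model) {
  if (inherits(model, "index_model")) return(model$index)
  if (inherits(model, "trait_model")) return(model$plsr$x_names)
  if (inherits(model, "plsr_trait_model")) return(model$x_names)
  stop("unsupported model type", call. = FALSE)
}
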