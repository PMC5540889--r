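# NIPALS PLS1 with a full coefficient path. For a univariate response the
# NIPALS iteration converges in one step per component, so each factor has a
# closed form: w = X'y / ||X'y||, t = X w, p = X't / t't, q = y't / t't,
# then X is deflated by t p'. Regression coefficients for the first a
# factors are accumulated through the basis r_a = w_a - sum_j (p_j' w_a) r_j.
pls1_nipals <- function(X, y, n_factors) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  if (stats::sd(y) == 0) {
    stop("degenerate response: y has zero variance", call. = FALSE)
  }
  A <- as.integer(n_factors)
  if (A < 1L || A > min(n - 1L, p)) {
    stop("n_factors must be in [1, min(rows - 1, columns)]", call. = FALSE)
  }
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  R <- matrix(0, p, A)                # W (P'W)^{-1}, built incrementally
  coef_path <- matrix(0, p, A)        # column a: coefficients using factors 1..a
  b <- numeric(p)
  a_used <- 0L
  tol <- 1e-12 * max(1, sum(Xc^2))
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn^2 <= tol) break             # no covariance left to model
    w <- w / wn
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt <= tol) break
    pvec <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pvec)
    yc <- yc - t * qa
    r <- w
    if (a > 1L) {
      for (j in seq_len(a - 1L)) r <- r - sum(P[, j] * w) * R[, j]
    }
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa; R[, a] <- r
    b <- b + r * qa
    coef_path[, a] <- b
    a_used <- a
  }
  if (a_used == 0L) {
    stop("degenerate predictors: centered X has no variance aligned with y",
         call. = FALSE)
  }
  list(
    x_mean = x_mean, y_mean = y_mean,
    weights = W[, seq_len(a_used), drop = FALSE],
    x_loadings = P[, seq_len(a_used), drop = FALSE],
    scores = Tm[, seq_len(a_used), drop = FALSE],
    y_loadings = q[seq_len(a_used)],
    coef_path = coef_path[, seq_len(a_used), drop = FALSE],
    n_factors_fit = a_used
  )
}

#' Fit a PLS1 regression model for one trait
#'
#' Partial least squares regression of a single chemical trait on the plant
#' reflectance spectra, computed with the NIPALS algorithm on mean-centered,
#' unscaled data (the standard treatment for reflectance spectra, where all
#' predictors share a unit). Deterministic: no random initialization.
#'
#' @param X calibration spectra, plants in rows, bands in columns.
#' @param y calibration trait values, one per row of `X`.
#' @param n_factors number of latent factors, in
#'   `[1, min(nrow(X) - 1, ncol(X))]`. If the spectra run out of usable rank
#'   earlier, the model is truncated with a warning.
#' @param trait optional trait name carried into reports.
#' @return A `plsr_model`: `x_mean`, `y_mean`, `weights` (bands x factors),
#'   `x_loadings`, `y_loadings`, `scores` (calibration scores, mutually
#'   orthogonal), `coefficients` (per-band regression vector at `n_factors`),
#'   `coef_path`, `n_factors`, `trait`.
#' @export
fit_plsr <- function(X, y, n_factors, trait = NA_character_) {
  fit <- pls1_nipals(X, y, n_factors)
  if (fit$n_factors_fit < n_factors) {
    warning(sprintf("rank deficiency: model truncated to %d factor(s)",
                    fit$n_factors_fit), call. = FALSE)
  }
  structure(
    c(fit, list(
      coefficients = fit$coef_path[, fit$n_factors_fit],
      n_factors = fit$n_factors_fit,
      trait = trait
    )),
    class = "plsr_model"
  )
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> trait=%s, %d factors, %d bands\n",
              x$trait, x$n_factors, length(x$coefficients)))
  invisible(x)
}

#' Predict trait values from spectra
#'
#' `yhat = y_mean + (X - x_mean) %*% coefficients`.
#'
#' @param object a `plsr_model`.
#' @param newdata spectra matrix with the model's band count.
#' @param n_factors predict with a truncated factor count (default: the
#'   model's own).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, n_factors = object$n_factors, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("incompatible model: band count mismatch (model has ",
         length(object$x_mean), " bands, data has ", ncol(X), ")", call. = FALSE)
  }
  if (n_factors < 1L || n_factors > object$n_factors) {
    stop("n_factors outside the fitted path", call. = FALSE)
  }
  b <- object$coef_path[, n_factors]
  drop(object$y_mean + sweep(X, 2L, object$x_mean) %*% b)
}

#' Select the PLS factor count by leave-one-out cross-validation
#'
#' For each candidate factor count `a = 1..A`, each plant is left out in
#' turn, the model is refit on the remainder, and the held-out plant is
#' predicted; `RMSE_CV(a)` is the root mean squared error of these held-out
#' predictions (divisor N). The selected size is the smallest `a` attaining
#' the minimum of the curve. `A` is capped at `max_factors`, at
#' `nrow(X) - 2` (so every fold remains fittable), and at `ncol(X)`.
#' The fold loop is deterministic: no randomness is involved.
#'
#' @param X calibration spectra (plants x bands), at least 3 rows.
#' @param y calibration trait values.
#' @param max_factors largest factor count considered (default 12).
#' @return List with `n_factors` (selected), `rmse_cv` (curve over
#'   `1..A`), `cv_predictions` (held-out predictions at the selected size),
#'   and `max_factors_used`.
#' @export
loocv_select <- function(X, y, max_factors = 12L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out selection needs at least 3 rows", call. = FALSE)
  A <- min(as.integer(max_factors), n - 2L, ncol(X))
  if (A < 1L) stop("max_factors too small after capping", call. = FALSE)
  pred <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    fit <- pls1_nipals(X[-i, , drop = FALSE], y[-i], A)
    a_fit <- fit$n_factors_fit
    xc <- X[i, ] - fit$x_mean
    ph <- fit$y_mean + drop(xc %*% fit$coef_path)
    pred[i, seq_len(a_fit)] <- ph
    if (a_fit < A) pred[i, (a_fit + 1L):A] <- ph[a_fit] # rank exhausted: flat
  }
  rmse_cv <- sqrt(colMeans((pred - y)^2))
  sel <- which.min(rmse_cv) # first minimum = smallest factor count on ties
  list(
    n_factors = sel,
    rmse_cv = rmse_cv,
    cv_predictions = pred[, sel],
    max_factors_used = A
  )
}
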