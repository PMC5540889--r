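#' Root mean squared error
#'
#' `sqrt(mean((y - yhat)^2))` with divisor N (not N-1), in the trait's units.
#'
#' @param y measured values.
#' @param yhat predicted values, same length.
#' @return Non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1L) {
    stop("y and yhat must have equal positive length", call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

#' Ratio of performance to deviation
#'
#' `sd(y) / rmse(y, yhat)`: the sample standard deviation of the measured
#' values (divisor N-1, the chemometrics convention) over the prediction
#' RMSE (divisor N). A model no better than predicting the mean scores
#' around 1; higher is better. A zero RMSE (perfect model) has no finite
#' RPD and is signalled as an error rather than returned as `Inf`.
#'
#' @inheritParams rmse
#' @return Positive scalar.
#' @export
rpd <- function(y, yhat) {
  if (length(y) < 2L) stop("RPD needs at least 2 observations", call. = FALSE)
  r <- rmse(y, yhat)
  if (r == 0) {
    stop("RPD undefined: RMSE is zero (perfect prediction)", call. = FALSE)
  }
  stats::sd(y) / r
}

#' Mean absolute percent error, set-mean normalized
#'
#' `mean(|y - yhat|) / mean(y) * 100`: the mean absolute error expressed as
#' a percentage of the evaluated set's own mean measured value. Note this is
#' not the classic per-observation percentage error — the denominator is the
#' single set mean, which keeps the statistic finite for near-zero
#' individual measurements.
#'
#' @inheritParams rmse
#' @return Percent (scalar).
#' @export
mape <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1L) {
    stop("y and yhat must have equal positive length", call. = FALSE)
  }
  m <- mean(y)
  if (m == 0) stop("MAPE undefined: mean of measured values is zero", call. = FALSE)
  mean(abs(y - yhat)) / m * 100
}

#' Coefficient of determination between measured and predicted values
#'
#' Default: the squared Pearson correlation of `y` and `yhat` (the usual
#' reading of "R-squared between lab-measured and model-predicted values").
#' `mode = "one-minus-ssr"` gives the alternative `1 - SSres/SStot`, which
#' also penalizes bias; the two agree when `yhat` is the least-squares fit.
#'
#' @inheritParams rmse
#' @param mode `"pearson-squared"` (default) or `"one-minus-ssr"`.
#' @return Scalar; in `[0, 1]` for the default mode.
#' @export
r_squared <- function(y, yhat, mode = c("pearson-squared", "one-minus-ssr")) {
  mode <- match.arg(mode)
  if (length(y) != length(yhat) || length(y) < 2L) {
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  }
  if (stats::var(y) == 0) stop("R^2 undefined: y has zero variance", call. = FALSE)
  if (mode == "pearson-squared") {
    if (stats::var(yhat) == 0) {
      stop("R^2 undefined: predictions have zero variance", call. = FALSE)
    }
    stats::cor(y, yhat)^2
  } else {
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
}

#' Classify a model by its RPD
#'
#' Standard chemometric quality bands: RPD below 1.5 is poor; 1.5 to 2.0
#' (inclusive) is fair, useful for qualitative screening; above 2.0 up to
#' 3.0 is a good model; above 3.0 supports quantitative analysis.
#'
#' @param rpd positive RPD value.
#' @return One of `"poor"`, `"fair/screening"`, `"good"`, `"quantitative"`.
#' @examples
#' classify_rpd(3.8)  # water-content-grade model
#' classify_rpd(1.09) # not quantifiable
#' @export
classify_rpd <- function(rpd) {
  stopifnot(is.numeric(rpd), length(rpd) == 1L, rpd > 0)
  if (rpd < 1.5) "poor"
  else if (rpd <= 2.0) "fair/screening"
  else if (rpd <= 3.0) "good"
  else "quantitative"
}

eval_stats <- function(y, yhat, trait, phase, model_size,
                       r2_mode = "pearson-squared") {
  data.frame(
    trait = trait, phase = phase, n = length(y),
    r2 = r_squared(y, yhat, mode = r2_mode),
    rmse = rmse(y, yhat),
    rpd = rpd(y, yhat),
    mape = mape(y, yhat),
    model_size = model_size,
    stringsAsFactors = FALSE
  )
}

#' Calibrate and evaluate per-trait PLSR models
#'
#' The full modeling report for a spectra matrix and chemistry table: for
#' each trait, the factor count is chosen by leave-one-out cross-validation
#' on the calibration half ([loocv_select()]), a final model is fit at that
#' size, and both the held-out cross-validation predictions and the
#' untouched validation half are scored with R-squared, RMSE, RPD and MAPE.
#' MAPE and RPD are computed against each evaluated set's own mean/SD.
#'
#' @param spectra matrix of plant spectra, rownames = plant ids.
#' @param chem chemistry data frame with `id` and trait columns.
#' @param split a [stratified_split()] of the plant ids.
#' @param traits trait columns to model (default: all numeric except weights).
#' @param max_factors LOOCV factor cap (default 12).
#' @param r2_mode passed to [r_squared()].
#' @return List with `report` (one row per trait and phase, Table-style),
#'   `models` (named list of `plsr_model`), `scatter` (per-plant measured vs
#'   predicted with species and phase, for calibration-style scatterplots).
#' @export
build_report <- function(spectra, chem, split, traits = NULL,
                         max_factors = 12L, r2_mode = "pearson-squared") {
  stopifnot(inherits(split, "split_spec"))
  spectra <- as.matrix(spectra)
  if (is.null(rownames(spectra))) stop("spectra must have plant-id rownames", call. = FALSE)
  if (is.null(traits)) {
    traits <- intersect(
      c("wc", "n", "p", "k", "mg", "ca", "s", "na", "fe", "mn", "b", "cu", "zn"),
      names(chem)
    )
  }
  keep_bands <- !apply(spectra, 2L, anyNA)
  spectra <- spectra[, keep_bands, drop = FALSE]
  cal_ids <- intersect(split$calibration_ids, rownames(spectra))
  val_ids <- intersect(split$validation_ids, rownames(spectra))
  Xcal <- spectra[cal_ids, , drop = FALSE]
  Xval <- spectra[val_ids, , drop = FALSE]
  chem_idx <- match(c(cal_ids, val_ids), chem$id)
  report <- list(); models <- list(); scatter <- list()
  for (tr in traits) {
    if (!tr %in% names(chem) || anyNA(chem[[tr]])) {
      warning("trait '", tr, "' missing or incomplete; skipped", call. = FALSE)
      next
    }
    ycal <- chem[[tr]][match(cal_ids, chem$id)]
    yval <- chem[[tr]][match(val_ids, chem$id)]
    sel <- loocv_select(Xcal, ycal, max_factors = max_factors)
    model <- fit_plsr(Xcal, ycal, sel$n_factors, trait = tr)
    yhat_val <- predict(model, Xval)
    report[[tr]] <- rbind(
      eval_stats(ycal, sel$cv_predictions, tr, "cross-validation",
                 model$n_factors, r2_mode),
      eval_stats(yval, yhat_val, tr, "validation", model$n_factors, r2_mode)
    )
    models[[tr]] <- model
    species <- if ("species" %in% names(chem)) {
      chem$species[match(c(cal_ids, val_ids), chem$id)]
    } else NA_character_
    scatter[[tr]] <- data.frame(
      trait = tr,
      id = c(cal_ids, val_ids),
      species = species,
      phase = rep(c("cross-validation", "validation"),
                  c(length(cal_ids), length(val_ids))),
      measured = c(ycal, yval),
      predicted = c(sel$cv_predictions, yhat_val),
      stringsAsFactors = FALSE
    )
  }
  list(
    report = do.call(rbind, c(report, list(make.row.names = FALSE))),
    models = models,
    scatter = do.call(rbind, c(scatter, list(make.row.names = FALSE)))
  )
}
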