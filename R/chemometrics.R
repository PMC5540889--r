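#' PCA screening of spectra for outliers
#'
#' Mean-centered principal component analysis of the spectra matrix. A plant
#' is flagged as a potential spectral outlier when any of its first
#' `n_components` scores lies more than 3 standard deviations from that
#' component's mean. Flags are advisory: flagged plants are retained by
#' default, mirroring standard chemometric practice of inspecting rather
#' than discarding (a flagged plant whose chemistry looks ordinary stays in).
#'
#' @param X spectra matrix (plants x bands); rownames used as plant ids.
#' @param n_components number of leading components to screen (default 3).
#' @param sd_limit flag threshold in component standard deviations.
#' @return List with `scores` (plants x components), `loadings`
#'   (bands x components, orthonormal), `explained_variance` (per-component
#'   variance share), `outlier` (logical per plant), `n_components`.
#' @export
pca_screen <- function(X, n_components = 3L, sd_limit = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_components + 1L) {
    stop("need at least n_components + 1 rows", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k_avail <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  k <- min(as.integer(n_components), k_avail)
  if (k < n_components) {
    warning(sprintf("rank-deficient spectra: only %d informative component(s)", k),
            call. = FALSE)
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sdevs <- pc$sdev[seq_len(k)]
  z <- sweep(scores, 2L, sdevs, "/")
  outlier <- apply(abs(z) > sd_limit, 1L, any)
  list(
    scores = scores,
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained_variance = pc$sdev^2 / sum(pc$sdev^2),
    outlier = outlier,
    n_components = k
  )
}

#' Stratified 50/50 calibration/validation split
#'
#' Splits plant ids into a calibration and a validation set so that every
#' stratum (species x treatment cell) is represented as evenly as parity
#' allows: a stratum of size `n` contributes `n * fraction` plants to
#' calibration rounded with a remainder carry across strata (so the overall
#' split hits the requested fraction even when single strata are odd), the
#' members chosen at random but reproducibly from `seed`.
#'
#' @param ids character vector of plant ids.
#' @param strata stratum label per id (e.g. `paste(species, treatment)`).
#' @param fraction calibration fraction in (0, 1); default 0.5.
#' @param seed integer RNG seed; the same seed always yields the same split.
#' @return A `split_spec`: list with `calibration_ids`, `validation_ids`,
#'   `strata` (named by id), `fraction`, `seed`.
#' @export
stratified_split <- function(ids, strata, fraction = 0.5, seed = 1L) {
  ids <- as.character(ids)
  stopifnot(length(ids) == length(strata), !anyDuplicated(ids),
            fraction > 0, fraction < 1)
  strata <- as.character(strata)
  sizes <- table(strata)
  if (any(sizes < 2L)) {
    stop("unsplittable stratum of size 1: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  cal <- character(0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  carry <- 0
  for (s in sort(unique(strata))) {
    members <- ids[strata == s]
    target <- length(members) * fraction + carry
    n_cal <- max(1L, min(length(members) - 1L, floor(target + 1e-9)))
    carry <- target - n_cal
    cal <- c(cal, sort(sample(members, n_cal)))
  }
  val <- setdiff(ids, cal)
  structure(
    list(
      calibration_ids = sort(cal), validation_ids = sort(val),
      strata = stats::setNames(strata, ids),
      fraction = fraction, seed = as.integer(seed)
    ),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d calibration / %d validation (seed %d)\n",
              length(x$calibration_ids), length(x$validation_ids), x$seed))
  invisible(x)
}

#' Check trait balance between calibration and validation sets
#'
#' Per trait, a Welch two-sample t-test compares the calibration and
#' validation means; a trait is flagged when p < `alpha`. No multiplicity
#' correction is applied — the report is advisory, the per-trait balance
#' table a study of this design would publish. Traits with zero pooled
#' variance are skipped with a note.
#'
#' @param chem chemistry data frame with an `id` column and trait columns.
#' @param split a [stratified_split()] result covering the chem rows.
#' @param traits trait column names; default: all numeric columns except id.
#' @param alpha flag level (default 0.05).
#' @return Data frame with one row per trait: `trait`, `mean_cal`,
#'   `mean_val`, `statistic`, `p_value`, `flagged`, `note`.
#' @export
check_split_balance <- function(chem, split, traits = NULL, alpha = 0.05) {
  stopifnot(inherits(split, "split_spec"), "id" %in% names(chem))
  if (!all(c(split$calibration_ids, split$validation_ids) %in% chem$id)) {
    stop("split refers to ids absent from the chemistry table", call. = FALSE)
  }
  if (is.null(traits)) {
    traits <- names(chem)[vapply(chem, is.numeric, logical(1L))]
  }
  cal <- chem[chem$id %in% split$calibration_ids, , drop = FALSE]
  val <- chem[chem$id %in% split$validation_ids, , drop = FALSE]
  rows <- lapply(traits, function(tr) {
    a <- cal[[tr]]; b <- val[[tr]]
    if (stats::var(c(a, b)) == 0) {
      return(data.frame(trait = tr, mean_cal = mean(a), mean_val = mean(b),
                        statistic = NA_real_, p_value = NA_real_,
                        flagged = FALSE, note = "zero variance; test skipped"))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(trait = tr, mean_cal = mean(a), mean_val = mean(b),
               statistic = unname(tt$statistic), p_value = tt$p.value,
               flagged = tt$p.value < alpha, note = "")
  })
  do.call(rbind, rows)
}
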