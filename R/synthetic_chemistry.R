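# Truncated-normal draws via inverse-CDF; vectorized, deterministic under
# the caller's RNG state.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# Frozen sampling parameters of the simulated greenhouse study. Water-content
# distributions are truncated hard at the pooled per-species ranges observed
# in such experiments (maize 79.6-91.0%, soybean 68.2-81.9%); nitrogen at the
# pooled 0.96-5.68%. Nutrient-responsive traits get low < medium < high
# treatment means; sodium and boron get no treatment effect (they are also
# spectrally silent in the simulator).
wc_params <- function(species, treatment) {
  switch(paste(species, treatment),
    "maize control"   = c(88.0, 1.5, 84.0, 91.0),
    "maize limited"   = c(82.5, 1.8, 79.6, 87.0),
    "maize nutrient"  = c(86.0, 1.8, 79.6, 91.0),
    "soybean control" = c(79.0, 1.3, 75.0, 81.9),
    "soybean limited" = c(71.5, 1.8, 68.2, 76.0),
    "soybean nutrient" = c(77.0, 2.0, 68.2, 81.9),
    stop("no water-content parameters for ", species, "/", treatment, call. = FALSE)
  )
}

# per trait: list(low, medium, high) of c(mean, sd) plus c(lower, upper)
# bounds; water-experiment plants draw from the medium level.
trait_params <- list(
  n  = list(low = c(1.6, 0.45), medium = c(3.2, 0.60), high = c(4.6, 0.55), bounds = c(0.96, 5.68)),
  p  = list(low = c(0.15, 0.05), medium = c(0.30, 0.05), high = c(0.45, 0.05), bounds = c(0.05, 0.70)),
  k  = list(low = c(1.2, 0.35), medium = c(2.2, 0.35), high = c(3.2, 0.35), bounds = c(0.40, 4.50)),
  mg = list(low = c(0.25, 0.06), medium = c(0.40, 0.06), high = c(0.55, 0.06), bounds = c(0.08, 0.90)),
  ca = list(low = c(0.80, 0.25), medium = c(1.30, 0.25), high = c(1.80, 0.25), bounds = c(0.20, 3.00)),
  s  = list(low = c(0.12, 0.04), medium = c(0.22, 0.04), high = c(0.32, 0.04), bounds = c(0.04, 0.50)),
  na = list(low = c(0.008, 0.003), medium = c(0.008, 0.003), high = c(0.008, 0.003), bounds = c(0.001, 0.02)),
  fe = list(low = c(70, 15), medium = c(100, 15), high = c(130, 15), bounds = c(30, 200)),
  mn = list(low = c(40, 12), medium = c(65, 12), high = c(90, 12), bounds = c(10, 150)),
  b  = list(low = c(40, 10), medium = c(40, 10), high = c(40, 10), bounds = c(10, 80)),
  cu = list(low = c(7, 2.5), medium = c(12, 2.5), high = c(17, 2.5), bounds = c(1, 30)),
  zn = list(low = c(25, 8), medium = c(40, 8), high = c(55, 8), bounds = c(5, 90))
)

#' Default study design of the simulator
#'
#' Two species, each split into a water-limitation experiment
#' (control/limited) and a nutrient-level experiment (low/medium/high).
#' The default counts reproduce the 120-plant layout: 15 plants per
#' water-treatment cell and 10 per nutrient-level cell, per species.
#'
#' @param n_water plants per species per water treatment (default 15).
#' @param n_nutrient plants per species per nutrient level (default 10).
#' @return Data frame with columns `species`, `experiment`, `treatment`, `n`.
#' @export
default_design <- function(n_water = 15L, n_nutrient = 10L) {
  water <- expand.grid(
    species = c("maize", "soybean"), experiment = "water",
    treatment = c("control", "limited"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  water$n <- as.integer(n_water)
  nutrient <- expand.grid(
    species = c("maize", "soybean"), experiment = "nutrient",
    treatment = c("low", "medium", "high"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  nutrient$n <- as.integer(n_nutrient)
  rbind(water, nutrient)
}

#' Sample a per-plant chemistry table
#'
#' Draws leaf chemistry for every plant of a study design from
#' treatment-shifted truncated Gaussians, frozen so that the pooled ranges
#' match the phenotyping study the simulator emulates: maize water content
#' stays within 79.6-91.0% and soybean within 68.2-81.9%, nitrogen within
#' 0.96-5.68%, and nutrient-responsive trait means are ordered
#' low < medium < high. Sodium and boron receive no treatment effect. Fresh
#' weight is drawn per species and dry weight derived from the target water
#' content, so the identity `wc = (w_fresh - w_dry) / w_fresh * 100` holds
#' exactly for every row.
#'
#' @param design a [default_design()]-style data frame; counts must be >= 1.
#' @param seed integer RNG seed.
#' @return Data frame with columns `id`, `species`, `experiment`,
#'   `treatment`, `w_fresh`, `w_dry`, `wc`, and the 12 nutrient traits
#'   (`n p k mg ca s na` in percent of dry mass, `fe mn b cu zn` in ppm).
#' @export
sample_chemistry <- function(design = default_design(), seed = 1L) {
  stopifnot(all(c("species", "experiment", "treatment", "n") %in% names(design)))
  if (any(design$n < 1L)) stop("invalid design: counts must be >= 1", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_len(nrow(design))) {
    sp <- design$species[i]; ex <- design$experiment[i]
    tr <- design$treatment[i]; n <- design$n[i]
    wcp <- if (ex == "water") wc_params(sp, tr) else wc_params(sp, "nutrient")
    wc_target <- rtruncnorm(n, wcp[1L], wcp[2L], wcp[3L], wcp[4L])
    w_fresh <- if (sp == "maize") {
      rtruncnorm(n, 120, 25, 40, 250)
    } else {
      rtruncnorm(n, 60, 15, 20, 120)
    }
    w_dry <- w_fresh * (1 - wc_target / 100)
    df <- data.frame(
      species = sp, experiment = ex, treatment = tr,
      w_fresh = w_fresh, w_dry = w_dry,
      wc = (w_fresh - w_dry) / w_fresh * 100,
      stringsAsFactors = FALSE
    )
    level <- if (ex == "nutrient") tr else "medium"
    for (trait in names(trait_params)) {
      pp <- trait_params[[trait]]
      ms <- pp[[level]]
      df[[trait]] <- rtruncnorm(n, ms[1L], ms[2L], pp$bounds[1L], pp$bounds[2L])
    }
    rows[[i]] <- df
  }
  chem <- do.call(rbind, rows)
  chem <- cbind(id = sprintf("plant_%03d", seq_len(nrow(chem))), chem,
                stringsAsFactors = FALSE)
  rownames(chem) <- NULL
  chem
}
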