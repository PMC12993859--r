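#' Depletion-experiment design
#'
#' Describes the pilot-scale depletion experiment the simulator emulates:
#' three fertilizer-strength treatments (100/50/25% of the control recipe),
#' three tanks per treatment, nightly overhead imaging from 4 to 26 days
#' after transplanting (DAT), and destructive sampling of 5 heads per tank
#' on DAT 11, 14, 18, 21, 23, 25 and 26. The default of 72 plants per tank
#' (216 per treatment) leaves room for the 35 heads removed per tank over
#' the sampling schedule.
#'
#' @param treatments named numeric vector of fertilizer fractions in (0, 1].
#' @param tanks_per_treatment tanks per treatment (default 3).
#' @param plants_per_tank plants per tank (default 72).
#' @param imaging_start,imaging_end imaging window in DAT (default 4..26).
#' @param sampling_days DATs with destructive sampling; must lie in
#'   `(imaging_start, imaging_end]`.
#' @param samples_per_tank_per_day heads cut per tank per sampling day.
#' @param seed master seed; per-stage RNG streams are derived from it by
#'   fixed offsets.
#' @return an `experiment_design` list.
#' @examples
#' d <- experiment_design(seed = 1)
#' @export
experiment_design <- function(treatments = c(T1 = 1.0, T2 = 0.5, T3 = 0.25),
                              tanks_per_treatment = 3,
                              plants_per_tank = 72,
                              imaging_start = 4,
                              imaging_end = 26,
                              sampling_days = c(11, 14, 18, 21, 23, 25, 26),
                              samples_per_tank_per_day = 5,
                              seed = 1) {
  if (is.null(names(treatments)) || any(!nzchar(names(treatments))))
    stop("treatments must be a named vector of fertilizer fractions")
  if (any(treatments <= 0 | treatments > 1))
    stop("fertilizer fractions must lie in (0, 1]")
  if (length(sampling_days) &&
      (any(sampling_days <= imaging_start) || any(sampling_days > imaging_end)))
    stop("sampling_days must lie in (imaging_start, imaging_end]")
  needed <- length(sampling_days) * samples_per_tank_per_day
  if (needed > plants_per_tank)
    stop("design infeasible: ", needed, " destructive samples requested per tank but only ",
         plants_per_tank, " plants per tank")
  structure(list(
    treatments = treatments,
    tanks_per_treatment = as.integer(tanks_per_treatment),
    plants_per_tank = as.integer(plants_per_tank),
    imaging_start = as.integer(imaging_start),
    imaging_end = as.integer(imaging_end),
    sampling_days = as.integer(sort(sampling_days)),
    samples_per_tank_per_day = as.integer(samples_per_tank_per_day),
    seed = as.integer(seed)
  ), class = "experiment_design")
}

#' Growth and reflectance model for the synthetic experiment
#'
#' Fresh weight follows a logistic curve in DAT; treatment scales the
#' asymptote multiplicatively (default T2 scale 0.79, anchored to the
#' observed end-of-experiment fresh-weight ratio of half-strength plants to
#' the control). Tissue nutrient concentrations are a per-nutrient baseline
#' times a per-treatment depletion multiplier. Variance has the nested
#' structure the analysis assumes: a dominant treatment effect, a
#' tank-within-treatment random effect, per-plant variation, and residual
#' measurement noise.
#'
#' Reflectance per channel is affine in a biomass index (fresh weight
#' relative to the control asymptote) and a nutrient index (tissue N
#' relative to baseline): healthy, N-rich canopies absorb more red/deep-red
#' and reflect more NIR, so normalized-difference indices separate
#' treatments by construction.
#'
#' @param fw_asymptote control-treatment fresh-weight asymptote (g).
#' @param fw_rate logistic growth rate (1/day).
#' @param fw_midpoint logistic midpoint (DAT).
#' @param treatment_scale named per-treatment multiplier on the asymptote.
#' @param dm_fraction dry matter as a fraction of fresh weight.
#' @param nutrient_baseline named baseline tissue concentrations (% of DM)
#'   for N, P, K, Ca, Mg, S.
#' @param nutrient_depletion named per-treatment multiplier applied to all
#'   nutrient baselines.
#' @param tank_sd SD of the lognormal tank-within-treatment effect on the
#'   asymptote (relative scale).
#' @param plant_sd SD of the lognormal per-plant asymptote effect.
#' @param conc_sd SD of the lognormal per-plant tissue-concentration effect.
#' @param residual_sd relative SD of multiplicative measurement noise on
#'   ground-truth rows.
#' @param pixel_noise_sd SD of additive Gaussian reflectance noise per pixel.
#' @param background background reflectance outside plant masks.
#' @param reflectance_link 10 x 3 matrix (rows = channels) of
#'   (intercept, biomass, nutrient) coefficients.
#' @return a `growth_model` list.
#' @export
growth_model <- function(fw_asymptote = 250,
                         fw_rate = 0.25,
                         fw_midpoint = 18,
                         treatment_scale = c(T1 = 1.0, T2 = 0.79, T3 = 0.55),
                         dm_fraction = 0.05,
                         nutrient_baseline = c(N = 5.3, P = 0.62, K = 8.0,
                                               Ca = 1.25, Mg = 0.42, S = 0.26),
                         nutrient_depletion = c(T1 = 1.0, T2 = 0.92, T3 = 0.72),
                         tank_sd = 0.03,
                         plant_sd = 0.05,
                         conc_sd = 0.03,
                         residual_sd = 0.02,
                         pixel_noise_sd = 0.01,
                         background = 0.02,
                         reflectance_link = default_reflectance_link()) {
  stopifnot(fw_asymptote > 0, fw_rate > 0, dm_fraction > 0, dm_fraction < 1,
            all(nutrient_baseline > 0),
            tank_sd >= 0, plant_sd >= 0, conc_sd >= 0, residual_sd >= 0,
            pixel_noise_sd >= 0)
  ord <- order(treatment_scale, decreasing = TRUE)
  if (!identical(ord, seq_along(treatment_scale)) && is.unsorted(rev(treatment_scale)))
    stop("treatment_scale must be non-increasing across treatments")
  stopifnot(is.matrix(reflectance_link), nrow(reflectance_link) == 10,
            ncol(reflectance_link) == 3)
  structure(list(
    fw_asymptote = fw_asymptote, fw_rate = fw_rate, fw_midpoint = fw_midpoint,
    treatment_scale = treatment_scale, dm_fraction = dm_fraction,
    nutrient_baseline = nutrient_baseline, nutrient_depletion = nutrient_depletion,
    tank_sd = tank_sd, plant_sd = plant_sd, conc_sd = conc_sd,
    residual_sd = residual_sd, pixel_noise_sd = pixel_noise_sd,
    background = background, reflectance_link = reflectance_link
  ), class = "growth_model")
}

#' Default affine reflectance link
#'
#' Rows follow the channel map; columns are (intercept, biomass coefficient,
#' nutrient coefficient). Signs encode the expected physiology: red and
#' deep-red reflectance falls with nitrogen status (chlorophyll absorption),
#' NIR reflectance rises with nitrogen status and canopy biomass.
#'
#' @return 10 x 3 numeric matrix with channel rownames.
#' @export
default_reflectance_link <- function() {
  m <- rbind(
    blue     = c(0.10, 0.00, -0.03),
    cyan     = c(0.12, 0.00, -0.03),
    green    = c(0.16, 0.02, -0.04),
    amber    = c(0.24, 0.00, -0.10),
    red      = c(0.30, 0.00, -0.18),
    deep_red = c(0.28, 0.00, -0.17),
    far_red  = c(0.32, 0.03,  0.08),
    nir850   = c(0.52, 0.05,  0.28),
    nir940   = c(0.50, 0.03,  0.20),
    white    = c(0.22, 0.05,  0.00)
  )
  colnames(m) <- c("intercept", "biomass", "nutrient")
  m
}

#' Read / write a design or growth model as YAML
#' @param path file path.
#' @export
read_experiment_design <- function(path) {
  x <- yaml::read_yaml(path)
  x$treatments <- unlist(x$treatments)
  do.call(experiment_design, x)
}

#' @rdname read_experiment_design
#' @param design an [experiment_design()].
#' @export
write_experiment_design <- function(design, path) {
  x <- unclass(design)
  x$treatments <- as.list(x$treatments)
  yaml::write_yaml(x, path)
  invisible(path)
}

rv_names <- function() c("FW_g", "DM_g", "N_pct", "P_pct", "K_pct",
                         "Ca_pct", "Mg_pct", "S_pct")

logistic_fw <- function(dat, asymptote, rate, midpoint) {
  asymptote / (1 + exp(-rate * (dat - midpoint)))
}

# Per-stage RNG streams derived from the master seed by fixed offsets, so
# e.g. adding pixel noise never perturbs the plant-effect draws.
stage_seed <- function(design, stage) {
  offsets <- c(effects = 0L, sampling = 1000L, measurement = 2000L,
               render = 3000L, pixels = 4000L)
  (design$seed + offsets[[stage]]) %% .Machine$integer.max
}
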