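#' A power, time, energy or mass quantity with uncertainty
#'
#' Mean and standard deviation plus a unit; the unit fixes the kind
#' (W = power, h = time, Wh/kWh = energy, g/kg = mass). Arithmetic on these
#' quantities carries uncertainty through the exact variance-of-product
#' rule rather than the first-order approximation.
#'
#' @param mean non-negative mean value.
#' @param sd non-negative standard deviation (default 0).
#' @param unit one of `"W"`, `"h"`, `"Wh"`, `"kWh"`, `"g"`, `"kg"`.
#' @return an `energy_quantity`.
#' @examples
#' energy_quantity(65.69, 0.30, "W")
#' @export
energy_quantity <- function(mean, sd = 0, unit = c("W", "h", "Wh", "kWh", "g", "kg")) {
  unit <- match.arg(unit)
  stopifnot(mean >= 0, sd >= 0)
  kind <- switch(unit, W = "power", h = "time", Wh = "energy",
                 kWh = "energy", g = "mass", kg = "mass")
  structure(list(mean = mean, sd = sd, unit = unit, kind = kind),
            class = "energy_quantity")
}

#' @export
print.energy_quantity <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.energy_quantity <- function(x, digits = 3, ...) {
  sprintf("%s ± %s %s", signif(x$mean, digits), signif(x$sd, digits), x$unit)
}

#' Energy from power and runtime with exact uncertainty propagation
#'
#' `E = P x t` (Wh from W and h). For independent P and t the variance of
#' the product is exact, not first order:
#' `sd_E = sqrt((mu_t sd_P)^2 + (mu_P sd_t)^2 + (sd_P sd_t)^2)`.
#'
#' @param power an `energy_quantity` in W.
#' @param time an `energy_quantity` in h.
#' @return an `energy_quantity` in Wh.
#' @examples
#' energy_from_power(energy_quantity(65.69, 0.30, "W"),
#'                   energy_quantity(2.0e-6, 2.35e-7, "h"))
#' @export
energy_from_power <- function(power, time) {
  stopifnot(inherits(power, "energy_quantity"), inherits(time, "energy_quantity"))
  if (power$unit != "W") stop("power must be in W, got ", power$unit)
  if (time$unit != "h") stop("time must be in h, got ", time$unit)
  mu <- power$mean * time$mean
  sd <- sqrt((time$mean * power$sd)^2 + (power$mean * time$sd)^2 +
               (power$sd * time$sd)^2)
  energy_quantity(mu, sd, "Wh")
}

#' Convert an energy quantity between Wh and kWh
#' @param x an energy `energy_quantity`.
#' @param unit target unit.
#' @export
convert_energy <- function(x, unit = c("kWh", "Wh")) {
  unit <- match.arg(unit)
  stopifnot(x$kind == "energy")
  if (x$unit == unit) return(x)
  f <- if (unit == "kWh") 1 / 1000 else 1000
  energy_quantity(x$mean * f, x$sd * f, unit)
}

#' Facility scenario for scaled energy and nitrogen accounting
#'
#' Defaults describe the comparison scenario: 10,000 lettuce heads grown
#' over 28 days with daily inference, tissue N of 0.383 +/- 0.052 g per
#' control head, a global nitrogen-use-efficiency of 46%, and an
#' industrial N-fixation energy intensity of 9.7-13.9 kWh per kg N
#' (11.11 kWh/kg average).
#'
#' @param n_heads heads of lettuce grown.
#' @param n_days days of daily inference.
#' @param tissue_n_g,tissue_n_sd_g mean and SD of tissue N per head (g).
#' @param nue nitrogen use efficiency in (0, 1].
#' @param n_intensity_kwh_kg named vector `c(low=, avg=, high=)` of
#'   N-fixation energy intensity (kWh per kg N).
#' @export
facility_scenario <- function(n_heads = 10000, n_days = 28,
                              tissue_n_g = 0.383, tissue_n_sd_g = 0.052,
                              nue = 0.46,
                              n_intensity_kwh_kg = c(low = 9.7, avg = 11.11,
                                                     high = 13.9)) {
  stopifnot(n_heads > 0, n_days > 0, tissue_n_g > 0, tissue_n_sd_g >= 0,
            nue > 0, nue <= 1)
  if (!(n_intensity_kwh_kg[["low"]] <= n_intensity_kwh_kg[["avg"]] &&
        n_intensity_kwh_kg[["avg"]] <= n_intensity_kwh_kg[["high"]]))
    stop("intensity range must satisfy low <= avg <= high")
  structure(list(n_heads = n_heads, n_days = n_days,
                 tissue_n_g = tissue_n_g, tissue_n_sd_g = tissue_n_sd_g,
                 nue = nue, n_intensity_kwh_kg = n_intensity_kwh_kg),
            class = "facility_scenario")
}

#' Scale per-sample inference energy to the facility scenario
#'
#' Total energy for daily inference on every head over the scenario period:
#' `E_total = E_sample x n_heads x n_days`. The relative uncertainty of the
#' per-sample energy is preserved by the linear scaling.
#'
#' @param per_sample per-sample `energy_quantity` in Wh.
#' @param scenario a [facility_scenario()].
#' @return an `energy_quantity` in Wh.
#' @export
scale_to_facility <- function(per_sample, scenario = facility_scenario()) {
  stopifnot(inherits(per_sample, "energy_quantity"))
  if (per_sample$unit != "Wh") stop("per-sample energy must be in Wh")
  f <- scenario$n_heads * scenario$n_days
  energy_quantity(per_sample$mean * f, per_sample$sd * f, "Wh")
}

#' Applied and wasted nitrogen with embodied energy
#'
#' Applied N = tissue N per head x heads / NUE; wasted N = applied x
#' (1 - NUE), i.e. applied minus the tissue total exactly. The relative
#' uncertainty of the tissue N measurement carries through both linear
#' quantities. Embodied energy multiplies wasted N by the low / average /
#' high fixation intensity.
#'
#' @param scenario a [facility_scenario()].
#' @return list with `applied_kg` and `wasted_kg` (`energy_quantity` mass
#'   values) and `embodied_kwh` (named numeric, low/avg/high).
#' @export
embodied_wasted_n <- function(scenario = facility_scenario()) {
  tissue_total_kg <- scenario$tissue_n_g * scenario$n_heads / 1000
  rel_sd <- scenario$tissue_n_sd_g / scenario$tissue_n_g
  applied <- tissue_total_kg / scenario$nue
  wasted <- applied * (1 - scenario$nue)
  list(
    applied_kg = energy_quantity(applied, applied * rel_sd, "kg"),
    wasted_kg = energy_quantity(wasted, wasted * rel_sd, "kg"),
    tissue_total_kg = energy_quantity(tissue_total_kg,
                                      tissue_total_kg * rel_sd, "kg"),
    embodied_kwh = wasted * scenario$n_intensity_kwh_kg
  )
}

#' Ratio of embodied (wasted-N) energy to model inference energy
#'
#' Reports both quotients: how many times the embodied energy exceeds the
#' GPU energy, and the GPU energy as a percentage of the embodied energy.
#'
#' @param model_energy model inference `energy_quantity` (Wh or kWh).
#' @param embodied_kwh embodied energy in kWh (scalar or the named vector
#'   from [embodied_wasted_n()]).
#' @return list `ratio` (embodied / GPU) and `gpu_pct` (100 x GPU /
#'   embodied), each with the shape of `embodied_kwh`.
#' @export
offset_ratio <- function(model_energy, embodied_kwh) {
  gpu_kwh <- convert_energy(model_energy, "kWh")$mean
  list(ratio = embodied_kwh / gpu_kwh, gpu_pct = 100 * gpu_kwh / embodied_kwh)
}

#' Read a power log and summarise it as a power quantity
#'
#' Consumes a CSV of `timestamp, watts` samples. The reported SD applies
#' the measurement floor of the power-monitoring interface: when the
#' observed SD is below `floor_w` (power draw is averaged over one second
#' and quoted +/- 5 W), the floor is used instead.
#'
#' @param path CSV path with a `watts` column.
#' @param floor_w SD floor in W (default 5).
#' @return an `energy_quantity` in W.
#' @export
read_power_log <- function(path, floor_w = 5) {
  log <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"watts" %in% names(log)) stop("power log must have a 'watts' column")
  s <- if (nrow(log) > 1) sd(log$watts) else 0
  energy_quantity(mean(log$watts), max(s, floor_w), "W")
}

#' Per-sample energy table for the three monitoring tiers
#'
#' The benchmark per-sample GPU energy quantities used by the scaling
#' comparison: AE training/inference from measured power and per-sample
#' runtime; RF and ViT per-sample inference energy from the module
#' benchmarks.
#'
#' @return named list of `energy_quantity` values (Wh per sample).
#' @export
benchmark_energies <- function() {
  list(
    ae_training = energy_from_power(energy_quantity(65.69, 0.30, "W"),
                                    energy_quantity(2.0e-6, 2.35e-7, "h")),
    ae_inference = energy_from_power(energy_quantity(69.94, 0.24, "W"),
                                     energy_quantity(2.55e-8, 1.74e-9, "h")),
    rf_inference = energy_quantity(1.60e-5, 1.1e-6, "Wh"),
    vit_inference = energy_quantity(3.49e-3, 2.5e-4, "Wh")
  )
}
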