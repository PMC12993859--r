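#' Simulate the depletion experiment
#'
#' Draws tank, plant and concentration effects, grows every plant along its
#' logistic fresh-weight curve, schedules destructive sampling, and returns
#' (1) the latent plant-state table for every plant and imaging night up to
#' its sampling day and (2) the ground-truth table for sampled plants on
#' sampling days, with multiplicative measurement noise. Identical seeds
#' give identical tables.
#'
#' @param design an [experiment_design()].
#' @param model a [growth_model()].
#' @return list with tibbles `states` and `ground_truth` (columns
#'   `plant_id, tank_id, treatment, DAT, FW_g, DM_g, N_pct, P_pct, K_pct,
#'   Ca_pct, Mg_pct, S_pct`; `states` also carries `sampled_dat`), plus the
#'   per-plant `roster`.
#' @examples
#' sim <- simulate_experiment(experiment_design(seed = 7), growth_model())
#' nrow(sim$ground_truth)  # 9 tanks x 7 days x 5 heads = 315
#' @export
simulate_experiment <- function(design, model = growth_model()) {
  stopifnot(inherits(design, "experiment_design"), inherits(model, "growth_model"))
  trts <- names(design$treatments)
  scale <- model$treatment_scale[trts]
  if (anyNA(scale)) stop("growth model lacks treatment_scale for: ",
                         paste(trts[is.na(scale)], collapse = ", "))

  roster <- tidyr::expand_grid(
    treatment = trts,
    tank = seq_len(design$tanks_per_treatment),
    plant = seq_len(design$plants_per_tank)
  )
  roster$tank_id <- sprintf("%s_tk%d", roster$treatment, roster$tank)
  roster$plant_id <- sprintf("%s_p%02d", roster$tank_id, roster$plant)

  nutr <- names(model$nutrient_baseline)

  # Stage 1: random effects (tank, plant, per-plant concentrations).
  set.seed(stage_seed(design, "effects"))
  tanks <- unique(roster$tank_id)
  tank_eff <- setNames(exp(rnorm(length(tanks), 0, model$tank_sd)), tanks)
  plant_eff <- exp(rnorm(nrow(roster), 0, model$plant_sd))
  conc_eff <- matrix(exp(rnorm(nrow(roster) * length(nutr), 0, model$conc_sd)),
                     nrow = nrow(roster),
                     dimnames = list(NULL, nutr))

  roster$asymptote <- model$fw_asymptote *
    unname(scale[roster$treatment]) *
    unname(tank_eff[roster$tank_id]) * plant_eff
  dep <- model$nutrient_depletion[roster$treatment]
  conc <- sweep(conc_eff, 2, model$nutrient_baseline, `*`) * dep
  colnames(conc) <- paste0(nutr, "_pct")
  roster <- dplyr::bind_cols(roster, tibble::as_tibble(conc))

  # Stage 2: destructive sampling schedule (without replacement per tank).
  set.seed(stage_seed(design, "sampling"))
  roster$sampled_dat <- NA_integer_
  if (length(design$sampling_days)) {
    for (tk in tanks) {
      idx <- which(roster$tank_id == tk)
      pool <- idx
      for (d in design$sampling_days) {
        take <- sample(pool, design$samples_per_tank_per_day)
        roster$sampled_dat[take] <- d
        pool <- setdiff(pool, take)
      }
    }
  }

  dats <- design$imaging_start:design$imaging_end
  states <- tidyr::expand_grid(row = seq_len(nrow(roster)), DAT = dats)
  last <- ifelse(is.na(roster$sampled_dat), design$imaging_end, roster$sampled_dat)
  states <- states[states$DAT <= last[states$row], ]
  r <- states$row
  fw <- logistic_fw(states$DAT, roster$asymptote[r], model$fw_rate, model$fw_midpoint)
  states_tbl <- tibble::tibble(
    plant_id = roster$plant_id[r],
    tank_id = roster$tank_id[r],
    treatment = roster$treatment[r],
    DAT = states$DAT,
    FW_g = fw,
    DM_g = fw * model$dm_fraction
  )
  for (nm in paste0(nutr, "_pct")) states_tbl[[nm]] <- roster[[nm]][r]
  states_tbl$sampled_dat <- roster$sampled_dat[r]

  # Stage 3: ground truth = sampled plants on their sampling day, with
  # multiplicative lognormal measurement noise on every measured quantity.
  gt <- states_tbl[!is.na(states_tbl$sampled_dat) &
                     states_tbl$DAT == states_tbl$sampled_dat, ]
  gt$sampled_dat <- NULL
  set.seed(stage_seed(design, "measurement"))
  meas_cols <- rv_names()
  if (nrow(gt)) {
    noise <- matrix(exp(rnorm(nrow(gt) * length(meas_cols), 0, model$residual_sd)),
                    nrow = nrow(gt))
    for (j in seq_along(meas_cols)) gt[[meas_cols[j]]] <- gt[[meas_cols[j]]] * noise[, j]
  }
  gt <- gt[order(gt$DAT, gt$tank_id, gt$plant_id), ]

  list(states = states_tbl, ground_truth = tibble::as_tibble(gt),
       roster = tibble::as_tibble(roster[, c("plant_id", "tank_id", "treatment",
                                             "asymptote", "sampled_dat")]))
}

#' One-way nested sums of squares for simulated responses
#'
#' Plain-arithmetic decomposition of the total sum of squares of `value`
#' into between-treatment, between-tank-within-treatment, and residual
#' components, used to confirm that simulated variance has the intended
#' nested structure (treatment-dominant).
#'
#' @param df data frame with the grouping columns.
#' @param value column name of the response.
#' @param treatment,tank grouping column names.
#' @return named numeric vector of sums of squares and their fractions.
#' @export
variance_decomposition <- function(df, value = "FW_g", treatment = "treatment",
                                   tank = "tank_id") {
  y <- df[[value]]; trt <- df[[treatment]]; tk <- df[[tank]]
  g <- mean(y)
  trt_mean <- tapply(y, trt, mean)[trt]
  tank_mean <- tapply(y, tk, mean)[tk]
  ss_trt <- sum((trt_mean - g)^2)
  ss_tank <- sum((tank_mean - trt_mean)^2)
  ss_res <- sum((y - tank_mean)^2)
  tot <- sum((y - g)^2)
  c(ss_treatment = ss_trt, ss_tank = ss_tank, ss_residual = ss_res,
    ss_total = tot,
    frac_treatment = ss_trt / tot, frac_tank = ss_tank / tot,
    frac_residual = ss_res / tot)
}

#' Fit the logistic fresh-weight curve per treatment
#'
#' Levenberg-Marquardt fit of `FW = A / (1 + exp(-r (DAT - m)))` to each
#' treatment's states. On noise-free simulator output this recovers the
#' generating parameters to numerical precision.
#'
#' @param states state or ground-truth table with `treatment`, `DAT`, `FW_g`.
#' @return tibble with columns `treatment`, `asymptote`, `rate`, `midpoint`.
#' @export
fit_growth_curve <- function(states) {
  fits <- lapply(split(states, states$treatment), function(d) {
    start <- list(A = max(d$FW_g) * 1.1, r = 0.3, m = median(d$DAT))
    fit <- minpack.lm::nlsLM(FW_g ~ A / (1 + exp(-r * (DAT - m))),
                             data = d, start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200,
                                                                  ftol = 1e-14,
                                                                  ptol = 1e-14))
    p <- coef(fit)
    tibble::tibble(treatment = d$treatment[1], asymptote = p[["A"]],
                   rate = p[["r"]], midpoint = p[["m"]])
  })
  dplyr::bind_rows(fits)
}

#' Channel reflectance means implied by the link for one plant state
#' @keywords internal
link_reflectance <- function(model, fw, n_pct) {
  beta <- pmin(fw / model$fw_asymptote, 1)
  nu <- pmin(n_pct / model$nutrient_baseline[["N"]], 1.5)
  L <- model$reflectance_link
  outer(rep(1, length(fw)), L[, "intercept"]) +
    outer(beta, L[, "biomass"]) + outer(nu, L[, "nutrient"])
}
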