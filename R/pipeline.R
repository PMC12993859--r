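#' Configuration for a tiered end-to-end run
#'
#' Ties the tiers together: continuous low-energy early warning (VI-AE) on
#' single-image features, and - only when the net flagged fraction of
#' monitored plants meets the trigger - deeper state estimation (RF),
#' RF-estimated trajectory screening (RF-AE), and the energy report. Net
#' flags are the flag rate among monitored plants in excess of the false
#' rate on held-out healthy plants, so a healthy facility does not trigger
#' deep analysis on reconstruction noise alone; the default trigger fires
#' at a net fraction of 10%.
#'
#' @param design an [experiment_design()] (or arguments via `...` won't be
#'   guessed - pass a design).
#' @param model a [growth_model()].
#' @param registry index registry (default: the five canonical indices,
#'   keeping the continuous tier light; pass [vi_registry()] for the full
#'   set).
#' @param captures captures per night in the simulation.
#' @param ew_features features monitored by the early-warning tier.
#' @param ew_window window length (days) of the early-warning screen.
#' @param trigger_fraction net flagged fraction that triggers deeper analysis.
#' @param rvs responses estimated by the deeper tier.
#' @param rf_num_trees forest size for the pipeline run (scaled down from
#'   the tuned 900 for interactive use; set `NULL` for the tuned values).
#' @param rf_ae_window window lengths of the RF-AE trajectory screen.
#' @param scenario a [facility_scenario()] for the energy report.
#' @param seed master seed recorded in the manifest.
#' @export
pipeline_config <- function(design = experiment_design(),
                            model = growth_model(),
                            registry = vi_registry(include_generic = FALSE),
                            captures = 2L,
                            ew_features = c("NDWI_median", "GNDVI_median",
                                            "GRVI_median"),
                            ew_window = 6,
                            trigger_fraction = 0.1,
                            rvs = c("FW_g", "N_pct"),
                            rf_num_trees = 300,
                            rf_ae_window = c(6, 10),
                            scenario = facility_scenario(),
                            seed = design$seed) {
  stopifnot(trigger_fraction >= 0, trigger_fraction <= 1)
  structure(list(design = design, model = model, registry = registry,
                 captures = as.integer(captures), ew_features = ew_features,
                 ew_window = ew_window, trigger_fraction = trigger_fraction,
                 rvs = rvs, rf_num_trees = rf_num_trees,
                 rf_ae_window = rf_ae_window, scenario = scenario,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the tiered monitoring pipeline end to end
#'
#' Stages execute in dependency order: simulate -> extract features ->
#' early-warning VI-AE -> (if triggered) pseudolabels + RF cross-validation
#' + trajectory estimation + RF-AE screen -> energy report. The returned
#' manifest records the config, its hash, seeds and package version, and is
#' sufficient to reproduce the run bit-identically with
#' [rerun_from_manifest()].
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a `tiered_run` list: `manifest`, `features`, `early_warning`,
#'   `estimation` (`NULL` when not triggered), `energy`.
#' @export
run_tiered <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stamp <- function(x) { attr(x, "config_hash") <- hash; x }
  hash <- rlang::hash(config)

  say("stage: simulate + extract (single-image and daily-average tables)")
  single <- simulate_features(config$design, config$model, config$registry,
                              captures = config$captures, mode = "single_image")
  daily <- simulate_features(config$design, config$model, config$registry,
                             captures = config$captures, mode = "daily_average")

  say("stage: early warning (VI-AE)")
  traj <- make_trajectories(single$features, config$ew_features)
  per_feature <- list()
  for (f in config$ew_features) {
    w <- trajectory_windows(traj, f, config$ew_window)
    trt <- attr(w, "treatment")
    healthy <- w[trt[rownames(w)] == "T1", , drop = FALSE]
    healthy <- healthy[order(rownames(healthy)), , drop = FALSE]
    cfg <- ae_config(seed = config$seed)
    n_train <- min(nrow(healthy), cfg$max_train)
    model <- fit_ae(healthy[seq_len(n_train), , drop = FALSE], cfg)
    held <- healthy[-seq_len(n_train), , drop = FALSE]
    if (!nrow(held)) stop("no held-out healthy plants for the early-warning baseline")
    monitored <- w[!rownames(w) %in% rownames(healthy), , drop = FALSE]
    per_feature[[f]] <- c(flag_rate = mean(detect_anomaly(model, monitored)),
                          false_rate = mean(detect_anomaly(model, held)))
  }
  pf <- do.call(rbind, per_feature)
  # net flags: flag rate among monitored (non-reference) plants in excess of
  # the false rate measured on held-out healthy plants
  net_flag_fraction <- mean(pmax(pf[, "flag_rate"] - pf[, "false_rate"], 0))
  triggered <- net_flag_fraction >= config$trigger_fraction
  early_warning <- stamp(list(net_flag_fraction = net_flag_fraction,
                              triggered = triggered,
                              per_feature = pf))

  estimation <- NULL
  if (triggered) {
    say("stage: state estimation (RF) + RF-AE screen")
    labeled <- assign_pseudolabels(single$features, single$ground_truth,
                                   rvs = config$rvs)
    folds <- enumerate_folds(labeled)
    cfg_fun <- if (is.null(config$rf_num_trees)) rf_config else
      function(rv) rf_config(rv, num_trees = config$rf_num_trees)
    cv <- run_cv(labeled, rvs = config$rvs, folds = folds,
                 config_fun = cfg_fun)
    est <- estimate_trajectories(labeled, daily$features, rvs = config$rvs,
                                 config_fun = cfg_fun)
    est_traj <- make_trajectories(est, config$rvs)
    rf_ae <- window_sweep(est_traj, config$rvs, L_range = config$rf_ae_window,
                          config = ae_config(seed = config$seed))
    estimation <- stamp(list(cv_summary = cv$summary, oof = cv$oof,
                             trajectories = est, rf_ae = rf_ae))
  } else {
    say("trigger not met; estimation tier skipped")
  }

  say("stage: energy report")
  energy <- stamp(energy_report(config$scenario))

  manifest <- list(
    config = config,
    config_hash = hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("nutrimon")),
    stages = c("simulate", "early_warning",
               if (triggered) c("estimation", "rf_ae"), "energy"),
    triggered = triggered
  )
  structure(list(manifest = manifest, features = stamp(single$features),
                 ground_truth = stamp(single$ground_truth),
                 early_warning = early_warning, estimation = estimation,
                 energy = energy),
            class = "tiered_run")
}

#' Re-run a pipeline from its manifest
#' @param manifest the `manifest` element of a [run_tiered()] result.
#' @param ... passed to [run_tiered()].
#' @export
rerun_from_manifest <- function(manifest, ...) {
  run_tiered(manifest$config, ...)
}

#' @export
print.tiered_run <- function(x, ...) {
  cat("<tiered_run>\n")
  cat("  config hash:", x$manifest$config_hash, "\n")
  cat(sprintf("  early warning: net flag fraction %.1f%% (%s)\n",
              100 * x$early_warning$net_flag_fraction,
              if (x$manifest$triggered) "estimation triggered"
              else "below trigger"))
  if (!is.null(x$estimation)) {
    cat("  cross-validated estimation:\n")
    print(x$estimation$cv_summary)
  }
  invisible(x)
}

#' Facility-scale energy report
#'
#' Scales the per-sample benchmark energies of each tier to the facility
#' scenario, computes the embodied energy of wasted nitrogen, and reports
#' the offset ratios.
#'
#' @param scenario a [facility_scenario()].
#' @param energies named list of per-sample `energy_quantity` values (Wh),
#'   default [benchmark_energies()].
#' @return list with `per_sample`, `monthly` (scaled quantities), the
#'   nitrogen accounting, and the ViT offset ratio.
#' @export
energy_report <- function(scenario = facility_scenario(),
                          energies = benchmark_energies()) {
  inference <- energies[grepl("inference", names(energies))]
  monthly <- lapply(inference, scale_to_facility, scenario = scenario)
  nitro <- embodied_wasted_n(scenario)
  vit_offset <- offset_ratio(monthly$vit_inference,
                             nitro$embodied_kwh[["avg"]])
  list(per_sample = energies, monthly = monthly, nitrogen = nitro,
       vit_offset = vit_offset, scenario = scenario)
}

#' Bar-chart comparison of scaled GPU energy vs embodied wasted-N energy
#'
#' Log-scale bar chart mirroring the facility comparison figure. Requires
#' ggplot2.
#'
#' @param report an [energy_report()].
#' @export
plot_energy_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- tibble::tibble(
    source = c(names(report$monthly), "embodied wasted N (avg)"),
    kwh = c(vapply(report$monthly, function(e) convert_energy(e, "kWh")$mean,
                   numeric(1)),
            report$nitrogen$embodied_kwh[["avg"]])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(source, kwh), y = kwh)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "energy over the scenario period (kWh, log scale)")
}
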