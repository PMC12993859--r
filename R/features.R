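#' Build a per-plant, per-DAT vegetation-index feature table from cubes
#'
#' For every night and capture, each registry index is evaluated over each
#' plant's mask and summarised as mean/median/SD of the foliar surface.
#' Per-capture records are then collapsed to one record per (plant, DAT):
#' either the single designated capture per night (`"single_image"`; the
#' second of eight hourly captures, standing in for the 11 pm exposure, or
#' the first capture when fewer exist) or the average of all captures
#' (`"daily_average"`).
#'
#' @param nights list of night records `list(DAT, capture, cube, masks)`,
#'   e.g. from [render_experiment()].
#' @param registry index registry tibble, see [vi_registry()].
#' @param mode `"single_image"` or `"daily_average"`.
#' @param roster optional tibble mapping `plant_id` to `tank_id` and
#'   `treatment`; by default both are parsed from ids of the form
#'   `"T1_tk1_p01"`.
#' @return tibble with `plant_id, tank_id, treatment, DAT, source` and one
#'   column per `{index}_{mean|median|std}` feature.
#' @export
build_feature_table <- function(nights, registry = vi_registry(),
                                mode = c("single_image", "daily_average"),
                                roster = NULL) {
  mode <- match.arg(mode)
  validate_registry(registry)
  recs <- list()
  for (nt in nights) {
    for (pid in names(nt$masks)) {
      mask <- nt$masks[[pid]]
      if (!any(mask)) next
      stats <- numeric(0)
      for (i in seq_len(nrow(registry))) {
        img <- compute_index(nt$cube, mask, registry$formula[i])
        s <- summarize_index(img)
        names(s) <- paste0(registry$name[i], "_", names(s))
        stats <- c(stats, s)
      }
      recs[[length(recs) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(plant_id = pid, DAT = nt$DAT, capture = nt$capture),
        tibble::as_tibble(as.list(stats))
      )
    }
  }
  percap <- dplyr::bind_rows(recs)
  if (!nrow(percap)) stop("no plant records produced")
  out <- aggregate_captures(percap, mode)
  attach_roster(out, roster)
}

# Collapse per-capture records to one row per (plant, DAT).
aggregate_captures <- function(percap, mode) {
  featcols <- setdiff(names(percap), c("plant_id", "tank_id", "treatment",
                                       "DAT", "capture"))
  if (mode == "single_image") {
    picked <- percap |>
      dplyr::group_by(DAT) |>
      dplyr::mutate(.keep_cap = if (dplyr::n_distinct(capture) == 8)
        sort(unique(capture))[2] else min(capture)) |>
      dplyr::ungroup()
    out <- picked[picked$capture == picked$.keep_cap, ]
    out$.keep_cap <- NULL
    out$capture <- NULL
    out$source <- "single_image"
  } else {
    out <- percap |>
      dplyr::group_by(plant_id, DAT) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(featcols), mean),
                       .groups = "drop")
    out$source <- "daily_average"
  }
  dplyr::relocate(out, dplyr::all_of(c("plant_id", "DAT", "source")))
}

attach_roster <- function(tbl, roster = NULL) {
  if (is.null(roster)) {
    tbl$tank_id <- sub("_p\\d+$", "", tbl$plant_id)
    tbl$treatment <- sub("_tk\\d+$", "", tbl$tank_id)
  } else {
    tbl <- dplyr::left_join(tbl,
                            roster[, c("plant_id", "tank_id", "treatment")],
                            by = "plant_id")
  }
  dplyr::relocate(tbl, dplyr::all_of(c("plant_id", "tank_id", "treatment",
                                       "DAT", "source")))
}

#' Simulate vegetation-index feature tables without rendering pixels
#'
#' The fast path from a simulated experiment to feature tables: for each
#' plant, night and capture, `n_pixels` foliar-surface reflectance samples
#' are drawn from the reflectance link plus pixel noise, registry indices
#' are evaluated on them, and mean/median/SD summaries are taken - exactly
#' what [build_feature_table()] computes from rendered cubes, without the
#' geometry. Used for trajectory-scale studies where thousands of
#' plant-nights are needed.
#'
#' @param design an [experiment_design()].
#' @param model a [growth_model()].
#' @param registry index registry tibble.
#' @param captures captures per night.
#' @param n_pixels foliar-surface samples per plant per capture.
#' @param mode `"single_image"` or `"daily_average"`.
#' @return list with `features` (the feature table), `ground_truth`,
#'   `states` and `roster` from the underlying [simulate_experiment()] call.
#' @export
simulate_features <- function(design, model = growth_model(),
                              registry = vi_registry(), captures = 1L,
                              n_pixels = 64L,
                              mode = c("single_image", "daily_average")) {
  mode <- match.arg(mode)
  validate_registry(registry)
  sim <- simulate_experiment(design, model)
  st <- sim$states
  nrows <- nrow(st)
  refl <- link_reflectance(model, st$FW_g, st$N_pct)  # nrows x 10
  chn <- msi_channels()$name
  colnames(refl) <- chn

  set.seed(stage_seed(design, "pixels"))
  percap <- list()
  for (cp in seq_len(captures)) {
    big <- refl[rep(seq_len(nrows), each = n_pixels), , drop = FALSE]
    if (model$pixel_noise_sd > 0)
      big <- big + matrix(rnorm(length(big), 0, model$pixel_noise_sd),
                          nrow(big), ncol(big))
    env <- new.env(parent = baseenv())
    for (nm in chn) assign(nm, big[, nm], envir = env)
    assign("nd", nd, envir = env); assign("rr", rr, envir = env)
    assign("safe_div", safe_div, envir = env)
    cols <- list()
    grp <- rep(seq_len(nrows), each = n_pixels)
    for (i in seq_len(nrow(registry))) {
      v <- eval(parse(text = registry$formula[i])[[1]], envir = env)
      m <- matrix(v, n_pixels, nrows)
      mu <- colMeans(m)
      stdev <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
      ms <- matrix(v[order(grp, v)], n_pixels, nrows)
      med <- if (n_pixels %% 2 == 1) ms[(n_pixels + 1) / 2, ]
             else (ms[n_pixels / 2, ] + ms[n_pixels / 2 + 1, ]) / 2
      nm <- registry$name[i]
      cols[[paste0(nm, "_mean")]] <- mu
      cols[[paste0(nm, "_median")]] <- med
      cols[[paste0(nm, "_std")]] <- stdev
    }
    percap[[cp]] <- dplyr::bind_cols(
      tibble::tibble(plant_id = st$plant_id, tank_id = st$tank_id,
                     treatment = st$treatment, DAT = st$DAT, capture = cp),
      tibble::as_tibble(cols)
    )
  }
  feats <- attach_roster(aggregate_captures(dplyr::bind_rows(percap), mode))
  list(features = feats, ground_truth = sim$ground_truth,
       states = sim$states, roster = sim$roster)
}

#' Names of the feature columns of a feature table
#' @param tbl feature table.
#' @export
feature_columns <- function(tbl) {
  setdiff(names(tbl), c("plant_id", "tank_id", "treatment", "DAT", "source",
                        "capture", rv_names(), "label_type", "label_dat"))
}

#' Write / read a feature or ground-truth table as CSV
#' @param tbl a tibble.
#' @param path file path.
#' @export
write_table_csv <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
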