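#' Build per-plant feature trajectories with destructive truncation
#'
#' Reshapes a feature table to long per-plant time series, one trajectory
#' per (plant, feature). A sampled plant's trajectory ends at its sampling
#' day; interior missing days are filled by linear interpolation (the
#' autoencoder needs dense fixed-length windows), while leading/trailing
#' gaps are left unfilled. Plants with fewer than two observations are
#' excluded with a warning.
#'
#' @param tbl feature table (or estimated-trajectory table) with `plant_id`,
#'   `treatment`, `DAT` and feature columns.
#' @param features which feature columns to keep (default: all).
#' @return a `trajectory_set`: long tibble `plant_id, treatment, feature,
#'   DAT, value` with attribute `start_dat`.
#' @export
make_trajectories <- function(tbl, features = NULL) {
  if (is.null(features)) features <- feature_columns(tbl)
  stopifnot(length(features) >= 1, all(features %in% names(tbl)))
  long <- tidyr::pivot_longer(
    tbl[, c("plant_id", "treatment", "DAT", features)],
    dplyr::all_of(features), names_to = "feature", values_to = "value"
  )
  n_obs <- table(long$plant_id[long$feature == features[1]])
  short <- names(n_obs)[n_obs < 2]
  if (length(short)) {
    warning("excluding ", length(short), " plant(s) with < 2 observations")
    long <- long[!long$plant_id %in% short, ]
  }
  if (!nrow(long)) stop("no trajectories left")
  filled <- long |>
    dplyr::group_by(plant_id, treatment, feature) |>
    dplyr::reframe({
      d <- DAT; v <- value
      grid <- seq(min(d), max(d))
      tibble::tibble(DAT = grid,
                     value = approx(d, v, xout = grid, method = "linear")$y)
    })
  structure(tibble::as_tibble(filled),
            class = c("trajectory_set", class(tibble::tibble())),
            start_dat = min(filled$DAT))
}

#' Extract fixed-length windows from a trajectory set
#'
#' Returns the window matrix for one feature: rows are plants whose
#' trajectory fully covers `start_dat .. start_dat + L - 1` (plants sampled
#' too early for the requested window are simply unavailable and dropped),
#' ordered by ascending plant id so "the first n" is deterministic.
#'
#' @param traj a [make_trajectories()] result.
#' @param feature feature name.
#' @param L window length in days (>= 2).
#' @param start_dat first DAT of the window (default 4).
#' @return numeric matrix (plants x L) with plant-id rownames and a
#'   `treatment` attribute (named character vector).
#' @export
trajectory_windows <- function(traj, feature, L, start_dat = 4) {
  stopifnot(L >= 2)
  days <- start_dat + seq_len(L) - 1
  d <- traj[traj$feature == feature & traj$DAT %in% days, ]
  if (!nrow(d)) stop("feature '", feature, "' not found or no coverage")
  wide <- tidyr::pivot_wider(d[, c("plant_id", "treatment", "DAT", "value")],
                             names_from = DAT, values_from = value)
  if (length(setdiff(as.character(days), names(wide))))
    stop("no trajectory covers the requested window (L = ", L, ")")
  wide <- wide[stats::complete.cases(wide), ]
  wide <- wide[order(wide$plant_id), ]
  m <- as.matrix(wide[, as.character(days)])
  rownames(m) <- wide$plant_id
  attr(m, "treatment") <- setNames(wide$treatment, wide$plant_id)
  attr(m, "start_dat") <- start_dat
  m
}
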