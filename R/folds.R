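#' Enumerate the 27 tank-permutation cross-validation folds
#'
#' With 3 treatments x 3 tanks, each fold keeps two tanks per treatment for
#' testing and the remaining tank for training (80%) and validation (20%).
#' All per-treatment choices of the held-in tank give 3^3 = 27 folds; every
#' tank is a test tank in exactly 18 of them, and each per-treatment test
#' pair occurs in 9.
#'
#' @param roster tibble with one row per tank: `tank_id`, `treatment` (a
#'   plant-level roster is also accepted and reduced to distinct tanks).
#' @return tibble with `fold_id` and list-columns `train_tanks` (3 ids) and
#'   `test_tanks` (6 ids).
#' @export
enumerate_folds <- function(roster) {
  tanks <- dplyr::distinct(roster[, c("tank_id", "treatment")])
  by_trt <- split(tanks$tank_id, tanks$treatment)
  if (length(by_trt) != 3 || any(lengths(by_trt) != 3))
    stop("fold enumeration requires exactly 3 treatments x 3 tanks; got ",
         paste(lengths(by_trt), collapse = "/"), " tanks per treatment")
  choices <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  trts <- names(by_trt)
  folds <- lapply(seq_len(nrow(choices)), function(i) {
    keep <- as.integer(choices[i, ])
    train <- vapply(1:3, function(j) by_trt[[j]][keep[j]], character(1))
    test <- unlist(lapply(1:3, function(j) by_trt[[j]][-keep[j]]))
    tibble::tibble(fold_id = i, train_tanks = list(train),
                   test_tanks = list(test))
  })
  dplyr::bind_rows(folds)
}

#' Assign labels and pseudolabels to image records
#'
#' Destructively sampled plants keep their own ground-truth row (label type
#' `"ground_truth"`, matched on plant and DAT). Every other record receives
#' its tank's mean response over the five destructive samples of the nearest
#' sampling day (earlier day wins ties) as a pseudolabel. Records from tanks
#' with no ground truth at all are dropped with a warning. The nearest-day
#' extension to non-sampling days is a documented convention: only the
#' sampling-day case is defined by the experimental protocol.
#'
#' @param features feature table (`plant_id, tank_id, DAT`, ...).
#' @param ground_truth ground-truth table with the response columns.
#' @param rvs response columns to label (default all eight).
#' @return `features` plus the response columns, `label_type`
#'   (`"ground_truth"` or `"pseudo"`) and `label_dat` (the sampling day the
#'   label came from).
#' @export
assign_pseudolabels <- function(features, ground_truth, rvs = rv_names()) {
  stopifnot(all(rvs %in% names(ground_truth)))
  tank_means <- ground_truth |>
    dplyr::group_by(tank_id, DAT) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(rvs), mean), .groups = "drop")

  no_gt <- setdiff(unique(features$tank_id), unique(ground_truth$tank_id))
  if (length(no_gt)) {
    warning("dropping records from tank(s) without ground truth: ",
            paste(no_gt, collapse = ", "))
    features <- features[!features$tank_id %in% no_gt, ]
  }
  if (!nrow(features)) stop("no records left to label")

  gt_key <- paste(ground_truth$plant_id, ground_truth$DAT)
  rec_key <- paste(features$plant_id, features$DAT)
  is_gt <- rec_key %in% gt_key

  out <- features
  out$label_type <- ifelse(is_gt, "ground_truth", "pseudo")
  out$label_dat <- NA_integer_
  for (rv in rvs) out[[rv]] <- NA_real_

  # own ground truth for sampled plants on their sampling day
  gt_idx <- match(rec_key, gt_key)
  hit <- which(is_gt)
  for (rv in rvs) out[[rv]][hit] <- ground_truth[[rv]][gt_idx[hit]]
  out$label_dat[hit] <- out$DAT[hit]

  # tank-mean pseudolabels from the nearest sampling day (earlier wins ties)
  need <- which(!is_gt)
  if (length(need)) {
    days_by_tank <- split(tank_means$DAT, tank_means$tank_id)
    tgt_day <- vapply(need, function(i) {
      days <- days_by_tank[[out$tank_id[i]]]
      dist <- abs(days - out$DAT[i])
      cand <- days[dist == min(dist)]
      min(cand)
    }, numeric(1))
    tm_key <- paste(tank_means$tank_id, tank_means$DAT)
    tm_idx <- match(paste(out$tank_id[need], tgt_day), tm_key)
    for (rv in rvs) out[[rv]][need] <- tank_means[[rv]][tm_idx]
    out$label_dat[need] <- as.integer(tgt_day)
  }
  out
}
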