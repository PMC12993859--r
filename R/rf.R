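#' Random-forest configuration per response variable
#'
#' Final tuned hyperparameters of the state-estimation forests: 900 trees
#' (1300 for P and S), depth 14 (12 for P and S), minimum split size 2,
#' minimum leaf size 1, sqrt feature subsampling, no bootstrap (every tree
#' sees the full training pool), squared-error splitting, fixed seed 50.
#' `num_trees`/`max_depth` overrides support scaled-down runs; the searched
#' grid from tuning (trees 500-1600, depth 5-16) is available via
#' [rf_search_grid()] but tuning is off by default.
#'
#' @param rv response variable name (one of [rv_names()]); `NULL` for the
#'   generic defaults.
#' @param num_trees,max_depth optional overrides.
#' @param seed forest seed (default 50).
#' @return list of ranger-ready settings.
#' @export
rf_config <- function(rv = NULL, num_trees = NULL, max_depth = NULL, seed = 50) {
  finals <- list(
    N_pct = c(900, 14), P_pct = c(1300, 12), K_pct = c(900, 14),
    Ca_pct = c(900, 14), Mg_pct = c(900, 14), S_pct = c(1300, 12),
    FW_g = c(900, 14), DM_g = c(900, 14)
  )
  base <- if (!is.null(rv) && rv %in% names(finals)) finals[[rv]] else c(900, 14)
  list(
    num_trees = if (is.null(num_trees)) base[1] else num_trees,
    max_depth = if (is.null(max_depth)) base[2] else max_depth,
    min_node_size = 1L,        # min leaf size 1 (split size 2 is implied)
    mtry_fun = function(p) max(1L, floor(sqrt(p))),
    bootstrap = FALSE,
    seed = as.integer(seed)
  )
}

#' Hyperparameter grid searched during tuning
#' @return list of candidate values per hyperparameter.
#' @export
rf_search_grid <- function() {
  list(num_trees = seq(500, 1600, by = 100), max_depth = 5:16,
       min_samples_split = c(2, 3), min_samples_leaf = c(1, 2, 3),
       max_features = c("sqrt", "log2"), bootstrap = c(TRUE, FALSE))
}

fit_rf <- function(X, y, config, importance = "none") {
  df <- as.data.frame(X)
  df$.y <- y
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = config$num_trees, max.depth = config$max_depth,
    min.node.size = config$min_node_size,
    mtry = config$mtry_fun(ncol(X)),
    replace = FALSE,
    sample.fraction = if (config$bootstrap) 0.632 else 1,
    importance = importance, seed = config$seed,
    num.threads = 1
  )
}

predict_rf <- function(fit, X) predict(fit, data = as.data.frame(X))$predictions

#' Feature-selection control parameters
#'
#' The three-stage per-fold selection: (1) recursive feature elimination
#' dropping the lowest-importance 20% per round down to `rfe_floor`
#' survivors; (2) removal of features below the `importance_quantile` of
#' impurity importance; (3) greedy correlation pruning dropping the
#' lower-ranked member of any pair with |r| above `cor_cutoff`. Survivors
#' are aggregated across folds and ranked by (frequency, median importance);
#' the top `n_final` become the fixed set.
#'
#' @param rfe_floor RFE stopping size (default 30).
#' @param rfe_drop_frac fraction dropped per RFE round (default 0.2).
#' @param importance_quantile stage-2 quantile cut (default 0.1).
#' @param cor_cutoff absolute-correlation cutoff (default 0.95).
#' @param n_final size of the fixed feature set (default 20).
#' @param num_trees trees per selection forest (smaller than the final
#'   forests; selection refits many times).
#' @export
fs_control <- function(rfe_floor = 30, rfe_drop_frac = 0.2,
                       importance_quantile = 0.1, cor_cutoff = 0.95,
                       n_final = 20, num_trees = 200) {
  list(rfe_floor = rfe_floor, rfe_drop_frac = rfe_drop_frac,
       importance_quantile = importance_quantile, cor_cutoff = cor_cutoff,
       n_final = n_final, num_trees = num_trees)
}

cor_prune <- function(X, ranked, cutoff) {
  keep <- ranked
  if (length(keep) < 2) return(keep)
  cm <- abs(suppressWarnings(cor(X[, keep, drop = FALSE])))
  cm[is.na(cm)] <- 0
  drop <- character(0)
  for (i in seq_along(keep)) {
    if (keep[i] %in% drop) next
    worse <- keep[-seq_len(i)]
    hit <- worse[cm[keep[i], worse] > cutoff]
    drop <- union(drop, hit)
  }
  setdiff(keep, drop)
}

select_fold_features <- function(X, y, control, config) {
  feats <- colnames(X)
  # stage 1: RFE down to the floor
  while (length(feats) > control$rfe_floor) {
    fit <- fit_rf(X[, feats, drop = FALSE], y,
                  utils::modifyList(config, list(num_trees = control$num_trees)),
                  importance = "impurity")
    imp <- sort(fit$variable.importance)
    n_drop <- max(1L, floor(length(feats) * control$rfe_drop_frac))
    n_drop <- min(n_drop, length(feats) - control$rfe_floor)
    feats <- setdiff(feats, names(imp)[seq_len(n_drop)])
  }
  fit <- fit_rf(X[, feats, drop = FALSE], y,
                utils::modifyList(config, list(num_trees = control$num_trees)),
                importance = "impurity")
  imp <- fit$variable.importance
  # stage 2: drop the low-importance tail
  cut <- quantile(imp, control$importance_quantile)
  feats <- names(imp)[imp > cut]
  if (!length(feats)) feats <- names(which.max(imp))
  # stage 3: correlation pruning, keeping the higher-ranked member
  ranked <- feats[order(imp[feats], decreasing = TRUE)]
  kept <- cor_prune(X, ranked, control$cor_cutoff)
  list(features = kept, importance = imp[kept])
}

#' Three-stage cross-fold feature selection
#'
#' Runs the per-fold RFE / importance-cut / correlation-prune cascade on the
#' training tanks of each fold, aggregates survivors across folds by
#' (frequency, median importance), and returns the fixed top set. A final
#' correlation prune is applied to the fixed set on the full pool, matching
#' the final-training protocol.
#'
#' @param labeled labeled feature table from [assign_pseudolabels()].
#' @param rv response variable to select for.
#' @param folds folds from [enumerate_folds()] (selection uses each fold's
#'   training tanks).
#' @param control an [fs_control()].
#' @param config an [rf_config()].
#' @return list with `features` (character, at most `n_final`; fewer with a
#'   warning when not enough survive) and the aggregate `ranking` tibble.
#' @export
select_features <- function(labeled, rv, folds = NULL, control = fs_control(),
                            config = rf_config(rv)) {
  featcols <- feature_columns(labeled)
  if (length(featcols) < control$n_final)
    warning("fewer candidate features (", length(featcols),
            ") than requested final set (", control$n_final, ")")
  if (is.null(folds)) folds <- enumerate_folds(labeled)
  per_fold <- lapply(seq_len(nrow(folds)), function(i) {
    pool <- labeled[labeled$tank_id %in% folds$train_tanks[[i]], ]
    sel <- select_fold_features(as.matrix(pool[, featcols]), pool[[rv]],
                                control, config)
    tibble::tibble(fold_id = folds$fold_id[i], feature = sel$features,
                   importance = unname(sel$importance))
  })
  agg <- dplyr::bind_rows(per_fold) |>
    dplyr::group_by(feature) |>
    dplyr::summarise(frequency = dplyr::n(),
                     median_importance = median(importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(frequency), dplyr::desc(median_importance))
  top <- head(agg$feature, control$n_final)
  if (length(top) < control$n_final)
    warning("only ", length(top), " features survived selection; returning all")
  # final correlation prune of the fixed set on the full pool
  ranked <- top
  final <- cor_prune(as.matrix(labeled[, featcols]), ranked, control$cor_cutoff)
  list(features = final, ranking = agg)
}

fold_split <- function(labeled, fold, val_fraction = 0.2, seed = 50) {
  test <- labeled[labeled$tank_id %in% fold$test_tanks[[1]] &
                    labeled$label_type == "ground_truth", ]
  pool <- labeled[labeled$tank_id %in% fold$train_tanks[[1]], ]
  set.seed(seed + fold$fold_id)
  n_val <- floor(nrow(pool) * val_fraction)
  val_idx <- sample(nrow(pool), n_val)
  list(train = pool[-val_idx, ], val = pool[val_idx, ], test = test)
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Tank-permutation cross-validated random-forest state estimation
#'
#' For every fold: the training tanks' records (labels and pseudolabels)
#' are split 80/20 into train and validation, a forest is fitted per
#' response on the training split, and evaluation uses only the labeled
#' records of the six test tanks. Plant-level leakage is asserted per fold.
#' Out-of-fold (OOF) predictions average each labeled record's predictions
#' over all folds in which its tank was held out.
#'
#' @param labeled labeled table from [assign_pseudolabels()].
#' @param rvs response variables to model (default all eight).
#' @param folds folds from [enumerate_folds()].
#' @param features fixed feature set (default: all feature columns).
#' @param config_fun function `rv -> rf_config`; default uses the tuned
#'   per-response settings.
#' @param val_fraction validation share of the training tanks (default 0.2).
#' @return list with `metrics` (per fold x rv: `r2`, `rmse`, n's),
#'   `summary` (cross-fold mean and SD per rv), and `oof` (per record x rv:
#'   observed, mean predicted, `r2`-ready).
#' @export
run_cv <- function(labeled, rvs = rv_names(), folds = NULL, features = NULL,
                   config_fun = rf_config, val_fraction = 0.2) {
  if (is.null(folds)) folds <- enumerate_folds(labeled)
  if (is.null(features)) features <- feature_columns(labeled)
  stopifnot(all(features %in% names(labeled)), all(rvs %in% names(labeled)))
  metrics <- list(); oof <- list()
  for (i in seq_len(nrow(folds))) {
    sp <- fold_split(labeled, folds[i, ], val_fraction)
    if (length(intersect(sp$test$plant_id,
                         c(sp$train$plant_id, sp$val$plant_id))))
      stop("leakage: test plants appear in the training pool (fold ",
           folds$fold_id[i], ")")
    if (!nrow(sp$test)) next
    Xtr <- as.matrix(sp$train[, features])
    Xte <- as.matrix(sp$test[, features])
    for (rv in rvs) {
      cfg <- config_fun(rv)
      fit <- fit_rf(Xtr, sp$train[[rv]], cfg)
      pred <- predict_rf(fit, Xte)
      obs <- sp$test[[rv]]
      metrics[[length(metrics) + 1L]] <- tibble::tibble(
        fold_id = folds$fold_id[i], rv = rv,
        r2 = r_squared(obs, pred),
        rmse = sqrt(mean((obs - pred)^2)),
        n_test = nrow(sp$test), n_train = nrow(sp$train), n_val = nrow(sp$val)
      )
      oof[[length(oof) + 1L]] <- tibble::tibble(
        fold_id = folds$fold_id[i], plant_id = sp$test$plant_id,
        DAT = sp$test$DAT, rv = rv, observed = obs, predicted = pred
      )
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  oof_all <- dplyr::bind_rows(oof)
  oof_agg <- oof_all |>
    dplyr::group_by(plant_id, DAT, rv) |>
    dplyr::summarise(observed = observed[1], predicted = mean(predicted),
                     n_folds = dplyr::n(), .groups = "drop")
  summary <- metrics |>
    dplyr::group_by(rv) |>
    dplyr::summarise(mean_r2 = mean(r2), sd_r2 = sd(r2),
                     mean_rmse = mean(rmse), sd_rmse = sd(rmse),
                     .groups = "drop")
  list(metrics = metrics, summary = summary, oof = oof_agg)
}

#' Estimate response-variable trajectories from daily-average features
#'
#' Refits one forest per response on the full labeled + pseudolabeled
#' single-image pool, then predicts the daily-average feature table (which
#' the forests never saw in training) to produce dense per-plant response
#' trajectories - the input of the high-resolution RF-AE screen.
#'
#' @param labeled labeled single-image table from [assign_pseudolabels()].
#' @param daily daily-average feature table covering the DAT grid.
#' @param rvs responses to estimate.
#' @param features fixed feature set (default: all feature columns).
#' @param config_fun function `rv -> rf_config`.
#' @return tibble `plant_id, tank_id, treatment, DAT` plus one column per
#'   estimated response, ready for [make_trajectories()].
#' @export
estimate_trajectories <- function(labeled, daily, rvs = rv_names(),
                                  features = NULL, config_fun = rf_config) {
  if (is.null(features)) features <- feature_columns(labeled)
  stopifnot(all(features %in% names(daily)))
  out <- daily[, c("plant_id", "tank_id", "treatment", "DAT")]
  Xtr <- as.matrix(labeled[, features])
  Xnew <- as.matrix(daily[, features])
  for (rv in rvs) {
    fit <- fit_rf(Xtr, labeled[[rv]], config_fun(rv))
    out[[rv]] <- predict_rf(fit, Xnew)
  }
  tibble::as_tibble(out)
}
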