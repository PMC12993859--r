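tank_roster <- function() {
  tidyr::expand_grid(treatment = c("T1", "T2", "T3"), tank = 1:3) |>
    dplyr::mutate(tank_id = sprintf("%s_tk%d", treatment, tank))
}

test_that("fold enumeration matches the brute-force tank permutation count", {
  folds <- enumerate_folds(tank_roster())
  expect_equal(nrow(folds), 27)
  expect_equal(length(unique(vapply(folds$test_tanks, paste, collapse = ",",
                                    character(1)))), 27)
  all_tanks <- tank_roster()$tank_id
  # each tank is held out for testing in exactly 18 of the 27 folds
  test_counts <- table(unlist(folds$test_tanks))
  expect_true(all(test_counts == 18))
  expect_setequal(names(test_counts), all_tanks)
  # brute force: per treatment, each 2-tank test pair appears in 9 folds
  for (trt in c("T1", "T2", "T3")) {
    pairs <- vapply(folds$test_tanks, function(tt) {
      paste(sort(grep(trt, tt, value = TRUE)), collapse = "+")
    }, character(1))
    expect_true(all(table(pairs) == 9))
    expect_equal(length(unique(pairs)), 3)
  }
  # every fold has 6 test + 3 train tanks, disjoint
  for (i in 1:27) {
    expect_length(folds$test_tanks[[i]], 6)
    expect_length(folds$train_tanks[[i]], 3)
    expect_length(intersect(folds$test_tanks[[i]], folds$train_tanks[[i]]), 0)
  }
})

test_that("fold enumeration rejects incomplete rosters", {
  r <- tank_roster()[-1, ]
  expect_error(enumerate_folds(r), "3 treatments x 3 tanks")
})

test_that("pseudolabels are tank means with nearest-earlier-day matching", {
  gt <- tibble::tibble(
    plant_id = sprintf("T1_tk1_p%02d", 1:5),
    tank_id = "T1_tk1", treatment = "T1", DAT = 14,
    FW_g = c(10, 12, 14, 16, 18), DM_g = 1, N_pct = 5, P_pct = 1, K_pct = 8,
    Ca_pct = 1, Mg_pct = 0.4, S_pct = 0.3
  )
  gt2 <- dplyr::mutate(gt, DAT = 11, FW_g = FW_g / 2,
                       plant_id = sprintf("T1_tk1_p%02d", 6:10))
  recs <- tibble::tibble(plant_id = "T1_tk1_p20", tank_id = "T1_tk1",
                         treatment = "T1", DAT = c(12, 14, 20), source = "s",
                         f1 = 0.5)
  lab <- assign_pseudolabels(recs, dplyr::bind_rows(gt, gt2))
  # sampling-day record: mean of the five samples
  expect_equal(lab$FW_g[lab$DAT == 14], 14)
  # DAT 12 sits between sampling days 11 and 14: earlier day wins the tie
  expect_equal(lab$FW_g[lab$DAT == 12], 7)
  expect_equal(lab$label_dat[lab$DAT == 12], 11L)
  # DAT 20 takes the nearest day (14)
  expect_equal(lab$FW_g[lab$DAT == 20], 14)
  expect_true(all(lab$label_type == "pseudo"))
  # a single ground-truth row is its own tank mean
  lab1 <- assign_pseudolabels(recs[1, ], gt[1, ])
  expect_equal(lab1$FW_g, 10)
})

test_that("sampled plants keep their own ground truth as labels", {
  fs <- simulate_features(small_design(seed = 5), growth_model(),
                          named_registry(), n_pixels = 8)
  lab <- assign_pseudolabels(fs$features, fs$ground_truth)
  gt_rows <- lab[lab$label_type == "ground_truth", ]
  expect_equal(nrow(gt_rows), nrow(fs$ground_truth))
  j <- dplyr::inner_join(gt_rows, fs$ground_truth, by = c("plant_id", "DAT"),
                         suffix = c("", ".gt"))
  expect_equal(j$FW_g, j$FW_g.gt)
})

test_that("tanks without any ground truth are dropped with a warning", {
  fs <- simulate_features(small_design(seed = 5), growth_model(),
                          named_registry(), n_pixels = 8)
  gt <- fs$ground_truth[fs$ground_truth$tank_id != "T1_tk1", ]
  expect_warning(lab <- assign_pseudolabels(fs$features, gt), "T1_tk1")
  expect_false("T1_tk1" %in% lab$tank_id)
})

test_that("feature selection finds signal, drops constants and duplicates", {
  set.seed(8)
  n <- 200
  tanks <- tank_roster()
  pool <- tibble::tibble(
    plant_id = sprintf("p%03d", 1:n),
    tank_id = sample(tanks$tank_id, n, replace = TRUE),
    DAT = sample(4:26, n, replace = TRUE), source = "s"
  )
  pool$treatment <- sub("_tk\\d+$", "", pool$tank_id)
  y <- runif(n)
  pool$FW_g <- y
  pool$oracle <- y                       # exact copy of the response
  pool$dup_oracle <- y                   # duplicate: |r| = 1 with oracle
  pool$const <- 1                        # zero-variance feature
  for (k in 1:22) pool[[paste0("noise", k)]] <- runif(n)
  pool$label_type <- "pseudo"
  ctrl <- fs_control(rfe_floor = 15, n_final = 10, num_trees = 100)
  sel <- select_features(pool, "FW_g", enumerate_folds(pool)[1:5, ], ctrl)
  expect_lte(length(sel$features), 10)
  expect_true("oracle" %in% sel$features || "dup_oracle" %in% sel$features)
  # duplicates cannot both survive correlation pruning
  expect_false(all(c("oracle", "dup_oracle") %in% sel$features))
  expect_false("const" %in% sel$features)
  # the perfect feature ranks first in the aggregate
  expect_true(sel$ranking$feature[1] %in% c("oracle", "dup_oracle"))
})

test_that("correlation pruning keeps the higher-ranked member of a pair", {
  set.seed(1)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, "b"] <- X[, "a"]                 # |r| = 1
  kept <- nutrimon:::cor_prune(X, c("a", "b", "c"), 0.95)
  expect_equal(kept, c("a", "c"))
})

test_that("cross-validation learns constructed signal and not shuffled labels", {
  fs <- simulate_features(small_design(seed = 2),
                          growth_model(residual_sd = 0, pixel_noise_sd = 0),
                          vi_registry(), n_pixels = 8)
  lab <- assign_pseudolabels(fs$features, fs$ground_truth)
  folds <- enumerate_folds(lab)
  cfg <- function(rv) rf_config(rv, num_trees = 150)
  cv <- run_cv(lab, rvs = "FW_g", folds = folds[1:6, ], config_fun = cfg)
  expect_true(all(cv$metrics$r2 >= 0.9))
  expect_true(all(cv$metrics$rmse >= 0))
  # summary is recomputable from the per-fold values
  expect_equal(cv$summary$mean_r2, mean(cv$metrics$r2))
  expect_equal(cv$summary$sd_r2, sd(cv$metrics$r2))
  # shuffling labels across records destroys the signal
  set.seed(3)
  lab2 <- lab
  lab2$FW_g <- sample(lab2$FW_g)
  cv2 <- run_cv(lab2, rvs = "FW_g", folds = folds[1:4, ], config_fun = cfg)
  expect_lt(mean(cv2$metrics$r2), 0.1)
})

test_that("no plant appears in both train and test of any fold", {
  fs <- simulate_features(small_design(seed = 2), growth_model(),
                          named_registry(), n_pixels = 8)
  lab <- assign_pseudolabels(fs$features, fs$ground_truth)
  folds <- enumerate_folds(lab)
  for (i in seq_len(nrow(folds))) {
    sp <- nutrimon:::fold_split(lab, folds[i, ])
    expect_length(intersect(sp$test$plant_id,
                            c(sp$train$plant_id, sp$val$plant_id)), 0)
    expect_true(all(sp$test$label_type == "ground_truth"))
    # 80/20 split of the training tanks
    expect_equal(nrow(sp$val), floor(0.2 * (nrow(sp$val) + nrow(sp$train))))
  }
})

test_that("estimated trajectories follow the features and truncation rules", {
  fs <- simulate_features(small_design(seed = 6), growth_model(),
                          named_registry(), n_pixels = 8)
  lab <- assign_pseudolabels(fs$features, fs$ground_truth)
  cfg <- function(rv) rf_config(rv, num_trees = 100)
  est <- estimate_trajectories(lab, fs$features, rvs = "FW_g",
                               config_fun = cfg)
  expect_setequal(names(est), c("plant_id", "tank_id", "treatment", "DAT",
                                "FW_g"))
  # truncated plant -> truncated estimated trajectory
  sampled11 <- fs$ground_truth$plant_id[fs$ground_truth$DAT == 11][1]
  expect_equal(max(est$DAT[est$plant_id == sampled11]), 11)
  # constant features predict a constant trajectory
  daily_const <- fs$features[fs$features$plant_id == sampled11, ]
  fc <- feature_columns(daily_const)
  daily_const[, fc] <- lapply(daily_const[, fc], function(x) rep(x[1], length(x)))
  est_const <- estimate_trajectories(lab, daily_const, rvs = "FW_g",
                                     config_fun = cfg)
  expect_equal(length(unique(round(est_const$FW_g, 9))), 1)
})

test_that("tuned configuration matches the per-response settings", {
  expect_equal(rf_config("P_pct")$num_trees, 1300)
  expect_equal(rf_config("P_pct")$max_depth, 12)
  expect_equal(rf_config("FW_g")$num_trees, 900)
  expect_equal(rf_config("FW_g")$max_depth, 14)
  expect_false(rf_config("FW_g")$bootstrap)
  expect_equal(rf_config("FW_g")$seed, 50L)
  expect_equal(rf_config("FW_g")$mtry_fun(106), 10)
  grid <- rf_search_grid()
  expect_true(all(rf_config("N_pct")$num_trees %in% grid$num_trees))
  expect_true(all(rf_config("N_pct")$max_depth %in% grid$max_depth))
})
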