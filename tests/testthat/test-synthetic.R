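test_that("design validation catches infeasible and malformed designs", {
  expect_error(experiment_design(plants_per_tank = 24), "infeasible")
  expect_error(experiment_design(treatments = c(T1 = 1.2, T2 = 0.5, T3 = 0.25)),
               "fraction")
  expect_error(experiment_design(sampling_days = c(2, 11)), "sampling_days")
  expect_s3_class(experiment_design(), "experiment_design")
})

test_that("default schedule yields 9 tanks x 7 days x 5 heads of ground truth", {
  sim <- simulate_experiment(experiment_design(seed = 4), growth_model())
  expect_equal(nrow(sim$ground_truth), 315)
  counts <- dplyr::count(sim$ground_truth, tank_id, DAT)
  expect_true(all(counts$n == 5))
  expect_equal(nrow(counts), 9 * 7)
  # sampled plants emit no states after their sampling day
  st <- sim$states
  sampled <- st[!is.na(st$sampled_dat), ]
  expect_true(all(sampled$DAT <= sampled$sampled_dat))
})

test_that("no sampling days means no ground truth and full survival", {
  d <- experiment_design(sampling_days = integer(0), plants_per_tank = 10,
                         seed = 2)
  sim <- simulate_experiment(d, growth_model())
  expect_equal(nrow(sim$ground_truth), 0)
  last <- tapply(sim$states$DAT, sim$states$plant_id, max)
  expect_true(all(last == d$imaging_end))
})

test_that("identical seeds reproduce identical tables", {
  a <- simulate_experiment(small_design(seed = 9), growth_model())
  b <- simulate_experiment(small_design(seed = 9), growth_model())
  expect_identical(a$states, b$states)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_experiment(small_design(seed = 10), growth_model())
  expect_false(identical(a$ground_truth, c$ground_truth))
})

test_that("plant states respect growth invariants", {
  sim <- simulate_experiment(small_design(seed = 3), growth_model())
  st <- sim$states
  expect_true(all(st$FW_g > 0))
  expect_true(all(st$DM_g < st$FW_g))
  expect_true(all(as.matrix(st[, paste0(c("N", "P", "K", "Ca", "Mg", "S"),
                                        "_pct")]) > 0))
  # fresh weight is non-decreasing along every living plant's trajectory
  mono <- tapply(st$FW_g, st$plant_id, function(x) all(diff(x) >= 0))
  expect_true(all(mono))
})

test_that("final fresh weight preserves the treatment ordering across seeds", {
  for (s in 1:10) {
    sim <- simulate_experiment(small_design(seed = s), growth_model())
    fin <- sim$states[sim$states$DAT == 26, ]
    m <- tapply(fin$FW_g, fin$treatment, mean)
    expect_true(m[["T1"]] >= m[["T2"]], info = paste("seed", s))
    expect_true(m[["T2"]] >= m[["T3"]], info = paste("seed", s))
  }
})

test_that("treatment dominates the simulated variance decomposition", {
  sim <- simulate_experiment(experiment_design(seed = 6), growth_model())
  vd <- variance_decomposition(sim$ground_truth[sim$ground_truth$DAT == 26, ])
  expect_gt(vd[["frac_treatment"]], vd[["frac_tank"]])
  expect_gt(vd[["frac_treatment"]], vd[["frac_residual"]])
  expect_gt(vd[["frac_treatment"]], 0.5)
  expect_equal(vd[["ss_total"]],
               vd[["ss_treatment"]] + vd[["ss_tank"]] + vd[["ss_residual"]])
})

test_that("logistic fit recovers generating parameters on noise-free output", {
  gm <- growth_model(tank_sd = 0, plant_sd = 0, conc_sd = 0, residual_sd = 0)
  sim <- simulate_experiment(small_design(seed = 1), gm)
  fit <- fit_growth_curve(sim$states)
  expect_equal(fit$rate, rep(gm$fw_rate, 3), tolerance = 1e-6)
  expect_equal(fit$midpoint, rep(gm$fw_midpoint, 3), tolerance = 1e-6)
  expect_equal(fit$asymptote,
               unname(gm$fw_asymptote * gm$treatment_scale[fit$treatment]),
               tolerance = 1e-6)
})

test_that("design YAML round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  d <- small_design(seed = 12)
  write_experiment_design(d, path)
  d2 <- read_experiment_design(path)
  expect_equal(d2, d)
})

test_that("rendered cubes follow the reflectance link exactly at zero noise", {
  gm <- separated_model()
  sim <- simulate_experiment(small_design(seed = 2), gm)
  slice <- sim$states[sim$states$DAT == 20, ][1:4, ]
  r <- render_cube(slice, gm, size = c(64, 64))
  expect_s3_class(r$cube, "msi_cube")
  # masks are pairwise disjoint
  overlap <- Reduce(`+`, r$masks)
  expect_true(all(overlap <= 1))
  # in-mask pixels carry exactly the link-predicted channel values
  refl <- nutrimon:::link_reflectance(gm, slice$FW_g, slice$N_pct)
  for (i in seq_len(nrow(slice))) {
    for (k in c("red", "nir850")) {
      vals <- unclass(r$cube)[, , k][r$masks[[i]]]
      expect_equal(unique(round(vals, 12)),
                   as.numeric(round(refl[i, k], 12)))
    }
  }
  # background outside all masks
  bg <- unclass(r$cube)[, , "red"][overlap == 0]
  expect_true(all(bg == gm$background))
})

test_that("healthy plants show higher NDVI than depleted ones at matched DAT", {
  gm <- separated_model()
  sim <- simulate_experiment(small_design(seed = 2), gm)
  slice <- sim$states[sim$states$DAT == 20, ]
  pick <- rbind(slice[slice$treatment == "T1", ][1, ],
                slice[slice$treatment == "T3", ][1, ])
  r <- render_cube(pick, gm, size = c(64, 64))
  ndvi <- function(pid) {
    img <- compute_index(r$cube, r$masks[[pid]], "nd(nir850, red)")
    mean(img, na.rm = TRUE)
  }
  # hand-evaluated link: T1 (nu=1) gives brighter NIR and darker red than T3
  expect_gt(ndvi(pick$plant_id[1]), ndvi(pick$plant_id[2]))
})

test_that("rendering fails when plants cannot be placed", {
  sim <- simulate_experiment(small_design(seed = 2), growth_model())
  slice <- sim$states[sim$states$DAT == 20, ][1:9, ]
  expect_error(render_cube(slice, growth_model(), size = c(12, 12)),
               "too small")
})

test_that("cubes and masks survive a TIFF/PNG round trip", {
  gm <- separated_model()
  sim <- simulate_experiment(small_design(seed = 2), gm)
  slice <- sim$states[sim$states$DAT == 20, ][1:2, ]
  r <- render_cube(slice, gm, size = c(48, 48))
  tf <- withr::local_tempfile(fileext = ".tif")
  pf <- withr::local_tempfile(fileext = ".png")
  write_msi_tiff(r$cube, tf)
  back <- read_msi_tiff(tf)
  expect_equal(dim(back), dim(r$cube))
  expect_equal(unclass(back)[, , "red"], unclass(r$cube)[, , "red"],
               tolerance = 1e-6)
  write_mask_png(r$masks[[1]], pf)
  expect_identical(read_mask_png(pf), r$masks[[1]])
})
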