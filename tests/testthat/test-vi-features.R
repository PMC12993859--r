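make_cube <- function(vals = NULL, n = 5, seed = 1) {
  if (is.null(vals)) {
    set.seed(seed)
    vals <- array(runif(n * n * 10), dim = c(n, n, 10))
  }
  msi_cube(vals)
}

test_that("channel map is ordered and well formed", {
  ch <- msi_channels()
  expect_equal(nrow(ch), 10)
  expect_true(all(diff(ch$peak_nm[1:9]) > 0))
  expect_silent(nutrimon:::validate_channel_map(ch))
})

test_that("normalized difference behaves on hand-computable pixels", {
  arr <- array(0.5, dim = c(2, 2, 10))
  cube <- msi_cube(arr)
  mask <- matrix(TRUE, 2, 2)
  # nir850 == red -> NDVI identically zero
  expect_true(all(compute_index(cube, mask, "nd(nir850, red)") == 0))
  arr[, , 8] <- 0.8; arr[, , 5] <- 0.2
  expect_equal(unique(as.numeric(compute_index(msi_cube(arr), mask,
                                               "nd(nir850, red)"))), 0.6)
})

test_that("zero denominators never produce non-finite values", {
  arr <- array(0, dim = c(3, 3, 10))
  cube <- msi_cube(arr)
  mask <- matrix(TRUE, 3, 3)
  img <- compute_index(cube, mask, "nd(nir850, red)")
  expect_true(all(img == 0))
  img2 <- compute_index(cube, mask, "rr(green, red)")
  expect_true(all(is.finite(img2)))
})

test_that("unknown channels and empty masks are rejected", {
  cube <- make_cube()
  expect_error(compute_index(cube, matrix(TRUE, 5, 5), "nd(swir, red)"),
               "unknown channel")
  expect_error(compute_index(cube, matrix(FALSE, 5, 5), "nd(nir850, red)"),
               "empty")
})

test_that("index values match a per-pixel brute-force oracle on random cubes", {
  reg <- vi_registry()
  for (seed in 1:3) {
    cube <- make_cube(n = 5, seed = seed)
    mask <- matrix(TRUE, 5, 5)
    for (row in c(1, 7, nrow(reg))) {
      img <- compute_index(cube, mask, reg$formula[row])
      # oracle: literal re-evaluation pixel by pixel with plain arithmetic
      e <- parse(text = reg$formula[row])[[1]]
      vars <- all.vars(e)
      for (i in 1:5) for (j in 1:5) {
        px <- lapply(vars, function(v) as.numeric(unclass(cube)[i, j, v]))
        names(px) <- vars
        px$nd <- function(a, b) if (abs(a + b) < 1e-9) 0 else (a - b) / (a + b)
        px$rr <- function(a, b) if (abs(b) < 1e-9) 0 else a / b
        expect_equal(img[i, j], eval(e, envir = px), tolerance = 1e-12)
      }
    }
  }
})

test_that("normalized differences are bounded and scale invariant", {
  for (seed in 1:5) {
    cube <- make_cube(n = 4, seed = seed)
    mask <- matrix(TRUE, 4, 4)
    img <- compute_index(cube, mask, "nd(nir850, red)")
    expect_true(all(img >= -1 & img <= 1))
    # uniform scaling of both channels leaves the index unchanged
    arr2 <- unclass(cube)
    arr2[, , 5] <- 0.37 * arr2[, , 5]
    arr2[, , 8] <- 0.37 * arr2[, , 8]
    img2 <- compute_index(msi_cube(arr2), mask, "nd(nir850, red)")
    expect_equal(img2, img, tolerance = 1e-12)
  }
})

test_that("foliar summaries use the population SD convention", {
  expect_equal(summarize_index(rep(0.4, 9)),
               c(mean = 0.4, median = 0.4, std = 0))
  # {0, 1} equally: mean 0.5 and population sd 0.5 (divisor n, not n-1)
  expect_equal(summarize_index(c(0, 1, 0, 1)),
               c(mean = 0.5, median = 0.5, std = 0.5))
  expect_equal(summarize_index(0.7), c(mean = 0.7, median = 0.7, std = 0))
})

test_that("registry structure is validated and round-trips through YAML", {
  reg <- vi_registry()
  expect_equal(nrow(reg), choose(9, 2))       # all narrow-band pairs
  expect_true(all(c("NDVI", "GNDVI", "NDRE", "NDWI", "GRVI") %in% reg$name))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_vi_registry(reg, path)
  expect_equal(read_vi_registry(path), reg)
  expect_error(validate_registry(tibble::tibble(name = "bad",
                                                formula = "nd(swir, red)")),
               "unknown channel")
  expect_error(validate_registry(tibble::tibble(name = "evil",
                                                formula = "system('ls')")),
               "disallowed")
})

test_that("feature tables carry three statistics per index", {
  gm <- separated_model()
  sim <- simulate_experiment(small_design(seed = 2, plants = 13), gm)
  slice <- sim$states[sim$states$DAT %in% c(10, 11), ]
  nights <- render_experiment(slice, gm, size = c(64, 96), captures = 1)
  reg <- named_registry()
  tbl <- build_feature_table(nights, reg, mode = "single_image")
  expect_equal(length(feature_columns(tbl)), nrow(reg) * 3)   # 5 x 3
  expect_true(all(tbl[[paste0(reg$name[1], "_std")]] >= 0))
  expect_equal(sort(unique(tbl$DAT)), c(10, 11))
})

test_that("identical captures make single-image and daily-average agree", {
  gm <- separated_model()   # zero pixel noise -> captures are identical
  sim <- simulate_experiment(small_design(seed = 2, plants = 13), gm)
  slice <- sim$states[sim$states$DAT == 10, ]
  nights <- render_experiment(slice, gm, size = c(64, 96), captures = 3)
  reg <- named_registry()
  single <- build_feature_table(nights, reg, mode = "single_image")
  daily <- build_feature_table(nights, reg, mode = "daily_average")
  fc <- feature_columns(single)
  expect_equal(as.data.frame(single[order(single$plant_id), fc]),
               as.data.frame(daily[order(daily$plant_id), fc]),
               tolerance = 1e-12)
})

test_that("hand-computed summaries match a two-night toy table", {
  # one plant, constant channels: summaries are the scalar index value
  arr <- array(0, dim = c(8, 8, 10))
  arr[, , 8] <- 0.8; arr[, , 5] <- 0.2; arr[, , 3] <- 0.4
  mask <- matrix(TRUE, 8, 8)
  nights <- list(
    list(DAT = 5, capture = 1, cube = msi_cube(arr, dat = 5),
         masks = list(T1_tk1_p01 = mask)),
    list(DAT = 6, capture = 1, cube = msi_cube(arr * 0.5, dat = 6),
         masks = list(T1_tk1_p01 = mask))
  )
  tbl <- build_feature_table(nights, named_registry())
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$NDVI_mean, c(0.6, 0.6))          # scale invariant
  expect_equal(tbl$GNDVI_median, c((0.8 - 0.4) / 1.2, (0.8 - 0.4) / 1.2))
  expect_equal(tbl$NDVI_std, c(0, 0))
  expect_equal(tbl$tank_id, c("T1_tk1", "T1_tk1"))
})

test_that("fast simulated features agree with rendered features at zero noise", {
  gm <- separated_model()
  d <- small_design(seed = 2, plants = 13)
  fs <- simulate_features(d, gm, named_registry(), n_pixels = 16)
  sim <- simulate_experiment(d, gm)
  slice <- sim$states[sim$states$DAT == 12, ]
  nights <- render_experiment(slice, gm, size = c(64, 96))
  rendered <- build_feature_table(nights, named_registry())
  fast <- fs$features[fs$features$DAT == 12, ]
  j <- dplyr::inner_join(rendered, fast, by = "plant_id",
                         suffix = c("_r", "_f"))
  expect_gt(nrow(j), 0)
  expect_equal(j$NDVI_mean_r, j$NDVI_mean_f, tolerance = 1e-10)
  expect_equal(j$NDWI_median_r, j$NDWI_median_f, tolerance = 1e-10)
})

test_that("synthetic treatments separate monotonically in NDVI at zero noise", {
  fs <- simulate_features(small_design(seed = 5), separated_model(),
                          named_registry(), n_pixels = 8)
  at20 <- fs$features[fs$features$DAT == 20, ]
  m <- tapply(at20$NDVI_mean, at20$treatment, mean)
  expect_true(m[["T1"]] > m[["T2"]])
  expect_true(m[["T2"]] > m[["T3"]])
})
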