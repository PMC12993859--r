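#' Render one imaging night as a multispectral cube with per-plant masks
#'
#' Plants are laid out on a grid and drawn as quasi-circular rosettes whose
#' radius grows with the square root of fresh weight; pixel reflectance per
#' channel follows the affine reflectance link plus optional Gaussian pixel
#' noise, and background pixels take the model's background value. Masks are
#' disjoint by construction (one grid cell per plant).
#'
#' @param states one-DAT slice of the state table (one row per visible plant).
#' @param model a [growth_model()].
#' @param size `c(height, width)` in pixels.
#' @param capture 1-based within-night capture index (metadata and noise
#'   stream only; the latent state is the same across a night).
#' @param seed seed for the pixel-noise stream; the default derives one from
#'   the plant ids, DAT and capture so re-rendering is reproducible.
#' @return list with `cube` (an [msi_cube()]) and `masks` (named list of
#'   logical matrices keyed by `plant_id`).
#' @export
render_cube <- function(states, model = growth_model(), size = c(128, 160),
                        capture = 1L, seed = NULL) {
  stopifnot(nrow(states) >= 1, length(size) == 2)
  dat <- unique(states$DAT)
  if (length(dat) != 1) stop("states must come from a single DAT")
  n <- nrow(states)
  H <- size[1]; W <- size[2]
  ncol_g <- ceiling(sqrt(n * W / H))
  nrow_g <- ceiling(n / ncol_g)
  cell_h <- H / nrow_g; cell_w <- W / ncol_g
  cell <- min(cell_h, cell_w)
  if (cell < 6) stop("image size too small to place ", n, " plants")
  if (is.null(seed)) {
    seed <- (sum(utf8ToInt(paste(states$plant_id, collapse = ""))) +
               1000L * dat + capture) %% .Machine$integer.max
  }
  set.seed(seed)

  refl <- link_reflectance(model, states$FW_g, states$N_pct)  # n x 10
  arr <- array(model$background, dim = c(H, W, 10))
  masks <- vector("list", n)
  names(masks) <- states$plant_id
  ys <- matrix(rep(seq_len(H), W), H, W)
  xs <- matrix(rep(seq_len(W), each = H), H, W)

  for (i in seq_len(n)) {
    gr <- (i - 1) %/% ncol_g; gc <- (i - 1) %% ncol_g
    cy <- (gr + 0.5) * cell_h; cx <- (gc + 0.5) * cell_w
    r0 <- 0.45 * cell * sqrt(min(states$FW_g[i] / model$fw_asymptote, 1))
    r0 <- max(r0, 1.5)
    phase <- runif(1, 0, 2 * pi)
    theta <- atan2(ys - cy, xs - cx)
    # scalloped edge gives the rosette its quasi-circular outline
    redge <- r0 * (1 + 0.08 * sin(5 * theta + phase))
    m <- (ys - cy)^2 + (xs - cx)^2 <= redge^2
    masks[[i]] <- m
    npix <- sum(m)
    for (k in 1:10) {
      vals <- rep(refl[i, k], npix)
      if (model$pixel_noise_sd > 0) vals <- vals + rnorm(npix, 0, model$pixel_noise_sd)
      slice <- arr[, , k]
      slice[m] <- vals
      arr[, , k] <- slice
    }
  }
  list(cube = msi_cube(arr, dat = dat, capture = capture), masks = masks)
}

#' Render all nights (and captures) of a simulated experiment
#'
#' Convenience wrapper over [render_cube()] producing the input expected by
#' [build_feature_table()]. Keep sizes and rosters small: rendering is meant
#' for pixel-level tests and demonstrations, while [simulate_features()] is
#' the fast path to full feature tables.
#'
#' @param states state table from [simulate_experiment()].
#' @param model a [growth_model()].
#' @param size image size in pixels, `c(height, width)`.
#' @param captures number of captures per night (hourly from 10 pm; 8 in the
#'   full acquisition schedule).
#' @return list of night records, each `list(DAT, capture, cube, masks)`.
#' @export
render_experiment <- function(states, model = growth_model(), size = c(128, 160),
                              captures = 1L) {
  nights <- list()
  for (d in sort(unique(states$DAT))) {
    slice <- states[states$DAT == d, ]
    for (cp in seq_len(captures)) {
      r <- render_cube(slice, model, size = size, capture = cp)
      nights[[length(nights) + 1L]] <- list(DAT = d, capture = cp,
                                            cube = r$cube, masks = r$masks)
    }
  }
  nights
}
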