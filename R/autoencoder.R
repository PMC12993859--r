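#' Autoencoder training configuration
#'
#' The early-warning tier uses a fixed-width 64-32-64 encoder-decoder
#' regardless of window length: the L-day window enters through a linear map
#' to width 64, hidden layers use ReLU, and the output layer is linear.
#' Training is full-batch Adam (learning rate 0.001) for 100 epochs on
#' min-max-normalised windows; the anomaly threshold is `multiplier` times
#' the mean per-window training reconstruction error at the final epoch.
#'
#' @param epochs training epochs (default 100).
#' @param lr Adam learning rate (default 0.001).
#' @param hidden hidden layer widths (default `c(64, 32, 64)`).
#' @param multiplier threshold multiplier on the final-epoch mean training
#'   error (default 1.5).
#' @param max_train cap on the number of training windows; the first
#'   `max_train` healthy windows in ascending plant-id order are used
#'   (default 40).
#' @param seed RNG seed for weight initialisation.
#' @export
ae_config <- function(epochs = 100, lr = 0.001, hidden = c(64, 32, 64),
                      multiplier = 1.5, max_train = 40, seed = 1) {
  stopifnot(epochs >= 1, lr > 0, length(hidden) == 3, multiplier > 0,
            max_train >= 1)
  list(epochs = epochs, lr = lr, hidden = hidden, multiplier = multiplier,
       max_train = max_train, seed = as.integer(seed))
}

relu <- function(x) pmax(x, 0)

ae_forward <- function(p, X) {
  h1 <- relu(sweep(X %*% p$W1, 2, p$b1, `+`))
  h2 <- relu(sweep(h1 %*% p$W2, 2, p$b2, `+`))
  h3 <- relu(sweep(h2 %*% p$W3, 2, p$b3, `+`))
  out <- sweep(h3 %*% p$W4, 2, p$b4, `+`)
  list(h1 = h1, h2 = h2, h3 = h3, out = out)
}

ae_init <- function(L, hidden, seed) {
  set.seed(seed)
  dims <- c(L, hidden, L)
  p <- list()
  for (i in 1:4) {
    p[[paste0("W", i)]] <- matrix(rnorm(dims[i] * dims[i + 1], 0,
                                        sqrt(2 / dims[i])),
                                  dims[i], dims[i + 1])
    p[[paste0("b", i)]] <- rep(0, dims[i + 1])
  }
  p
}

# One full-batch gradient step worth of grads for mean-squared
# reconstruction loss; returns grads in the same shape as the params.
ae_grads <- function(p, X, fwd) {
  n <- nrow(X); L <- ncol(X)
  d_out <- 2 * (fwd$out - X) / (n * L)
  g <- list()
  g$W4 <- t(fwd$h3) %*% d_out; g$b4 <- colSums(d_out)
  d3 <- (d_out %*% t(p$W4)) * (fwd$h3 > 0)
  g$W3 <- t(fwd$h2) %*% d3; g$b3 <- colSums(d3)
  d2 <- (d3 %*% t(p$W3)) * (fwd$h2 > 0)
  g$W2 <- t(fwd$h1) %*% d2; g$b2 <- colSums(d2)
  d1 <- (d2 %*% t(p$W2)) * (fwd$h1 > 0)
  g$W1 <- t(X) %*% d1; g$b1 <- colSums(d1)
  g
}

adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

#' Fit the early-warning autoencoder on healthy windows
#'
#' Trains on healthy (control-treatment) windows only: if the window matrix
#' carries a `treatment` attribute, non-T1 rows are dropped; rows are then
#' ordered by plant id and capped at the first `max_train` (default 40, or
#' as many as destructive sampling left available). Min-max normalisation
#' per window position is fitted on the training windows and stored with the
#' model. The detection threshold is `multiplier` x mean per-window training
#' MSE at the final epoch.
#'
#' @param windows numeric matrix (windows x L) with plant-id rownames,
#'   e.g. from [trajectory_windows()].
#' @param config an [ae_config()].
#' @param healthy_treatment treatment label treated as healthy (default
#'   `"T1"`), used only when `windows` has a `treatment` attribute.
#' @return an `ae_model` with elements `params`, `norm`, `tau`,
#'   `train_error`, `n_train`, `config`.
#' @export
fit_ae <- function(windows, config = ae_config(), healthy_treatment = "T1") {
  stopifnot(is.matrix(windows))
  trt <- attr(windows, "treatment")
  if (!is.null(trt)) windows <- windows[trt[rownames(windows)] == healthy_treatment, , drop = FALSE]
  if (nrow(windows) == 0) stop("no healthy windows to train on")
  if (nrow(windows) < 2) stop("need at least 2 healthy windows")
  if (ncol(windows) < 2) stop("window length must be >= 2")
  if (anyNA(windows)) stop("windows contain missing values")
  if (!is.null(rownames(windows))) windows <- windows[order(rownames(windows)), , drop = FALSE]
  n_use <- min(nrow(windows), config$max_train)
  train <- windows[seq_len(n_use), , drop = FALSE]

  mins <- apply(train, 2, min)
  rng <- apply(train, 2, max) - mins
  rng[rng == 0] <- 1                      # constant positions map to 0
  X <- sweep(sweep(train, 2, mins), 2, rng, `/`)

  L <- ncol(X)
  p <- ae_init(L, config$hidden, config$seed)
  state <- list(m = lapply(p, function(w) w * 0), v = lapply(p, function(w) w * 0))
  for (t in seq_len(config$epochs)) {
    fwd <- ae_forward(p, X)
    g <- ae_grads(p, X, fwd)
    upd <- adam_step(p, g, state, config$lr, t)
    p <- upd$p; state <- upd$state
  }
  final <- ae_forward(p, X)
  per_window <- rowMeans((final$out - X)^2)
  train_error <- mean(per_window)
  structure(list(params = p, norm = list(mins = mins, rng = rng),
                 tau = config$multiplier * train_error,
                 train_error = train_error, n_train = n_use,
                 input_dim = L, config = config),
            class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf("<ae_model L=%d -> %s; n_train=%d; train MSE=%.3g; tau=%.3g>\n",
              x$input_dim, paste(x$config$hidden, collapse = "-"),
              x$n_train, x$train_error, x$tau))
  invisible(x)
}

#' Per-window reconstruction error
#'
#' Mean squared deviation between the normalised window and its
#' reconstruction, one value per window.
#'
#' @param model an `ae_model`.
#' @param windows matrix (windows x L) or a single window vector.
#' @return numeric vector of non-negative errors.
#' @export
reconstruction_error <- function(model, windows) {
  if (is.vector(windows)) windows <- matrix(windows, nrow = 1)
  if (ncol(windows) != model$input_dim)
    stop("window length ", ncol(windows), " does not match model input ",
         model$input_dim)
  X <- sweep(sweep(windows, 2, model$norm$mins), 2, model$norm$rng, `/`)
  out <- ae_forward(model$params, X)$out
  rowMeans((out - X)^2)
}

#' Flag anomalous windows by reconstruction error
#'
#' A window is anomalous iff its reconstruction error strictly exceeds the
#' threshold (ties are healthy, a deterministic boundary rule).
#'
#' @param model an `ae_model`.
#' @param windows window matrix or single window.
#' @param tau threshold; defaults to the model's fitted threshold.
#' @return logical vector, `TRUE` = anomalous.
#' @export
detect_anomaly <- function(model, windows, tau = model$tau) {
  reconstruction_error(model, windows) > tau
}

#' Sweep window lengths and features for net detection
#'
#' For each (feature, window length L) cell: windows starting at
#' `start_dat` are extracted, the AE is trained on the first `max_train`
#' healthy (T1) windows, the false detection rate is measured on the
#' held-out T1 windows and the true detection rate on each treated group
#' (T2, T3) separately; net = true - false.
#'
#' @param traj a [make_trajectories()] trajectory set.
#' @param features feature names to sweep.
#' @param L_range window lengths (default 6:22).
#' @param config an [ae_config()].
#' @param treatments treated groups to score (default `c("T2", "T3")`).
#' @param start_dat first DAT of every window (default 4).
#' @return tibble: `feature, L, treatment, n_train, n_test_healthy,
#'   n_test_treated, true_rate, false_rate, net_rate`.
#' @export
window_sweep <- function(traj, features, L_range = 6:22, config = ae_config(),
                         treatments = c("T2", "T3"), start_dat = 4) {
  rows <- list()
  for (f in features) {
    for (L in L_range) {
      w <- trajectory_windows(traj, f, L, start_dat)
      trt <- attr(w, "treatment")
      healthy <- w[trt[rownames(w)] == "T1", , drop = FALSE]
      if (nrow(healthy) < 2) stop("not enough healthy windows for L = ", L)
      healthy <- healthy[order(rownames(healthy)), , drop = FALSE]
      n_train <- min(nrow(healthy), config$max_train)
      if (n_train == nrow(healthy))
        stop("no held-out healthy windows at L = ", L,
             "; false detection rate undefined")
      model <- fit_ae(healthy[seq_len(n_train), , drop = FALSE], config)
      held <- healthy[-seq_len(n_train), , drop = FALSE]
      false_rate <- mean(detect_anomaly(model, held))
      for (tg in treatments) {
        treated <- w[trt[rownames(w)] == tg, , drop = FALSE]
        if (!nrow(treated)) next
        true_rate <- mean(detect_anomaly(model, treated))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          feature = f, L = L, treatment = tg,
          n_train = n_train, n_test_healthy = nrow(held),
          n_test_treated = nrow(treated),
          true_rate = true_rate, false_rate = false_rate,
          net_rate = true_rate - false_rate
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Top features of a sweep by mean net detection
#' @param report a [window_sweep()] report.
#' @param k how many features (default 5).
#' @export
top_features <- function(report, k = 5) {
  report |>
    dplyr::group_by(feature) |>
    dplyr::summarise(mean_net = mean(net_rate), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(mean_net)) |>
    head(k)
}

#' Heatmap of net detection across features and window lengths
#'
#' Mirrors the sweep visualisation: one tile per (feature, L), filled by
#' net detection rate, facetted by treated group. Requires ggplot2.
#'
#' @param report a [window_sweep()] report.
#' @export
plot_sweep_heatmap <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(report, ggplot2::aes(x = L, y = feature, fill = net_rate)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~treatment, ncol = 1) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "window length (days)", y = NULL,
                  fill = "net detection")
}
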