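# Shared fixtures, all generated in code at test time.

# Compact design: 3 sampling days x 4 heads = 12 of 20 plants sampled per tank.
small_design <- function(seed = 1, plants = 20) {
  experiment_design(plants_per_tank = plants,
                    sampling_days = c(11, 18, 26),
                    samples_per_tank_per_day = 4,
                    seed = seed)
}

# Deterministic regime: treatment separation with all variability off.
separated_model <- function() {
  growth_model(tank_sd = 0, plant_sd = 0, conc_sd = 0, residual_sd = 0,
               pixel_noise_sd = 0,
               nutrient_depletion = c(T1 = 1, T2 = 0.8, T3 = 0.5))
}

# Null regime: every treatment identical to the control.
null_model <- function() {
  growth_model(treatment_scale = c(T1 = 1, T2 = 1, T3 = 1),
               nutrient_depletion = c(T1 = 1, T2 = 1, T3 = 1))
}

named_registry <- function() vi_registry(include_generic = FALSE)

# Window matrix with plant-id rownames and treatment attribute.
toy_windows <- function(n, L = 6, scale = 1, noise_sd = 0, treatment = "T1",
                        seed = 1) {
  set.seed(seed)
  base <- 0.5 + 0.03 * (seq_len(L) - 1)
  m <- t(vapply(seq_len(n), function(i) {
    scale * base * (1 + rnorm(1, 0, noise_sd))
  }, numeric(L)))
  rownames(m) <- sprintf("%s_tk%d_p%02d", treatment, (seq_len(n) - 1) %% 3 + 1,
                         seq_len(n))
  attr(m, "treatment") <- setNames(rep(treatment, n), rownames(m))
  m
}

# Per-plant constant-channel crops whose values follow a reflectance link;
# used by the transformer tests (channels encode the responses directly).
vit_toy_data <- function(seed = 5, dats = c(8, 14, 20, 26), image_size = 12,
                         noise_sd = 0.005) {
  d <- experiment_design(plants_per_tank = 6, sampling_days = c(11, 18, 26),
                         samples_per_tank_per_day = 2, seed = seed)
  sim <- simulate_experiment(d, growth_model(residual_sd = 0))
  st <- sim$states[sim$states$DAT %in% dats, ]
  link <- default_reflectance_link()
  link[, "biomass"] <- c(0.1, 0.1, 0.2, 0.1, 0.15, 0.15, 0.2, 0.25, 0.2, 0.25)
  gm <- growth_model(reflectance_link = link)
  refl <- nutrimon:::link_reflectance(gm, st$FW_g, st$N_pct)
  n <- nrow(st)
  X <- array(0, dim = c(n, 10, image_size, image_size))
  set.seed(seed + 1)
  for (i in seq_len(n)) {
    for (k in 1:10) {
      X[i, k, , ] <- refl[i, k] +
        matrix(rnorm(image_size^2, 0, noise_sd), image_size, image_size)
    }
  }
  meta <- st[, c("plant_id", "tank_id", "treatment", "DAT",
                 nutrimon:::rv_names())]
  meta$label_type <- "ground_truth"
  list(X = X, meta = meta)
}
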