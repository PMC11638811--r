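# Independent oracles and small fixture builders shared across tests.

# Brute-force 2-D DFT directional power: explicit double loop over the
# definition, independent of the package's matrix-product implementation.
# Forward waves (posterior row leading) put power at positive temporal
# frequency paired with negative spatial frequency.
bf_dft_power <- function(seg, direction, f, fs) {
  C <- nrow(seg)
  N <- ncol(seg)
  k <- round(f * N / fs)
  s_set <- if (direction == "forward") {
    C - seq_len((C - 1) %/% 2)        # negative spatial frequencies
  } else {
    seq_len((C - 1) %/% 2)            # positive spatial frequencies
  }
  pw <- vapply(s_set, function(s) {
    acc <- 0 + 0i
    for (cc in 0:(C - 1)) {
      for (tt in 0:(N - 1)) {
        acc <- acc + seg[cc + 1, tt + 1] *
          exp(-2i * pi * (cc * s / C + tt * k / N))
      }
    }
    Mod(acc)^2
  }, numeric(1))
  max(pw)
}

# independent JZS BF10 oracle: Cauchy prior x noncentral-t likelihood,
# integrated over the effect size delta (different parameterization from the
# package's g-mixture quadrature)
oracle_jzs_bf <- function(t, n, r = sqrt(2) / 2) {
  num <- suppressWarnings(stats::integrate(
    function(d) stats::dt(t, n - 1, ncp = d * sqrt(n)) *
      stats::dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-12, subdivisions = 2000L
  ))$value
  num / stats::dt(t, n - 1)
}

# independent ZS regression BF oracle: Simpson's rule on u = g / (1 + g)
oracle_reg_bf <- function(n, r2, r_scale = sqrt(2) / 4, m = 20001L) {
  u <- seq(1e-10, 1 - 1e-10, length.out = m)
  g <- u / (1 - u)
  fx <- exp((n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2))) *
    sqrt(n * r_scale^2 / 2) / gamma(0.5) * g^(-1.5) *
    exp(-n * r_scale^2 / (2 * g)) / (1 - u)^2
  h <- u[2] - u[1]
  w <- rep(c(4, 2), length.out = m - 2)
  h / 3 * (fx[1] + sum(w * fx[2:(m - 1)]) + fx[m])
}

# a minimal seven-channel recording whose single axis is the identity map
make_seven_channel_epochs <- function(data_list, fs = 1000, tmin = 0,
                                      trials = NULL) {
  arr <- array(NA_real_, c(length(data_list), 7L, ncol(data_list[[1]])))
  for (i in seq_along(data_list)) arr[i, , ] <- data_list[[i]]
  eeg_epochs(arr, paste0("v", 1:7), fs, tmin, trials)
}

seven_axis <- function() {
  tibble::tibble(axis = "axis7", channels = list(paste0("v", 1:7)))
}

# frozen validation study design: 3 distractor-load levels with forward
# wave amplitude rising with load on the midline axis
load_effect_design <- function(seed, n_participants = 30,
                               n_trials_per_condition = 3, effect = TRUE) {
  em <- if (effect) {
    tibble::tibble(axis = "midline", direction = "forward",
                   amplitude = c(0.1, 0.2, 0.3), phase_step = 2 * pi / 7,
                   load = c(2, 4, 6))
  } else NULL
  design_spec("ds1", n_participants = n_participants,
              n_trials_per_condition = n_trials_per_condition,
              loads = c(2, 4, 6), sides = "left",
              lateral_items = "targets",
              channels = c("Oz", "Pz", "Cz", "Fz"),
              participant_sd = 0.1, effect_map = em, seed = seed)
}

# run the load-effect design through the full pipeline to condition cells
load_effect_cells <- function(seed, ...) {
  sim <- simulate_dataset(load_effect_design(seed, ...))
  wp <- compute_wave_power(sim, axes = "midline", template = "ds1",
                           time_range = c(0.2, 1.2))
  ret <- average_retention(wp, c(0.2, 1.2))
  aggregate_trials(dplyr::select(ret, dplyr::all_of(
    c("participant", "load", "direction", "band", "trial", "power_db"))))
}
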