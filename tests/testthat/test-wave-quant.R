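test_that("sliding windows are counted and centred correctly", {
  ws <- slide_windows(matrix(0, 7, 2400), window_spec(), fs = 1000,
                      tmin = -0.8)
  expect_length(ws$segments, 20L)
  expect_equal(ws$centers[1], -0.55)
  expect_equal(ws$centers[20], 1.35)

  one <- slide_windows(matrix(0, 7, 500), window_spec(), fs = 1000)
  expect_length(one$segments, 1L)

  # set-size template: 737 samples at 250 Hz, 125-sample window, 25 steps
  ds2 <- slide_windows(matrix(0, 7, 737), window_spec(), fs = 250)
  expect_length(ds2$segments, 25L)

  expect_error(slide_windows(matrix(0, 7, 100), window_spec(), fs = 1000),
               "longer than the epoch")
  expect_error(slide_windows(matrix(0, 7, 500), window_spec(0.5, 0.0301),
                             fs = 1000), "whole samples")
})

test_that("directional power matches the brute-force DFT oracle", {
  withr::with_seed(42, {
    for (i in 1:50) {
      seg <- matrix(rnorm(7 * 32), 7)
      f <- sample(1:15, 1)
      for (dir in c("forward", "backward")) {
        got <- directional_power(seg, dir, f, fs = 32)
        ref <- bf_dft_power(seg, dir, f, fs = 32)
        expect_lt(abs(got / ref - 1), 1e-10)
      }
    }
  })
})

test_that("a posterior-leading plane wave is classified as forward", {
  seg <- make_plane_wave(wave_spec(10, pi / 7, phase0 = 0.3), 7, 500, 1000)
  fw <- directional_power(seg, "forward", 10, 1000)
  bw <- directional_power(seg, "backward", 10, 1000)
  # oracle-derived ratio for a pi/7 gradient (0.5 cycles/array): 7.85 --
  # spatial leakage feeds both quadrants, but forward dominates clearly
  expect_equal(fw / bw, bf_dft_power(seg, "forward", 10, 1000) /
                 bf_dft_power(seg, "backward", 10, 1000), tolerance = 1e-9)
  expect_gt(fw / bw, 5)
  # an on-bin gradient (one cycle across the array) is essentially pure
  seg2 <- make_plane_wave(wave_spec(10, 2 * pi / 7, phase0 = 1), 7, 500, 1000)
  expect_gt(directional_power(seg2, "forward", 10, 1000) /
              directional_power(seg2, "backward", 10, 1000), 1e10)
})

test_that("calibration pin: generator forward waves yield FW > BW in dB", {
  for (f in c(8, 10, 12)) {
    for (ps in c(pi / 14, pi / 7, 2 * pi / 7, pi / 2)) {
      seg <- make_plane_wave(wave_spec(f, ps, phase0 = 0.9), 7, 500, 1000)
      fw <- normalize_db(directional_power(seg, "forward", f, 1000),
                         seg, f, 1000)
      bw <- normalize_db(directional_power(seg, "backward", f, 1000),
                         seg, f, 1000)
      expect_gt(fw, bw)
      # mirrored: negative step is backward
      segb <- make_plane_wave(wave_spec(f, -ps, phase0 = 0.9), 7, 500, 1000)
      expect_gt(
        normalize_db(directional_power(segb, "backward", f, 1000),
                     segb, f, 1000),
        normalize_db(directional_power(segb, "forward", f, 1000),
                     segb, f, 1000))
    }
  }
})

test_that("spatially uniform oscillations have symmetric direction power", {
  seg <- make_plane_wave(wave_spec(10, 0, phase0 = 0.5), 7, 500, 1000)
  fw <- directional_power(seg, "forward", 10, 1000)
  bw <- directional_power(seg, "backward", 10, 1000)
  # all in-band energy sits on the excluded zero-spatial-frequency midline
  expect_equal(fw, bw, tolerance = 1e-9)
  expect_lt(fw / directional_power(
    make_plane_wave(wave_spec(10, 2 * pi / 7, phase0 = 0.5), 7, 500, 1000),
    "forward", 10, 1000), 1e-20)
})

test_that("time reversal swaps forward and backward power", {
  withr::with_seed(6, {
    seg <- matrix(rnorm(7 * 100), 7)
    for (f in c(5, 10, 20)) {
      expect_equal(directional_power(seg[, 100:1], "forward", f, 100),
                   directional_power(seg, "backward", f, 100),
                   tolerance = 1e-10)
    }
  })
})

test_that("channel flips swap FW_dB and BW_dB at machine precision", {
  withr::with_seed(7, {
    for (i in 1:20) {
      seg <- matrix(rnorm(7 * 64), 7)
      f <- sample(1:30, 1)
      fw <- normalize_db(directional_power(seg, "forward", f, 64), seg, f, 64)
      bw <- normalize_db(directional_power(seg, "backward", f, 64), seg, f, 64)
      rev <- seg[7:1, ]
      expect_equal(normalize_db(directional_power(rev, "forward", f, 64),
                                rev, f, 64), bw, tolerance = 1e-12)
      expect_equal(normalize_db(directional_power(rev, "backward", f, 64),
                                rev, f, 64), fw, tolerance = 1e-12)
    }
  })
})

test_that("dB normalization has a 0 dB parity baseline", {
  withr::with_seed(8, {
    seg <- matrix(rnorm(7 * 250), 7)
    fft_f <- alphawaves:::segment_spectra(seg, 11L)$fft_f  # 10 Hz at 250 Hz
    expect_identical(normalize_db(fft_f, seg, 10, 250), 0)
    expect_equal(normalize_db(10 * fft_f, seg, 10, 250), 10)
    expect_error(normalize_db(1, matrix(0, 7, 250), 10, 250), "degenerate")
    expect_error(directional_power(seg, "forward", 10.7, 250), "grid")
  })
})

test_that("direction power in dB is invariant to amplitude scaling", {
  withr::with_seed(9, {
    seg <- matrix(rnorm(7 * 128), 7) +
      make_plane_wave(wave_spec(16, pi / 6, phase0 = 0), 7, 128, 128)
    for (c in c(0.1, 3, 250)) {
      expect_equal(
        normalize_db(directional_power(c * seg, "forward", 16, 128),
                     c * seg, 16, 128),
        normalize_db(directional_power(seg, "forward", 16, 128),
                     seg, 16, 128),
        tolerance = 1e-12)
    }
  })
})

test_that("FW_dB rises monotonically with injected forward amplitude", {
  withr::with_seed(12, {
    noise <- make_noise(7, 500, 1000, exponent = 1, scale = 1)
    wave <- make_plane_wave(wave_spec(10, 2 * pi / 7, phase0 = 0.4),
                            7, 500, 1000)
    db <- vapply(c(0.1, 0.3, 0.6, 1, 2, 5), function(a) {
      seg <- noise + a * wave
      normalize_db(directional_power(seg, "forward", 10, 1000), seg, 10, 1000)
    }, numeric(1))
    expect_true(all(diff(db) > 0))
  })
})

test_that("band averaging uses closed intervals on the bin grid", {
  df <- tidyr::crossing(trial = 1L, time = 0, freq = seq(2, 30, by = 2),
                        direction = "forward")
  df$power_db <- as.numeric(df$freq)
  alpha <- band_average(df, c(8, 12), "alpha")
  expect_equal(alpha$power_db, mean(c(8, 10, 12)))
  theta <- band_average(df, c(4, 7), "theta")
  expect_equal(theta$power_db, mean(c(4, 6)))
  single <- band_average(df, c(10, 10), "one")
  expect_equal(single$power_db, 10)
  expect_error(band_average(df, c(0.5, 1.5)), "no frequency bins")
})

test_that("the batched pipeline equals per-segment computation", {
  withr::with_seed(13, {
    rec <- make_seven_channel_epochs(
      lapply(1:3, function(i) matrix(rnorm(7 * 700), 7)), fs = 1000,
      tmin = -0.1)
    wp <- compute_wave_power(rec, axes = seven_axis(), per_bin = TRUE,
                             max_freq = 30)
    st <- build_axis_stack(rec, paste0("v", 1:7))
    for (case in list(c(2, 3, 12), c(1, 1, 8), c(3, 2, 24))) {
      tr <- case[1]; win <- case[2]; f <- case[3]
      seg <- st[tr, , (100 * (win - 1) + 1):(100 * (win - 1) + 500)]
      ref <- normalize_db(directional_power(seg, "backward", f, 1000),
                          seg, f, 1000)
      got <- wp$power_db[wp$trial == tr & wp$freq == f &
                           wp$direction == "backward" &
                           abs(wp$time - (-0.1 + 0.25 + 0.1 * (win - 1))) <
                             1e-9]
      expect_equal(got, ref, tolerance = 1e-12)
    }
  })
})

test_that("the optional Hann taper preserves direction recovery", {
  withr::with_seed(15, {
    rec <- make_seven_channel_epochs(lapply(1:5, function(i) {
      make_noise(7, 700, 1000, scale = 0.5) +
        make_plane_wave(wave_spec(10, pi / 7, 1), 7, 700, 1000)
    }), fs = 1000)
    plain <- compute_wave_power(rec, axes = seven_axis())
    tapered <- compute_wave_power(rec, axes = seven_axis(), taper = TRUE)
    gap <- function(df) {
      mean(df$power_db[df$direction == "forward"]) -
        mean(df$power_db[df$direction == "backward"])
    }
    expect_gt(gap(plain), 1)
    expect_gt(gap(tapered), 1)
    expect_false(isTRUE(all.equal(plain$power_db, tapered$power_db)))
  })
})

test_that("stationary band power scales with squared amplitude", {
  base <- make_plane_wave(wave_spec(10, 0, phase0 = 0), 7, 500, 1000)
  rec1 <- make_seven_channel_epochs(list(base), fs = 1000)
  rec2 <- make_seven_channel_epochs(list(2 * base), fs = 1000)
  p1 <- stationary_band_power(rec1, axes = seven_axis(), band = c(8, 12))
  p2 <- stationary_band_power(rec2, axes = seven_axis(), band = c(8, 12))
  expect_equal(p2$power / p1$power, 4)
  rec0 <- make_seven_channel_epochs(list(0 * base), fs = 1000)
  expect_equal(stationary_band_power(rec0, axes = seven_axis(),
                                     band = c(8, 12))$power, 0)
})

test_that("white-noise band power follows the flat-spectrum share", {
  withr::with_seed(14, {
    recs <- lapply(1:40, function(i) matrix(rnorm(7 * 500), 7))
    rec <- make_seven_channel_epochs(recs, fs = 1000)
    bandp <- stationary_band_power(rec, axes = seven_axis(),
                                   band = c(2, 500))
    alpha <- stationary_band_power(rec, axes = seven_axis(),
                                   band = c(100, 200))
    # mean per-bin power is flat: a 51-bin slice equals the all-bin mean
    expect_equal(mean(alpha$power), mean(bandp$power), tolerance = 0.1)
  })
})
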