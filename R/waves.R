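#' Sliding-window specification
#'
#' Window length and step for the sliding 2-D spectral analysis. Defaults to
#' the 500 ms window advanced in 100 ms steps used throughout the package.
#' Both must resolve to whole numbers of samples at the recording's sampling
#' rate; this is checked when the window is applied.
#'
#' @param length window length in seconds.
#' @param step step between consecutive window starts in seconds.
#' @return A `window_spec` list.
#' @export
window_spec <- function(length = 0.5, step = 0.1) {
  if (length <= 0 || step <= 0) abort("window length and step must be > 0.")
  structure(list(length = length, step = step), class = "window_spec")
}

# 0-based start samples of fully contained windows; first window at epoch start
window_starts <- function(n_samples, fs, w) {
  len <- w$length * fs
  stp <- w$step * fs
  if (abs(len - round(len)) > 1e-9 || abs(stp - round(stp)) > 1e-9) {
    abort(sprintf(
      "window length/step (%g/%g s) are not whole samples at fs = %g Hz.",
      w$length, w$step, fs))
  }
  len <- as.integer(round(len))
  stp <- as.integer(round(stp))
  if (len > n_samples) abort("window is longer than the epoch.")
  list(starts = seq.int(0L, n_samples - len, by = stp), len = len)
}

#' Cut an axis stack into sliding windows
#'
#' Moves a window of `w$length` seconds across a single-trial axis stack in
#' steps of `w$step` seconds. Windows start at the epoch start and only fully
#' contained windows are emitted; each is labelled by its center time.
#'
#' @param stack a `7 x samples` (more generally `channels x samples`) matrix.
#' @param w a [window_spec()].
#' @param fs sampling rate in Hz.
#' @param tmin time of the first sample in seconds (default 0).
#' @return A list with `segments` (list of `channels x window` matrices) and
#'   `centers` (numeric vector of window center times in seconds).
#' @export
#' @examples
#' sw <- slide_windows(matrix(rnorm(7 * 700), 7), window_spec(), fs = 1000)
#' length(sw$segments)
slide_windows <- function(stack, w = window_spec(), fs, tmin = 0) {
  ws <- window_starts(ncol(stack), fs, w)
  segs <- map(ws$starts, function(s) stack[, (s + 1):(s + ws$len), drop = FALSE])
  list(segments = segs,
       centers = tmin + (ws$starts + ws$len / 2) / fs)
}

# Two-dimensional power spectrum machinery ---------------------------------
#
# A segment is a channels x time matrix treated as an image. Its 2-D DFT is
# computed as the temporal DFT of every channel followed by the spatial DFT
# of every temporal column; the intermediate per-channel temporal spectra
# also provide the normalization denominator FFT_f (mean 1-D temporal power
# over the channels, same transform length and scaling as the 2-D temporal
# axis). A planar wave with a monotonic phase shift across channels
# concentrates power off the zero-spatial-frequency midline: with `C`
# channels, positive temporal bins pair with spatial bins -1..-3
# cycles/array for posterior-leading (forward) waves and +1..+3 for
# anterior-leading (backward) waves. The zero-spatial-frequency row holds
# standing-wave power and belongs to neither direction; temporal DC is
# likewise excluded. No detrending, tapering or zero-padding is applied.

# DFT operator matrices for a segment of n samples, evaluated only at the
# temporal bins `cols` (1-based): `et` maps time -> frequency per channel,
# `es` is the 7-point (generally C-point) spatial DFT.
dft_mats <- function(n, cols, n_channels = 7L, taper = FALSE) {
  k <- cols - 1
  et <- exp(-2i * pi * outer(seq_len(n) - 1, k) / n)
  if (taper) {
    # Hann taper folded into the temporal operator: numerator and the
    # FFT_f denominator are tapered identically
    et <- (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))) * et
  }
  cs <- seq_len(n_channels) - 1
  es <- exp(-2i * pi * outer(cs, cs) / n_channels)
  list(et = et, es = es)
}

# per-segment spectra at the requested temporal bins (1-based FFT columns):
# p2 = 2-D power (spatial x temporal), fft_f = channel-mean 1-D power
segment_spectra <- function(segment, cols,
                            mats = dft_mats(ncol(segment), cols,
                                            nrow(segment))) {
  tt <- segment %*% mats$et            # C x m: temporal DFT per channel
  fft_f <- colMeans(Mod(tt)^2)
  p2 <- Mod(mats$es %*% tt)^2          # spatial DFT per temporal bin
  list(p2 = p2, fft_f = fft_f)
}

# 1-based FFT column index for temporal frequency f (errors off-grid)
temporal_bin <- function(f, n, fs) {
  k <- f * n / fs
  if (abs(k - round(k)) > 1e-6) {
    abort(sprintf("%g Hz is not on the %g Hz bin grid of a %d-sample window.",
                  f, fs / n, n))
  }
  k <- as.integer(round(k))
  if (k < 1 || k > floor(n / 2)) {
    abort(sprintf("%g Hz is outside (0, Nyquist].", f))
  }
  k + 1L
}

quadrant_rows <- function(n_channels, direction) {
  half <- (n_channels - 1) %/% 2
  if (direction == "forward") {
    n_channels - seq_len(half) + 1L     # negative spatial frequencies
  } else {
    seq_len(half) + 1L                  # positive spatial frequencies
  }
}

#' Directional (forward/backward) spectral power of one segment
#'
#' Computes the zero-centered 2-D discrete Fourier power spectrum of a
#' channels-by-time segment and returns, for the column at temporal
#' frequency `f`, the maximum power over the nonzero spatial frequencies of
#' the quadrant carrying the requested propagation direction (forward =
#' posterior row leads). Conjugate-symmetric quadrant pairs carry identical
#' power, so only the positive temporal half is inspected. The
#' zero-spatial-frequency (standing wave) row is excluded.
#'
#' @param segment `channels x time` numeric matrix (rows posterior-first).
#' @param direction `"forward"` or `"backward"`.
#' @param f temporal frequency in Hz; must lie on the segment's bin grid.
#' @param fs sampling rate in Hz.
#' @return Raw (unnormalized) spectral power, a non-negative scalar.
#' @export
#' @examples
#' seg <- make_plane_wave(wave_spec(10, pi / 7, phase0 = 0), 7, 500, 1000)
#' directional_power(seg, "forward", 10, fs = 1000) >
#'   directional_power(seg, "backward", 10, fs = 1000)
directional_power <- function(segment, direction = c("forward", "backward"),
                              f, fs) {
  direction <- arg_match(direction)
  col <- temporal_bin(f, ncol(segment), fs)
  sp <- segment_spectra(segment, col)
  max(sp$p2[quadrant_rows(nrow(segment), direction), 1L])
}

#' Normalize directional power to decibels
#'
#' Expresses a raw directional power as `10 log10(raw / FFT_f)`, where
#' `FFT_f` is the 1-D temporal power at the same frequency averaged over the
#' channels of the same segment (same transform length and scaling as the
#' 2-D transform's temporal axis). 0 dB therefore means parity with the
#' segment's average temporal power at that frequency, the baseline against
#' which travelling-wave content is judged.
#'
#' @param raw raw directional power (see [directional_power()]).
#' @param segment the segment the power was measured on.
#' @param f temporal frequency in Hz, on the segment's bin grid.
#' @param fs sampling rate in Hz.
#' @return Normalized power in dB.
#' @export
normalize_db <- function(raw, segment, f, fs) {
  col <- temporal_bin(f, ncol(segment), fs)
  fft_f <- segment_spectra(segment, col)$fft_f
  if (fft_f == 0) {
    abort(sprintf("degenerate segment: zero mean temporal power at %g Hz.", f))
  }
  10 * log10(raw / fft_f)
}

#' Average per-bin wave power over a frequency band
#'
#' Arithmetic mean of per-bin dB values over the bins whose center frequency
#' lies in the closed interval `[band[1], band[2]]`. With 500 ms windows the
#' bin grid is 2 Hz, so the 8-12 Hz alpha band averages bins {8, 10, 12} Hz.
#'
#' @param df long tibble of per-bin values with columns `freq` and
#'   `power_db` (as returned by [compute_wave_power()] with
#'   `per_bin = TRUE`); all other columns are treated as grouping keys.
#' @param band numeric `c(lo, hi)` in Hz.
#' @param name band label for the output `band` column.
#' @return Tibble with the grouping keys, `band` and band-mean `power_db`.
#' @export
band_average <- function(df, band = c(8, 12), name = "alpha") {
  sel <- filter(df, .data$freq >= band[1] - 1e-9, .data$freq <= band[2] + 1e-9)
  if (!nrow(sel)) {
    abort(sprintf("band [%g, %g] Hz intersects no frequency bins.",
                  band[1], band[2]))
  }
  keys <- setdiff(names(sel), c("freq", "power_db"))
  sel %>%
    group_by(across(all_of(keys))) %>%
    summarise(power_db = mean(.data$power_db), .groups = "drop") %>%
    mutate(band = name, .before = "power_db")
}

#' Frequency bands used throughout the package
#'
#' Alpha 8-12 Hz (the band of interest), plus the theta 4-7 Hz and beta
#' 13-30 Hz neighbours used for frequency-specificity checks. Band
#' membership is a closed interval on bin centers.
#'
#' @return Named list of `c(lo, hi)` vectors in Hz.
#' @export
default_bands <- function() {
  list(alpha = c(8, 12), theta = c(4, 7), beta = c(13, 30))
}

#' Sliding-window directional wave power
#'
#' The package's core measurement. For every trial and every requested axis,
#' the axis channels are interpolated to seven virtual channels
#' (posterior-first), a sliding window (default 500 ms length, 100 ms step)
#' cuts the stack into channels-by-time segments, and each segment's 2-D
#' Fourier power spectrum yields forward and backward wave power per
#' temporal-frequency bin, normalized to dB against the segment's mean
#' temporal power at the same bin (see [directional_power()] and
#' [normalize_db()]). Per-bin dB values are then averaged within frequency
#' bands (alpha 8-12 Hz by default).
#'
#' Bins where the segment has exactly zero mean temporal power (possible
#' only for degenerate noiseless input) yield `NaN`.
#'
#' @param x an [eeg_epochs()] object, or a tibble with an `epochs` list
#'   column (as returned by [simulate_dataset()]), in which case all other
#'   columns (e.g. `participant`) are carried through.
#' @param axes tibble of axes as from [axis_set()] (default: all axes of
#'   `template`), or a character vector of axis names to select from it.
#' @param template recording template used to look up default axes when
#'   `axes` is `NULL` or a name vector.
#' @param window a [window_spec()].
#' @param bands named list of `c(lo, hi)` bands in Hz (default alpha only);
#'   ignored when `per_bin = TRUE`.
#' @param per_bin return per-frequency-bin values instead of band averages.
#' @param time_range optional `c(t0, t1)`: only windows whose center lies in
#'   this closed interval (seconds) are computed.
#' @param max_freq highest temporal frequency (Hz) evaluated when
#'   `per_bin = TRUE` (default 40).
#' @param taper apply a Hann taper along the time axis of every segment
#'   (applied identically to the directional numerator and the `FFT_f`
#'   denominator). Off by default: the canonical measure uses the raw
#'   rectangular window.
#' @param ... unused.
#' @return A long tibble: one row per trial x axis x window x band (or
#'   frequency bin) x direction, with trial metadata columns joined in, and
#'   `power_db` holding the normalized directional power.
#' @export
#' @examples
#' d <- design_spec("ds2", n_participants = 1, n_trials_per_condition = 2,
#'                  set_sizes = 3, sides = "left", seed = 2)
#' rec <- simulate_dataset(d)$epochs[[1]]
#' compute_wave_power(rec, axes = "midline", template = "ds2")
compute_wave_power <- function(x, ...) UseMethod("compute_wave_power")

#' @rdname compute_wave_power
#' @export
compute_wave_power.eeg_epochs <- function(x, axes = NULL, template = NULL,
                                          window = window_spec(),
                                          bands = list(alpha = c(8, 12)),
                                          per_bin = FALSE, time_range = NULL,
                                          max_freq = 40, taper = FALSE, ...) {
  axes <- resolve_axes(axes, template)
  ws <- window_starts(dim(x$data)[3L], x$fs, window)
  centers <- x$times[1L] + (ws$starts + ws$len / 2) / x$fs
  keep <- if (is.null(time_range)) {
    rep(TRUE, length(centers))
  } else {
    centers >= time_range[1] - 1e-9 & centers <= time_range[2] + 1e-9
  }
  starts <- ws$starts[keep]
  centers <- centers[keep]
  if (!length(starts)) abort("no sliding window lies in `time_range`.")

  n <- ws$len
  bin_hz <- x$fs / n
  if (per_bin) {
    freqs <- seq(bin_hz, min(max_freq, x$fs / 2), by = bin_hz)
  } else {
    freqs <- sort(unique(unlist(map(bands, function(b) {
      fr <- seq(bin_hz, x$fs / 2, by = bin_hz)
      sel <- fr[fr >= b[1] - 1e-9 & fr <= b[2] + 1e-9]
      if (!length(sel)) {
        abort(sprintf("band [%g, %g] Hz intersects no bins of the %g Hz grid.",
                      b[1], b[2], bin_hz))
      }
      sel
    }))))
  }
  cols <- map_dbl(freqs, temporal_bin, n = n, fs = x$fs)
  mats <- dft_mats(n, cols, taper = taper)
  fw_rows <- quadrant_rows(7L, "forward")
  bw_rows <- quadrant_rows(7L, "backward")
  n_tr <- dim(x$data)[1L]
  nw <- length(starts)
  nf <- length(freqs)

  res <- map_dfr(seq_len(nrow(axes)), function(a) {
    stack <- build_axis_stack(x, electrode_axis(axes$axis[a],
                                                axes$channels[[a]],
                                                check_unique = FALSE))
    vals <- array(NA_real_, c(n_tr, nw, nf, 2L))
    perm <- aperm(stack, c(2L, 1L, 3L))      # 7 x trials x samples
    dim(perm) <- c(7L * n_tr, dim(stack)[3L])
    for (wi in seq_len(nw)) {
      # all trials of this window in two complex matrix products
      seg_all <- perm[, (starts[wi] + 1):(starts[wi] + n), drop = FALSE]
      tt <- seg_all %*% mats$et              # (7 * trials) x bins
      dim(tt) <- c(7L, n_tr * nf)
      fft_f <- matrix(colMeans(Mod(tt)^2), n_tr, nf)
      p2 <- Mod(mats$es %*% tt)^2            # spatial DFT, trials batched
      fw <- matrix(do.call(pmax, lapply(fw_rows, function(r) p2[r, ])),
                   n_tr, nf)
      bw <- matrix(do.call(pmax, lapply(bw_rows, function(r) p2[r, ])),
                   n_tr, nf)
      denom <- ifelse(fft_f > 0, fft_f, NaN)
      vals[, wi, , 1L] <- 10 * log10(fw / denom)
      vals[, wi, , 2L] <- 10 * log10(bw / denom)
    }
    tibble(
      axis = axes$axis[a],
      trial = rep(x$trials$trial, times = nw * nf * 2L),
      time = rep(rep(centers, each = n_tr), times = nf * 2L),
      freq = rep(rep(freqs, each = n_tr * nw), times = 2L),
      direction = rep(c("forward", "backward"), each = n_tr * nw * nf),
      power_db = as.vector(vals)
    )
  })

  if (!per_bin) {
    res <- map_dfr(names(bands), function(nm) {
      band_average(res, bands[[nm]], nm)
    })
  }
  left_join(res, x$trials, by = "trial")
}

#' @rdname compute_wave_power
#' @export
compute_wave_power.data.frame <- function(x, ...) {
  if (!"epochs" %in% names(x)) {
    abort("expected an `epochs` list column (see simulate_dataset()).")
  }
  carry <- select(x, -"epochs")
  map_dfr(seq_len(nrow(x)), function(i) {
    dplyr::bind_cols(carry[i, , drop = FALSE],
                     compute_wave_power(x$epochs[[i]], ...))
  })
}

resolve_axes <- function(axes, template) {
  if (is.null(axes)) {
    if (is.null(template)) abort("supply `axes` or `template`.")
    return(axis_set(template))
  }
  if (is.character(axes)) {
    if (is.null(template)) abort("supply `template` to look up axis names.")
    tbl <- axis_set(template, include_variants = TRUE)
    bad <- setdiff(axes, tbl$axis)
    if (length(bad)) {
      abort(sprintf("unknown axis name(s): %s", paste(bad, collapse = ", ")))
    }
    return(tbl[match(axes, tbl$axis), , drop = FALSE])
  }
  as_tibble(axes)
}

#' Conventional (stationary) band power
#'
#' The non-directional control measure: per sliding window, the 1-D temporal
#' power spectrum of each of the seven interpolated channels is averaged
#' over channels and over the band's frequency bins. Same windowing and
#' transform scaling as the wave measure, no directional decomposition.
#'
#' @inheritParams compute_wave_power.eeg_epochs
#' @param band numeric `c(lo, hi)` in Hz.
#' @param x an [eeg_epochs()] object.
#' @return Tibble with one row per trial x axis x window: `trial`, `axis`,
#'   `time`, `power` (raw power units) plus trial metadata.
#' @export
stationary_band_power <- function(x, axes = NULL, template = NULL,
                                  window = window_spec(), band = c(8, 12),
                                  time_range = NULL) {
  stopifnot(inherits(x, "eeg_epochs"))
  axes <- resolve_axes(axes, template)
  ws <- window_starts(dim(x$data)[3L], x$fs, window)
  centers <- x$times[1L] + (ws$starts + ws$len / 2) / x$fs
  keep <- if (is.null(time_range)) rep(TRUE, length(centers)) else
    centers >= time_range[1] - 1e-9 & centers <= time_range[2] + 1e-9
  starts <- ws$starts[keep]
  centers <- centers[keep]
  n <- ws$len
  bin_hz <- x$fs / n
  fr <- seq(bin_hz, x$fs / 2, by = bin_hz)
  fr <- fr[fr >= band[1] - 1e-9 & fr <= band[2] + 1e-9]
  if (!length(fr)) abort("band intersects no frequency bins.")
  cols <- map_dbl(fr, temporal_bin, n = n, fs = x$fs)
  mats <- dft_mats(n, cols)

  res <- map_dfr(seq_len(nrow(axes)), function(a) {
    stack <- build_axis_stack(x, electrode_axis(axes$axis[a],
                                                axes$channels[[a]],
                                                check_unique = FALSE))
    map_dfr(seq_len(dim(stack)[1L]), function(i) {
      tr <- stack[i, , ]
      pw <- map_dbl(seq_along(starts), function(wi) {
        seg <- tr[, (starts[wi] + 1):(starts[wi] + n), drop = FALSE]
        mean(Mod(seg %*% mats$et)^2)
      })
      tibble(axis = axes$axis[a], trial = x$trials$trial[i],
             time = centers, power = pw)
    })
  })
  left_join(res, x$trials, by = "trial")
}
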