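#' Plane-wave component specification
#'
#' Describes one sinusoidal plane-wave component travelling along an
#' electrode axis: an oscillation at `freq` Hz whose phase advances by
#' `phase_step` radians per channel step. A positive `phase_step` means the
#' most posterior channel leads, i.e. the wave travels posterior-to-anterior
#' (forward); a negative step gives a backward wave; zero gives a standing
#' (spatially uniform) oscillation.
#'
#' @param freq temporal frequency in Hz (must stay below Nyquist when the
#'   wave is rendered).
#' @param phase_step phase advance per channel step in radians, `|x| < pi`.
#' @param amplitude peak amplitude, arbitrary units, `>= 0`.
#' @param onset,offset active interval in seconds from the start of the
#'   rendered epoch (`NULL` = whole epoch); the wave is zero outside.
#' @param phase0 initial phase in radians, or `"random"` to draw a fresh
#'   uniform phase each time the wave is rendered (the default: the wave
#'   measure is phase-gradient based, and per-trial random phase avoids
#'   spurious across-trial coherence).
#' @return A `wave_spec` list.
#' @export
#' @examples
#' wave_spec(freq = 10, phase_step = pi / 7)
wave_spec <- function(freq = 10, phase_step = pi / 7, amplitude = 1,
                      onset = NULL, offset = NULL, phase0 = "random") {
  if (!is.numeric(freq) || freq <= 0) abort("`freq` must be positive (Hz).")
  if (abs(phase_step) >= pi) abort("|phase_step| must be < pi radians.")
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  if (!is.null(onset) && !is.null(offset) && onset >= offset) {
    abort("`onset` must be earlier than `offset`.")
  }
  if (!identical(phase0, "random") && !is.numeric(phase0)) {
    abort('`phase0` must be numeric radians or "random".')
  }
  structure(list(freq = freq, phase_step = phase_step, amplitude = amplitude,
                 onset = onset, offset = offset, phase0 = phase0),
            class = "wave_spec")
}

#' Render a plane wave as a channels-by-samples matrix
#'
#' Channel `c` (0-based, row 1 = most posterior), sample `t` takes the value
#' `amplitude * sin(2 pi freq t / fs - c * phase_step + phase0)` inside the
#' spec's `[onset, offset]` interval and 0 outside.
#'
#' @param spec a [wave_spec()].
#' @param n_channels,n_samples matrix dimensions.
#' @param fs sampling rate in Hz; must exceed twice the wave frequency.
#' @return A `n_channels x n_samples` numeric matrix.
#' @export
#' @examples
#' w <- make_plane_wave(wave_spec(10, pi / 7, phase0 = 0), 7, 1000, fs = 1000)
make_plane_wave <- function(spec, n_channels, n_samples, fs) {
  stopifnot(inherits(spec, "wave_spec"))
  if (fs <= 2 * spec$freq) {
    abort(sprintf("wave frequency %g Hz is at or above Nyquist (fs = %g Hz).",
                  spec$freq, fs))
  }
  phase0 <- if (identical(spec$phase0, "random")) {
    stats::runif(1, 0, 2 * pi)
  } else {
    spec$phase0
  }
  tt <- (seq_len(n_samples) - 1) / fs
  ch <- seq_len(n_channels) - 1
  m <- spec$amplitude *
    sin(outer(-ch * spec$phase_step, 2 * pi * spec$freq * tt + phase0, "+"))
  onset <- spec$onset %||% 0
  offset <- spec$offset %||% (n_samples / fs)
  m[, tt < onset | tt > offset] <- 0
  m
}

#' Generate 1/f background noise
#'
#' Spectrally shaped Gaussian noise whose expected power spectral density
#' falls off as `1 / f^exponent` (exponent 0 = white noise). Shaping is done
#' in the frequency domain (amplitude filter `f^(-exponent/2)`, DC removed);
#' each channel is rescaled to standard deviation `scale`. With
#' `spatially_coherent = TRUE` every channel carries the same realization (a
#' purely standing background); otherwise channels are independent.
#'
#' @param n_channels,n_samples matrix dimensions.
#' @param fs sampling rate in Hz.
#' @param exponent aperiodic slope `beta >= 0` of the `1/f^beta` spectrum.
#' @param scale per-channel standard deviation, `>= 0`.
#' @param spatially_coherent share one realization across channels.
#' @return A `n_channels x n_samples` numeric matrix.
#' @export
#' @examples
#' withr::with_seed(1, make_noise(2, 500, fs = 1000, exponent = 1))
make_noise <- function(n_channels, n_samples, fs, exponent = 1, scale = 1,
                       spatially_coherent = FALSE) {
  if (exponent < 0) abort("`exponent` must be >= 0.")
  if (scale < 0) abort("`scale` must be >= 0.")
  if (scale == 0) return(matrix(0, n_channels, n_samples))
  k <- seq_len(n_samples) - 1
  f <- pmin(k, n_samples - k) * fs / n_samples  # two-sided bin frequencies
  h <- c(0, f[-1]^(-exponent / 2))              # drop DC
  nc <- if (spatially_coherent) 1L else n_channels
  w <- mvfft(matrix(rnorm(nc * n_samples), n_samples, nc))
  x <- Re(mvfft(w * h, inverse = TRUE)) / n_samples
  sds <- apply(x, 2, sd)
  x <- sweep(x, 2, ifelse(sds > 0, sds / scale, 1), "/")
  if (spatially_coherent) {
    matrix(x[, 1L], n_channels, n_samples, byrow = TRUE)
  } else {
    t(x)
  }
}

#' Specify a simulated lateralized working-memory study
#'
#' Defines the design of a synthetic dataset: the recording template
#' (montage, sampling rate, epoch span; see [sim_template()]), the number of
#' participants and trials, the condition factors, and an *effect map* that
#' injects plane-wave components whose amplitude or phase gradient depends on
#' condition. The effect map is the ground truth that downstream recovery
#' tests check against.
#'
#' The effect map is a tibble with one row per injected wave component.
#' Columns `axis` (`"midline"`, `"left"`, `"right"`, `"contra"`, `"ipsi"`),
#' `direction` (`"forward"`/`"backward"`) and `amplitude` are required;
#' optional columns `freq` (default 10 Hz), `phase_step` (magnitude, default
#' `pi/7`; the sign is set by `direction`), `onset`/`offset` (seconds
#' relative to display onset; default whole epoch) and any condition columns
#' (`load`, `set_size`, `side`, `lateral_items`) restrict the rows to
#' matching trials; an absent condition column means "applies to all".
#' `contra`/`ipsi` axes are resolved per trial from the trial's `side`.
#'
#' @param template `"ds1"` (distractor load 2/4/6, lateralized targets or
#'   distractors) or `"ds2"` (set size 1/3/6, lateralized targets).
#' @param n_participants,n_trials_per_condition design sizes, `>= 1`.
#' @param loads,set_sizes condition levels for the load/set-size factor
#'   (template-dependent; pass `NULL` to use the template default).
#' @param sides lateral sides used, default `c("left", "right")`.
#' @param lateral_items for `"ds1"` only: which item type is lateral,
#'   default `c("targets", "distractors")`.
#' @param effect_map tibble of injected wave components (see Details);
#'   `NULL` = pure noise.
#' @param noise_exponent,noise_scale,noise_coherent background-noise
#'   parameters passed to [make_noise()].
#' @param participant_sd log-normal SD of a per-participant multiplicative
#'   factor applied to all injected wave amplitudes (between-participant
#'   heterogeneity); 0 = identical participants.
#' @param channels optional montage restriction (labels to generate);
#'   defaults to the template's axis channels.
#' @param seed RNG seed making [simulate_dataset()] fully reproducible.
#' @return A `design_spec` list.
#' @export
design_spec <- function(template = c("ds1", "ds2"),
                        n_participants = 10,
                        n_trials_per_condition = 10,
                        loads = NULL, set_sizes = NULL,
                        sides = c("left", "right"),
                        lateral_items = c("targets", "distractors"),
                        effect_map = NULL,
                        noise_exponent = 1, noise_scale = 1,
                        noise_coherent = FALSE,
                        participant_sd = 0,
                        channels = NULL,
                        seed = 1L) {
  template <- arg_match(template)
  if (n_participants < 1 || n_trials_per_condition < 1) {
    abort("participant and trial counts must be >= 1.")
  }
  bad <- setdiff(sides, c("left", "right"))
  if (length(bad)) abort(sprintf("unknown side(s): %s", paste(bad, collapse = ", ")))
  if (template == "ds1") {
    loads <- loads %||% c(2, 4, 6)
    conditions <- tidyr::crossing(load = loads, side = sides,
                                  lateral_items = lateral_items)
  } else {
    set_sizes <- set_sizes %||% c(1, 3, 6)
    conditions <- tidyr::crossing(set_size = set_sizes, side = sides)
  }
  if (!is.null(effect_map)) {
    effect_map <- as_tibble(effect_map)
    need <- setdiff(c("axis", "direction", "amplitude"), names(effect_map))
    if (length(need)) {
      abort(sprintf("effect_map lacks column(s): %s", paste(need, collapse = ", ")))
    }
  }
  structure(list(
    template = template,
    n_participants = as.integer(n_participants),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    conditions = conditions,
    effect_map = effect_map,
    noise_exponent = noise_exponent, noise_scale = noise_scale,
    noise_coherent = noise_coherent,
    participant_sd = participant_sd,
    channels = channels,
    seed = as.integer(seed)
  ), class = "design_spec")
}

# rows of the effect map applying to one trial (condition columns match or
# are absent), with contra/ipsi axes resolved to left/right via the side
resolve_effects <- function(effect_map, trial_row) {
  if (is.null(effect_map) || nrow(effect_map) == 0) return(effect_map)
  cond_cols <- intersect(names(effect_map),
                         c("load", "set_size", "side", "lateral_items"))
  keep <- rep(TRUE, nrow(effect_map))
  for (cc in cond_cols) {
    keep <- keep & (is.na(effect_map[[cc]]) |
                      effect_map[[cc]] == trial_row[[cc]])
  }
  em <- effect_map[keep, , drop = FALSE]
  if (!nrow(em)) return(em)
  opposite <- if (trial_row$side == "left") "right" else "left"
  em$axis <- dplyr::case_when(
    em$axis == "contra" ~ opposite,
    em$axis == "ipsi" ~ trial_row$side,
    TRUE ~ em$axis
  )
  em
}

#' Simulate an epoched multichannel EEG dataset
#'
#' Draws one epoched recording per participant according to a
#' [design_spec()]: 1/f background noise on every montage channel plus the
#' effect map's plane-wave components rendered directly onto the channels of
#' the targeted axis (no volume-conduction model: the wave measure operates
#' on axis channel stacks, so waves are generated where they are measured).
#' Each wave component draws a fresh uniform initial phase per trial unless
#' its spec pins `phase0`. The result is bit-reproducible for a given design
#' (including its `seed`).
#'
#' @param design a [design_spec()].
#' @return A tibble with columns `participant` and `epochs` (list column of
#'   [eeg_epochs()] objects).
#' @export
#' @examples
#' d <- design_spec("ds2", n_participants = 1, n_trials_per_condition = 1,
#'                  set_sizes = 3, sides = "left", seed = 7)
#' simulate_dataset(d)
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  tpl <- sim_template(design$template)
  chans <- design$channels %||% tpl$channels
  axes <- axis_set(design$template)
  axes <- axes[map_dbl(axes$channels, ~ length(intersect(.x, chans))) ==
                 lengths(axes$channels), , drop = FALSE]
  n_ch <- length(chans)
  n_s <- tpl$n_samples

  withr::with_seed(design$seed, {
    out <- map(seq_len(design$n_participants), function(p) {
      pfac <- if (design$participant_sd > 0) {
        exp(rnorm(1, 0, design$participant_sd))
      } else 1
      trials <- tidyr::uncount(design$conditions,
                               design$n_trials_per_condition)
      trials$trial <- seq_len(nrow(trials))
      cond_idx <- rep(seq_len(nrow(design$conditions)),
                      each = design$n_trials_per_condition)
      resolved <- map(seq_len(nrow(design$conditions)), function(ci) {
        resolve_effects(design$effect_map, design$conditions[ci, ])
      })
      dat <- array(0, c(nrow(trials), n_ch, n_s))
      for (i in seq_len(nrow(trials))) {
        dat[i, , ] <- make_noise(n_ch, n_s, tpl$fs, design$noise_exponent,
                                 design$noise_scale, design$noise_coherent)
        em <- resolved[[cond_idx[i]]]
        if (!is.null(em) && nrow(em)) {
          for (j in seq_len(nrow(em))) {
            ai <- match(em$axis[j], axes$axis)
            if (is.na(ai)) {
              abort(sprintf("effect map targets unknown axis '%s'.", em$axis[j]))
            }
            ax_chans <- axes$channels[[ai]]
            # effect-map phase steps are per interpolated (7-channel) step so
            # the measured gradient is comparable across axes; rescale to the
            # axis' own channel spacing
            step <- abs(em[["phase_step"]][j] %|NA|% (pi / 7)) *
              6 / (length(ax_chans) - 1)
            if (em$direction[j] == "backward") step <- -step
            ws <- wave_spec(
              freq = em[["freq"]][j] %|NA|% 10,
              phase_step = step,
              amplitude = em$amplitude[j] * pfac,
              onset = (em[["onset"]][j] %|NA|% tpl$tmin) - tpl$tmin,
              offset = (em[["offset"]][j] %|NA|%
                          (tpl$tmin + (n_s - 1) / tpl$fs)) - tpl$tmin,
              phase0 = "random"
            )
            w <- make_plane_wave(ws, length(ax_chans), n_s, tpl$fs)
            idx <- match(ax_chans, chans)
            dat[i, idx, ] <- dat[i, idx, ] + w
          }
        }
      }
      eeg_epochs(dat, chans, tpl$fs, tpl$tmin, trials)
    })
    tibble(participant = seq_len(design$n_participants), epochs = out)
  })
}

# NA-coalescing helper for optional effect-map columns
`%|NA|%` <- function(x, y) {
  if (is.null(x) || length(x) == 0 || is.na(x)) y else x
}
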