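#' Write and read the plain-text epochs container
#'
#' The package's interchange format for epoched EEG: a directory holding
#' `meta.json` (sampling rate, epoch start, dimensions, channel labels),
#' `trials.csv` (per-trial metadata) and `data.csv` (one row per
#' trial-channel pair, one column per sample). Numeric values are written
#' with shortest round-trip precision, so a write/read cycle reproduces the
#' recording bit-exactly.
#'
#' @param x an [eeg_epochs()] object.
#' @param path directory to create/read.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns an [eeg_epochs()].
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "eeg_epochs"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(x$data)
  meta <- list(format = "alphawaves-epochs", version = 1L,
               fs = x$fs, tmin = x$times[1L],
               n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
               channels = x$channels)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(x$trials, file.path(path, "trials.csv"))
  flat <- matrix(aperm(x$data, c(3L, 2L, 1L)), nrow = d[1L] * d[2L],
                 byrow = TRUE)
  # %.17g guarantees an exact double round trip through base R's parser
  txt <- matrix(sprintf("%.17g", flat), nrow = nrow(flat))
  tab <- data.frame(trial = rep(x$trials$trial, each = d[2L]),
                    channel = rep(x$channels, d[1L]), txt)
  names(tab) <- c("trial", "channel", paste0("s", seq_len(d[3L])))
  utils::write.csv(tab, file.path(path, "data.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @param template optional recording template name; when the file's
#'   sampling rate disagrees with the template, the file wins with a
#'   warning.
#' @export
read_epochs <- function(path, template = NULL) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("'%s' is not an epochs container (no meta.json).", path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("fs", "tmin", "n_trials", "n_channels", "n_samples",
                  "channels")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("container metadata lacks required field '%s'.", field))
    }
  }
  if (!is.null(template)) {
    tpl <- sim_template(template)
    if (!isTRUE(all.equal(tpl$fs, meta$fs))) {
      warn(sprintf(
        "container fs (%g Hz) overrides template '%s' fs (%g Hz).",
        meta$fs, template, tpl$fs))
    }
  }
  trials <- readr::read_csv(file.path(path, "trials.csv"),
                            show_col_types = FALSE)
  tab <- utils::read.csv(file.path(path, "data.csv"), check.names = FALSE)
  expected <- meta$n_trials * meta$n_channels
  if (nrow(tab) != expected || ncol(tab) != meta$n_samples + 2L) {
    abort(sprintf(
      "truncated container: data.csv is %d x %d, expected %d x %d.",
      nrow(tab), ncol(tab), expected, meta$n_samples + 2L))
  }
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  arr <- aperm(array(t(vals), c(meta$n_samples, meta$n_channels,
                                meta$n_trials)), c(3L, 2L, 1L))
  eeg_epochs(arr, meta$channels, as.numeric(meta$fs), as.numeric(meta$tmin),
             trials)
}

# ---------------------------------------------------------------------------

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) against the pipeline schema
#' before any computation: required keys, known template and axis names,
#' numeric bands, a defined `analysis_band`, a valid window and retention
#' interval and a known trial statistic.
#'
#' @param config a list or path to a YAML file.
#' @return The normalized configuration list, invisibly classed
#'   `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path.")
  for (key in c("template", "bands", "analysis_band", "retention")) {
    if (is.null(config[[key]])) {
      abort(sprintf("config lacks required key '%s'.", key))
    }
  }
  config$template <- arg_match0(config$template, c("ds1", "ds2"))
  if (is.null(config$simulate) && is.null(config$input)) {
    abort("config needs either a `simulate` block or an `input` path.")
  }
  bands <- config$bands
  if (is.null(names(bands)) || any(names(bands) == "")) {
    abort("`bands` must be a named list of [lo, hi] pairs.")
  }
  for (nm in names(bands)) {
    b <- unlist(bands[[nm]])
    if (length(b) != 2 || !is.numeric(b) || b[1] > b[2] || b[1] <= 0) {
      abort(sprintf("band '%s' must be a numeric [lo, hi] pair with 0 < lo <= hi.", nm))
    }
    config$bands[[nm]] <- b
  }
  if (!config$analysis_band %in% names(bands)) {
    abort(sprintf("unknown band name '%s': bands define only %s.",
                  config$analysis_band,
                  paste(names(bands), collapse = ", ")))
  }
  ret <- unlist(config$retention)
  if (length(ret) != 2 || ret[1] > ret[2]) {
    abort("`retention` must be [t0, t1] seconds with t0 <= t1.")
  }
  config$retention <- ret
  w <- config$window %||% list(length = 0.5, step = 0.1)
  config$window <- window_spec(w$length %||% 0.5, w$step %||% 0.1)
  config$statistic <- arg_match0(config$statistic %||% "mean",
                                 c("mean", "median"))
  config$axes <- unlist(config$axes) %||% axis_set(config$template)$axis
  known <- axis_set(config$template, include_variants = TRUE)$axis
  bad <- setdiff(config$axes, known)
  if (length(bad)) {
    abort(sprintf("unknown axis name(s) in config: %s",
                  paste(bad, collapse = ", ")))
  }
  config$stats <- config$stats %||% list(method = "bic")
  config$stats$method <- arg_match0(config$stats$method %||% "bic",
                                    c("bic", "quadrature", "mc"))
  invisible(structure(config, class = "pipeline_config"))
}

config_design <- function(config, seed) {
  sim <- config$simulate
  em <- sim$effect_map
  if (!is.null(em)) em <- bind_rows(map(em, as_tibble))
  design_spec(
    template = config$template,
    n_participants = sim$n_participants %||% 3,
    n_trials_per_condition = sim$n_trials_per_condition %||% 4,
    loads = unlist(sim$loads),
    set_sizes = unlist(sim$set_sizes),
    sides = unlist(sim$sides) %||% c("left", "right"),
    lateral_items = unlist(sim$lateral_items) %||%
      c("targets", "distractors"),
    effect_map = em,
    noise_exponent = sim$noise_exponent %||% 1,
    noise_scale = sim$noise_scale %||% 1,
    noise_coherent = isTRUE(sim$noise_coherent),
    participant_sd = sim$participant_sd %||% 0,
    seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain on a configuration: simulate (or load) epochs,
#' compute sliding-window directional wave power on the configured axes,
#' average the retention interval, collapse trials to condition cells
#' (relabelling hemispheric axes as contra/ipsilateral when the design is
#' lateralized), and run the Bayesian analyses (condition RM-ANOVA per
#' direction on the midline axis; per-timepoint contra-vs-ipsi t tests when
#' both lateral axes are configured). Result tables are written as CSV plus
#' a JSON provenance record (config hash, seed, versions, timestamp); given
#' the same configuration and seed the CSV outputs are byte-identical
#' across runs.
#'
#' @param config list or YAML path (see [validate_config()]).
#' @param out_dir output directory (default `config$out_dir`, or a
#'   temporary directory).
#' @param seed integer seed overriding `config$seed`.
#' @return Invisibly, a list with `wave_power`, `cells`, `anova`,
#'   `timecourse`, `config` and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- validate_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("alphawaves-run-")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dat <- if (!is.null(config$simulate)) {
    simulate_dataset(config_design(config, seed))
  } else {
    tibble(participant = 1L,
           epochs = list(read_epochs(config$input, config$template)))
  }

  wave <- compute_wave_power(
    dat, axes = config$axes, template = config$template,
    window = config$window, bands = config$bands
  )
  factor_col <- if (config$template == "ds1") "load" else "set_size"

  ret <- average_retention(
    select(wave, -any_of(c("freq"))), config$retention
  )
  has_lat <- all(c("left", "right") %in% config$axes) &&
    "side" %in% names(ret)
  cells_in <- if (has_lat) assign_roles(ret) else ret
  key_cols <- intersect(
    c("participant", "axis", "role", "band", "direction", factor_col),
    names(cells_in))
  cells <- aggregate_trials(
    select(cells_in, all_of(c(key_cols, "trial", "power_db"))),
    config$statistic)

  band <- config$analysis_band
  anova <- NULL
  if ("midline" %in% config$axes &&
      length(unique(cells[[factor_col]])) >= 2) {
    mid <- filter(cells, .data$axis == "midline", .data$band == !!band)
    anova <- map(c(forward = "forward", backward = "backward"), function(dd) {
      rm_anova_bf(filter(mid, .data$direction == dd), factor_col,
                  method = config$stats$method, seed = seed)
    })
  }

  tc <- NULL
  if (has_lat) {
    lat <- wave %>%
      filter(.data$axis != "midline", .data$band == !!band) %>%
      assign_roles() %>%
      group_by(.data$participant, .data$time, .data$role, .data$direction) %>%
      summarise(power_db = mean(.data$power_db), .groups = "drop")
    tc <- map(c(forward = "forward", backward = "backward"), function(dd) {
      timecourse_bf(filter(lat, .data$direction == dd))
    })
  }

  readr::write_csv(wave, file.path(out_dir, "wave_power.csv"))
  readr::write_csv(cells, file.path(out_dir, "condition_cells.csv"))
  if (!is.null(anova)) {
    readr::write_csv(
      bind_rows(imap(anova, function(a, dd) mutate(tidy(a), direction = dd))),
      file.path(out_dir, "bf_results.csv"))
  }
  if (!is.null(tc)) {
    readr::write_csv(
      bind_rows(imap(tc, function(x, dd)
        mutate(as_tibble(x), direction = dd))),
      file.path(out_dir, "bf_timecourse.csv"))
  }
  prov <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    package_version = as.character(utils::packageVersion("alphawaves")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(wave_power = wave, cells = cells, anova = anova,
                 timecourse = tc, config = config, out_dir = out_dir))
}
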