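#' Epoched EEG container
#'
#' A minimal in-memory container for segmented (epoched) multichannel EEG:
#' a `trials x channels x samples` numeric array plus channel labels, the
#' sampling rate, the epoch time axis (seconds, 0 = memory-display onset) and
#' a per-trial metadata table. All analysis functions in the package consume
#' this object and return plain tibbles.
#'
#' @param data numeric array with dimensions `trials x channels x samples`.
#' @param channels character vector of channel labels, one per array row 2.
#' @param fs sampling rate in Hz.
#' @param tmin time of the first sample in seconds relative to epoch time zero
#'   (memory-display onset); typically negative.
#' @param trials tibble of per-trial metadata with one row per trial; a
#'   `trial` id column is added when absent.
#'
#' @return An object of class `eeg_epochs`: a list with elements `data`,
#'   `channels`, `fs`, `times` and `trials`.
#' @export
#' @examples
#' x <- eeg_epochs(array(0, c(2, 3, 100)), c("Oz", "Pz", "Cz"), fs = 100,
#'                 tmin = -0.2)
#' x
eeg_epochs <- function(data, channels, fs, tmin, trials = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-d array (trials x channels x samples).")
  }
  if (length(channels) != dim(data)[2L]) {
    abort(sprintf("%d channel labels supplied for %d data channels.",
                  length(channels), dim(data)[2L]))
  }
  if (anyDuplicated(channels)) abort("channel labels must be unique.")
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive sampling rate in Hz.")
  n_trials <- dim(data)[1L]
  if (is.null(trials)) trials <- tibble(trial = seq_len(n_trials))
  trials <- as_tibble(trials)
  if (!"trial" %in% names(trials)) trials$trial <- seq_len(n_trials)
  if (nrow(trials) != n_trials) {
    abort(sprintf("trial table has %d rows for %d trials.", nrow(trials), n_trials))
  }
  structure(
    list(
      data = data,
      channels = as.character(channels),
      fs = fs,
      times = tmin + (seq_len(dim(data)[3L]) - 1) / fs,
      trials = trials
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
    d[1L], d[2L], d[3L], x$fs, x$times[1L], x$times[length(x$times)]
  ))
  extra <- setdiff(names(x$trials), "trial")
  if (length(extra)) cat("trial metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Recording templates for the two emulated study designs
#'
#' Montage, sampling rate and epoch span for the two dataset layouts the
#' synthetic generator emulates: `"ds1"`, a 32-channel 10/10 montage sampled
#' at 1000 Hz with epochs from -800 to 1600 ms around memory-display onset
#' (lateralized change-detection design, distractor load 2/4/6); and `"ds2"`,
#' a 20-channel 10/20-style montage at 250 Hz with epochs from -1400 to
#' 1548 ms (lateralized whole-report design, set size 1/3/6). Simulated
#' channels are generated directly on the analysis axes, so the generator
#' montage is the union of the template's axis channels.
#'
#' @param template `"ds1"` or `"ds2"`.
#' @return A list with `fs`, `tmin`, `n_samples`, `channels` (the generated
#'   montage) and `retention` (the retention-period averaging interval in
#'   seconds).
#' @export
#' @examples
#' sim_template("ds1")$fs
sim_template <- function(template) {
  template <- arg_match0(template, c("ds1", "ds2"))
  axes <- axis_set(template)
  chans <- unique(unlist(axes$channels))
  switch(template,
    ds1 = list(template = "ds1", fs = 1000, tmin = -0.8, n_samples = 2400L,
               channels = chans, retention = c(0.2, 1.2)),
    ds2 = list(template = "ds2", fs = 250, tmin = -1.4, n_samples = 737L,
               channels = chans, retention = c(0.25, 1.55))
  )
}
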