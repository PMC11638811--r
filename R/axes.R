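.axes_cache <- new.env(parent = emptyenv())

#' Electrode axis definitions
#'
#' An electrode axis is an ordered list of channel labels running from the
#' most posterior to the most anterior site of one scalp line (midline, left
#' or right hemisphere). Axes for the two built-in recording templates are
#' shipped as an editable YAML file (`system.file("extdata", "axes.yaml",
#' package = "alphawaves")`); custom axes can be supplied with
#' `electrode_axis()` or through the same YAML schema.
#'
#' The printed source listing of the `ds2` midline contains a repeated label;
#' the default `midline` entry uses the corrected reading and the literal
#' listing is available as the `midline_literal` variant (see
#' `include_variants`).
#'
#' @param template `"ds1"` or `"ds2"`.
#' @param include_variants also return documentation-only axis variants
#'   (currently the literal `ds2` midline listing, which contains a duplicate
#'   label and is excluded by default).
#' @param file optional path to an axis YAML file replacing the shipped one.
#' @return A tibble with columns `axis` (name) and `channels` (list column of
#'   posterior-first channel labels).
#' @export
#' @examples
#' axis_set("ds1")
axis_set <- function(template, include_variants = FALSE, file = NULL) {
  template <- arg_match0(template, c("ds1", "ds2"))
  if (is.null(file)) {
    file <- system.file("extdata", "axes.yaml", package = "alphawaves")
  }
  key <- paste(normalizePath(file), file.mtime(file))
  defs <- .axes_cache[[key]]
  if (is.null(defs)) {
    defs <- yaml::read_yaml(file)
    .axes_cache[[key]] <- defs
  }
  if (is.null(defs[[template]])) {
    abort(sprintf("axis file has no entry for template '%s'.", template))
  }
  tbl <- tibble(
    axis = names(defs[[template]]),
    channels = map(defs[[template]], function(a) as.character(a$channels))
  )
  if (!include_variants) {
    tbl <- filter(tbl, !grepl("_literal$", .data$axis))
  }
  walk(seq_len(nrow(tbl)), function(i) {
    electrode_axis(tbl$axis[i], tbl$channels[[i]],
                   check_unique = !grepl("_literal$", tbl$axis[i]))
  })
  tbl
}

#' Construct a validated electrode axis
#'
#' @param name axis name (e.g. `"midline"`, `"left"`, `"right"`).
#' @param channels ordered channel labels, most posterior first.
#' @param check_unique require unique labels (default). Only documented
#'   literal-listing variants may disable this.
#' @return A list with `name` and `channels`, classed `electrode_axis`.
#' @export
electrode_axis <- function(name, channels, check_unique = TRUE) {
  channels <- as.character(channels)
  if (length(channels) < 3) {
    abort(sprintf("axis '%s' needs at least 3 channels, got %d.",
                  name, length(channels)))
  }
  if (check_unique && anyDuplicated(channels)) {
    abort(sprintf("axis '%s' has duplicated channel labels.", name))
  }
  structure(list(name = name, channels = channels), class = "electrode_axis")
}

# 7 x k weight matrix for linear interpolation on rank positions 0..k-1
# rescaled to [0, 1]; rows are output positions j/6, j = 0..6.
axis_interp_weights <- function(k, n_out = 7L) {
  stopifnot(k >= 2)
  r <- (seq_len(n_out) - 1) / (n_out - 1) * (k - 1)
  i0 <- pmin(floor(r), k - 2)
  w <- r - i0
  W <- matrix(0, n_out, k)
  W[cbind(seq_len(n_out), i0 + 1)] <- 1 - w
  W[cbind(seq_len(n_out), i0 + 2)] <- W[cbind(seq_len(n_out), i0 + 2)] + w
  W
}

#' Interpolate an axis to seven virtual channels
#'
#' Extracts the channels of one posterior-to-anterior axis and linearly
#' interpolates them to seven virtual channels so that all axes have the same
#' spatial sampling. Interpolation positions are the channel ranks along the
#' axis (equally spaced, rescaled to \[0, 1\]), not 3-d scalp distances: the
#' seven output rows sit at positions 0, 1/6, ..., 1 and a seven-channel axis
#' maps to itself unchanged. Row 1 of the result is the most posterior
#' channel.
#'
#' @param x an `eeg_epochs` object, or a single `channels x samples` matrix
#'   already restricted to the axis (posterior-first row order).
#' @param axis an `electrode_axis` or a character vector of posterior-first
#'   channel labels (required for `eeg_epochs` input).
#' @param ... unused.
#' @return For a matrix: a `7 x samples` matrix. For `eeg_epochs`: a
#'   `trials x 7 x samples` array with attributes `axis`, `fs` and `times`.
#' @export
#' @examples
#' m <- matrix(rep(0:3, each = 5), nrow = 4, byrow = FALSE)
#' build_axis_stack(m)[, 1]
build_axis_stack <- function(x, ...) UseMethod("build_axis_stack")

#' @rdname build_axis_stack
#' @export
build_axis_stack.matrix <- function(x, ...) {
  if (nrow(x) < 2) abort("axis matrix needs at least 2 channel rows.")
  axis_interp_weights(nrow(x)) %*% x
}

#' @rdname build_axis_stack
#' @export
build_axis_stack.eeg_epochs <- function(x, axis, ...) {
  if (inherits(axis, "electrode_axis")) {
    name <- axis$name
    chans <- axis$channels
  } else {
    name <- NA_character_
    chans <- as.character(axis)
  }
  missing <- setdiff(chans, x$channels)
  if (length(missing)) {
    abort(sprintf("axis channel(s) not present in recording: %s",
                  paste(missing, collapse = ", ")))
  }
  idx <- match(chans, x$channels)
  W <- axis_interp_weights(length(idx))
  d <- dim(x$data)
  out <- array(NA_real_, c(d[1L], 7L, d[3L]))
  for (i in seq_len(d[1L])) {
    out[i, , ] <- W %*% x$data[i, idx, ]
  }
  structure(out, axis = name, fs = x$fs, times = x$times)
}

#' Map hemispheric axes to contra/ipsilateral roles
#'
#' Relabels per-trial results on the `left`/`right` axes as contralateral or
#' ipsilateral to the items of interest. Visual input projects
#' contralaterally, so items presented on the left make the right axis
#' contralateral (and symmetrically). The midline axis is unaffected. In
#' designs where either targets or distractors can be the lateral cluster
#' (`lateral_items` column), asking for the items of the opposite type flips
#' the assignment, since those items sit in the opposite hemifield.
#'
#' @param df a tibble with columns `axis` (`"left"`, `"right"`, `"midline"`)
#'   and `side` (`"left"`/`"right"`, the hemifield of the lateral stimulus
#'   cluster); optionally `lateral_items` naming which item type is lateral.
#' @param items_of_interest `"targets"` or `"distractors"`: which items the
#'   contra/ipsi labels should refer to.
#' @return `df` with an added `role` column
#'   (`"contra"`, `"ipsi"`, `"midline"`).
#' @export
#' @examples
#' df <- tibble::tibble(axis = c("left", "right"), side = "left")
#' assign_roles(df)$role
assign_roles <- function(df, items_of_interest = "targets") {
  items_of_interest <- arg_match0(items_of_interest, c("targets", "distractors"))
  if (!all(c("axis", "side") %in% names(df))) {
    abort("`df` must have `axis` and `side` columns.")
  }
  bad <- setdiff(unique(df$side), c("left", "right"))
  if (length(bad)) {
    abort(sprintf("unknown side label(s): %s", paste(bad, collapse = ", ")))
  }
  lateral <- if ("lateral_items" %in% names(df)) df$lateral_items else "targets"
  lateral <- rep_len(lateral, nrow(df))
  item_side <- ifelse(lateral == items_of_interest,
                      df$side,
                      ifelse(df$side == "left", "right", "left"))
  mutate(df, role = dplyr::case_when(
    .data$axis == "midline" ~ "midline",
    .data$axis == item_side ~ "ipsi",
    TRUE ~ "contra"
  ))
}
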