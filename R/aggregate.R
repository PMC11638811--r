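#' Average wave power over a retention interval
#'
#' Collapses a per-window series to one value per trial (and per axis, band
#' and direction) by averaging the sliding windows whose *center* lies in
#' the closed interval `[interval[1], interval[2]]` — the retention-period
#' averaging used for the condition-level analyses (0.2-1.2 s for the
#' `ds1` template, 0.25-1.55 s for `ds2`; see [sim_template()]).
#'
#' @param df tibble with a `time` column (window centers, seconds) and a
#'   `power_db` value column; all other columns are grouping keys.
#' @param interval numeric `c(t0, t1)` in seconds, closed.
#' @return Tibble with one row per key and the interval-mean `power_db`.
#' @export
#' @examples
#' df <- tibble::tibble(trial = 1, time = c(0.1, 0.5, 1.3), power_db = 1:3)
#' average_retention(df, c(0.2, 1.2))
average_retention <- function(df, interval) {
  if (length(interval) != 2 || interval[1] > interval[2]) {
    abort("`interval` must be c(t0, t1) with t0 <= t1.")
  }
  sel <- filter(df, .data$time >= interval[1] - 1e-9,
                .data$time <= interval[2] + 1e-9)
  if (!nrow(sel)) abort("no window center lies in the retention interval.")
  keys <- setdiff(names(sel), c("time", "power_db"))
  sel %>%
    group_by(across(all_of(keys))) %>%
    summarise(power_db = mean(.data$power_db), .groups = "drop")
}

#' Collapse trials to condition cells
#'
#' Aggregates per-trial values to one cell per participant x condition x
#' axis (or role) x direction x band, using the mean across trials by
#' default or the median for the robustness variant. Keys with no trials
#' are impossible by construction here, but cells whose value is missing
#' (e.g. from degenerate segments) propagate `NA` explicitly rather than
#' being dropped.
#'
#' @param df per-trial tibble with a `power_db` value column; `trial` is
#'   consumed, every other column is a grouping key.
#' @param statistic `"mean"` or `"median"` across trials.
#' @return Condition-cell tibble: one row per unique key, with `statistic`
#'   and the aggregated `value` (dB).
#' @export
#' @examples
#' df <- tibble::tibble(participant = 1, load = 2, trial = 1:3,
#'                      power_db = c(1, 1, 10))
#' aggregate_trials(df)$value          # mean 4
#' aggregate_trials(df, "median")$value # median 1
aggregate_trials <- function(df, statistic = c("mean", "median")) {
  statistic <- arg_match(statistic)
  fun <- if (statistic == "mean") mean else median
  keys <- setdiff(names(df), c("trial", "power_db"))
  out <- df %>%
    group_by(across(all_of(keys))) %>%
    summarise(value = fun(.data$power_db), .groups = "drop") %>%
    mutate(statistic = statistic)
  if (anyNA(out$value)) {
    warn(sprintf("%d condition cell(s) have missing values.",
                 sum(is.na(out$value))))
  }
  out
}

#' Pool condition cells across subexperiments
#'
#' Binds the condition-cell tables of several subexperiments into one table,
#' tagging every participant with the source experiment, and optionally
#' restricts the pool to experiments in which a factor has all of its
#' required levels — the rule used for the factorial analyses, which can
#' only use subexperiments that ran every level (the per-timepoint contrasts
#' use all experiments).
#'
#' @param tables named list of condition-cell tibbles (names become the
#'   `experiment` tag), or a single tibble that already has an `experiment`
#'   column (`scheme` filtering only).
#' @param scheme optional list `list(factor = "load", levels = c(2, 4, 6))`:
#'   keep only experiments whose cells contain every listed level of the
#'   factor. `NULL` pools everything.
#' @return The pooled tibble with an `experiment` column.
#' @export
#' @examples
#' a <- tibble::tibble(participant = 1:2, load = 2, value = 0)
#' b <- tibble::tibble(participant = 3:4, load = 2, value = 0)
#' nrow(pool_conditions(list(e1 = a, e2 = b)))
pool_conditions <- function(tables, scheme = NULL) {
  if (is.data.frame(tables)) {
    if (!"experiment" %in% names(tables)) {
      abort("a single table must already carry an `experiment` column.")
    }
    pooled <- as_tibble(tables)
  } else {
    if (is.null(names(tables)) || any(names(tables) == "")) {
      abort("`tables` must be a named list of condition-cell tables.")
    }
    common <- map(tables, names)
    walk(common, function(nm) {
      if (!setequal(setdiff(nm, "experiment"),
                    setdiff(common[[1]], "experiment"))) {
        abort("subexperiment tables have conflicting column sets.")
      }
    })
    pooled <- bind_rows(imap(tables, function(tb, nm) {
      mutate(as_tibble(tb), experiment = nm)
    }))
  }
  if (is.null(scheme)) return(pooled)
  if (!all(c("factor", "levels") %in% names(scheme))) {
    abort("`scheme` must be list(factor = <column>, levels = <values>).")
  }
  fac <- scheme$factor
  if (!fac %in% names(pooled)) {
    abort(sprintf("pooled table has no '%s' column.", fac))
  }
  keep <- pooled %>%
    group_by(.data$experiment) %>%
    summarise(ok = all(scheme$levels %in% .data[[fac]]), .groups = "drop") %>%
    filter(.data$ok) %>%
    pull(.data$experiment)
  filter(pooled, .data$experiment %in% keep)
}
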