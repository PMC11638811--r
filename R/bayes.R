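# Bayesian inference layer: JZS t tests, repeated-measures ANOVA inclusion
# Bayes factors, post hoc comparisons, BF linear regression, Cowan's K.

new_bf_result <- function(kind, effect, bf, method, error = NA_real_,
                          seed = NA_integer_, extra = list()) {
  structure(c(list(kind = kind, effect = effect, bf = bf, method = method,
                   error = error, seed = seed), extra),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bf_result:%s> %s  BF10 = %.4g  (%s%s)\n",
              x$kind, x$effect, x$bf, x$method,
              if (is.finite(x$error)) sprintf(", rel. error %.2g", x$error) else ""))
  invisible(x)
}

# inverse-gamma(1/2, scale b) density of the JZS mixing parameter g
dinvgamma_half <- function(g, b) {
  sqrt(b) / gamma(0.5) * g^(-1.5) * exp(-b / g)
}

# JZS one-sample BF10 from a t statistic (Cauchy prior scale r on the
# standardized effect; numerical quadrature over the g mixture)
jzs_bf_t <- function(t, n, r_scale = sqrt(2) / 2) {
  nu <- n - 1
  log_lik <- function(g) {
    -0.5 * log1p(n * g) - (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu))
  }
  num <- integrate(function(g) exp(log_lik(g)) *
                     dinvgamma_half(g, r_scale^2 / 2),
                   0, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  num / exp(log_den)
}

#' JZS Bayesian t test
#'
#' Default Bayesian t test with the Jeffreys-Zellner-Siow prior: a Cauchy
#' prior with scale `r_scale` on the standardized effect size, integrated by
#' deterministic numerical quadrature. Pass paired differences (or a single
#' sample tested against zero), or a precomputed t statistic via `t` and
#' `n`.
#'
#' @param x numeric vector of (paired) differences; ignored when `t` is
#'   given.
#' @param t,n alternative input: the t statistic and sample size.
#' @param r_scale Cauchy prior scale (default `sqrt(2)/2`, the common
#'   default for t tests).
#' @return A `bf_result` with `bf` = BF10 (evidence for a nonzero effect).
#' @export
#' @examples
#' jzs_ttest_bf(t = 3, n = 30)$bf
jzs_ttest_bf <- function(x = NULL, t = NULL, n = NULL,
                         r_scale = sqrt(2) / 2) {
  if (is.null(t)) {
    if (is.null(x) || length(x) < 2) abort("need at least 2 paired differences.")
    if (!all(is.finite(x))) abort("differences must be finite.")
    if (sd(x) == 0) abort("zero variance: t statistic undefined.")
    n <- length(x)
    t <- mean(x) / (sd(x) / sqrt(n))
  } else {
    if (is.null(n) || n < 2) abort("`n` must accompany `t` and be >= 2.")
  }
  new_bf_result("t_test", "difference != 0", jzs_bf_t(t, n, r_scale),
                "quadrature", extra = list(t = t, n = n, r_scale = r_scale))
}

#' Cowan's K working-memory capacity
#'
#' `K = set_size * (hit - false_alarm)`: the estimated number of items held
#' in working memory given a change-detection hit rate and false-alarm rate.
#'
#' @param set_size number of memoranda (vectorized).
#' @param hit,false_alarm rates in `[0, 1]` (vectorized).
#' @return Numeric vector of K values.
#' @export
#' @examples
#' k_capacity(4, 0.75, 0.25)  # 2
k_capacity <- function(set_size, hit, false_alarm) {
  if (any(hit < 0 | hit > 1 | false_alarm < 0 | false_alarm > 1)) {
    abort("hit and false-alarm rates must lie in [0, 1].")
  }
  set_size * (hit - false_alarm)
}

# ---------------------------------------------------------------------------
# Repeated-measures ANOVA inclusion Bayes factors

# all effect sets (models) over `factors` that respect marginality:
# an interaction enters only together with all its margins
anova_model_space <- function(factors) {
  effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, paste, collapse = ":", simplify = FALSE)
  }))
  parts <- lapply(effects, function(e) strsplit(e, ":", fixed = TRUE)[[1]])
  names(parts) <- effects
  subsets <- unlist(lapply(0:length(effects), function(k) {
    utils::combn(effects, k, simplify = FALSE)
  }), recursive = FALSE)
  keep <- vapply(subsets, function(m) {
    all(vapply(m, function(e) {
      margins <- setdiff(unlist(lapply(
        seq_len(length(parts[[e]]) - 1),
        function(k) utils::combn(parts[[e]], k, paste, collapse = ":",
                                 simplify = FALSE))), e)
      length(margins) == 0 || all(margins %in% m)
    }, logical(1)))
  }, logical(1))
  subsets[keep]
}

# partial R^2 of the model terms after projecting out the participant
# blocks, plus residual dimensions, for the g-prior marginal likelihood
partial_fit <- function(dat, terms, id) {
  x0 <- stats::model.matrix(stats::reformulate(id), dat)
  q0 <- qr(x0)
  y_r <- qr.resid(q0, dat$.y)
  if (!length(terms)) {
    return(list(r2 = 0, p = 0L, q = q0$rank))
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  xm <- stats::model.matrix(stats::reformulate(terms), dat)[, -1, drop = FALSE]
  x_r <- qr.resid(q0, xm)
  qx <- qr(x_r)
  p <- qx$rank
  fitted <- qr.fitted(qx, y_r)
  r2 <- sum(fitted^2) / sum(y_r^2)
  list(r2 = r2, p = p, q = q0$rank)
}

# log marginal likelihood ratio (model vs participant-only null)
model_log_bf <- function(fit, n, method, r_scale, n_mc) {
  if (fit$p == 0L) return(list(log_bf = 0, rel_err = 0))
  a <- (n - fit$q - fit$p) / 2
  b <- (n - fit$q) / 2
  one_minus_r2 <- max(1 - fit$r2, 1e-15)
  if (method == "bic") {
    # Schwarz approximation on the nuisance-projected residual dimension
    return(list(log_bf = -0.5 * fit$p * log(n) - b * log(one_minus_r2),
                rel_err = NA_real_))
  }
  log_int <- function(g) a * log1p(g) - b * log(1 + g * one_minus_r2)
  if (method == "quadrature") {
    # deterministic integration of the Zellner-Siow g prior, with the
    # integrand's peak factored out for numerical range
    shift <- stats::optimize(function(lg) log_int(exp(lg)),
                             c(-10, 25), maximum = TRUE)$objective
    val <- integrate(function(g) {
      exp(log_int(g) - shift) * dinvgamma_half(g, n * r_scale^2 / 2)
    }, 0, Inf, rel.tol = 1e-9, subdivisions = 1000L)$value
    return(list(log_bf = shift + log(val), rel_err = NA_real_))
  }
  # Monte Carlo over the Zellner-Siow g prior: g ~ InvGamma(1/2, n r^2 / 2)
  g <- 1 / rgamma(n_mc, shape = 0.5, rate = n * r_scale^2 / 2)
  lw <- log_int(g)
  m <- max(lw)
  w <- exp(lw - m)
  est <- mean(w)
  list(log_bf = m + log(est),
       rel_err = sd(w) / (sqrt(n_mc) * est))
}

#' Repeated-measures ANOVA inclusion Bayes factors
#'
#' Enumerates the space of fixed-effect models over the given
#' within-participant factors (main effects and interactions, marginality
#' respected: an interaction enters only with its main effects), always
#' including a participant intercept, and scores each model's marginal
#' likelihood by a deterministic BIC (Schwarz) approximation (default,
#' fast), by deterministic quadrature of the Zellner-Siow g prior on the
#' effect coefficients (the convention default Bayesian ANOVAs report), or
#' by Monte Carlo integration of the same g prior (with an error estimate).
#' The inclusion Bayes factor of an effect uses the
#' matched-models rule: the posterior mass (equal prior over models) of
#' models containing the effect but none of its higher-order interactions,
#' divided by the mass of the same models with the effect removed.
#'
#' Participants with incomplete factorial cells are dropped listwise with a
#' warning; duplicated cells are an error.
#'
#' @param cells condition-cell tibble (see [aggregate_trials()]).
#' @param factors character vector of factor column names (1 or more).
#' @param dv name of the value column (default `"value"`).
#' @param id participant identifier column (default `"participant"`).
#' @param method `"bic"` (fast deterministic Schwarz approximation),
#'   `"quadrature"` (deterministic Zellner-Siow g-prior integration, the
#'   recommended setting for reporting) or `"mc"` (g-prior Monte Carlo;
#'   reports a relative error estimate and uses `seed`).
#' @param r_scale g-prior scale for the `"mc"` method (default 0.5, the
#'   common fixed-effects default).
#' @param n_mc Monte Carlo sample size per model.
#' @param seed RNG seed for the `"mc"` method.
#' @return A `bf_anova` object: list with `effects` (tibble of effect,
#'   `bf_incl`, error), `models` (model space with log BF vs the
#'   participant-only null and posterior probabilities), `method`, `seed`.
#'   `tidy()` returns the effects table.
#' @export
#' @examples
#' cells <- tidyr::crossing(participant = 1:8, load = c(2, 4, 6))
#' cells$value <- rnorm(nrow(cells)) + 0.5 * cells$load
#' tidy(rm_anova_bf(cells, "load"))
rm_anova_bf <- function(cells, factors, dv = "value", id = "participant",
                        method = c("bic", "quadrature", "mc"), r_scale = 0.5,
                        n_mc = 10000L, seed = 1L) {
  method <- arg_match(method)
  missing_cols <- setdiff(c(factors, dv, id), names(cells))
  if (length(missing_cols)) {
    abort(sprintf("cells table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dat <- tibble(.y = cells[[dv]])
  dat[[id]] <- factor(cells[[id]])
  for (f in factors) dat[[f]] <- factor(cells[[f]])
  n_cells <- prod(vapply(factors, function(f) nlevels(dat[[f]]), integer(1)))
  counts <- dat %>%
    group_by(across(all_of(c(id, factors)))) %>%
    summarise(k = dplyr::n(), .groups = "drop")
  if (any(counts$k > 1)) {
    abort("non-factorial layout: duplicated participant x condition cells.")
  }
  complete <- counts %>%
    group_by(across(all_of(id))) %>%
    summarise(k = dplyr::n(), .groups = "drop")
  bad <- complete[[id]][complete$k < n_cells]
  nas <- unique(dat[[id]][!is.finite(dat$.y)])
  drop_ids <- union(as.character(bad), as.character(nas))
  if (length(drop_ids)) {
    warn(sprintf("dropping %d participant(s) with incomplete cells.",
                 length(drop_ids)))
    dat <- dat[!(as.character(dat[[id]]) %in% drop_ids), , drop = FALSE]
    dat[[id]] <- droplevels(dat[[id]])
  }
  if (nlevels(dat[[id]]) < 3) abort("need >= 3 complete participants.")

  space <- anova_model_space(factors)
  n <- nrow(dat)
  fits <- withr::with_seed(seed, map(space, function(m) {
    fit <- partial_fit(dat, m, id)
    model_log_bf(fit, n, method, r_scale, n_mc)
  }))
  log_bf <- map_dbl(fits, "log_bf")
  rel_err <- map_dbl(fits, "rel_err")
  post <- exp(log_bf - max(log_bf))
  post <- post / sum(post)
  model_names <- map(space, function(m) if (length(m)) m else character(0))
  models <- tibble(
    model = vapply(model_names, function(m) {
      if (length(m)) paste(m, collapse = " + ") else "null (participant only)"
    }, character(1)),
    terms = model_names,
    log_bf = log_bf,
    rel_err = rel_err,
    post_prob = post
  )

  effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, paste, collapse = ":", simplify = FALSE)
  }))
  eff_tbl <- map_dfr(effects, function(e) {
    parts_e <- strsplit(e, ":", fixed = TRUE)[[1]]
    higher <- vapply(models$terms, function(m) {
      any(vapply(m, function(tm) {
        tp <- strsplit(tm, ":", fixed = TRUE)[[1]]
        length(tp) > length(parts_e) && all(parts_e %in% tp)
      }, logical(1)))
    }, logical(1))
    has_e <- vapply(models$terms, function(m) e %in% m, logical(1))
    num_idx <- which(has_e & !higher)
    den_idx <- vapply(num_idx, function(i) {
      target <- setdiff(models$terms[[i]], e)
      which(vapply(models$terms, function(m) setequal(m, target),
                   logical(1)))[1]
    }, integer(1))
    err <- if (method == "mc") {
      sqrt(max(models$rel_err[num_idx], 0)^2 +
             max(models$rel_err[den_idx], 0)^2)
    } else NA_real_
    tibble(effect = e,
           bf_incl = sum(models$post_prob[num_idx]) /
             sum(models$post_prob[den_idx]),
           error = err)
  })

  structure(list(effects = eff_tbl, models = models, method = method,
                 seed = if (method == "mc") seed else NA_integer_,
                 n_participants = nlevels(dat[[id]])),
            class = "bf_anova")
}

#' @export
print.bf_anova <- function(x, ...) {
  cat(sprintf("<bf_anova> %d participants, method %s\n",
              x$n_participants, x$method))
  print(x$effects)
  invisible(x)
}

#' @rdname rm_anova_bf
#' @param x a `bf_anova` object.
#' @param ... unused.
#' @export
tidy.bf_anova <- function(x, ...) {
  mutate(x$effects, method = x$method, seed = x$seed)
}

#' @rdname rm_anova_bf
#' @export
glance.bf_anova <- function(x, ...) {
  best <- which.max(x$models$post_prob)
  tibble(n_models = nrow(x$models),
         best_model = x$models$model[best],
         best_post_prob = x$models$post_prob[best],
         n_participants = x$n_participants,
         method = x$method)
}

#' @export
tidy.bf_result <- function(x, ...) {
  tibble(kind = x$kind, effect = x$effect, bf = x$bf, method = x$method,
         error = x$error, seed = x$seed)
}

#' @export
glance.bf_result <- function(x, ...) tidy(x)

#' Post hoc pairwise Bayesian comparison
#'
#' Paired JZS t test between two levels of a factor: participant-wise level
#' means are differenced and passed to [jzs_ttest_bf()]. Uncorrected, as is
#' conventional for Bayes-factor post hoc comparisons; flagged as post hoc
#' in the result.
#'
#' @inheritParams rm_anova_bf
#' @param factor factor column name.
#' @param levels length-2 vector: the two levels to compare (first minus
#'   second).
#' @param r_scale Cauchy prior scale passed to [jzs_ttest_bf()].
#' @return A `bf_result` (kind `"posthoc"`) with the BF10 and the mean
#'   difference in `$mean_diff`.
#' @export
posthoc_pairwise_bf <- function(cells, factor, levels, dv = "value",
                                id = "participant", r_scale = sqrt(2) / 2) {
  if (length(levels) != 2) abort("`levels` must have exactly 2 entries.")
  present <- unique(cells[[factor]])
  if (!all(levels %in% present)) {
    abort(sprintf("level(s) not present in '%s': %s", factor,
                  paste(setdiff(levels, present), collapse = ", ")))
  }
  wide <- cells %>%
    filter(.data[[factor]] %in% levels) %>%
    group_by(.data[[id]], .data[[factor]]) %>%
    summarise(value = mean(.data[[dv]]), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = all_of(factor),
                       values_from = "value")
  d <- wide[[as.character(levels[1])]] - wide[[as.character(levels[2])]]
  d <- d[is.finite(d)]
  res <- if (length(d) >= 2 && sd(d) == 0 && all(d == 0)) {
    # degenerate but well-defined null case: every participant shows exactly
    # no difference, evidence equals the t = 0 Bayes factor
    jzs_ttest_bf(t = 0, n = length(d), r_scale = r_scale)
  } else {
    jzs_ttest_bf(d, r_scale = r_scale)
  }
  new_bf_result("posthoc", sprintf("%s: %s vs %s", factor, levels[1], levels[2]),
                res$bf, "quadrature",
                extra = list(mean_diff = mean(d), t = res$t, n = res$n,
                             r_scale = r_scale))
}

#' Per-participant slopes of wave power against a condition factor
#'
#' Ordinary least-squares slope of the response against the numeric factor
#' level, fitted separately per participant — the "change magnitude" summary
#' regressed on working-memory capacity.
#'
#' @inheritParams rm_anova_bf
#' @param predictor numeric condition column (e.g. `load` or `set_size`).
#' @return Tibble with one row per participant and the fitted `slope`.
#' @export
fit_slopes <- function(cells, predictor, dv = "value", id = "participant") {
  cells %>%
    group_by(.data[[id]]) %>%
    summarise(slope = {
      xx <- as.numeric(.data[[predictor]])
      yy <- .data[[dv]]
      sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
    }, .groups = "drop")
}

#' Bayes-factor linear regression
#'
#' BF10 for a single-predictor linear regression under the
#' Jeffreys-Zellner-Siow prior on the standardized coefficient
#' (Zellner-Siow mixture of g priors, scale `r_scale`), integrated by
#' deterministic quadrature. Used to relate per-participant wave-power
#' slopes to working-memory capacity K. A numerically perfect linear
#' relation gives `Inf`.
#'
#' @param x predictor vector (e.g. per-participant slopes).
#' @param y response vector (e.g. K values).
#' @param r_scale prior scale (default `sqrt(2)/4`, the common regression
#'   default).
#' @return A `bf_result` (kind `"regression"`) with `$slope` the OLS slope.
#' @export
#' @examples
#' bf_linear_regression(1:10, (1:10) * 2 + rnorm(10))$bf
bf_linear_regression <- function(x, y, r_scale = sqrt(2) / 4) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need >= 3 complete (x, y) pairs.")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need >= 3 complete (x, y) pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant x or y: regression undefined.")
  n <- length(x)
  r2 <- stats::cor(x, y)^2
  slope <- stats::cov(x, y) / stats::var(x)
  if (1 - r2 < 1e-12) {
    return(new_bf_result("regression", "slope != 0", Inf, "quadrature",
                         extra = list(slope = slope, n = n, r2 = r2)))
  }
  bf <- integrate(function(g) {
    exp((n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2))) *
      dinvgamma_half(g, n * r_scale^2 / 2)
  }, 0, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
  new_bf_result("regression", "slope != 0", bf, "quadrature",
                extra = list(slope = slope, n = n, r2 = r2,
                             r_scale = r_scale))
}

#' Per-timepoint Bayesian contrast of contralateral vs ipsilateral power
#'
#' Applies the JZS paired t test at every window center to the
#' participant-level contralateral-minus-ipsilateral difference, returning
#' the BF10 series with the conventional BF10 > 3 evidence threshold
#' annotated. No multiple-comparison correction is applied; the threshold is
#' an annotation, not a gate.
#'
#' @param df tibble with columns `participant`, `time`, `role`
#'   (`"contra"`/`"ipsi"`) and a value column (participant-level means).
#' @param dv value column name (default `"power_db"`).
#' @param r_scale Cauchy prior scale for the t tests.
#' @param threshold evidence threshold to annotate (default 3).
#' @return A `bf_timecourse` tibble: `time`, `n`, `mean_diff`, `t`, `bf10`,
#'   `exceeds` (BF10 > threshold).
#' @export
timecourse_bf <- function(df, dv = "power_db", r_scale = sqrt(2) / 2,
                          threshold = 3) {
  need <- setdiff(c("participant", "time", "role", dv), names(df))
  if (length(need)) {
    abort(sprintf("missing column(s): %s", paste(need, collapse = ", ")))
  }
  wide <- df %>%
    filter(.data$role %in% c("contra", "ipsi")) %>%
    group_by(.data$participant, .data$time, .data$role) %>%
    summarise(value = mean(.data[[dv]]), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "role", values_from = "value")
  if (!all(c("contra", "ipsi") %in% names(wide))) {
    abort("both 'contra' and 'ipsi' roles are required.")
  }
  incomplete <- wide$participant[!is.finite(wide$contra) |
                                   !is.finite(wide$ipsi)]
  if (length(incomplete)) {
    abort("every participant needs both roles at every time point.")
  }
  out <- wide %>%
    group_by(.data$time) %>%
    summarise(
      n = dplyr::n(),
      mean_diff = mean(.data$contra - .data$ipsi),
      bf = list(jzs_ttest_bf(.data$contra - .data$ipsi, r_scale = r_scale)),
      .groups = "drop"
    ) %>%
    mutate(t = map_dbl(.data$bf, "t"),
           bf10 = map_dbl(.data$bf, "bf"),
           exceeds = .data$bf10 > threshold) %>%
    select(-"bf")
  structure(out, threshold = threshold,
            class = c("bf_timecourse", class(out)))
}
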