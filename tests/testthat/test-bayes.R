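test_that("Cowan's K follows the capacity formula", {
  expect_equal(k_capacity(4, 0.75, 0.25), 2)
  expect_equal(k_capacity(6, 1, 0), 6)
  expect_equal(k_capacity(3, 0.4, 0.4), 0)
  expect_equal(k_capacity(c(1, 3, 6), c(1, 0.9, 0.5), c(0, 0.1, 0.5)),
               c(1, 2.4, 0))
  expect_error(k_capacity(4, 1.2, 0), "rates")
  expect_error(k_capacity(4, 0.5, -0.1), "rates")
})

test_that("JZS t-test BF matches an independent noncentral-t oracle", {
  for (n in c(5, 15, 30, 60)) {
    for (t in c(0, 1, 2, 3, 5)) {
      bf <- jzs_ttest_bf(t = t, n = n)$bf
      expect_lt(abs(bf / oracle_jzs_bf(t, n) - 1), 0.005)
      if (t == 0) expect_lt(bf, 1)
    }
  }
})

test_that("JZS BF10 is increasing in |t| and invariant to rescaling", {
  bfs <- vapply(seq(0, 6, by = 0.5),
                function(t) jzs_ttest_bf(t = t, n = 20)$bf, numeric(1))
  expect_true(all(diff(bfs) > 0))

  withr::with_seed(30, {
    x <- rnorm(12, 0.4)
    expect_equal(jzs_ttest_bf(x)$bf, jzs_ttest_bf(7.3 * x)$bf,
                 tolerance = 1e-9)
  })
  expect_error(jzs_ttest_bf(rep(1, 5)), "variance")
  expect_error(jzs_ttest_bf(1), "at least 2")
  expect_error(jzs_ttest_bf(t = 2, n = 1), "n")
})

test_that("ANOVA model space respects marginality", {
  space <- alphawaves:::anova_model_space(c("a", "b"))
  labels <- vapply(space, paste, collapse = "+", FUN.VALUE = character(1))
  expect_setequal(labels,
                  c("", "a", "b", "a+b", "a+b+a:b"))
})

test_that("a one-factor inclusion BF collapses to the pairwise model BF", {
  withr::with_seed(31, {
    cells <- tidyr::crossing(participant = 1:12, load = c(2, 4, 6))
    cells$value <- rnorm(nrow(cells)) + 0.3 * as.numeric(cells$load)
    for (m in c("bic", "quadrature")) {
      res <- rm_anova_bf(cells, "load", method = m)
      expect_equal(res$effects$bf_incl,
                   exp(res$models$log_bf[res$models$model == "load"]),
                   tolerance = 1e-9)
    }
  })
})

test_that("interaction inclusion uses matched models", {
  withr::with_seed(32, {
    cells <- tidyr::crossing(participant = 1:10, a = c("x", "y"),
                             b = c("u", "v"))
    cells$value <- rnorm(nrow(cells))
    res <- rm_anova_bf(cells, c("a", "b"), method = "quadrature")
    md <- res$models
    expect_equal(
      res$effects$bf_incl[res$effects$effect == "a:b"],
      md$post_prob[md$model == "a + b + a:b"] /
        md$post_prob[md$model == "a + b"],
      tolerance = 1e-9)
    # main effect a: models {a, a+b} vs {null, b}
    expect_equal(
      res$effects$bf_incl[res$effects$effect == "a"],
      sum(md$post_prob[md$model %in% c("a", "a + b")]) /
        sum(md$post_prob[md$model %in% c("null (participant only)", "b")]),
      tolerance = 1e-9)
  })
})

test_that("inclusion BFs detect simulated effects and respect the null", {
  withr::with_seed(33, {
    bf_one <- function(effect) {
      cells <- tidyr::crossing(participant = 1:30, load = c(2, 4, 6))
      shift <- effect * (as.numeric(factor(cells$load)) - 2) # d ~ 1 per step
      cells$value <- rnorm(nrow(cells)) + shift +
        rep(rnorm(30), each = 3)                             # participant
      tidy(rm_anova_bf(cells, "load", method = "quadrature"))$bf_incl
    }
    with_effect <- replicate(50, bf_one(1))
    expect_gte(mean(with_effect > 10), 0.9)
    under_null <- replicate(50, bf_one(0))
    expect_lt(median(under_null), 1)
  })
})

test_that("Monte Carlo and quadrature g-prior integrals agree", {
  withr::with_seed(34, {
    cells <- tidyr::crossing(participant = 1:15, load = c(2, 4, 6))
    cells$value <- rnorm(nrow(cells)) + 0.4 * as.numeric(cells$load)
    q <- tidy(rm_anova_bf(cells, "load", method = "quadrature"))
    m1 <- tidy(rm_anova_bf(cells, "load", method = "mc", seed = 1))
    m2 <- tidy(rm_anova_bf(cells, "load", method = "mc", seed = 2))
    expect_identical(
      tidy(rm_anova_bf(cells, "load", method = "mc", seed = 1)), m1)
    tol <- 6 * (m1$error + m2$error) + 1e-6
    expect_lt(abs(log(m1$bf_incl / q$bf_incl)), tol)
    expect_lt(abs(log(m1$bf_incl / m2$bf_incl)), tol)
    expect_true(is.finite(m1$error) && m1$error > 0)
  })
})

test_that("incomplete participants are dropped listwise; duplicates fail", {
  withr::with_seed(35, {
    cells <- tidyr::crossing(participant = 1:8, load = c(2, 4, 6))
    cells$value <- rnorm(nrow(cells))
    broken <- cells[-2, ]
    expect_warning(res <- rm_anova_bf(broken, "load"), "incomplete")
    expect_equal(res$n_participants, 7L)
    dup <- dplyr::bind_rows(cells, cells[1, ])
    expect_error(rm_anova_bf(dup, "load"), "duplicated")
  })
})

test_that("post hoc comparisons are symmetric and handle exact nulls", {
  withr::with_seed(36, {
    cells <- tidyr::crossing(participant = 1:10, load = c(2, 4))
    cells$value <- rnorm(nrow(cells)) + ifelse(cells$load == 4, 0.8, 0)
    ab <- posthoc_pairwise_bf(cells, "load", c(2, 4))
    ba <- posthoc_pairwise_bf(cells, "load", c(4, 2))
    expect_equal(ab$bf, ba$bf, tolerance = 1e-9)
    expect_equal(ab$mean_diff, -ba$mean_diff)
    expect_equal(ab$kind, "posthoc")

    same <- tidyr::crossing(participant = 1:6, load = c(2, 4))
    same$value <- rep(rnorm(6), each = 2)   # identical level means
    expect_lt(posthoc_pairwise_bf(same, "load", c(2, 4))$bf, 1)
    expect_error(posthoc_pairwise_bf(cells, "load", c(2, 9)), "present")
  })
})

test_that("a one-SD shift is detected by post hoc BFs in most replicates", {
  withr::with_seed(37, {
    hits <- replicate(50, {
      # participant-wise level differences drawn as N(1, 1): a one-SD shift
      cells <- tidyr::crossing(participant = 1:30, load = c(2, 4))
      base <- rnorm(30)
      cells$value <- base[cells$participant] +
        ifelse(cells$load == 4, rnorm(30, 1, 1)[cells$participant], 0)
      posthoc_pairwise_bf(cells, "load", c(4, 2))$bf > 3
    })
    expect_gte(mean(hits), 0.9)
  })
})

test_that("regression BF matches quadrature oracle and handles extremes", {
  withr::with_seed(38, {
    x <- rnorm(20)
    y <- 0.6 * x + rnorm(20)
    res <- bf_linear_regression(x, y)
    expect_lt(abs(res$bf / oracle_reg_bf(res$n, res$r2) - 1), 0.005)

    perfect <- bf_linear_regression(1:10, 2 * (1:10) + 3)
    expect_gt(perfect$bf, 100)
    expect_equal(perfect$slope, 2)

    expect_error(bf_linear_regression(rep(1, 5), rnorm(5)), "constant")
    expect_error(bf_linear_regression(1:2, 1:2), "pairs")
  })
})

test_that("slope extraction is exact on linear per-participant data", {
  cells <- tidyr::crossing(participant = 1:5, load = c(2, 4, 6))
  slopes_true <- seq(-1, 1, length.out = 5)
  cells$value <- slopes_true[cells$participant] * cells$load +
    cells$participant
  got <- fit_slopes(cells, "load")
  expect_equal(got$slope, slopes_true)
})

test_that("null regressions favour the null across replicates", {
  withr::with_seed(39, {
    bfs <- replicate(20, bf_linear_regression(rnorm(76), rnorm(76))$bf)
    expect_lt(median(bfs), 1)
  })
})

test_that("timecourse BFs flag evidence per window and validate input", {
  withr::with_seed(40, {
    df <- tidyr::crossing(participant = 1:14, time = seq(0, 0.9, by = 0.1),
                          role = c("contra", "ipsi"))
    df$power_db <- rnorm(nrow(df)) +
      ifelse(df$role == "contra" & df$time >= 0.5, 1.5, 0)
    out <- timecourse_bf(df)
    expect_equal(nrow(out), 10L)
    expect_true(all(out$exceeds == (out$bf10 > 3)))
    expect_gt(mean(out$bf10[out$time >= 0.5]),
              mean(out$bf10[out$time < 0.5]))

    single <- dplyr::filter(df, participant == 1)
    expect_error(timecourse_bf(single), "at least 2")
    expect_error(timecourse_bf(dplyr::filter(df, role == "contra")),
                 "ipsi")
    expect_error(timecourse_bf(dplyr::select(df, -time)), "time")
  })
})

test_that("tidy and glance summarize BF objects", {
  withr::with_seed(41, {
    cells <- tidyr::crossing(participant = 1:8, a = c("x", "y"),
                             b = c("u", "v"))
    cells$value <- rnorm(nrow(cells))
    res <- rm_anova_bf(cells, c("a", "b"))
    td <- tidy(res)
    expect_setequal(td$effect, c("a", "b", "a:b"))
    expect_true(all(td$bf_incl > 0))
    gl <- glance(res)
    expect_equal(gl$n_models, 5L)
    tt <- tidy(jzs_ttest_bf(t = 2, n = 10))
    expect_equal(tt$kind, "t_test")
  })
})
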