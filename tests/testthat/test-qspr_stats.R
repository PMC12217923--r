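test_that("pearson_correlation handles exact lines and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_error(pearson_correlation(x, rep(3, 5)), "zero variance")
  expect_error(pearson_correlation(x[1:2], x[1:2]), "at least 3")
  expect_error(pearson_correlation(x, x[1:3]), "equal length")
})

test_that("f_upper_tail_p matches the regularized incomplete beta form", {
  expect_equal(f_upper_tail_p(0, 1, 13), 1)
  # independent route: P(F > f) = I_{df2/(df2 + df1 f)}(df2/2, df1/2)
  beta_tail <- function(f, df1, df2) {
    stats::pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
  }
  for (f in c(0.1, 1, 4.6, 6.8854, 20.0359, 49.9422)) {
    expect_equal(f_upper_tail_p(f, 1, 13), beta_tail(f, 1, 13))
  }
  expect_equal(round(f_upper_tail_p(6.8854, 1, 13), 4), 0.0210)
  expect_equal(round(f_upper_tail_p(20.0359, 1, 13), 4), 0.0006)
  # monotone decreasing in f
  expect_true(all(diff(f_upper_tail_p(seq(0, 30, 0.5), 1, 13)) < 0))
})

test_that("fit_simple_regression recovers an exact line", {
  ti <- c(1, 2, 3, 4, 7)
  fit <- fit_simple_regression(ti, 3 + 2 * ti)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$see, 0)
  expect_equal(fit$p_value, 0)
  expect_true(fit$significant)
})

test_that("closed-form OLS equals a numeric least-squares minimizer", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    ti <- rnorm(n, 100, 20)
    p <- 5 + 0.3 * ti + rnorm(n, 0, 4)
    fit <- fit_simple_regression(ti, p)
    sse <- function(th) sum((p - th[1] - th[2] * ti)^2)
    num <- stats::optim(c(0, 0), sse, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(fit$intercept, num$par[1], tolerance = 1e-6)
    expect_equal(fit$slope, num$par[2], tolerance = 1e-6)
  }
})

test_that("fit diagnostics satisfy their defining identities", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    ti <- rnorm(n, 50, 10)
    p <- 2 - 0.5 * ti + rnorm(n, 0, 3)
    fit <- fit_simple_regression(ti, p)
    expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)
    expect_equal(fit$f_stat,
                 fit$r_squared * (n - 2) / (1 - fit$r_squared),
                 tolerance = 1e-9)
    expect_identical(fit$significant, fit$p_value < 0.05)
    res <- p - fit$intercept - fit$slope * ti
    expect_equal(fit$see, sqrt(sum(res^2) / (n - 2)))
  }
})

test_that("rescaling the index rescales only the slope", {
  set.seed(31)
  ti <- rnorm(20, 1000, 150)
  p <- 10 + 0.02 * ti + rnorm(20, 0, 1)
  f1 <- fit_simple_regression(ti, p)
  f2 <- fit_simple_regression(ti * 250, p)
  expect_equal(f2$slope, f1$slope / 250)
  expect_equal(f2$intercept, f1$intercept)
  expect_equal(f2$pearson_r, f1$pearson_r)
  expect_equal(f2$r_squared, f1$r_squared)
  expect_equal(f2$f_stat, f1$f_stat)
  expect_equal(f2$p_value, f1$p_value)
  expect_equal(f2$see, f1$see)
})

test_that("degenerate predictors are rejected", {
  expect_error(fit_simple_regression(rep(4, 6), rnorm(6)), "zero variance")
  expect_error(fit_simple_regression(1:2, 1:2), "at least 3")
})

test_that("the report propagates per-cell failures without aborting", {
  idx <- data.frame(drug = letters[1:5], good = c(1, 3, 2, 5, 4),
                    flat = rep(7, 5))
  prop <- data.frame(drug = letters[1:5], boiling_point = c(2, 6, 4, 10, 8))
  rep <- suppressWarnings(qspr_report_from_tables(idx, prop))
  expect_equal(rep$correlation["good", "boiling_point"], 1)
  expect_true(is.na(rep$correlation["flat", "boiling_point"]))
  expect_null(rep$fits[["flat"]][["boiling_point"]])
})

test_that("the report rejects mismatched drug names, naming them", {
  idx <- data.frame(drug = c("a", "b", "c"), w = c(1, 2, 3))
  prop <- data.frame(drug = c("a", "b", "x"), boiling_point = c(1, 2, 3))
  expect_error(qspr_report_from_tables(idx, prop), "unmatched: c, x")
})

test_that("small reports warn about low power instead of failing", {
  idx <- data.frame(drug = c("a", "b", "c"), w = c(1, 2, 4))
  prop <- data.frame(drug = c("a", "b", "c"), boiling_point = c(3, 5, 10))
  expect_warning(rep <- qspr_report_from_tables(idx, prop), "low.*power")
  expect_equal(rep$n, 3L)
  expect_false(is.na(rep$correlation["w", "boiling_point"]))
})

test_that("report rows align drugs before fitting", {
  idx <- data.frame(drug = c("a", "b", "c", "d"), w = c(1, 2, 3, 4))
  prop <- data.frame(drug = c("d", "c", "b", "a"),
                     boiling_point = c(8, 6, 4, 2))
  rep <- suppressWarnings(qspr_report_from_tables(idx, prop))
  expect_equal(rep$correlation["w", "boiling_point"], 1)
})
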