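test_that("a noiseless linear relation is recovered exactly", {
  x <- c(1, 2, 3, 5, 8, 13)
  fit <- qspr_fit(x, 2 * x, family = "linear")
  expect_equal(fit$A, 0, tolerance = 1e-9)
  expect_equal(fit$b, 2, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("F-test p-values match the regularized incomplete-beta oracle", {
  expect_equal(f_pvalue(0, 1, 13), 1)
  expect_equal(f_pvalue(1, 1, 1), 0.5)     # symmetric point of F(1,1)
  expect_lt(f_pvalue(249.667, 1, 13), 1e-8)
  # oracle: upper tail of F equals I_{df2/(df2 + df1 F)}(df2/2, df1/2)
  for (F in c(0.3, 1.7, 4, 25)) {
    for (dfs in list(c(1, 13), c(2, 12), c(3, 7))) {
      oracle <- stats::pbeta(dfs[2] / (dfs[2] + dfs[1] * F),
                             dfs[2] / 2, dfs[1] / 2)
      expect_equal(f_pvalue(F, dfs[1], dfs[2]), oracle, tolerance = 1e-12)
    }
  }
  expect_error(f_pvalue(1, 0, 5), regexp = "degrees of freedom")
  expect_error(f_pvalue(-1, 1, 5))
})

test_that("coefficients agree with a normal-equations solve on random instances", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    x <- runif(n, 1, 50)
    y <- 3 + 0.5 * x + rnorm(n)
    fam <- sample(c("linear", "quadratic", "logarithmic"), 1)
    fit <- qspr_fit(x, y, family = fam)
    z <- if (fam == "logarithmic") log(x) else x
    X <- if (fam == "quadratic") cbind(1, z, z^2) else cbind(1, z)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$A, beta[1], tolerance = 1e-9)
    expect_equal(fit$b, beta[2], tolerance = 1e-9)
    if (fam == "quadratic") expect_equal(fit$c, beta[3], tolerance = 1e-9)
    # r, r2, F are mutually consistent
    k <- fit$df1
    expect_equal(fit$F, (fit$r2 / k) / ((1 - fit$r2) / fit$df2),
                 tolerance = 1e-10)
    expect_equal(abs(fit$r), sqrt(fit$r2), tolerance = 1e-12)
  }
})

test_that("quadratic fits on linear data reduce to the linear coefficients", {
  set.seed(4)
  x <- runif(12, 1, 30)
  y <- 5 + 2 * x
  quad <- qspr_fit(x, y, family = "quadratic")
  expect_equal(quad$A, 5, tolerance = 1e-6)
  expect_equal(quad$b, 2, tolerance = 1e-6)
  expect_equal(quad$c, 0, tolerance = 1e-8)
})

test_that("fitted curves pass through the mean point and predict sensibly", {
  d <- qspr_data("published")
  for (fam in c("linear", "logarithmic")) {
    fit <- qspr(MW ~ SDD, d, family = fam)
    xbar_scale <- if (fam == "logarithmic") exp(mean(log(d$SDD))) else mean(d$SDD)
    expect_equal(predict(fit, x = xbar_scale), mean(d$MW), tolerance = 1e-9)
  }
  fit <- qspr(MW ~ SDD, d, family = "linear")
  # evaluating near the thalidomide SDD value lands near its printed equation
  expect_equal(predict(fit, x = 48.3333), 265.2, tolerance = 0.01)
  expect_equal(predict(fit, newdata = data.frame(SDD = 48.3333)),
               predict(fit, x = 48.3333))
  expect_error(predict(qspr(MW ~ SDD, d, family = "logarithmic"), x = -1),
               class = "qspr_domain_error")
})

test_that("condition diagnostics separate benign and pathological designs", {
  x <- seq(1, 100, length.out = 15)
  expect_true(condition_check(cbind(1, x))$pass)

  big <- x * 1e50
  cc <- condition_check(cbind(1, big, big^2))
  expect_false(cc$pass)
  expect_gt(cc$condition, 1e8)

  scaled <- cbind(1, scale(big), scale(big^2))
  expect_true(condition_check(scaled)$pass)
})

test_that("exponential-index designs degenerate rather than fit silently", {
  inp <- regression_input_table("published")
  expect_error(
    qspr_fit(inp$indices$EPi2, inp$properties$MW, family = "quadratic"),
    class = "qspr_degenerate_error")
  err <- tryCatch(
    qspr_fit(inp$indices$EPi2, inp$properties$MW, family = "quadratic"),
    error = identity)
  expect_true(is.finite(err$condition_number) || is.infinite(err$condition_number))
  expect_match(conditionMessage(err), "condition")

  tbl <- qspr_table("published")
  expect_equal(nrow(tbl), 108L)
  dg <- tbl[tbl$degenerate, ]
  expect_true(all(dg$Family == "quadratic"))
  expect_setequal(unique(dg$Index), c("EPi1", "EPi2"))
  expect_true(all(nzchar(dg$note)))
  # but their logarithmic and linear rows fit
  expect_false(any(tbl$degenerate[tbl$Family == "logarithmic"]))
})

test_that("domain and input validation errors are raised", {
  expect_error(qspr_fit(c(-1, 2, 3, 4), 1:4, family = "logarithmic"),
               class = "qspr_domain_error")
  expect_error(qspr_fit(1:3, 1:2, family = "linear"), regexp = "length")
  expect_error(qspr_fit(1:3, 1:3, family = "quadratic"),
               regexp = "at least")
  d <- qspr_data("published")
  expect_error(qspr(MW ~ SDD + GA, d), regexp = "one predictor")
})

test_that("model methods behave like standard fitted-model objects", {
  d <- qspr_data("published")
  fit <- qspr(MW ~ ABC_R, d, family = "linear")
  expect_named(coef(fit), c("A", "b"))
  expect_length(residuals(fit), 15L)
  expect_equal(fitted(fit) + residuals(fit), d$MW)

  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(15L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 2))

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  expect_output(print(summary(fit)), "mean point")
})

test_that("paper-precision formatting rounds to three decimals", {
  tbl <- qspr_table("published", families = "linear")
  fmt <- format_qspr_table(tbl)
  mw <- fmt[fmt$Index == "SDD" & fmt$Property == "MW", ]
  expect_equal(mw$b, 4.962)
  expect_equal(mw$P, "0.000")
})
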