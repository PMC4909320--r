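test_that("Pareto sampling respects its support and seed", {
  x <- sample_powerlaw_areas(2.5, 0.04, 500, seed = 3)
  expect_true(all(x >= 0.04))
  expect_identical(x, sample_powerlaw_areas(2.5, 0.04, 500, seed = 3))
  expect_false(identical(x, sample_powerlaw_areas(2.5, 0.04, 500, seed = 4)))
  expect_error(sample_powerlaw_areas(1, 0.04, 10), "alpha")
  expect_error(sample_powerlaw_areas(2, 0.04, 0))
})

test_that("the Hill estimator recovers a known exponent", {
  x <- sample_powerlaw_areas(alpha = 2.0, xmin = 0.01, n = 1e4, seed = 1)
  fit <- fit_powerlaw(x, xmin = 0.01)
  expect_gt(fit$alpha, 1.9)
  expect_lt(fit$alpha, 2.1)
  expect_equal(fit$se_alpha, (fit$alpha - 1) / sqrt(1e4))
  expect_equal(fit$n_tail, 1e4)
  # closed-form Hill estimate computed directly from its formula
  expect_equal(fit$alpha, 1 + length(x) / sum(log(x / 0.01)))
})

test_that("fits are refused on degenerate or undersized samples", {
  expect_error(fit_powerlaw(rep(2.5, 40)), class = "rootchamber_refusal")
  expect_error(fit_powerlaw(sample_powerlaw_areas(2, 1, 5, seed = 1), xmin = 1),
               class = "rootchamber_refusal")
  expect_error(fit_powerlaw(1), class = "rootchamber_refusal")
})

test_that("exponent recovery stays within 3 standard errors", {
  hits <- 0
  n_sim <- 120
  for (s in seq_len(n_sim)) {
    x <- sample_powerlaw_areas(alpha = 1.8, xmin = 0.02, n = 400, seed = 5000 + s)
    fit <- fit_powerlaw(x, xmin = 0.02)
    if (abs(fit$alpha - 1.8) <= 3 * fit$se_alpha) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("the OLS log-binned slope agrees with the MLE on large samples", {
  x <- sample_powerlaw_areas(alpha = 2.2, xmin = 0.01, n = 2e4, seed = 9)
  mle <- fit_powerlaw(x, xmin = 0.01)
  ols <- fit_powerlaw(x, method = "ols", xmin = 0.01, bins_per_decade = 6)
  expect_equal(ols$alpha, mle$alpha, tolerance = 0.15)
})

test_that("KS-based xmin selection finds the tail of a mixed sample", {
  # uniform body below 0.1 plus a Pareto tail starting at 0.1
  body <- withr::with_seed(2, runif(400, 0.01, 0.1))
  tail <- sample_powerlaw_areas(alpha = 2.5, xmin = 0.1, n = 600, seed = 2)
  fit <- fit_powerlaw(c(body, tail))
  expect_gt(fit$xmin, 0.05)
  expect_equal(fit$alpha, 2.5, tolerance = 0.3)
})

test_that("a Pareto fit to exponential data has visibly worse gof", {
  worse <- 0
  for (s in 1:40) {
    pareto <- sample_powerlaw_areas(2, 0.01, 300, seed = 100 + s)
    expo <- withr::with_seed(200 + s, 0.01 + stats::rexp(300, rate = 50))
    g_p <- fit_powerlaw(pareto, xmin = 0.01)$gof
    g_e <- fit_powerlaw(expo, xmin = 0.01)$gof
    if (g_e > g_p) worse <- worse + 1
  }
  expect_gte(worse / 40, 0.95)
})

test_that("truncation sensitivity quantifies the upward bias of a clipped tail", {
  x <- sample_powerlaw_areas(2.0, 0.01, 2000, seed = 21)
  same <- truncation_sensitivity(x, 0, xmin = 0.01)
  expect_equal(same$alpha_shift, 0)
  expect_equal(same$truncated$alpha, same$full$alpha)

  ts <- truncation_sensitivity(x, 0.10, xmin = 0.01)
  expect_gt(ts$alpha_shift, 0) # removing the largest areas steepens the fit
  # direct refit oracle: Hill formula on the kept order statistics
  kept <- sort(x)[1:1800]
  expect_equal(ts$truncated$alpha, 1 + length(kept) / sum(log(kept / 0.01)))

  # heavy truncation leaving a tail below the minimum is refused
  small <- sample_powerlaw_areas(2, 0.01, 15, seed = 3)
  expect_error(truncation_sensitivity(small, 0.49, xmin = 0.01),
               class = "rootchamber_refusal")
  expect_error(truncation_sensitivity(x, 0.5))
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- fit_powerlaw(sample_powerlaw_areas(2, 0.01, 200, seed = 1), xmin = 0.01)
  td <- tidy(fit)
  expect_equal(td$term, "alpha")
  gl <- glance(fit)
  expect_named(gl, c("alpha", "se_alpha", "xmin", "n_tail", "gof", "method"))
  ts <- truncation_sensitivity(sample_powerlaw_areas(2, 0.01, 200, seed = 1),
                               0.1, xmin = 0.01)
  expect_equal(tidy(ts)$sample, c("full", "truncated"))
})
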