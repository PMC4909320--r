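test_that("group summaries report t-based confidence intervals", {
  df <- tibble::tibble(
    rh = rep(c("55%", "95%"), each = 4),
    span = c(rep(2, 4), c(3, 4, 5, 6))
  )
  s <- summarize_by_group(df, "rh")
  expect_equal(nrow(s), 2)
  z <- s[s$group == "55%", ]
  expect_equal(z$ci_lo, z$mean) # identical values: zero-width CI
  expect_equal(z$ci_hi, z$mean)
  nz <- s[s$group == "95%", ]
  half <- qt(0.975, 3) * sd(c(3, 4, 5, 6)) / 2
  expect_equal(nz$ci_hi - nz$mean, half)

  expect_warning(
    s1 <- summarize_by_group(tibble::tibble(g = c("a", "a", "b"), v = 1:3), "g"),
    "singleton"
  )
  expect_true(is.na(s1$ci_lo[s1$group == "b"]))
})

test_that("confidence intervals achieve nominal coverage", {
  cover <- 0
  n_rep <- 400
  for (s in seq_len(n_rep)) {
    x <- withr::with_seed(s, rnorm(15, mean = 1, sd = 1))
    sm <- summarize_by_group(tibble::tibble(g = "a", v = x), "g")
    if (sm$ci_lo <= 1 && 1 <= sm$ci_hi) cover <- cover + 1
  }
  expect_gt(cover / n_rep, 0.91)
  expect_lt(cover / n_rep, 0.99)
})

test_that("two-group tests behave on degenerate and identical inputs", {
  expect_equal(two_group_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  a <- c(1.2, 2.4, 3.1, 0.8)
  welch <- two_group_test(a, a)
  expect_equal(welch$estimate, 0)
  expect_gte(welch$p_value, 0.999)
  perm <- two_group_test(a, a, method = "permutation", n_perm = 199)
  expect_equal(perm$p_value, 1)
  expect_error(two_group_test(1, c(1, 2)))
})

test_that("Welch test power tracks the analytic t-test power", {
  n_rep <- 800
  rej <- 0
  for (s in seq_len(n_rep)) {
    g <- withr::with_seed(20000 + s, list(rnorm(15), rnorm(15, mean = 1)))
    if (two_group_test(g[[1]], g[[2]])$p_value <= 0.05) rej <- rej + 1
  }
  analytic <- stats::power.t.test(n = 15, delta = 1, sd = 1)$power
  expect_equal(rej / n_rep, analytic, tolerance = 0.05 / analytic)
})

test_that("pearson_r matches the two-pass textbook formula and affine invariance", {
  x <- withr::with_seed(1, rnorm(50))
  y <- withr::with_seed(2, x + rnorm(50, sd = 0.3))
  textbook <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), textbook, tolerance = 1e-12)
  expect_equal(pearson_r(2 * x + 1, y), pearson_r(x, y))
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 50)), class = "rootchamber_refusal")
  expect_error(pearson_r(1:2, 2:3))
})

test_that("heterogeneity CV is the percent SD over the mean and scale-free", {
  expect_equal(heterogeneity_cv(tibble::tibble(nutrient = "p",
                                               concentration_mg_per_L = rep(7, 5))), 0)
  two <- tibble::tibble(nutrient = "p", concentration_mg_per_L = c(90, 110))
  expect_equal(heterogeneity_cv(two), 100 * sd(c(90, 110)) / 100)
  expect_equal(round(heterogeneity_cv(two), 2), 14.14)
  scaled <- dplyr::mutate(two, concentration_mg_per_L = concentration_mg_per_L * 17)
  expect_equal(heterogeneity_cv(scaled), heterogeneity_cv(two))
  expect_error(heterogeneity_cv(two[1, ]))
})

test_that("the near/far deviation test is exact on mirrored tables", {
  conc <- c(18, 19, 20, 21)
  tab <- tibble::tibble(
    distance_to_root_mm = c(1, 2, 3, 4, 6, 7, 8, 9),
    nutrient = "phosphorus",
    concentration_mg_per_L = c(conc, conc)
  )
  r <- near_far_deviation_test(tab, n_perm = 99)
  expect_equal(r$estimate, 0)
  expect_equal(r$mean_dev_near, -r$mean_dev_far) # deviations sum to zero
  expect_gte(r$p_welch, 0.999)

  oneside <- dplyr::mutate(tab, distance_to_root_mm = 1)
  expect_error(near_far_deviation_test(oneside), class = "rootchamber_refusal")
})

test_that("an injected depletion is detected with high power", {
  rej <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    tab <- generate_spot_table(spot_spec(seed = 40000 + s, n_spots = 48,
                                         near_effect = -0.5))
    r <- near_far_deviation_test(tab, n_perm = 99, seed = s)
    if (r$p_welch <= 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.9)
})

test_that("Holm adjustment is applied across nutrients", {
  spec <- spot_spec(seed = 9, n_spots = 30,
                    mean_concentration = c(a = 10, b = 100, c = 1000))
  r <- near_far_deviation_test(generate_spot_table(spec), n_perm = 99)
  expect_equal(nrow(r), 3)
  expect_true(all(r$p_welch_holm >= r$p_welch))
})
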