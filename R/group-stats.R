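#' Group summaries with t-based 95% confidence intervals
#'
#' Mean and Student-t 95% CI of each phenotype within each group (e.g. the
#' 55/75/95 %RH growth conditions). Singleton groups get a mean but no CI,
#' with a warning.
#'
#' @param records Data frame of per-plant records (one row per plant).
#' @param group Name of the grouping column (string).
#' @param phenotypes Character vector of numeric columns to summarize;
#'   default: every numeric column except the grouping column.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with columns `group`, `phenotype`, `n`, `mean`, `ci_lo`,
#'   `ci_hi`.
#' @export
summarize_by_group <- function(records, group, phenotypes = NULL,
                               conf_level = 0.95) {
  records <- as_tibble(records)
  if (!group %in% names(records)) abort(paste0("no column `", group, "`."))
  if (is.null(phenotypes)) {
    phenotypes <- setdiff(names(records)[vapply(records, is.numeric, logical(1))], group)
  }
  long <- tidyr::pivot_longer(
    dplyr::select(records, dplyr::all_of(c(group, phenotypes))),
    cols = dplyr::all_of(phenotypes), names_to = "phenotype", values_to = "value"
  )
  out <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(group = .data[[group]], .data$phenotype) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean = mean(.data$value),
      half = ifelse(.data$n >= 2,
                    qt(1 - (1 - conf_level) / 2, .data$n - 1) *
                      sd(.data$value) / sqrt(.data$n),
                    NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_lo = .data$mean - .data$half,
                  ci_hi = .data$mean + .data$half) |>
    dplyr::select(-"half")
  if (any(out$n < 2)) warn("singleton group(s): no confidence interval computed.")
  out
}

#' Two-group comparison of a phenotype
#'
#' Welch's unequal-variance t-test by default — safe when group variances
#' differ — with a seeded mean-difference permutation test as a
#' distribution-free alternative. When both groups are constant and equal
#' the difference is exactly zero and p = 1 by convention.
#'
#' @param a,b Numeric vectors of the two groups.
#' @param method `"welch"` or `"permutation"`.
#' @param n_perm Permutations for `method = "permutation"`.
#' @param seed Seed for the permutation null.
#' @return Tibble with `estimate` (mean of `a` minus mean of `b`),
#'   `statistic`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
two_group_test <- function(a, b, method = c("welch", "permutation"),
                           n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values.")
  est <- mean(a) - mean(b)
  if (var(a) == 0 && var(b) == 0 && est == 0) {
    return(tibble(estimate = 0, statistic = 0, p_value = 1,
                  method = method, n_a = length(a), n_b = length(b)))
  }
  if (method == "welch") {
    tt <- t.test(a, b)
    tibble(estimate = est, statistic = unname(tt$statistic),
           p_value = tt$p.value, method = "welch",
           n_a = length(a), n_b = length(b))
  } else {
    z <- c(a, b); n <- length(a)
    exceed <- withr::with_seed(seed, {
      count <- 0L
      for (i in seq_len(n_perm)) {
        zp <- sample(z)
        d <- mean(zp[seq_len(n)]) - mean(zp[-seq_len(n)])
        if (abs(d) >= abs(est) - 1e-12) count <- count + 1L
      }
      count
    })
    tibble(estimate = est, statistic = est,
           p_value = (1 + exceed) / (n_perm + 1), method = "permutation",
           n_a = length(a), n_b = length(b))
  }
}

#' Pearson product-moment correlation
#'
#' Validated wrapper around the standard product-moment coefficient, used
#' e.g. for the span-biomass calibration claim (image-derived span is an
#' excellent linear proxy for destructively measured root biomass).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs.")
  if (var(x) == 0 || var(y) == 0) {
    abort("correlation undefined: zero variance.", class = "rootchamber_refusal")
  }
  stats::cor(x, y, method = "pearson")
}

#' Point-to-point nutrient concentration heterogeneity
#'
#' The coefficient of variation (one standard deviation as a percentage of
#' the mean) of spot concentrations across the growth sheet, per nutrient.
#'
#' @param table Spot table with `concentration_mg_per_L` and `nutrient`
#'   columns (see [generate_spot_table()]).
#' @param nutrient Optional nutrient label to filter on.
#' @return CV in percent.
#' @export
heterogeneity_cv <- function(table, nutrient = NULL) {
  table <- as_tibble(table)
  if (!is.null(nutrient)) table <- dplyr::filter(table, .data$nutrient == !!nutrient)
  x <- table$concentration_mg_per_L
  if (length(x) < 2) abort("need at least 2 spots to estimate heterogeneity.")
  100 * sd(x) / mean(x)
}

#' Near-root versus far-root nutrient deviation test
#'
#' Tests whether nutrient concentrations near the root (distance below
#' `cutoff`) deviate from the sheet average differently than far spots —
#' i.e. whether root uptake depletes (or evaporation enriches) its
#' immediate neighbourhood. Per nutrient, each spot's deviation from the
#' per-sheet grand mean is computed, and the mean deviation of the near
#' group is compared with the far group by Welch's t-test and by a seeded
#' permutation test; Holm-adjusted p-values are reported alongside the raw
#' ones when several nutrients are tested.
#'
#' @param table Spot table with `distance_to_root_mm`, `nutrient` and
#'   `concentration_mg_per_L` columns.
#' @param cutoff Near/far threshold in mm (default 5).
#' @param n_perm Permutations (default 10000).
#' @param seed Seed for the permutation null.
#' @return Tibble with one row per nutrient: group sizes, mean deviations
#'   with 95% CIs, `p_welch`, `p_perm`, and Holm-adjusted columns.
#' @export
near_far_deviation_test <- function(table, cutoff = 5, n_perm = 10000, seed = 1) {
  table <- as_tibble(table)
  needed <- c("distance_to_root_mm", "nutrient", "concentration_mg_per_L")
  if (!all(needed %in% names(table))) {
    abort(paste0("spot table needs columns: ", paste(needed, collapse = ", ")))
  }
  out <- purrr::map_dfr(split(table, table$nutrient), function(tb) {
    dev <- tb$concentration_mg_per_L - mean(tb$concentration_mg_per_L)
    near <- dev[tb$distance_to_root_mm < cutoff]
    far <- dev[tb$distance_to_root_mm >= cutoff]
    if (length(near) < 2 || length(far) < 2) {
      abort(sprintf("nutrient %s: need >= 2 spots on each side of the %g mm cutoff.",
                    tb$nutrient[1], cutoff),
            class = "rootchamber_refusal")
    }
    ci <- function(v) {
      if (length(v) < 2) return(c(NA_real_, NA_real_))
      h <- qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
      mean(v) + c(-h, h)
    }
    welch <- two_group_test(near, far, method = "welch")
    perm <- two_group_test(near, far, method = "permutation",
                           n_perm = n_perm, seed = seed)
    tibble(
      nutrient = tb$nutrient[1], n_near = length(near), n_far = length(far),
      mean_dev_near = mean(near), ci_lo_near = ci(near)[1], ci_hi_near = ci(near)[2],
      mean_dev_far = mean(far), ci_lo_far = ci(far)[1], ci_hi_far = ci(far)[2],
      estimate = welch$estimate, p_welch = welch$p_value, p_perm = perm$p_value,
      seed = seed
    )
  })
  out$p_welch_holm <- stats::p.adjust(out$p_welch, method = "holm")
  out$p_perm_holm <- stats::p.adjust(out$p_perm, method = "holm")
  out
}
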