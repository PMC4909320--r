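#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical CDFs, evaluated
#' correctly in the presence of ties (the CDFs are compared only after all
#' observations sharing a value have been processed).
#'
#' @param x,y Numeric samples.
#' @return The KS statistic in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  o <- order(c(x, y))
  lab <- c(rep(TRUE, length(x)), rep(FALSE, length(y)))[o]
  z <- c(x, y)[o]
  ks_from_ordered(lab, length(x), length(y), c(diff(z) > 0, TRUE))
}

ks_from_ordered <- function(lab_sorted, n, m, keep) {
  cx <- cumsum(lab_sorted) / n
  cy <- cumsum(!lab_sorted) / m
  max(abs(cx - cy)[keep])
}

#' Seeded permutation Kolmogorov-Smirnov test
#'
#' Two-sample KS test with a label-permutation null: sample labels are
#' shuffled `n_perm` times and the p-value is the add-one permutation
#' p-value `(1 + #{D_perm >= D_obs}) / (n_perm + 1)`, which is exact-level
#' by construction and free of the large-sample approximation of the
#' classical KS p-value.
#'
#' @param x,y Numeric samples.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed; the global RNG state is untouched.
#' @return Tibble with `statistic`, `p_value`, `n_perm`, `seed`.
#' @export
ks_permutation_test <- function(x, y, n_perm = 10000, seed = 1) {
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) abort("both samples need at least 2 values.")
  z <- c(x, y)
  o <- order(z)
  keep <- c(diff(z[o]) > 0, TRUE)
  lab <- c(rep(TRUE, n), rep(FALSE, m))
  obs <- ks_from_ordered(lab[o], n, m, keep)
  exceed <- withr::with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      d <- ks_from_ordered(sample(lab)[o], n, m, keep)
      if (d >= obs - 1e-12) count <- count + 1L
    }
    count
  })
  tibble(statistic = obs, p_value = (1 + exceed) / (n_perm + 1),
         n_perm = n_perm, seed = seed)
}

#' Compare void-area distributions across environmental conditions
#'
#' Tests whether the size distribution of root-enclosed areas is robust to
#' the growth condition (e.g. 55/75/95 %RH): for every pair of conditions it
#' reports the two-sample KS statistic with a seeded permutation p-value,
#' and for every condition a power-law tail fit, with pairwise exponent
#' differences and their propagated standard errors.
#'
#' @param sets Named list of numeric area vectors (cm2), one per condition,
#'   or a data frame with `condition` and `area_cm2` columns (areas pooled
#'   over the plants of each condition).
#' @param n_perm Permutations for each pairwise test.
#' @param seed Integer seed recorded in the report.
#' @param xmin Passed to [fit_powerlaw()] (default: KS-selected per
#'   condition).
#' @param min_tail Minimum areas per condition (default 10); smaller groups
#'   are refused.
#' @return List of class `void_comparison`: `pairwise` (tibble: conditions,
#'   `ks_stat`, `p_perm`, `alpha_diff`, `se_diff`), `fits` (named list of
#'   `powerlaw_fit`), `seed`, `n_perm`. [tidy()] returns the pairwise table.
#' @export
compare_area_distributions <- function(sets, n_perm = 10000, seed = 1,
                                       xmin = NULL, min_tail = 10) {
  if (is.data.frame(sets)) {
    if (!all(c("condition", "area_cm2") %in% names(sets))) {
      abort("data frame needs `condition` and `area_cm2` columns.")
    }
    sets <- split(sets$area_cm2, sets$condition)
  }
  if (length(sets) < 2) abort("need at least 2 conditions.")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("conditions must be named.")
  }
  sizes <- lengths(sets)
  if (any(sizes < min_tail)) {
    abort(sprintf("undersized groups (< %d areas): %s", min_tail,
                  paste(names(sets)[sizes < min_tail], collapse = ", ")),
          class = "rootchamber_refusal")
  }
  fits <- purrr::map(sets, fit_powerlaw, xmin = xmin, min_tail = min_tail)
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(seq_along(pairs), function(i) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    ks <- ks_permutation_test(sets[[a]], sets[[b]], n_perm = n_perm,
                              seed = seed + i - 1L)
    tibble(
      condition_a = a, condition_b = b,
      n_a = length(sets[[a]]), n_b = length(sets[[b]]),
      ks_stat = ks$statistic, p_perm = ks$p_value,
      alpha_a = fits[[a]]$alpha, alpha_b = fits[[b]]$alpha,
      alpha_diff = fits[[a]]$alpha - fits[[b]]$alpha,
      se_diff = sqrt(fits[[a]]$se_alpha^2 + fits[[b]]$se_alpha^2)
    )
  })
  structure(list(pairwise = pairwise, fits = fits, seed = seed, n_perm = n_perm),
            class = "void_comparison")
}

#' @export
print.void_comparison <- function(x, ...) {
  cat(sprintf("<void_comparison> %d conditions, %d permutations (seed %d)\n",
              length(x$fits), x$n_perm, x$seed))
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_area_distributions
#' @param x A `void_comparison`.
#' @param ... Unused.
#' @export
tidy.void_comparison <- function(x, ...) x$pairwise
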