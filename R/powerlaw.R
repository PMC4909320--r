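#' Fit a power-law tail to void areas
#'
#' Fits `p(x) ~ x^-alpha` for `x >= xmin`. The default method is the
#' continuous maximum-likelihood (Hill) estimator
#' `alpha = 1 + n / sum(log(x_i / xmin))` with standard error
#' `(alpha - 1) / sqrt(n)`; the alternative `"ols"` method regresses log
#' density of the log-binned histogram on log bin centre, which mirrors the
#' visual straight-line reading of a log-log plot but is statistically
#' inferior. Goodness of fit is the Kolmogorov-Smirnov distance between the
#' empirical tail and the fitted Pareto CDF.
#'
#' @param areas Areas in cm2 (`void_area_set`, data frame with `area_cm2`,
#'   or numeric vector).
#' @param method `"mle"` (default) or `"ols"`.
#' @param xmin Lower cutoff of the tail in cm2. `NULL` (default) selects
#'   `xmin` over candidate data values by minimizing the KS distance, the
#'   standard data-driven cutoff choice.
#' @param min_tail Minimum tail size; the fit is refused below it
#'   (default 10).
#' @param bins_per_decade Binning for the `"ols"` method.
#' @return An object of class `powerlaw_fit`: list with `alpha`, `xmin`,
#'   `se_alpha`, `n_tail`, `gof` (KS distance), and `method`. Use [tidy()]
#'   or [glance()] for tibble output.
#' @examples
#' x <- sample_powerlaw_areas(alpha = 2, xmin = 0.01, n = 500, seed = 1)
#' fit_powerlaw(x, xmin = 0.01)
#' @export
fit_powerlaw <- function(areas, method = c("mle", "ols"), xmin = NULL,
                         min_tail = 10, bins_per_decade = 5) {
  method <- match.arg(method)
  x <- as_area_vector(areas)
  if (length(unique(x)) < 2) {
    abort("degenerate sample: a single unique value cannot constrain a power law.",
          class = "rootchamber_refusal")
  }
  if (is.null(xmin)) {
    xmin <- select_xmin_ks(x, min_tail = min_tail)
  }
  tail_x <- x[x >= xmin]
  n <- length(tail_x)
  if (n < min_tail) {
    abort(sprintf("insufficient tail: %d values >= xmin, need %d.", n, min_tail),
          class = "rootchamber_refusal")
  }
  if (method == "mle") {
    alpha <- 1 + n / sum(log(tail_x / xmin))
    se <- (alpha - 1) / sqrt(n)
  } else {
    b <- log_binned_frequency(tail_x, bins_per_decade = bins_per_decade)
    b <- b[b$count > 0, ]
    if (nrow(b) < 3) abort("too few occupied bins for an OLS slope.", class = "rootchamber_refusal")
    fit <- lm(log10(density) ~ log10(bin_center), data = b)
    alpha <- -coef(fit)[[2]]
    se <- summary(fit)$coefficients[2, 2]
  }
  structure(
    list(alpha = alpha, xmin = xmin, se_alpha = se, n_tail = n,
         gof = ks_pareto(tail_x, alpha, xmin), method = method),
    class = "powerlaw_fit"
  )
}

# KS distance between a sample (all >= xmin) and the Pareto(alpha, xmin) CDF
ks_pareto <- function(x, alpha, xmin) {
  x <- sort(x)
  n <- length(x)
  theo <- 1 - (x / xmin)^(1 - alpha)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  max(pmax(abs(emp_hi - theo), abs(emp_lo - theo)))
}

# data-driven xmin: the candidate value minimizing the KS distance of the
# Hill fit to its own tail, among candidates leaving at least min_tail points
select_xmin_ks <- function(x, min_tail = 10) {
  cand <- sort(unique(x))
  cand <- cand[seq_len(max(1, length(cand) - max(0L, min_tail - 1L)))]
  if (length(cand) > 200) { # thin the candidate grid for large samples
    cand <- cand[unique(round(seq(1, length(cand), length.out = 200)))]
  }
  ks <- vapply(cand, function(xm) {
    tail_x <- x[x >= xm]
    if (length(tail_x) < min_tail) return(Inf)
    a <- 1 + length(tail_x) / sum(log(tail_x / xm))
    ks_pareto(tail_x, a, xm)
  }, numeric(1))
  cand[which.min(ks)]
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> alpha = %.4f (se %.4f), xmin = %g cm2, n_tail = %d, KS = %.4f [%s]\n",
    x$alpha, x$se_alpha, x$xmin, x$n_tail, x$gof, x$method
  ))
  invisible(x)
}

#' @rdname fit_powerlaw
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = "alpha", estimate = x$alpha, std.error = x$se_alpha)
}

#' @rdname fit_powerlaw
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(alpha = x$alpha, se_alpha = x$se_alpha, xmin = x$xmin,
         n_tail = x$n_tail, gof = x$gof, method = x$method)
}

#' Sensitivity of the power-law exponent to large-area truncation
#'
#' Imperfect thresholding of photographed root systems preferentially breaks
#' the largest enclosed areas (their perimeters are longest), truncating the
#' upper tail of the observed distribution. This helper quantifies how much
#' the fitted exponent moves when the largest areas are removed: it drops
#' the top `drop_top_fraction` of areas and refits with the same settings.
#'
#' @inheritParams fit_powerlaw
#' @param drop_top_fraction Fraction of the largest areas to drop, in
#'   `[0, 0.5)`.
#' @return List of class `truncation_sensitivity` with elements `full` and
#'   `truncated` (both `powerlaw_fit`) and `alpha_shift`.
#' @export
truncation_sensitivity <- function(areas, drop_top_fraction, method = "mle",
                                   xmin = NULL, min_tail = 10) {
  if (drop_top_fraction < 0 || drop_top_fraction >= 0.5) {
    abort("`drop_top_fraction` must be in [0, 0.5).")
  }
  x <- as_area_vector(areas)
  full <- fit_powerlaw(x, method = method, xmin = xmin, min_tail = min_tail)
  k <- floor(drop_top_fraction * length(x))
  kept <- if (k > 0) sort(x)[seq_len(length(x) - k)] else x
  trunc_fit <- fit_powerlaw(kept, method = method,
                            xmin = xmin %||% full$xmin, min_tail = min_tail)
  structure(
    list(full = full, truncated = trunc_fit,
         alpha_shift = trunc_fit$alpha - full$alpha,
         drop_top_fraction = drop_top_fraction),
    class = "truncation_sensitivity"
  )
}

#' @export
print.truncation_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<truncation_sensitivity> drop %.0f%%: alpha %.4f -> %.4f (shift %+.4f)\n",
    100 * x$drop_top_fraction, x$full$alpha, x$truncated$alpha, x$alpha_shift
  ))
  invisible(x)
}

#' @rdname truncation_sensitivity
#' @param x A `truncation_sensitivity`.
#' @param ... Unused.
#' @export
tidy.truncation_sensitivity <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$full), sample = "full", .before = 1),
    dplyr::mutate(glance(x$truncated), sample = "truncated", .before = 1)
  )
}
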