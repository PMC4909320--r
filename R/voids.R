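#' Label connected components of a binary matrix
#'
#' Thin wrapper over the compiled breadth-first labelling kernel. Enclosure
#' analysis uses the standard digital-topology duality: background pixels
#' are 4-connected while root (foreground) pixels are treated as 8-connected
#' barriers, which prevents diagonal root "walls" from leaking.
#'
#' @param mask Logical matrix; `TRUE` cells are labelled.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 outside the mask).
#' @keywords internal
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask), is.logical(mask))
  .label_components_cpp(mask, as.integer(connectivity))
}

#' Extract background areas fully enclosed by roots
#'
#' Finds the connected components of background pixels (4-connectivity, with
#' root pixels acting as 8-connected barriers) and discards every component
#' that touches the image border: those regions are not enclosed by the root
#' system. The remaining components are the enclosed voids — the topology
#' phenotype of the root system — reported as physical areas in descending
#' order.
#'
#' @param mask A [root_mask()].
#' @param min_area_cm2 Optional lower size filter in cm2 (default 0: every
#'   void down to a single pixel is kept).
#' @return A tibble of class `void_area_set` with columns `source_id`,
#'   `area_cm2` and `n_pixels`, ordered by decreasing area, and attributes
#'   `pixel_size` (mm/px) and `n_voids`. Zero rows when nothing is enclosed.
#' @examples
#' ring <- matrix(FALSE, 5, 5)
#' ring[2:4, 2:4] <- TRUE
#' ring[3, 3] <- FALSE
#' extract_enclosed_areas(root_mask(ring, pixel_size = 1))
#' @export
extract_enclosed_areas <- function(mask, min_area_cm2 = 0) {
  stopifnot(inherits(mask, "root_mask"))
  lab <- label_components(!mask$grid, connectivity = 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  counts <- tabulate(lab)
  enclosed <- setdiff(which(counts > 0), border)
  px_area <- mask$pixel_size^2 / 100
  n_pixels <- counts[enclosed]
  out <- tibble(
    source_id = mask$source_id,
    area_cm2 = n_pixels * px_area,
    n_pixels = as.integer(n_pixels)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$area_cm2))
  out <- dplyr::filter(out, .data$area_cm2 >= min_area_cm2)
  structure(out,
    class = c("void_area_set", class(tibble())),
    pixel_size = mask$pixel_size, n_voids = nrow(out)
  )
}

#' Log-binned size-frequency distribution
#'
#' Bins positive areas into logarithmically spaced bins spanning whole
#' decades from `floor(log10(min))` to `ceiling(log10(max))` (extended by
#' one bin when the maximum falls exactly on the top edge; bins are closed
#' on the left). Counts conserve the sample size; the density column
#' divides counts by the linear bin width and the total count, so that on a
#' log-log plot a power law `p(x) ~ x^-alpha` appears as a line of slope
#' `-alpha`.
#'
#' @param areas A `void_area_set`, or any data frame with an `area_cm2`
#'   column (e.g. areas pooled over several plants of one condition), or a
#'   bare numeric vector of areas in cm2.
#' @param bins_per_decade Number of bins per factor of 10 (default 5).
#' @return A tibble of class `binned_distribution` with columns `bin_lo`,
#'   `bin_hi`, `bin_center` (geometric), `count` and `density`.
#' @export
log_binned_frequency <- function(areas, bins_per_decade = 5) {
  x <- as_area_vector(areas)
  if (length(x) == 0) abort("no areas to bin.")
  if (bins_per_decade < 1) abort("`bins_per_decade` must be >= 1.")
  lo <- floor(log10(min(x)))
  hi <- ceiling(log10(max(x)))
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  if (max(x) >= edges[length(edges)]) {
    edges <- c(edges, 10^(hi + 1 / bins_per_decade))
  }
  bin <- findInterval(x, edges)
  count <- tabulate(bin, nbins = length(edges) - 1)
  width <- diff(edges)
  structure(
    tibble(
      bin_lo = edges[-length(edges)],
      bin_hi = edges[-1],
      bin_center = sqrt(edges[-length(edges)] * edges[-1]),
      count = as.integer(count),
      density = count / (width * length(x))
    ),
    class = c("binned_distribution", class(tibble())),
    bins_per_decade = bins_per_decade, n = length(x)
  )
}

as_area_vector <- function(areas) {
  x <- if (is.data.frame(areas)) {
    if (!"area_cm2" %in% names(areas)) abort("data frame needs an `area_cm2` column.")
    areas$area_cm2
  } else {
    as.numeric(areas)
  }
  if (anyNA(x) || any(x <= 0)) abort("areas must be positive and non-missing.")
  x
}
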