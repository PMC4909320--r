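#' @title Scalar root-system phenotypes from a binary mask
#' @description
#' Three image-derived phenotypes summarize a 2D root system grown on a flat
#' sheet:
#' * **projected area** — the physical area covered by root pixels, in cm2;
#' * **span** — half of the maximum width of the system, where the maximum
#'   width is read as the maximum Feret (caliper) diameter over root pixel
#'   centres, in cm;
#' * **symmetry** — the ratio of the system's maximal extents along two
#'   perpendicular directions (the Feret-maximal direction and its normal),
#'   reported as min/max so it lies in (0, 1]; 1 indicates an isotropic
#'   system.
#'
#' Distances are measured between pixel centres; a single-pixel mask has zero
#' span. For symmetry both extents are floored at one pixel so that the
#' statistic stays in (0, 1] for degenerate (e.g. collinear) masks: any
#' nonempty set of pixels is at least one pixel wide.
#' @name phenotypes
NULL

# root pixel centres in physical mm: columns x (= col index) and y (= row index)
mask_points <- function(mask) {
  idx <- which(mask$grid, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 1) * mask$pixel_size,
        y = (idx[, 1] - 1) * mask$pixel_size)
}

# maximum Feret diameter of 2D points plus the maximizing pair's direction.
# Uses the convex hull when there are enough points; the diameter of a point
# set equals the diameter of its hull.
feret_max <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(list(d = 0, theta = 0))
  hull <- if (n > 3) unique(grDevices::chull(pts)) else seq_len(n)
  hp <- pts[hull, , drop = FALSE]
  m <- nrow(hp)
  if (m == 1) return(list(d = 0, theta = 0))
  d2 <- as.matrix(stats::dist(hp))^2
  k <- arrayInd(which.max(d2), dim(d2))
  p1 <- hp[k[1], ]; p2 <- hp[k[2], ]
  list(d = sqrt(max(d2)), theta = atan2(p2[2] - p1[2], p2[1] - p1[1]))
}

# extent (max - min projection) of points along direction theta
extent_along <- function(pts, theta) {
  proj <- pts[, 1] * cos(theta) + pts[, 2] * sin(theta)
  max(proj) - min(proj)
}

#' Projected root surface area
#'
#' @param mask A [root_mask()].
#' @return Area in cm2: root pixel count times `pixel_size^2 / 100`.
#' @rdname phenotypes
#' @export
projected_area <- function(mask) {
  stopifnot(inherits(mask, "root_mask"))
  sum(mask$grid) * mask$pixel_size^2 / 100
}

#' Root span
#'
#' @return Span in cm: half the maximum Feret diameter of root pixel
#'   centres. `NA` (with a warning) for an empty mask; 0 for a single pixel.
#' @rdname phenotypes
#' @export
root_span <- function(mask) {
  stopifnot(inherits(mask, "root_mask"))
  pts <- mask_points(mask)
  if (nrow(pts) == 0) {
    warn("span undefined for an empty mask.")
    return(NA_real_)
  }
  feret_max(pts)$d / 2 / 10 # mm -> cm, half width
}

#' Root symmetry
#'
#' @return Dimensionless ratio in (0, 1]; `NA` (with a warning) for masks
#'   with fewer than 2 root pixels.
#' @rdname phenotypes
#' @export
root_symmetry <- function(mask) {
  stopifnot(inherits(mask, "root_mask"))
  pts <- mask_points(mask)
  if (nrow(pts) < 2) {
    warn("symmetry undefined for masks with < 2 root pixels.")
    return(NA_real_)
  }
  symmetry_of_points(pts, floor_extent = mask$pixel_size)
}

# symmetry of a point set: extent perpendicular to the Feret-maximal
# direction over the Feret diameter, both floored at `floor_extent`.
symmetry_of_points <- function(pts, floor_extent = 0) {
  f <- feret_max(pts)
  d1 <- max(f$d, floor_extent)
  d2 <- max(extent_along(pts, f$theta + pi / 2), floor_extent)
  d2 / d1
}

#' Phenotype a batch of masks, optionally joining biomass data
#'
#' Computes [projected_area()], [root_span()] and [root_symmetry()] for each
#' mask and returns one row per mask. When a biomass table is supplied its
#' columns (`root_biomass_mg`, `shoot_biomass_mg`, `rh_condition`, and any
#' others) are joined by `source_id`; biomass is always input data measured
#' at harvest, never computed from the image.
#'
#' @param masks A list of [root_mask()] objects with unique `source_id`s.
#' @param biomass Optional data frame (or CSV path) with a `source_id`
#'   column.
#' @return A tibble with columns `source_id`, `projected_area_cm2`,
#'   `span_cm`, `symmetry`, plus any biomass columns.
#' @export
phenotype_batch <- function(masks, biomass = NULL) {
  if (inherits(masks, "root_mask")) masks <- list(masks)
  ids <- purrr::map_chr(masks, "source_id")
  if (anyDuplicated(ids)) abort("duplicate source_ids in mask batch.")
  records <- purrr::map_dfr(masks, function(m) {
    npx <- sum(m$grid)
    tibble(
      source_id = m$source_id,
      projected_area_cm2 = projected_area(m),
      span_cm = if (npx >= 1) root_span(m) else NA_real_,
      symmetry = if (npx >= 2) root_symmetry(m) else NA_real_
    )
  })
  if (!is.null(biomass)) {
    if (is.character(biomass)) biomass <- read.csv(biomass)
    biomass <- as_tibble(biomass)
    if (!"source_id" %in% names(biomass)) abort("biomass table needs a source_id column.")
    biomass$source_id <- as.character(biomass$source_id)
    orphans <- setdiff(biomass$source_id, records$source_id)
    if (length(orphans)) {
      warn(paste0("biomass ids with no mask: ", paste(orphans, collapse = ", ")))
    }
    records <- dplyr::left_join(records, biomass, by = "source_id")
  }
  records
}
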