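#' Specification of a synthetic 2D root system
#'
#' Parameters of the stochastic generator that emulates a thresholded image
#' of a root system grown on a flat sheet. Each primary axis is a
#' discrete-step random walk radiating from a single insertion point at the
#' image centre (the seedling plug hole); laterals initiate along every
#' axis as a Poisson process. Crossing axes produce the entangled,
#' loop-forming structures whose enclosed background regions are the
#' topology phenotype; the ground-truth voids are therefore defined on the
#' rasterized mask, exactly as the measured phenotype is defined on the
#' thresholded photograph.
#'
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   mask.
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size mm per pixel.
#' @param n_primary Number of primary axes leaving the insertion point.
#' @param step_length mm advanced per growth step.
#' @param branch_rate Expected lateral initiations per mm of axis, in
#'   `[0, 1]`.
#' @param angle_sd Heading noise per step, degrees.
#' @param lateral_angle Mean branching angle of a lateral off its parent,
#'   degrees.
#' @param max_total_length Total root length budget in mm, shared by all
#'   axes; growth stops when it is spent.
#' @param root_width Stroke thickness of the rasterized axes, pixels.
#' @param anisotropy Dimensionless bias in `[0, 1]`: the step displacement
#'   along the vertical image axis is scaled by `1 - anisotropy`, so 0
#'   gives isotropic growth (true symmetry near 1) and 1 collapses the
#'   system onto a horizontal line (minimal symmetry).
#' @return List of class `root_spec`.
#' @export
root_spec <- function(seed = 1, image_size = c(256, 256), pixel_size = 0.25,
                      n_primary = 4, step_length = 1, branch_rate = 0.08,
                      angle_sd = 12, lateral_angle = 55,
                      max_total_length = 1500, root_width = 1,
                      anisotropy = 0) {
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(step_length, "step_length")
  check_positive_scalar(max_total_length, "max_total_length")
  check_positive_scalar(angle_sd, "angle_sd", allow_zero = TRUE)
  check_positive_scalar(lateral_angle, "lateral_angle", allow_zero = TRUE)
  if (branch_rate < 0 || branch_rate > 1) abort("branch_rate must be in [0, 1] per mm.")
  if (anisotropy < 0 || anisotropy > 1) abort("anisotropy must be in [0, 1].")
  if (length(image_size) != 2 || any(image_size < 2)) {
    abort("image_size must be c(rows, cols), both >= 2.")
  }
  if (root_width < 1) abort("root_width must be >= 1 pixel.")
  if (n_primary < 1) {
    abort("n_primary must be >= 1: a root system needs at least one axis.",
          class = "rootchamber_empty_structure")
  }
  if (step_length >= min(image_size) * pixel_size / 2) {
    abort("image too small to contain a single growth step.",
          class = "rootchamber_sizing_error")
  }
  structure(
    list(seed = as.integer(seed), image_size = as.integer(image_size),
         pixel_size = pixel_size, n_primary = as.integer(n_primary),
         step_length = step_length, branch_rate = branch_rate,
         angle_sd = angle_sd, lateral_angle = lateral_angle,
         max_total_length = max_total_length, root_width = as.integer(root_width),
         anisotropy = anisotropy),
    class = "root_spec"
  )
}

#' Generate a synthetic root mask with known ground truth
#'
#' Runs the branching random-walk growth model of [root_spec()], rasterizes
#' the resulting axes into a binary [root_mask()], and records the
#' ground-truth phenotypes: the true span (half the maximum Feret diameter
#' of the axis points), the true symmetry (perpendicular-extent ratio of
#' the axis points), and the true enclosed-void areas of the rasterized
#' mask. All randomness flows from the spec's seed through a local RNG; the
#' global RNG state is untouched.
#'
#' @param spec A [root_spec()].
#' @param source_id Identifier stored in the mask (default
#'   `"synthetic-<seed>"`).
#' @return List of class `synthetic_root`: `mask` ([root_mask()]),
#'   `polylines` (list of n x 2 matrices of axis points, mm), `true_span_cm`,
#'   `true_symmetry`, `true_void_areas_cm2`, and the `spec`.
#' @examples
#' sr <- generate_root_mask(root_spec(seed = 42))
#' sr$true_span_cm
#' root_span(sr$mask)
#' @export
generate_root_mask <- function(spec, source_id = NULL) {
  stopifnot(inherits(spec, "root_spec"))
  polylines <- withr::with_seed(spec$seed, grow_axes(spec))
  mask <- rasterize_polylines(polylines, spec$image_size, spec$pixel_size,
                              spec$root_width,
                              source_id = source_id %||% paste0("synthetic-", spec$seed))
  pts <- do.call(rbind, polylines)
  voids <- extract_enclosed_areas(mask)
  structure(
    list(mask = mask, polylines = polylines,
         true_span_cm = feret_max(pts)$d / 2 / 10,
         true_symmetry = if (nrow(pts) >= 2) symmetry_of_points(pts) else NA_real_,
         true_void_areas_cm2 = voids$area_cm2,
         spec = spec),
    class = "synthetic_root"
  )
}

#' @export
print.synthetic_root <- function(x, ...) {
  cat(sprintf(
    "<synthetic_root> seed %d: %d axes, span %.2f cm, symmetry %.3f, %d voids\n",
    x$spec$seed, length(x$polylines), x$true_span_cm, x$true_symmetry,
    length(x$true_void_areas_cm2)
  ))
  invisible(x)
}

# branching random-walk growth; returns list of axis polylines in mm.
# Axes are grown depth-first; laterals are queued and grown in spawn order,
# all against a shared total-length budget.
grow_axes <- function(spec) {
  w_mm <- (spec$image_size[2] - 1) * spec$pixel_size
  h_mm <- (spec$image_size[1] - 1) * spec$pixel_size
  origin <- c(w_mm / 2, h_mm / 2)
  ang0 <- runif(1, 0, 2 * pi)
  queue <- lapply(seq_len(spec$n_primary), function(i) {
    list(pos = origin, heading = ang0 + 2 * pi * (i - 1) / spec$n_primary)
  })
  budget <- spec$max_total_length
  polylines <- list()
  while (length(queue) > 0 && budget >= spec$step_length) {
    ax <- queue[[1]]
    queue <- queue[-1]
    pts <- matrix(ax$pos, ncol = 2)
    heading <- ax$heading
    repeat {
      if (budget < spec$step_length) break
      heading <- heading + rnorm(1, 0, spec$angle_sd * pi / 180)
      step <- spec$step_length * c(cos(heading),
                                   sin(heading) * (1 - spec$anisotropy))
      nxt <- pts[nrow(pts), ] + step
      if (nxt[1] < 0 || nxt[1] > w_mm || nxt[2] < 0 || nxt[2] > h_mm) break
      pts <- rbind(pts, nxt)
      budget <- budget - spec$step_length
      n_lat <- rpois(1, spec$branch_rate * spec$step_length)
      if (n_lat > 0) {
        for (k in seq_len(n_lat)) {
          side <- sample(c(-1, 1), 1)
          queue <- c(queue, list(list(
            pos = nxt,
            heading = heading + side * spec$lateral_angle * pi / 180 +
              rnorm(1, 0, spec$angle_sd * pi / 180)
          )))
        }
      }
    }
    polylines <- c(polylines, list(unname(pts)))
  }
  if (length(polylines) == 0) polylines <- list(matrix(origin, ncol = 2))
  polylines
}

#' Rasterize axis polylines into a binary mask
#'
#' Draws each polyline onto the pixel grid by dense sampling along every
#' segment, then thickens the stroke to `root_width` pixels with a square
#' brush. Re-running this function on the polylines stored in a
#' [generate_root_mask()] result reproduces its mask exactly.
#'
#' @param polylines List of n x 2 matrices of (x, y) points in mm.
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size mm per pixel.
#' @param root_width Stroke width in pixels.
#' @param source_id Identifier for the resulting mask.
#' @return A [root_mask()].
#' @export
rasterize_polylines <- function(polylines, image_size, pixel_size,
                                root_width = 1, source_id = "rasterized") {
  nr <- image_size[1]; nc <- image_size[2]
  grid <- matrix(FALSE, nr, nc)
  sample_gap <- pixel_size / 4
  for (pl in polylines) {
    if (nrow(pl) == 1) {
      pxy <- pl
    } else {
      pieces <- lapply(seq_len(nrow(pl) - 1), function(i) {
        p1 <- pl[i, ]; p2 <- pl[i + 1, ]
        len <- sqrt(sum((p2 - p1)^2))
        tt <- seq(0, 1, length.out = max(2, ceiling(len / sample_gap) + 1))
        cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2]))
      })
      pxy <- do.call(rbind, pieces)
    }
    col <- round(pxy[, 1] / pixel_size) + 1
    row <- round(pxy[, 2] / pixel_size) + 1
    ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
    grid[cbind(row[ok], col[ok])] <- TRUE
  }
  if (root_width > 1) {
    lo <- -floor((root_width - 1) / 2)
    hi <- ceiling((root_width - 1) / 2)
    idx <- which(grid, arr.ind = TRUE)
    thick <- matrix(FALSE, nr, nc)
    for (dr in lo:hi) {
      for (dc in lo:hi) {
        r2 <- idx[, 1] + dr; c2 <- idx[, 2] + dc
        ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
        thick[cbind(r2[ok], c2[ok])] <- TRUE
      }
    }
    grid <- thick
  }
  root_mask(grid, pixel_size, source_id)
}
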