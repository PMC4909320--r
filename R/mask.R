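#' Binary root-system mask
#'
#' The basic unit of 2D root phenotyping: a binary raster in which `TRUE`
#' marks root pixels, together with the physical pixel size. Coordinates are
#' row-major with the origin at the top-left pixel centre; the physical
#' position of pixel `(row, col)` is `(col - 1, row - 1) * pixel_size` in mm.
#'
#' @param grid Logical matrix (or 0/1 numeric matrix), `TRUE` = root pixel.
#' @param pixel_size Physical pixel size in mm per pixel (> 0).
#' @param source_id Free-text identifier carried into downstream tables.
#' @return An object of class `root_mask`: a list with elements `grid`
#'   (logical matrix), `pixel_size` (mm/pixel) and `source_id`.
#' @examples
#' m <- root_mask(matrix(c(0, 1, 1, 0), 2, 2), pixel_size = 0.5)
#' projected_area(m)
#' @export
root_mask <- function(grid, pixel_size, source_id = "mask") {
  if (!is.matrix(grid)) abort("`grid` must be a matrix.", class = "rootchamber_format_error")
  if (is.numeric(grid)) {
    if (!all(grid %in% c(0, 1))) {
      abort("numeric `grid` must be binary (0/1).", class = "rootchamber_format_error")
    }
    grid <- grid > 0
  }
  if (!is.logical(grid)) abort("`grid` must be logical or 0/1 numeric.", class = "rootchamber_format_error")
  if (anyNA(grid)) abort("`grid` must not contain NA.", class = "rootchamber_format_error")
  if (max(dim(grid)) < 2) abort("mask must have at least one dimension >= 2.", class = "rootchamber_format_error")
  check_positive_scalar(pixel_size, "pixel_size")
  structure(
    list(grid = grid, pixel_size = pixel_size, source_id = as.character(source_id)),
    class = "root_mask"
  )
}

#' @export
print.root_mask <- function(x, ...) {
  cat(sprintf(
    "<root_mask> %s: %d x %d px at %g mm/px, %d root pixels\n",
    x$source_id, nrow(x$grid), ncol(x$grid), x$pixel_size, sum(x$grid)
  ))
  invisible(x)
}

#' Load a root mask from a PNG or TIFF image
#'
#' Reads a single-channel image and binarizes it into a [root_mask()].
#' Grayscale images are thresholded according to `threshold_policy`; images
#' that are already binary pass through unchanged. Multi-channel images are
#' accepted only when all colour channels are identical (an alpha channel,
#' if present, is ignored); otherwise there is no defensible conversion rule
#' and a format error is raised. Orientation is preserved: row 1 of the grid
#' is the top row of the image.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param pixel_size Physical pixel size in mm per pixel. If `NULL`, a JSON
#'   sidecar `<path>.json` with a `pixel_size_mm` key is consulted.
#' @param threshold_policy Either `"otsu"` (Otsu's method on the grayscale
#'   histogram), or a fixed numeric threshold. Numeric thresholds greater
#'   than 1 are interpreted on the 8-bit 0-255 scale, otherwise on the
#'   normalized 0-1 scale read from file. Pixels strictly above the
#'   threshold are root. The default `"auto"` passes binary images through
#'   and applies Otsu to genuinely grayscale ones.
#' @param source_id Identifier; defaults to the file name without extension.
#' @return A [root_mask()].
#' @export
load_mask <- function(path, pixel_size = NULL, threshold_policy = "auto",
                      source_id = NULL) {
  if (!file.exists(path)) abort(paste0("image not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format: .", ext), class = "rootchamber_format_error")
  )
  img <- collapse_channels(img, path)
  if (is.null(pixel_size)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      pixel_size <- meta$pixel_size_mm
    }
    if (is.null(pixel_size)) {
      abort("`pixel_size` not given and no JSON sidecar with pixel_size_mm found.")
    }
  }
  vals <- sort(unique(as.vector(img)))
  binary_already <- length(vals) <= 2
  thr <- resolve_threshold(threshold_policy, img, binary_already)
  grid <- img > thr
  if (!any(grid)) warn(paste0("mask '", path, "' contains no root pixels."))
  source_id <- source_id %||% tools::file_path_sans_ext(basename(path))
  root_mask(grid, pixel_size, source_id)
}

collapse_channels <- function(img, path) {
  if (length(dim(img)) == 2) return(img)
  nch <- dim(img)[3]
  channels <- if (nch %in% c(2L, 4L)) seq_len(nch - 1L) else seq_len(nch)
  first <- img[, , channels[1]]
  for (ch in channels[-1]) {
    if (!isTRUE(all.equal(img[, , ch], first, tolerance = 1e-9))) {
      abort(
        paste0("multi-channel image with unequal channels: ", path,
               " (convert to grayscale first)"),
        class = "rootchamber_format_error"
      )
    }
  }
  first
}

resolve_threshold <- function(policy, img, binary_already) {
  if (is.numeric(policy)) {
    if (policy > 1) policy / 255 else policy
  } else if (identical(policy, "otsu")) {
    otsu_threshold(img)
  } else if (identical(policy, "auto")) {
    if (binary_already) mean(range(img)) else otsu_threshold(img)
  } else {
    abort("`threshold_policy` must be \"auto\", \"otsu\" or a number.")
  }
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustively searches 256 candidate levels for the threshold maximizing
#' the between-class variance of the intensity histogram (equivalently,
#' minimizing the weighted intra-class variance).
#'
#' @param img Numeric matrix or array of intensities in `[0, 1]`.
#' @return Threshold on the 0-1 scale; pixels above it are foreground.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(img)
  if (length(unique(v)) < 2) return(mean(range(v)))
  breaks <- seq(0, 1, length.out = 257)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[256]
  # between-class variance for thresholds placed after each bin
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  breaks[k + 1]
}

#' Write a root mask to PNG with a JSON sidecar
#'
#' Writes an 8-bit single-channel PNG (0 = background, 255 = root) and a
#' sidecar `<path>.json` recording the physical pixel size plus any extra
#' metadata (e.g. the generator seed and spec).
#'
#' @param mask A [root_mask()].
#' @param path Output PNG path.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, meta = list()) {
  stopifnot(inherits(mask, "root_mask"))
  png::writePNG(mask$grid * 1, path)
  sidecar <- c(list(pixel_size_mm = mask$pixel_size, source_id = mask$source_id), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

check_positive_scalar <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) {
    abort(sprintf("`%s` must be a %s finite number.", name,
                  if (allow_zero) "non-negative" else "positive"))
  }
  invisible(x)
}
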