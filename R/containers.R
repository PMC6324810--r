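#' Image containers
#'
#' Pixel data are not tabular, so images travel in lightweight S3 containers
#' wrapping plain numeric arrays, in the style of EBImage. Everything the
#' containers feed into or out of (profiles, histograms, interval tables,
#' reports) is a tibble.
#'
#' * `image_stack`: 3-D intensity array indexed `[y, x, z]` with an XY pixel
#'   size and a Z spacing, both in micrometres. Depth is measured downward
#'   from the uppermost substrate plane, so slice `k` sits at depth
#'   `z_origin + (k - 1) * z_spacing`.
#' * `image2d`: 2-D intensity matrix `[y, x]` with a pixel size.
#' * `binary_mask`: 2-D logical matrix `[y, x]` with a pixel size.
#'
#' @param voxels numeric array `[y, x, z]`, intensities `>= 0`.
#' @param pixels numeric matrix (`image2d`) or logical matrix (`binary_mask`).
#' @param pixel_size XY pixel size, um.
#' @param z_spacing slice spacing, um.
#' @param z_origin depth of the first slice, um.
#' @return An object of the corresponding class.
#' @name containers
NULL

#' @rdname containers
#' @export
image_stack <- function(voxels, pixel_size, z_spacing, z_origin = 0) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (any(voxels < 0)) stop("stack intensities must be >= 0")
  if (pixel_size <= 0 || z_spacing <= 0) {
    stop("pixel_size and z_spacing must be > 0")
  }
  structure(
    list(voxels = voxels, pixel_size = pixel_size,
         z_spacing = z_spacing, z_origin = z_origin),
    class = "image_stack"
  )
}

#' @rdname containers
#' @export
image2d <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0)) stop("image intensities must be >= 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size), class = "image2d")
}

#' @rdname containers
#' @export
binary_mask <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels))
  if (!is.logical(pixels)) {
    pixels <- pixels > 0
  }
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "binary_mask")
}

#' Depths of the slices of a stack
#' @param stack an `image_stack`.
#' @return numeric vector of slice depths, um.
#' @export
slice_depths <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  stack$z_origin + (seq_len(dim(stack$voxels)[3]) - 1) * stack$z_spacing
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d slices | %.4f um/px, dz %.2f um\n",
              d[2], d[1], d[3], x$pixel_size, x$z_spacing))
  invisible(x)
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px | %.4f um/px | range [%.3g, %.3g]\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px | %.4f um/px | %.2f%% foreground\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size,
              100 * mean(x$pixels)))
  invisible(x)
}
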