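#' Maximum intensity projection
#'
#' Collapses a Z-stack to a 2-D image by taking the per-pixel maximum over
#' slices.
#'
#' @param stack an [image_stack()] with at least one slice.
#' @return An [image2d()].
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (d[3] < 1) stop("stack has no slices")
  out <- stack$voxels[, , 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, stack$voxels[, , k])
  image2d(out, stack$pixel_size)
}

#' Rotate grooves to the vertical reference axis and crop
#'
#' Rotates the image so the groove axis becomes vertical (the 0-degree
#' reference direction for all orientation statistics) and takes a centred
#' crop of exactly `crop_px` pixels. Intensity images are resampled
#' bilinearly; a pure multiple-of-90-degree rotation is performed exactly
#' (no interpolation). The crop must not reach outside the rotated valid
#' region.
#'
#' @param image an [image2d()].
#' @param groove_angle angle of the groove axis in the input, degrees
#'   counter-clockwise from vertical.
#' @param crop_px `c(width, height)` of the output, px.
#' @return An [image2d()] of exactly `crop_px`.
#' @export
rotate_and_crop <- function(image, groove_angle = 0,
                            crop_px = c(2400, 2100)) {
  stopifnot(inherits(image, "image2d"))
  nxo <- crop_px[1]
  nyo <- crop_px[2]
  nx <- ncol(image$pixels)
  ny <- nrow(image$pixels)
  a <- groove_angle %% 360
  th <- a * pi / 180
  # required input size for a centred crop with no out-of-bounds sampling
  need_x <- abs(nxo * cos(th)) + abs(nyo * sin(th))
  need_y <- abs(nxo * sin(th)) + abs(nyo * cos(th))
  if (nx < need_x - 1e-9 || ny < need_y - 1e-9) {
    stop(sprintf(
      "crop of %d x %d px rotated by %.1f deg needs an input of at least %d x %d px (got %d x %d)",
      nxo, nyo, groove_angle, ceiling(need_x), ceiling(need_y), nx, ny))
  }
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  xo <- seq_len(nxo) - (nxo + 1) / 2
  yo <- seq_len(nyo) - (nyo + 1) / 2
  if (a %% 90 == 0) {
    k <- (a / 90) %% 4
    px <- image$pixels
    if (k >= 1) for (i in seq_len(k)) px <- t(px)[, nrow(px):1, drop = FALSE]
    ctx <- (ncol(px) + 1) / 2
    cty <- (nrow(px) + 1) / 2
    out <- px[round(cty + yo), round(ctx + xo), drop = FALSE]
    return(image2d(out, image$pixel_size))
  }
  # output pixel (xo, yo) samples the input at the +groove_angle rotation
  # (y axis points down, so the ccw rotation matrix has flipped sign)
  sx <- outer(yo, xo, function(y, x) cx + x * cos(th) - y * sin(th))
  sy <- outer(yo, xo, function(y, x) cy + x * sin(th) + y * cos(th))
  out <- bilinear_sample(image$pixels, sy, sx)
  image2d(out, image$pixel_size)
}

# vectorized bilinear sampling; coords must be in-bounds
bilinear_sample <- function(m, sy, sx) {
  dims <- dim(sy)
  ny <- nrow(m)
  nx <- ncol(m)
  sy <- pmin(pmax(as.vector(sy), 1), ny)
  sx <- pmin(pmax(as.vector(sx), 1), nx)
  y0 <- pmin(floor(sy), ny - 1)
  x0 <- pmin(floor(sx), nx - 1)
  fy <- sy - y0
  fx <- sx - x0
  v <- m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    m[cbind(y0 + 1, x0 + 1)] * fy * fx
  matrix(v, dims[1], dims[2])
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the envelope of a ball of the given
#' radius rolled under the intensity surface (grayscale erosion then dilation
#' with a spherical structuring element) and subtracts it, clamping at zero.
#' Intensities are treated on the 8-bit convention (1.0 intensity unit = 255
#' gray levels = 255 px of ball height). For radii of 16 px and above the
#' image is first reduced by a block-minimum shrink, the ball rolled at
#' reduced scale, and the background re-enlarged bilinearly (set
#' `shrink = 1` to force the full-resolution construction). Borders are
#' mirror-padded.
#'
#' The background is estimated on a 3 x 3 mean pre-smoothed copy (so the ball
#' rides through the noise floor instead of under it, removing the noise
#' pedestal) and subtracted from the unsmoothed image; `presmooth = FALSE`
#' disables this.
#'
#' @param image an [image2d()].
#' @param radius_px ball radius, px (`>= 1`).
#' @param shrink integer shrink factor, or `NULL` to choose automatically
#'   (1 below radius 16, else 4).
#' @param presmooth estimate the background on a 3 x 3 mean-filtered copy.
#' @return An [image2d()]; never exceeds the input anywhere.
#' @export
rolling_ball_subtract <- function(image, radius_px = 50, shrink = NULL,
                                  presmooth = TRUE) {
  stopifnot(inherits(image, "image2d"), radius_px >= 1)
  if (is.null(shrink)) shrink <- if (radius_px < 16) 1L else 4L
  px <- image$pixels * 255            # 8-bit gray-level convention
  src <- if (presmooth) mean3x3(px) else px
  bg <- rolling_ball_background(src, radius_px, shrink)
  image2d(pmax(px - bg, 0) / 255, image$pixel_size)
}

mean3x3 <- function(px) {
  pad <- mirror_pad(px, 1)
  acc <- matrix(0, nrow(px), ncol(px))
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + pad[seq_len(nrow(px)) + dy, seq_len(ncol(px)) + dx]
  }
  acc / 9
}

rolling_ball_background <- function(px, radius_px, shrink) {
  ny <- nrow(px)
  nx <- ncol(px)
  if (shrink > 1) {
    ny2 <- ceiling(ny / shrink)
    nx2 <- ceiling(nx / shrink)
    pad <- px[c(seq_len(ny), rep(ny, ny2 * shrink - ny)),
              c(seq_len(nx), rep(nx, nx2 * shrink - nx)), drop = FALSE]
    small <- matrix(Inf, ny2, nx2)
    for (dy in seq_len(shrink)) for (dx in seq_len(shrink)) {
      small <- pmin(small, pad[seq(dy, by = shrink, length.out = ny2),
                               seq(dx, by = shrink, length.out = nx2)])
    }
    r2 <- max(radius_px / shrink, 1)
  } else {
    small <- px
    r2 <- radius_px
  }
  bg_small <- ball_close_under(small, r2)
  if (shrink > 1) {
    sy <- (seq_len(ny) - 0.5) / shrink + 0.5
    sx <- (seq_len(nx) - 0.5) / shrink + 0.5
    bilinear_sample(bg_small, matrix(sy, ny, nx), matrix(sx, ny, nx, byrow = TRUE))
  } else {
    bg_small
  }
}

# grayscale erosion then dilation with a non-flat ball of radius r
# (heights in the same units as the image); mirror padding
ball_close_under <- function(m, r) {
  ri <- ceiling(r)
  offs <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  h <- sqrt(pmax(r^2 - offs$dy^2 - offs$dx^2, 0))
  ny <- nrow(m)
  nx <- ncol(m)
  pad <- mirror_pad(m, ri)
  ero <- matrix(Inf, ny, nx)
  for (i in seq_len(nrow(offs))) {
    ero <- pmin(ero, pad[seq_len(ny) + ri + offs$dy[i],
                         seq_len(nx) + ri + offs$dx[i]] - h[i])
  }
  pad <- mirror_pad(ero, ri)
  dil <- matrix(-Inf, ny, nx)
  for (i in seq_len(nrow(offs))) {
    dil <- pmax(dil, pad[seq_len(ny) + ri + offs$dy[i],
                         seq_len(nx) + ri + offs$dx[i]] + h[i])
  }
  dil
}

mirror_pad <- function(m, r) {
  ny <- nrow(m)
  nx <- ncol(m)
  iy <- c(rev(seq_len(min(r, ny))), seq_len(ny),
          ny + 1 - rev(seq_len(min(r, ny))))
  if (r > ny) iy <- c(rep(1, r - ny), iy, rep(ny, r - ny))
  ix <- c(rev(seq_len(min(r, nx))), seq_len(nx),
          nx + 1 - rev(seq_len(min(r, nx))))
  if (r > nx) ix <- c(rep(1, r - nx), ix, rep(nx, r - nx))
  m[iy, ix, drop = FALSE]
}

#' Auto-contrast and conversion to 8-bit
#'
#' Linear rescale mapping the `saturation_fraction/2` and
#' `1 - saturation_fraction/2` intensity quantiles to 0 and 255, clipping
#' outside; output is integer-valued in `[0, 255]`. A constant image has no
#' contrast to stretch and maps to all zeros with a warning.
#'
#' @param image an [image2d()].
#' @param saturation_fraction total fraction of pixels saturated (split
#'   between the two tails).
#' @return An [image2d()] with integer values in `[0, 255]`.
#' @export
autocontrast_to_8bit <- function(image, saturation_fraction = 0.007) {
  stopifnot(inherits(image, "image2d"),
            saturation_fraction >= 0, saturation_fraction < 1)
  q <- stats::quantile(image$pixels,
                       c(saturation_fraction / 2, 1 - saturation_fraction / 2),
                       names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: no contrast to stretch; output is all zeros")
    return(image2d(matrix(0, nrow(image$pixels), ncol(image$pixels)),
                   image$pixel_size))
  }
  sc <- round(255 * (image$pixels - q[1]) / (q[2] - q[1]))
  image2d(pmin(pmax(sc, 0), 255), image$pixel_size)
}

#' Phansalkar local thresholding
#'
#' Local adaptive binarization for low-contrast images. With intensities
#' normalized to `[0, 1]` and local mean `m` and standard deviation `s` over
#' the window of the given radius, the threshold is
#' `t = m * (1 + p * exp(-q * m) + k * (s / r - 1))` and a pixel is foreground
#' iff its normalized intensity exceeds `t`. Borders are mirror-padded.
#'
#' @param image8 an [image2d()] in the 8-bit range (values in `[0, 255]`).
#' @param radius_px window radius, px.
#' @param k,r,p,q method constants (defaults are the values the method is
#'   conventionally distributed with, on unit-normalized intensities).
#' @param window `"disc"` (default) or `"square"` local window.
#' @return A [binary_mask()].
#' @export
phansalkar_mask <- function(image8, radius_px = 5, k = 0.25, r = 0.5,
                            p = 2, q = 10, window = c("disc", "square")) {
  stopifnot(inherits(image8, "image2d"), radius_px >= 1)
  window <- match.arg(window)
  if (max(image8$pixels) > 255) stop("image must be in the 8-bit range")
  I8 <- round(image8$pixels)          # 8-bit grays; sums are exact integers
  kern <- phansalkar_kernel(radius_px, window)
  n <- sum(kern)
  pad <- mirror_pad(I8, radius_px)
  s1 <- round(EBImage::filter2(pad, kern, boundary = 0))
  s2 <- round(EBImage::filter2(pad * pad, kern, boundary = 0))
  core <- seq_len(nrow(I8)) + radius_px
  corx <- seq_len(ncol(I8)) + radius_px
  mu <- s1[core, corx] / (n * 255)
  va <- pmax(s2[core, corx] / (n * 255^2) - mu^2, 0)
  sd <- sqrt(va)
  t <- mu * (1 + p * exp(-q * mu) + k * (sd / r - 1))
  binary_mask(I8 / 255 > t, image8$pixel_size)
}

phansalkar_kernel <- function(radius_px, window) {
  d <- 2 * radius_px + 1
  if (window == "square") return(matrix(1, d, d))
  off <- -radius_px:radius_px
  (outer(off^2, off^2, "+") <= radius_px^2) * 1
}

#' Remove small particles from a binary mask
#'
#' Deletes 8-connected foreground components whose physical area is strictly
#' below `min_area_um2`; components at or above the cutoff are untouched.
#' Idempotent.
#'
#' @param mask a [binary_mask()].
#' @param min_area_um2 area cutoff, square um.
#' @return A [binary_mask()].
#' @export
filter_small_particles <- function(mask, min_area_um2 = 400) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_components8(mask$pixels)
  if (max(lab) == 0) return(mask)
  areas_px <- tabulate(lab[lab > 0])
  keep <- areas_px * mask$pixel_size^2 >= min_area_um2
  out <- mask$pixels
  out[lab > 0] <- keep[lab[lab > 0]]
  binary_mask(out, mask$pixel_size)
}

#' 8-connected component labeling
#'
#' Labels foreground components of a logical matrix with 8-connectivity
#' (diagonal contact joins), so thin diagonal vessel fragments stay whole.
#'
#' @param m logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components8 <- function(m) {
  stopifnot(is.logical(m))
  fg <- which(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  if (length(fg) == 0) return(lab)
  id <- matrix(0L, nrow(m), ncol(m))
  id[fg] <- seq_along(fg)
  ny <- nrow(m)
  nx <- ncol(m)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    ys <- seq_len(ny - abs(s[1])) + max(s[1], 0L)
    xs <- seq_len(nx - s[2]) + s[2]
    a <- id[ys - s[1], xs - s[2], drop = FALSE]
    b <- id[ys, xs, drop = FALSE]
    both <- a > 0L & b > 0L
    edges[[length(edges) + 1]] <- cbind(a[both], b[both])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_graph(t(e), n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}
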