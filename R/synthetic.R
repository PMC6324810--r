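#' Synthetic confocal co-culture stacks
#'
#' Generates Z-stacks emulating CD31-stained microcapillary-like structures on
#' a patterned substrate: filaments are smooth random curves with a Gaussian
#' cross-profile, laid over the substrate with a controllable orientation
#' concentration and groove-containment probability. The stack carries a faint
#' substrate surface signal (bioceramic autofluorescence) and each structure's
#' Z position tracks the substrate depth profile at its x position, so depth
#' profiles are recoverable from the stack. Background is a low-amplitude
#' smooth gradient plus per-voxel Gaussian noise.
#'
#' Orientations are drawn from a wrapped-normal-like distribution on the
#' half-circle centred on the groove axis (0 degrees): the doubled angle is
#' normal with standard deviation `1/sqrt(kappa)` radians, so `kappa = 0`
#' means exactly uniform and larger `kappa` concentrates orientations.
#' Filaments flagged as contained are placed inside a groove interval; their
#' along-image x-span is capped so every centreline vertex stays inside the
#' groove (containment physically constrains orientation, as on the real
#' substrates).
#'
#' @param design design name or one-row design tibble.
#' @param n_filaments number of filaments.
#' @param alignment_kappa orientation concentration, `>= 0` (0 = uniform).
#' @param containment_prob probability a filament is confined to a groove.
#' @param filament_width_um full width (FWHM of the Gaussian cross-profile), um.
#' @param snr peak filament amplitude over background noise standard deviation.
#' @param image_size_px `c(width, height)` in pixels, each `>= 256`.
#' @param pixel_size um per pixel.
#' @param n_slices number of Z slices; slices span `[0, depth + 50]` um.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param phase lateral phase of the substrate pattern, um.
#' @param substrate_glow amplitude of the substrate surface signal relative to
#'   the filament peak (1.0).
#' @param background amplitude of the smooth 2-D polynomial background
#'   gradient relative to the filament peak.
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (list: `filaments` tibble with one row per filament, `vertices` tibble of
#'   centreline vertices, plus `design`, `phase`, `seed`).
#' @export
generate_coculture_stack <- function(design,
                                     n_filaments = 40,
                                     alignment_kappa = 0,
                                     containment_prob = 0,
                                     filament_width_um = 20,
                                     snr = 8,
                                     image_size_px = c(1200, 1050),
                                     pixel_size = 2.3917,
                                     n_slices = 10,
                                     seed = 1,
                                     phase = 0,
                                     substrate_glow = 0.25,
                                     background = 0.08) {
  design <- as_design(design)
  stopifnot(containment_prob >= 0, containment_prob <= 1,
            alignment_kappa >= 0, n_filaments >= 0, snr > 0,
            n_slices >= 1)
  if (any(image_size_px < 256)) stop("image_size_px must be at least 256 x 256")
  if (containment_prob > 0 && design$polarity == "flat") {
    stop("containment_prob > 0 is meaningless for a flat design (no grooves)")
  }
  set.seed(as.integer(seed))

  nx <- image_size_px[1]
  ny <- image_size_px[2]
  extent_x <- nx * pixel_size
  extent_y <- ny * pixel_size
  grooves <- groove_truth(design, extent_x, phase)

  filaments <- vector("list", n_filaments)
  vertices <- vector("list", n_filaments)
  line_img <- matrix(0, ny, nx)

  for (i in seq_len(n_filaments)) {
    theta <- draw_orientation(alignment_kappa)
    len <- stats::runif(1, 500, 3000)
    amp <- stats::runif(1, 25, 50)        # meander amplitude, um
    contained <- stats::runif(1) < containment_prob
    if (contained) {
      gi <- sample.int(nrow(grooves), 1,
                       prob = grooves$end - grooves$start)
      a <- grooves$start[gi]
      b <- grooves$end[gi]
      pad <- 5
      half_w <- (b - a) / 2 - pad
      amp <- min(amp, max(half_w / 2, 1))
      # cap the x-span of the straight component so vertices stay inside
      max_sin <- max((half_w - amp) * 2 / len, 0)
      if (abs(sin(theta * pi / 180)) > max_sin) {
        theta <- sign(theta) * asin(max_sin) * 180 / pi
      }
      xc <- stats::runif(1, a + half_w * 0.2 + pad, b - half_w * 0.2 - pad)
      yc <- stats::runif(1, 0, extent_y)
    } else {
      xc <- stats::runif(1, 0, extent_x)
      yc <- stats::runif(1, 0, extent_y)
    }
    cl <- filament_centerline(xc, yc, theta, len, amp)
    if (contained) {
      margin <- min(filament_width_um / 2, (b - a) / 4)
      cl$x <- pmin(pmax(cl$x, a + margin), b - margin)
    }
    # realized orientation from the end-to-end chord, groove axis = 0 (y axis)
    dx <- cl$x[nrow(cl)] - cl$x[1]
    dy <- cl$y[nrow(cl)] - cl$y[1]
    ang <- atan2(dx, dy) * 180 / pi
    ang <- ((ang + 90) %% 180) - 90
    brightness <- stats::runif(1, 0.75, 1)
    filaments[[i]] <- tibble::tibble(
      filament = i, orientation = ang, length_um = len,
      contained = contained, brightness = brightness
    )
    vertices[[i]] <- tibble::tibble(filament = i, x = cl$x, y = cl$y)
    line_img <- splat_centerline(line_img, cl, brightness, pixel_size, nx, ny)
  }

  # Gaussian cross-profile: convolve the unit-amplitude centreline image and
  # renormalize so an isolated straight filament peaks at its brightness.
  sigma_px <- (filament_width_um / 2.355) / pixel_size
  fil2d <- blur_lines(line_img, sigma_px)

  # substrate autofluorescence: weak uniform sheet lying on the surface
  glow2d <- matrix(substrate_glow, ny, nx)

  # distribute 2-D signal into slices: depth depends only on x
  z_max <- design$depth + 50
  z_spacing <- if (n_slices > 1) z_max / (n_slices - 1) else z_max
  zs <- (seq_len(n_slices) - 1) * z_spacing
  xc_um <- (seq_len(nx) - 0.5) * pixel_size
  depth_x <- profile_z(design, xc_um, phase)
  # full amplitude in the slice nearest the structure depth, with a
  # one-slice Gaussian bleed into neighbouring slices
  w <- outer(zs, depth_x, function(z, d) exp(-0.5 * ((z - d) / z_spacing)^2))
  w <- sweep(w, 2, apply(w, 2, max), "/")

  noise_sd <- 1 / snr
  bg <- background_gradient(ny, nx) * background
  vox <- array(0, dim = c(ny, nx, n_slices))
  signal2d <- fil2d + glow2d
  for (k in seq_len(n_slices)) {
    slice <- sweep(signal2d, 2, w[k, ], "*") + bg +
      matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
    vox[, , k] <- pmax(slice, 0)
  }

  truth <- list(
    filaments = if (n_filaments > 0) dplyr::bind_rows(filaments) else
      tibble::tibble(filament = integer(0), orientation = numeric(0),
                     length_um = numeric(0), contained = logical(0),
                     brightness = numeric(0)),
    vertices = if (n_filaments > 0) dplyr::bind_rows(vertices) else
      tibble::tibble(filament = integer(0), x = numeric(0), y = numeric(0)),
    design = design, phase = phase, seed = seed
  )
  list(stack = image_stack(vox, pixel_size, z_spacing), truth = truth)
}

# wrapped-normal-like draw on [-90, 90), degrees; kappa = 0 -> uniform
draw_orientation <- function(kappa) {
  if (kappa == 0) return(stats::runif(1, -90, 90))
  a2 <- stats::rnorm(1, 0, 1 / sqrt(kappa))     # doubled angle, radians
  ang <- (a2 / 2) * 180 / pi
  ((ang + 90) %% 180) - 90
}

# smooth random centreline: straight run along direction theta (degrees
# from the vertical groove axis) plus a two-scale spline-smoothed transverse
# meander (~120 um wavelength at 25-50 um amplitude, ~40 um wavelength at
# cell-scale amplitude) emulating the multi-scale tortuosity of capillary
# networks; local tangents spread over roughly +/- 25 degrees
filament_centerline <- function(xc, yc, theta, len, amp, step = 8) {
  t <- seq(-len / 2, len / 2, by = step)
  th <- theta * pi / 180
  n1 <- max(4, round(len / 120))
  off <- stats::spline(seq(min(t), max(t), length.out = n1),
                       stats::rnorm(n1, 0, amp), xout = t)$y
  n2 <- max(4, round(len / 40))
  off <- off + stats::spline(seq(min(t), max(t), length.out = n2),
                             stats::rnorm(n2, 0, 9), xout = t)$y
  off <- pmin(pmax(off, -2 * amp), 2 * amp)
  x <- xc + t * sin(th) + off * cos(th)
  y <- yc + t * cos(th) - off * sin(th)
  tibble::tibble(x = x, y = y)
}

# mark centreline pixels (max-combine so crossings do not double intensity)
splat_centerline <- function(img, cl, value, pixel_size, nx, ny) {
  # resample densely at ~half-pixel spacing
  seglen <- sqrt(diff(cl$x)^2 + diff(cl$y)^2)
  s <- c(0, cumsum(seglen))
  ss <- seq(0, s[length(s)], by = pixel_size / 2)
  px <- ceiling(stats::approx(s, cl$x, xout = ss)$y / pixel_size)
  py <- ceiling(stats::approx(s, cl$y, xout = ss)$y / pixel_size)
  keep <- px >= 1 & px <= nx & py >= 1 & py <= ny
  idx <- unique(cbind(py[keep], px[keep]))
  if (nrow(idx) > 0) img[idx] <- pmax(img[idx], value)
  img
}

# Gaussian blur normalized so a 1-px-wide line of 1s keeps unit peak
blur_lines <- function(img, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  g <- stats::dnorm(-r:r, sd = sigma_px)
  g <- g / sum(g)
  k2 <- outer(g, g)
  out <- pmax(EBImage::filter2(img, k2, boundary = 0), 0)
  out / max(g)
}

# smooth low-order 2-D polynomial gradient in [0, 1]
background_gradient <- function(ny, nx) {
  u <- matrix(seq(0, 1, length.out = nx), ny, nx, byrow = TRUE)
  v <- matrix(seq(0, 1, length.out = ny), ny, nx)
  a <- stats::runif(6, -1, 1)
  g <- a[1] + a[2] * u + a[3] * v + a[4] * u * v + a[5] * u^2 + a[6] * v^2
  (g - min(g)) / max(max(g) - min(g), 1e-12)
}

#' Synthetic binary mask with components of exact pixel areas
#'
#' Places one compact connected component per requested area, none touching
#' (even diagonally), for testing particle-size filters.
#'
#' @param areas_px integer pixel areas, one component each.
#' @param image_size_px `c(width, height)` pixels.
#' @param pixel_size um per pixel.
#' @param seed integer seed.
#' @param max_tries placement retries per component before giving up.
#' @return A [binary_mask()].
#' @export
generate_particle_mask <- function(areas_px, image_size_px = c(256, 256),
                                   pixel_size = 2.3917, seed = 1,
                                   max_tries = 200) {
  set.seed(as.integer(seed))
  nx <- image_size_px[1]
  ny <- image_size_px[2]
  m <- matrix(FALSE, ny, nx)
  occupied <- matrix(FALSE, ny, nx)   # components dilated by 1 px
  for (a in areas_px) {
    stopifnot(a >= 1)
    blob <- compact_blob(a)           # offsets relative to a seed pixel
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      oy <- sample.int(ny, 1)
      ox <- sample.int(nx, 1)
      yy <- blob[, 1] + oy
      xx <- blob[, 2] + ox
      if (any(yy < 1 | yy > ny | xx < 1 | xx > nx)) next
      if (any(occupied[cbind(yy, xx)])) next
      m[cbind(yy, xx)] <- TRUE
      for (dy in -1:1) for (dx in -1:1) {
        y2 <- pmin(pmax(yy + dy, 1), ny)
        x2 <- pmin(pmax(xx + dx, 1), nx)
        occupied[cbind(y2, x2)] <- TRUE
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place a particle of ", a,
           " px without contact after ", max_tries, " tries")
    }
  }
  binary_mask(m, pixel_size)
}

# first `area` pixels of a spiral-of-rings growth: compact, 4-connected
compact_blob <- function(area) {
  r <- ceiling(sqrt(area))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[order(g$dy^2 + g$dx^2, abs(g$dy), g$dx), ]
  as.matrix(g[seq_len(area), c("dy", "dx")])
}
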