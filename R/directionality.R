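#' Fourier-spectrum orientation histogram
#'
#' Distribution of structure orientations in an image, computed from the 2-D
#' power spectrum: the image is apodized with a separable Hann window, the
#' spectral power of each frequency sample is accumulated into the orientation
#' bin of the spatial structure it represents (perpendicular to the frequency
#' vector), and the histogram is normalized to unit sum. The DC bin and the
#' lowest-frequency annulus (below 3 cycles per image) are excluded as
#' background residual, and only frequencies inside the inscribed Nyquist disc
#' are used so the pixel grid does not bias the angular distribution.
#'
#' Angles are measured from the groove axis (vertical after
#' [rotate_and_crop()]), counter-clockwise positive, on `[-90, 90)`.
#'
#' @param image an [image2d()], background-subtracted, at least 128 px in each
#'   dimension.
#' @param n_bins number of orientation bins over 180 degrees.
#' @return A tibble with columns `angle` (bin centres, degrees) and `weight`
#'   (non-negative, unit sum), class `orientation_histogram`.
#' @export
orientation_histogram <- function(image, n_bins = 90) {
  stopifnot(inherits(image, "image2d"), n_bins >= 18)
  px <- image$pixels
  ny <- nrow(px)
  nx <- ncol(px)
  if (ny < 128 || nx < 128) stop("image must be at least 128 px in each dimension")
  if (all(px == 0)) stop("all-zero image has no orientation content")
  w <- hann(ny) %o% hann(nx)
  P <- Mod(stats::fft(px * w))^2
  fy <- fft_freq(ny)           # cycles / px, matrix rows
  fx <- fft_freq(nx)           # cycles / px, matrix cols
  FY <- matrix(fy, ny, nx)
  FX <- matrix(fx, ny, nx, byrow = TRUE)
  fr <- sqrt(FX^2 + FY^2)
  # cycles per image (relative to the shorter side for the low-freq cut)
  cyc <- fr * min(ny, nx)
  # the low-frequency parts of the exact zero-frequency lines carry
  # frame-coherent row/column-mean structure (illumination, coverage
  # fluctuations) and window leakage, not oriented structure: excluded
  use <- cyc >= 3 & fr <= 0.5 &
    !(FY == 0 & cyc < 32) & !(FX == 0 & cyc < 32)
  # structure direction is perpendicular to the frequency vector; with the
  # y axis pointing down, a structure at +a degrees ccw from vertical puts
  # spectral energy along (fx, fy) || (cos a, sin a)
  ang <- atan2(FY[use], FX[use]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  pw <- P[use]
  width <- 180 / n_bins
  # soft binning: power splits linearly between the two nearest bin centres
  pos <- (ang + 90) / width - 0.5
  b0 <- floor(pos)
  f2 <- pos - b0
  bin0 <- (b0 %% n_bins) + 1
  bin1 <- ((b0 + 1) %% n_bins) + 1
  weight <- vapply(split(c(pw * (1 - f2), pw * f2),
                         factor(c(bin0, bin1), levels = seq_len(n_bins))),
                   sum, numeric(1))
  weight[is.na(weight)] <- 0
  weight <- weight / sum(weight)
  out <- tibble::tibble(angle = -90 + (seq_len(n_bins) - 0.5) * width,
                        weight = unname(weight))
  class(out) <- c("orientation_histogram", class(out))
  out
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

fft_freq <- function(n) {
  k <- 0:(n - 1)
  ((k + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' Degree of Alignment (DOA)
#'
#' Ratio of the orientation-histogram signal along the groove axis (0
#' degrees) to the signal perpendicular to it (90 degrees): 1 indicates
#' random alignment. Signals are the mean bin weights within
#' `window_deg` of 0 and of +/-90 (wrapped).
#'
#' @param hist an [orientation_histogram()].
#' @param window_deg half-width of the angular window, degrees.
#' @return A one-row tibble (`doa`, `signal_along`, `signal_perp`,
#'   `infinite`), class `doa_result`. A zero perpendicular signal yields an
#'   infinite-alignment sentinel (`doa = Inf`, `infinite = TRUE`), never a
#'   silent division.
#' @export
degree_of_alignment <- function(hist, window_deg = 2) {
  stopifnot(all(c("angle", "weight") %in% names(hist)), window_deg > 0)
  if (abs(sum(hist$weight) - 1) > 1e-9) stop("histogram must be normalized")
  d0 <- pmin(abs(hist$angle), 180 - abs(hist$angle))
  d90 <- abs(90 - abs(hist$angle))
  along <- mean(hist$weight[d0 <= window_deg])
  perp <- mean(hist$weight[d90 <= window_deg])
  inf <- perp <= 0
  out <- tibble::tibble(
    doa = if (inf) Inf else along / perp,
    signal_along = along, signal_perp = perp, infinite = inf
  )
  class(out) <- c("doa_result", class(out))
  out
}
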