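#' Groove-detection parameters
#'
#' The six tunable parameters of the depth-profile groove detector, with
#' the defaults used throughout the pipeline. Their roles in [detect_grooves()]:
#' `rolling_z_window` is the span of the rolling mean used to robustly
#' estimate the ridge level and depth range (and half of it is both the
#' edge-refinement search window and the interval merge distance);
#' `z_threshold` is the depth cut for candidate groove points, as a fraction
#' of the depth range; `slope_factor` gates edge refinement relative to the
#' steepest slope of the profile; `curvature` scales the smoothing span
#' (`curvature * rolling_z_window`); `depth_weighting` weights the curvature
#' term of the interval score and is the score floor below which intervals
#' are discarded; `line_width` is the width of the band averaged to measure
#' depth profiles in [depth_profile_from_stack()].
#'
#' @param line_width band width for depth profiles, um.
#' @param rolling_z_window rolling window, um.
#' @param z_threshold depth cut, fraction of depth range, in (0, 1].
#' @param slope_factor edge-slope gate, fraction of max slope, in (0, 1].
#' @param curvature smoothing span as a fraction of the rolling window.
#' @param depth_weighting curvature score weight and score floor.
#' @return A named list, class `groovej_params`.
#' @export
groovej_params <- function(line_width = 300, rolling_z_window = 100,
                           z_threshold = 0.5, slope_factor = 0.35,
                           curvature = 0.4, depth_weighting = 0.01) {
  stopifnot(line_width > 0, rolling_z_window > 0,
            z_threshold > 0, z_threshold <= 1,
            slope_factor > 0, slope_factor <= 1,
            curvature > 0, curvature <= 1,
            depth_weighting > 0, depth_weighting <= 1)
  structure(list(line_width = line_width,
                 rolling_z_window = rolling_z_window,
                 z_threshold = z_threshold, slope_factor = slope_factor,
                 curvature = curvature, depth_weighting = depth_weighting),
            class = "groovej_params")
}

#' Measure a depth profile from a Z-stack
#'
#' Averages intensity over a horizontal band of width `line_width` centred on
#' `line_y` (default: the vertical centre of the stack), per column and slice;
#' after subtracting each column's minimum slice intensity (out-of-focus
#' background is flat in Z), the depth at each x is the intensity-weighted
#' centroid of the Z column in um (`method = "argmax"` takes the brightest
#' slice instead). Columns whose total intensity falls below 1% of the median
#' column total are marked missing and linearly interpolated from neighbours;
#' more than 50% missing columns is an error.
#'
#' @param stack an [image_stack()].
#' @param params a [groovej_params()].
#' @param line_y band centre, um from the top of the image (default centre).
#' @param method `"centroid"` (default) or `"argmax"`.
#' @return A tibble with columns `x` (um) and `z` (um, depth down).
#' @export
depth_profile_from_stack <- function(stack, params = groovej_params(),
                                     line_y = NULL, method = c("centroid", "argmax")) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  d <- dim(stack$voxels)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  ps <- stack$pixel_size
  if (is.null(line_y)) line_y <- ny * ps / 2
  half <- params$line_width / 2
  rows <- which(abs((seq_len(ny) - 0.5) * ps - line_y) <= half)
  if (length(rows) == 0) stop("line_y outside the image")
  x <- (seq_len(nx) - 0.5) * ps
  zs <- slice_depths(stack)
  if (nz == 1) return(tibble::tibble(x = x, z = rep(zs, nx)))
  # band-averaged intensity: slices x columns
  s <- vapply(seq_len(nz),
              function(k) colMeans(stack$voxels[rows, , k, drop = FALSE]),
              numeric(nx))
  s <- t(s)                                   # nz x nx
  s <- sweep(s, 2, apply(s, 2, min), "-")
  # suppress the residual noise floor: keep the dominant Z response of each
  # column (the centroid is otherwise pulled toward mid-stack)
  cmax <- apply(s, 2, max)
  s[s < 0.25 * rep(cmax, each = nz)] <- 0
  tot <- colSums(s)
  missing <- tot < 0.01 * stats::median(tot)
  if (mean(missing) > 0.5) {
    stop("more than 50% of columns have no depth signal")
  }
  z <- if (method == "centroid") {
    colSums(s * zs) / tot
  } else {
    zs[apply(s, 2, which.max)]
  }
  z[missing] <- NA
  if (any(missing)) {
    z <- stats::approx(x[!missing], z[!missing], xout = x, rule = 2)$y
  }
  tibble::tibble(x = x, z = z)
}

#' Detect groove intervals in a depth profile
#'
#' Re-implementation of depth-profile groove detection: (1) the profile is
#' smoothed with a moving mean of span `curvature * rolling_z_window`;
#' (2) the ridge level and depth range are estimated robustly as the extremes
#' of a `rolling_z_window` moving mean; (3) candidate groove points are those
#' deeper than `z_threshold` times the depth range below the ridge level;
#' (4) each candidate-run edge snaps to the steepest-slope point within
#' `rolling_z_window / 2`, provided that slope reaches `slope_factor` times
#' the profile's maximum absolute slope; (5) intervals are scored as
#' normalized depth plus `depth_weighting` times normalized mean absolute
#' curvature, and intervals scoring below `depth_weighting` are discarded;
#' (6) intervals closer than `rolling_z_window / 2` are merged. A flat
#' profile (depth range below 1% of the rolling window) yields an empty
#' groove set.
#'
#' @param profile tibble with uniform `x` (um) and `z` (um, depth down).
#' @param params a [groovej_params()].
#' @return A tibble of half-open intervals `start`, `end` (um) with a `score`
#'   column and attribute `extent`.
#' @export
detect_grooves <- function(profile, params = groovej_params()) {
  stopifnot(all(c("x", "z") %in% names(profile)), nrow(profile) >= 8)
  dx <- diff(profile$x)
  if (max(dx) - min(dx) > 1e-6 * mean(dx)) stop("profile must be uniformly sampled")
  dx <- mean(dx)
  extent <- nrow(profile) * dx
  if (extent < 2 * params$rolling_z_window) {
    stop("profile extent must be at least twice the rolling window")
  }
  empty <- tibble::tibble(start = numeric(0), end = numeric(0),
                          score = numeric(0))

  zs <- moving_mean(profile$z, span_samples(params$curvature *
                                              params$rolling_z_window, dx))
  zr <- moving_mean(profile$z, span_samples(params$rolling_z_window, dx))
  ridge <- min(zr)
  rng <- max(zr) - ridge
  if (rng < 0.01 * params$rolling_z_window) {
    attr(empty, "extent") <- extent
    return(empty)
  }

  cand <- (zs - ridge) >= params$z_threshold * rng
  runs <- true_runs(cand)
  if (nrow(runs) == 0) {
    attr(empty, "extent") <- extent
    return(empty)
  }

  slope <- c(0, diff(zs)) / dx
  smax <- max(abs(slope))
  search <- max(1L, round(params$rolling_z_window / 2 / dx))
  n <- nrow(profile)
  snap <- function(j) {
    win <- max(1L, j - search):min(n, j + search)
    jb <- win[which.max(abs(slope[win]))]
    if (abs(slope[jb]) >= params$slope_factor * smax) jb else j
  }
  starts <- vapply(as.integer(runs$start), snap, numeric(1))
  ends <- vapply(as.integer(runs$end), snap, numeric(1))
  bad <- ends <= starts
  starts <- starts[!bad]; ends <- ends[!bad]
  if (length(starts) == 0) {
    attr(empty, "extent") <- extent
    return(empty)
  }

  # score: normalized depth + depth_weighting * normalized mean |curvature|
  curv <- abs(c(0, diff(zs, differences = 2), 0)) / dx^2
  cmax <- max(curv, 1e-12)
  iv <- purrr::map_dfr(seq_along(starts), function(i) {
    sel <- starts[i]:ends[i]
    tibble::tibble(
      start = profile$x[starts[i]] - dx / 2,
      end = profile$x[ends[i]] + dx / 2,
      score = mean(zs[sel] - ridge) / rng +
        params$depth_weighting * mean(curv[sel]) / cmax
    )
  })
  iv <- iv[iv$score >= params$depth_weighting, ]
  iv <- iv[order(iv$start), ]

  # merge overlapping intervals and gaps below rolling_z_window / 2
  merged <- list()
  for (i in seq_len(nrow(iv))) {
    if (length(merged) > 0 &&
        iv$start[i] - merged[[length(merged)]]$end <
          params$rolling_z_window / 2) {
      last <- merged[[length(merged)]]
      last$end <- max(last$end, iv$end[i])
      last$score <- max(last$score, iv$score[i])
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1]] <- iv[i, ]
    }
  }
  out <- dplyr::bind_rows(merged)
  out$start <- pmax(out$start, 0)
  out$end <- pmin(out$end, extent)
  out <- out[out$end > out$start, ]
  attr(out, "extent") <- extent
  out
}

span_samples <- function(span_um, dx) {
  k <- max(1L, round(span_um / dx))
  if (k %% 2 == 0) k <- k + 1L
  k
}

moving_mean <- function(z, k) {
  if (k <= 1) return(z)
  n <- length(z)
  h <- (k - 1) %/% 2
  zp <- c(rep(z[1], h), z, rep(z[n], h))
  cs <- c(0, cumsum(zp))
  (cs[(k + 1):(n + k)] - cs[1:n]) / k
}

true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' Vertically averaged signal profile
#'
#' Mean foreground fraction of each image column (grooves run vertically
#' after [rotate_and_crop()]), against position in um.
#'
#' @param mask a [binary_mask()] from the localization preprocessing path, or
#'   an [image2d()] to use grayscale intensities instead.
#' @return A tibble with columns `x` (um) and `value`, attribute `extent`.
#' @export
vertical_signal_profile <- function(mask) {
  stopifnot(inherits(mask, "binary_mask") || inherits(mask, "image2d"))
  px <- mask$pixels * 1
  out <- tibble::tibble(
    x = (seq_len(ncol(px)) - 0.5) * mask$pixel_size,
    value = colMeans(px)
  )
  attr(out, "extent") <- ncol(px) * mask$pixel_size
  out
}

#' Degree of Containment (DOC)
#'
#' Ratio of the average signal per unit length inside groove regions to that
#' outside: 1 indicates a uniform distribution of signal across the
#' cross-section. Lengths are measured as the summed sample spacing of the
#' profile points falling inside/outside the intervals, so a constant
#' profile gives exactly 1.
#'
#' @param profile tibble from [vertical_signal_profile()].
#' @param grooves groove interval tibble ([detect_grooves()] or
#'   [groove_truth()]).
#' @return A one-row tibble (`doc`, `in_groove_mean`, `outside_mean`,
#'   `groove_length`, `outside_length`, `infinite`, `undefined`), class
#'   `doc_result`. All signal inside grooves yields an infinite-containment
#'   sentinel; an empty groove set (flat design) yields `undefined = TRUE`.
#' @export
degree_of_containment <- function(profile, grooves) {
  stopifnot(all(c("x", "value") %in% names(profile)))
  inside <- in_grooves(profile$x, grooves)
  dx <- mean(diff(profile$x))
  glen <- sum(inside) * dx
  olen <- sum(!inside) * dx
  if (glen == 0 || olen == 0) {
    out <- tibble::tibble(doc = NA_real_, in_groove_mean = NA_real_,
                          outside_mean = NA_real_, groove_length = glen,
                          outside_length = olen, infinite = FALSE,
                          undefined = TRUE)
    class(out) <- c("doc_result", class(out))
    return(out)
  }
  gmean <- mean(profile$value[inside])
  omean <- mean(profile$value[!inside])
  inf <- omean <= 0 && gmean > 0
  out <- tibble::tibble(
    doc = if (inf) Inf else if (omean == 0) NA_real_ else gmean / omean,
    in_groove_mean = gmean, outside_mean = omean,
    groove_length = glen, outside_length = olen,
    infinite = inf, undefined = FALSE
  )
  class(out) <- c("doc_result", class(out))
  out
}
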