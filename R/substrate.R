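#' The seven substrate architectures
#'
#' Post-sintering (measured) dimensions of the patterned bioceramic
#' substrates: three concave/convex pairs built from two radii of curvature,
#' plus a flat control. Feature width is the opening of a groove (or footprint
#' of a ridge), periodicity the centre-to-centre spacing, depth the measured
#' groove depth (ridge height for convex designs). `designed_radius_um` keeps
#' the pre-shrinkage design radius as metadata only; all computations use the
#' measured values.
#'
#' @return A tibble with one row per architecture.
#' @export
substrate_designs <- function() {
  tibble::tribble(
    ~name,          ~feature_width, ~periodicity, ~depth, ~polarity, ~designed_radius_um,
    "large",        660,            1240,         300,    "concave", 400,
    "large_deep",   660,            1240,         585,    "concave", 400,
    "large_convex", 660,            1240,         300,    "convex",  400,
    "small",        330,            630,          150,    "concave", 200,
    "small_deep",   330,            630,          300,    "concave", 200,
    "small_convex", 330,            630,          150,    "convex",  200,
    "flat",         0,              0,            0,      "flat",    NA_real_
  )
}

#' Look up one substrate design
#'
#' @param name one of `"large"`, `"large_deep"`, `"large_convex"`, `"small"`,
#'   `"small_deep"`, `"small_convex"`, `"flat"`.
#' @return A one-row tibble (see [substrate_designs()]).
#' @export
#' @examples
#' make_design("large")
make_design <- function(name) {
  designs <- substrate_designs()
  if (!is.character(name) || length(name) != 1 || !name %in% designs$name) {
    stop("unknown design '", paste(name, collapse = ","),
         "'; valid designs: ", paste(designs$name, collapse = ", "))
  }
  designs[designs$name == name, ]
}

as_design <- function(design) {
  if (is.character(design)) return(make_design(design))
  stopifnot(is.data.frame(design), nrow(design) == 1,
            all(c("name", "feature_width", "periodicity", "depth",
                  "polarity") %in% names(design)))
  design
}

# Cross-section of one feature, depth below the ridge plane at signed
# distance d (um) from the feature centre. Elliptical dip of half-width
# width/2 and the measured depth; when depth exceeds width/2 the dip is a
# semicircle of radius width/2 sitting under vertical walls that make up the
# remaining depth.
feature_depth <- function(d, width, depth) {
  half <- width / 2
  z <- numeric(length(d))
  inside <- abs(d) < half
  if (depth >= half) {
    z[inside] <- (depth - half) + sqrt(pmax(half^2 - d[inside]^2, 0))
  } else {
    z[inside] <- depth * sqrt(pmax(1 - (d[inside] / half)^2, 0))
  }
  z
}

#' Analytic depth profile of a substrate design
#'
#' Surface depth below the ridge plane along the cross-sectional axis
#' (perpendicular to the grooves). Depth increases downward; ridge tops and
#' the flats of concave designs sit at z = 0. Concave designs are periodic
#' dips; convex designs are a base plane at `depth` minus periodic bumps
#' whose tops define z = 0. `phase` shifts the pattern laterally.
#'
#' @param design design name or one-row design tibble.
#' @param extent cross-sectional length, um.
#' @param sampling sample spacing, um (samples sit at pixel centres).
#' @param phase lateral shift of the pattern, um, in `[0, periodicity)`.
#' @return A tibble with columns `x` (um, pixel centres) and `z` (um, depth).
#' @export
#' @examples
#' depth_profile("large", extent = 2480, sampling = 2)
depth_profile <- function(design, extent, sampling = 2.3917, phase = 0) {
  design <- as_design(design)
  stopifnot(extent > 0, sampling > 0)
  if (design$polarity != "flat") {
    if (phase < 0 || phase >= design$periodicity) {
      stop("phase must lie in [0, periodicity)")
    }
    if (sampling > design$feature_width / 4) {
      stop("sampling of ", sampling, " um undersamples features of width ",
           design$feature_width, " um (need <= width/4)")
    }
  }
  n <- max(1L, floor(extent / sampling))
  x <- (seq_len(n) - 0.5) * sampling
  z <- profile_z(design, x, phase)
  tibble::tibble(x = x, z = z)
}

# depth at arbitrary positions x (um)
profile_z <- function(design, x, phase = 0) {
  design <- as_design(design)
  if (design$polarity == "flat") return(numeric(length(x)))
  p <- design$periodicity
  # feature centres at phase + p/2 + k p
  d <- ((x - phase) %% p) - p / 2
  f <- feature_depth(d, design$feature_width, design$depth)
  if (design$polarity == "concave") f else design$depth - f
}

#' Ground-truth groove intervals of a design
#'
#' Half-open intervals `[start, end)` (um) along the cross-sectional axis
#' marking groove regions: the dips of concave designs, and the regions
#' between convexities for convex designs. Partial intervals clipped at the
#' extent boundary are kept. Flat designs have no grooves.
#'
#' @inheritParams depth_profile
#' @return A tibble with columns `start`, `end` (um) and attribute `extent`.
#' @export
#' @examples
#' groove_truth("large", extent = 5740)
groove_truth <- function(design, extent, phase = 0) {
  design <- as_design(design)
  stopifnot(extent > 0)
  if (design$polarity == "flat") {
    out <- tibble::tibble(start = numeric(0), end = numeric(0))
    attr(out, "extent") <- extent
    return(out)
  }
  if (phase < 0 || phase >= design$periodicity) {
    stop("phase must lie in [0, periodicity)")
  }
  p <- design$periodicity
  w <- design$feature_width
  # feature spans: [phase + k p + (p - w)/2, + w)
  k <- seq(floor((-phase - (p - w) / 2) / p) - 1,
           ceiling((extent - phase) / p) + 1)
  fs <- phase + k * p + (p - w) / 2
  fe <- fs + w
  keep <- fe > 0 & fs < extent
  fs <- pmax(fs[keep], 0)
  fe <- pmin(fe[keep], extent)
  if (design$polarity == "concave") {
    out <- tibble::tibble(start = fs, end = fe)
  } else {
    # grooves are the complement of the bump spans
    edges <- sort(c(0, fs, fe, extent))
    starts <- utils::head(edges, -1)
    ends <- edges[-1]
    mid <- (starts + ends) / 2
    in_bump <- vapply(mid, function(m) any(m >= fs & m < fe), logical(1))
    out <- tibble::tibble(start = starts[!in_bump & ends > starts],
                          end = ends[!in_bump & ends > starts])
  }
  out <- out[out$end > out$start, ]
  out <- out[order(out$start), ]
  attr(out, "extent") <- extent
  out
}

#' Total groove / non-groove length of a groove set
#' @param grooves tibble from [groove_truth()] or [detect_grooves()].
#' @return named numeric vector `c(groove, outside)` in um.
#' @export
groove_lengths <- function(grooves) {
  extent <- attr(grooves, "extent")
  stopifnot(!is.null(extent))
  g <- sum(grooves$end - grooves$start)
  c(groove = g, outside = extent - g)
}

#' Membership of positions in groove intervals
#' @param x positions, um.
#' @param grooves groove interval tibble.
#' @return logical vector, TRUE where x falls inside a groove.
#' @export
in_grooves <- function(x, grooves) {
  if (nrow(grooves) == 0) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(grooves))) {
    out <- out | (x >= grooves$start[i] & x < grooves$end[i])
  }
  out
}

#' Read substrate designs from a plain-text config
#'
#' Each design is a YAML map entry with fields `feature_width`, `periodicity`,
#' `depth` and `polarity`, so new 2.5-D architectures can be added without
#' code changes.
#'
#' @param path YAML file path.
#' @return tibble like [substrate_designs()] (without design radius metadata).
#' @export
read_designs <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap_dfr(raw, function(d, nm) {
    tibble::tibble(
      name = nm,
      feature_width = as.numeric(d$feature_width),
      periodicity = as.numeric(d$periodicity),
      depth = as.numeric(d$depth),
      polarity = match.arg(d$polarity, c("concave", "convex", "flat")),
      designed_radius_um = if (is.null(d$designed_radius_um)) NA_real_
                           else as.numeric(d$designed_radius_um)
    )
  })
}
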