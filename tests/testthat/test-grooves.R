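test_that("groove detection recovers all six architectures from analytic profiles", {
  for (nm in c("large", "large_deep", "large_convex",
               "small", "small_deep", "small_convex")) {
    pr <- depth_profile(nm, 5740, sampling = 2.3917)
    det <- detect_grooves(pr)
    tr <- groove_truth(nm, 5740)
    expect_equal(nrow(det), nrow(tr), info = nm)
    cen_err <- abs((det$start + det$end) / 2 - (tr$start + tr$end) / 2)
    expect_lt(max(cen_err), 30)
    wid_err <- abs((det$end - det$start) - (tr$end - tr$start)) /
      (tr$end - tr$start)
    expect_lt(max(wid_err), 0.15)
    # sorted and disjoint
    expect_true(all(det$end > det$start))
    expect_true(all(diff(det$start) > 0))
    expect_true(all(utils::head(det$end, -1) <= det$start[-1]))
  }
})

test_that("flat profiles yield an empty groove set, not an error", {
  pr <- depth_profile("flat", 5740, sampling = 2.3917)
  det <- detect_grooves(pr)
  expect_equal(nrow(det), 0)
  expect_equal(attr(det, "extent"), nrow(pr) * 2.3917, tolerance = 3)

  noisy <- tibble::tibble(x = pr$x, z = stats::rnorm(nrow(pr), 0, 0.2))
  expect_equal(nrow(detect_grooves(noisy)), 0)
})

test_that("depth profiles from stacks recover the substrate relief", {
  sim <- generate_coculture_stack("large", n_filaments = 20,
                                  alignment_kappa = 0, containment_prob = 1,
                                  seed = 7)
  dp <- depth_profile_from_stack(sim$stack)
  gt <- groove_truth("large", 1200 * 2.3917)
  full <- gt[gt$end - gt$start > 600, ]
  centres <- (full$start + full$end) / 2
  rec <- stats::approx(dp$x, dp$z, xout = centres)$y
  expect_true(all(abs(rec - 300) < 0.6 * sim$stack$z_spacing))

  # a single-slice stack has a flat profile at that slice's depth
  one <- image_stack(array(runif(64 * 64), dim = c(64, 64, 1)), 1, 1,
                     z_origin = 12)
  dp1 <- depth_profile_from_stack(one)
  expect_true(all(dp1$z == 12))

  # flat substrate: negligible relief
  simf <- generate_coculture_stack("flat", n_filaments = 10, seed = 3)
  dpf <- depth_profile_from_stack(simf$stack)
  expect_lt(stats::sd(dpf$z), simf$stack$z_spacing)
})

test_that("vertical signal profiles average mask columns", {
  m <- matrix(FALSE, 10, 8)
  full <- binary_mask(!m, 2)
  expect_true(all(vertical_signal_profile(full)$value == 1))

  m[, 3] <- TRUE
  sp <- vertical_signal_profile(binary_mask(m, 2))
  expect_equal(sp$value, c(0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(sp$x, (1:8 - 0.5) * 2)
  expect_equal(attr(sp, "extent"), 16)
})

test_that("DOC follows its defining identities", {
  gt <- groove_truth("large", 5740)
  xs <- (1:2400 - 0.5) * (5740 / 2400)
  # constant profile: exactly 1 for any groove set
  cst <- tibble::tibble(x = xs, value = rep(0.37, 2400))
  r <- degree_of_containment(cst, gt)
  expect_equal(r$doc, 1)
  expect_false(r$undefined)

  # block profile: grooves spanning 2000 um hold mass 300, the 3740 um
  # outside holds 187 -> DOC = (300/2000)/(187/3740) = 3
  g2 <- tibble::tibble(start = 0, end = 2000)
  attr(g2, "extent") <- 5740
  dx <- 5740 / 2400
  inside <- xs < 2000
  v <- ifelse(inside, 300 / 2000, 187 / 3740)
  r2 <- degree_of_containment(tibble::tibble(x = xs, value = v), g2)
  expect_equal(r2$doc, 3, tolerance = 1e-12)
  expect_equal(r2$in_groove_mean * sum(inside) * dx, 300, tolerance = 1)

  # profile entirely inside grooves: infinite-containment sentinel
  v3 <- ifelse(inside, 1, 0)
  r3 <- degree_of_containment(tibble::tibble(x = xs, value = v3), g2)
  expect_true(r3$infinite)
  expect_identical(r3$doc, Inf)

  # no grooves at all: undefined, flagged
  g0 <- groove_truth("flat", 5740)
  r0 <- degree_of_containment(cst, g0)
  expect_true(r0$undefined)
  expect_true(is.na(r0$doc))

  # invariant under uniform scaling of the profile
  v4 <- stats::runif(2400)
  a <- degree_of_containment(tibble::tibble(x = xs, value = v4), gt)$doc
  b <- degree_of_containment(tibble::tibble(x = xs, value = v4 * 5), gt)$doc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("containment-1 masks concentrate signal mass inside grooves", {
  sim <- generate_coculture_stack("large", n_filaments = 20,
                                  alignment_kappa = 4, containment_prob = 1,
                                  seed = 9)
  sub <- rolling_ball_subtract(max_projection(sim$stack), 50)
  mask <- filter_small_particles(phansalkar_mask(autocontrast_to_8bit(sub)))
  sp <- vertical_signal_profile(mask)
  gt <- groove_truth("large", 1200 * 2.3917)
  mass_in <- sum(sp$value[in_grooves(sp$x, gt)])
  expect_gt(mass_in / sum(sp$value), 0.8)
})
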