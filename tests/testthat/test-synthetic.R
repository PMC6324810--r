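test_that("identical arguments and seed give bit-identical stacks", {
  a <- generate_coculture_stack("small", n_filaments = 6, alignment_kappa = 2,
                                containment_prob = 0.5,
                                image_size_px = c(256, 256), n_slices = 4,
                                seed = 11)
  b <- generate_coculture_stack("small", n_filaments = 6, alignment_kappa = 2,
                                containment_prob = 0.5,
                                image_size_px = c(256, 256), n_slices = 4,
                                seed = 11)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$filaments, b$truth$filaments)
  # a different seed changes the voxels
  c <- generate_coculture_stack("small", n_filaments = 6, alignment_kappa = 2,
                                containment_prob = 0.5,
                                image_size_px = c(256, 256), n_slices = 4,
                                seed = 12)
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("a stack with no filaments measures at the null references", {
  sim <- generate_coculture_stack("large", n_filaments = 0,
                                  image_size_px = c(512, 448), seed = 1)
  expect_equal(nrow(sim$truth$filaments), 0)
  expect_equal(nrow(sim$truth$vertices), 0)
  sub <- rolling_ball_subtract(max_projection(sim$stack), 50)
  # what survives segmentation is spatially unbiased noise: containment at
  # the uniform reference, alignment at the random reference
  d <- degree_of_alignment(orientation_histogram(sub))$doa
  expect_lt(abs(d - 1), 0.35)
  img8 <- suppressWarnings(autocontrast_to_8bit(sub))
  mask <- filter_small_particles(phansalkar_mask(img8))
  sp <- vertical_signal_profile(mask)
  gt <- groove_truth("large", 512 * 2.3917)
  expect_lt(abs(degree_of_containment(sp, gt)$doc - 1), 0.2)
})

test_that("containment-1 filaments stay inside groove intervals", {
  sim <- generate_coculture_stack("large", n_filaments = 20,
                                  alignment_kappa = 0, containment_prob = 1,
                                  seed = 7)
  gt <- groove_truth("large", 1200 * 2.3917)
  expect_true(all(in_grooves(sim$truth$vertices$x, gt)))
  expect_true(all(sim$truth$filaments$contained))
  # and under 10% of the rendered filament intensity (noise-free render)
  # falls outside the grooves: the Gaussian cross-profile tail only
  pure <- generate_coculture_stack("large", n_filaments = 20,
                                   alignment_kappa = 0, containment_prob = 1,
                                   seed = 7, snr = 1e9, substrate_glow = 0,
                                   background = 0, n_slices = 2)
  colmass <- colSums(max_projection(pure$stack)$pixels)
  xs <- (seq_along(colmass) - 0.5) * pure$stack$pixel_size
  expect_lt(sum(colmass[!in_grooves(xs, gt)]) / sum(colmass), 0.1)

  expect_error(
    generate_coculture_stack("flat", containment_prob = 0.5, seed = 1),
    "flat"
  )
})

test_that("orientation concentration behaves like a wrapped distribution", {
  # kappa = 0: uniform orientations (chi-square GoF aggregated over seeds)
  th <- unlist(lapply(1:40, function(s) {
    generate_coculture_stack("flat", n_filaments = 40, alignment_kappa = 0,
                             image_size_px = c(256, 256), n_slices = 2,
                             seed = s)$truth$filaments$orientation
  }))
  expect_true(all(th >= -90 & th < 90))
  counts <- table(cut(th, breaks = seq(-90, 90, by = 18)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # circular variance strictly decreasing in kappa
  cv <- vapply(c(0, 1, 4, 16), function(k) {
    th <- unlist(lapply(1:6, function(s) {
      generate_coculture_stack("flat", n_filaments = 40, alignment_kappa = k,
                               image_size_px = c(256, 256), n_slices = 2,
                               seed = 100 + s)$truth$filaments$orientation
    }))
    circular_variance(th)
  }, numeric(1))
  expect_true(all(diff(cv) < 0))
})

test_that("particle masks have exactly the requested component areas", {
  pm <- generate_particle_mask(c(50, 70, 100), c(256, 256), 2.3917, seed = 3)
  lab <- oracle_label_flood(pm$pixels)
  expect_equal(sort(tabulate(lab[lab > 0])), c(50, 70, 100))
  # 70 px at 2.3917 um/px is just over the 400 um2 cutoff
  expect_equal(70 * 2.3917^2, 400.5, tolerance = 1e-3)

  empty <- generate_particle_mask(numeric(0), c(64, 64), 1, seed = 1)
  expect_equal(sum(empty$pixels), 0)

  expect_error(
    generate_particle_mask(rep(400, 50), c(64, 64), 1, seed = 1, max_tries = 5),
    "could not place"
  )
})
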