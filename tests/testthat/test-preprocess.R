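test_that("maximum projection takes the per-pixel max over slices", {
  vox <- array(0, dim = c(4, 5, 3))
  vox[2, 3, ] <- c(1, 5, 2)
  vox[1, 1, 2] <- 7
  st <- image_stack(vox, 1, 1)
  mp <- max_projection(st)
  expect_equal(mp$pixels[2, 3], 5)
  expect_equal(mp$pixels[1, 1], 7)
  expect_equal(mp$pixels[4, 5], 0)

  one <- image_stack(array(runif(20), dim = c(4, 5, 1)), 1, 1)
  expect_equal(max_projection(one)$pixels, one$voxels[, , 1])

  zero <- image_stack(array(0, dim = c(4, 5, 2)), 1, 1)
  expect_true(all(max_projection(zero)$pixels == 0))
})

test_that("rotate_and_crop brings the groove axis to vertical", {
  # horizontal stripes rotated by 90 degrees become vertical structures
  ys <- matrix(rep(1:300, 300), 300, 300)
  horiz <- image2d(0.5 + 0.5 * sin(2 * pi * ys / 6), 1)
  rot <- rotate_and_crop(horiz, 90, c(200, 200))
  expect_equal(dim(rot$pixels), c(200, 200))
  # stripes are now constant along columns
  expect_equal(stats::sd(rot$pixels[, 1]), 0)
  h <- orientation_histogram(rot)
  expect_lt(abs(h$angle[which.max(h$weight)]), 2.5)

  # angle 0 is a pure centred crop (no interpolation)
  img <- image2d(matrix(runif(300 * 300), 300, 300), 1)
  cr <- rotate_and_crop(img, 0, c(200, 150))
  expect_identical(cr$pixels, img$pixels[76:225, 51:250])

  # a crop larger than the rotated valid region is rejected
  expect_error(rotate_and_crop(img, 45, c(280, 280)), "at least")

  # stripes at +30 degrees come to the reference axis
  xs <- matrix(rep(1:400, each = 400), 400, 400)
  ys <- matrix(rep(1:400, 400), 400, 400)
  th <- 30 * pi / 180
  st30 <- image2d(0.5 + 0.5 * sin(2 * pi * (xs * cos(th) + ys * sin(th)) / 16), 1)
  r30 <- rotate_and_crop(st30, 30, c(250, 250))
  h30 <- orientation_histogram(r30)
  expect_lt(abs(h30$angle[which.max(h30$weight)]), 5.1)
})

test_that("rolling-ball subtraction removes backgrounds, keeps thin lines", {
  # constant image: background fully removed
  cst <- image2d(matrix(0.5, 300, 300), 1)
  expect_lt(max(rolling_ball_subtract(cst, 50)$pixels), 1e-6 * 0.5)

  # narrow bright line preserved within 5% amplitude
  li <- matrix(0, 300, 300)
  li[, 150:152] <- 1
  rb <- rolling_ball_subtract(image2d(li, 1), 50)
  expect_gt(min(rb$pixels[100:200, 151]), 0.95)

  # adding a large smooth gradient barely changes the output
  u <- matrix(seq(0, 0.4, length.out = 300), 300, 300, byrow = TRUE)
  rb2 <- rolling_ball_subtract(image2d(li + u, 1), 50)
  expect_lt(max(abs(rb2$pixels - rb$pixels)), 0.1)

  # never exceeds the input
  set.seed(3)
  img <- image2d(matrix(runif(200 * 200), 200, 200), 1)
  out <- rolling_ball_subtract(img, 20)
  expect_true(all(out$pixels <= img$pixels + 1e-12))
  expect_true(all(out$pixels >= 0))

  # exact (unshrunk) construction agrees with a small-radius opening oracle
  li2 <- matrix(0, 80, 80)
  li2[, 40] <- 1
  ex <- rolling_ball_subtract(image2d(li2, 1), 10, shrink = 1)
  expect_gt(min(ex$pixels[20:60, 40]), 0.95)
})

test_that("auto-contrast maps tail quantiles to 0 and 255", {
  ramp <- image2d(matrix(seq(0, 1, length.out = 10000), 100, 100), 1)
  out <- autocontrast_to_8bit(ramp, 0.007)
  expect_true(all(out$pixels == round(out$pixels)))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  q <- stats::quantile(ramp$pixels, c(0.0035, 0.9965))
  # 35 px clipped at each end
  expect_equal(sum(ramp$pixels < q[1]), 35)
  expect_equal(sum(ramp$pixels > q[2]), 35)
  expect_true(all(out$pixels[ramp$pixels < q[1]] == 0))
  expect_true(all(out$pixels[ramp$pixels > q[2]] == 255))

  expect_warning(out0 <- autocontrast_to_8bit(image2d(matrix(1, 10, 10), 1)),
                 "constant")
  expect_true(all(out0$pixels == 0))
})

test_that("phansalkar_mask matches the literal per-pixel oracle", {
  # analytic case: constant normalized ~0.5 image is all foreground
  cst <- image2d(matrix(128, 40, 40), 1)
  I <- 128 / 255
  t_analytic <- I * (1 + 2 * exp(-10 * I) - 0.25)
  expect_lt(t_analytic, I)
  expect_true(all(phansalkar_mask(cst)$pixels))

  # all-zero image: nothing exceeds the zero threshold
  expect_false(any(phansalkar_mask(image2d(matrix(0, 40, 40), 1))$pixels))

  # oracle equivalence on random 8-bit images, disc and square windows
  for (s in 1:4) {
    set.seed(s)
    img <- image2d(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), 1)
    expect_identical(phansalkar_mask(img)$pixels, oracle_phansalkar(img))
  }
  set.seed(9)
  img <- image2d(matrix(sample(0:255, 48 * 48, TRUE), 48, 48), 1)
  m_sq <- phansalkar_mask(img, window = "square")
  expect_false(identical(m_sq$pixels, phansalkar_mask(img)$pixels))

  expect_error(phansalkar_mask(image2d(matrix(300, 20, 20), 1)), "8-bit")
})

test_that("particle filtering drops only sub-threshold components", {
  pm <- generate_particle_mask(c(50, 70, 100), c(256, 256), 2.3917, seed = 3)
  out <- filter_small_particles(pm, 400)
  lab <- oracle_label_flood(out$pixels)
  # 50 px = 286 um2 removed; 70 px = 400.5 um2 and 100 px kept
  expect_equal(sort(tabulate(lab[lab > 0])), c(70, 100))

  # idempotent, never grows foreground, never splits survivors
  twice <- filter_small_particles(out, 400)
  expect_identical(twice$pixels, out$pixels)
  expect_lte(sum(out$pixels), sum(pm$pixels))
  expect_equal(max(oracle_label_flood(out$pixels)), 2)

  empty <- binary_mask(matrix(FALSE, 32, 32), 2.3917)
  expect_equal(sum(filter_small_particles(empty)$pixels), 0)
})

test_that("component labeling is 8-connected and matches flood fill", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(c(1, 2, 3), c(1, 2, 3))] <- TRUE   # a diagonal chain: one component
  m[5, 5] <- TRUE
  lab <- label_components8(m)
  expect_equal(max(lab), 2)
  expect_equal(length(unique(lab[cbind(c(1, 2, 3), c(1, 2, 3))])), 1)

  set.seed(21)
  for (i in 1:3) {
    r <- matrix(runif(40 * 40) < 0.35, 40, 40)
    a <- label_components8(r)
    b <- oracle_label_flood(r)
    # same partition (labels may differ): the label cross-table must be a
    # permutation matrix pattern
    expect_equal(max(a), max(b))
    ct <- table(a[r], b[r])
    expect_true(all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1))
  }
})
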