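test_that("a straight phantom renders an axis-aligned column", {
  sp <- phantom_spec(curve_kind = "straight", noise_sigma = 0)
  b <- generate_phantom(sp)
  tm <- unclass(b$truth_mask)
  cols <- which(colSums(tm) > 0)
  # every mask row spans the same columns
  rows <- which(rowSums(tm) > 0)
  for (r in rows) expect_identical(which(tm[r, ]), cols)
  expect_true(all(abs(b$truth_curve$col - b$truth_curve$col[1]) < 1e-9))
  expect_identical(b$truth_angle_deg, 0)
})

test_that("phantom generation is bit-identical per seed", {
  sp <- phantom_spec(curve_kind = "circular_arc", arc_central_angle_deg = 30,
                     noise_sigma = 0.02, seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(as.vector(a$image), as.vector(b$image))
  c2 <- generate_phantom(phantom_spec(curve_kind = "circular_arc",
                                      arc_central_angle_deg = 30,
                                      noise_sigma = 0.02, seed = 43))
  expect_false(identical(as.vector(a$image), as.vector(c2$image)))
  # and it must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_phantom(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("truth angle equals half the central angle of a circular arc", {
  for (phi in c(5, 20, 40, 60, 90)) {
    sp <- phantom_spec(curve_kind = "circular_arc",
                       arc_central_angle_deg = phi, noise_sigma = 0)
    expect_equal(truth_angle(sp), phi / 2, tolerance = 1e-6)
  }
  expect_identical(truth_angle(phantom_spec(curve_kind = "straight")), 0)
})

test_that("cosine truth angle matches a dense supersampling oracle", {
  sp <- phantom_spec(curve_kind = "cosine", apex_deviation_px = 25,
                     noise_sigma = 0)
  a10 <- truth_angle(sp, supersample = 10)
  cv <- spinecobb:::phantom_curve(sp)
  r <- seq(cv$r0, cv$r1, length.out = 10001)
  oracle <- classify_scoliosis(center_curve(r, cv$col_of_row(r)),
                               min_dev_px = 0)$angle_deg
  expect_equal(a10, oracle, tolerance = 1e-4)
})

test_that("doubling the pixel geometry leaves the truth angle unchanged", {
  s1 <- phantom_spec(curve_kind = "circular_arc", arc_central_angle_deg = 37,
                     noise_sigma = 0)
  s2 <- phantom_spec(image_side = 512, curve_kind = "circular_arc",
                     arc_central_angle_deg = 37, vertebra_width_px = 56,
                     gap_px = 6, margin_px = 40, noise_sigma = 0)
  expect_equal(truth_angle(s1), truth_angle(s2), tolerance = 1e-6)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(fg_level = 0.2, bg_level = 0.8))
  expect_error(phantom_spec(arc_central_angle_deg = 150))
  # blocks wider than the frame walk out of it
  expect_error(generate_phantom(phantom_spec(curve_kind = "circular_arc",
                                             arc_central_angle_deg = 120,
                                             vertebra_width_px = 200)),
               "exits the frame")
})

test_that("the noiseless phantom's mask midline reproduces the analytic curve", {
  sp <- phantom_spec(curve_kind = "circular_arc", arc_central_angle_deg = 40,
                     noise_sigma = 0)
  b <- generate_phantom(sp)
  e <- canny_edges(b$truth_mask, 1)
  cv <- smooth_center_curve(repair_curve_tips(extract_center_curve(e, 0)), 5)
  tc <- approx(b$truth_curve$row, b$truth_curve$col, xout = cv$row, rule = 2)$y
  expect_lt(sqrt(mean((cv$col - tc)^2)), 1.0)
})
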