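make_label_map <- function(m) label_map(m)

test_that("spine label selection favors bright centered regions", {
  lab <- matrix(0L, 32, 32); lab[, 12:20] <- 1L
  img <- matrix(0.1, 32, 32); img[, 12:20] <- 0.9
  lm <- make_label_map(lab)
  expect_identical(select_spine_label(lm, radiograph(img)), 1L)

  single <- make_label_map(matrix(0L, 8, 8))
  expect_identical(select_spine_label(single, radiograph(matrix(0.5, 8, 8))), 0L)

  # bright at the edge loses to a dimmer centered region
  lab2 <- matrix(0L, 32, 32); lab2[, 1:4] <- 1L; lab2[, 14:18] <- 2L
  img2 <- matrix(0.05, 32, 32); img2[, 1:4] <- 0.95; img2[, 14:18] <- 0.5
  expect_identical(select_spine_label(make_label_map(lab2), radiograph(img2)), 2L)

  expect_identical(select_spine_label(lm, radiograph(img), override = 5), 5L)
})

test_that("spine mask keeps only the largest 4-connected component", {
  lab <- matrix(0L, 32, 32); lab[, 12:20] <- 1L
  m <- spine_binary_mask(make_label_map(lab), 1L)
  expect_identical(unclass(m)[, , drop = TRUE], lab == 1L)
  expect_identical(attr(m, "area"), sum(lab == 1L))

  # detached 3-pixel speck with the same label is removed
  lab[3, 28] <- 1L; lab[4, 28] <- 1L; lab[3, 29] <- 1L
  m2 <- spine_binary_mask(make_label_map(lab), 1L)
  expect_identical(attr(m2, "area"), 32L * 9L)
  expect_false(any(m2[, 28:29]))

  expect_error(spine_binary_mask(make_label_map(lab), 7L), "absent")
})

test_that("background subtraction recovers a fragmented column as one mask", {
  # column split into three labels (as vertebra-level segmentation does)
  lab <- matrix(0L, 48, 48)
  lab[5:18, 20:28] <- 1L; lab[19:30, 20:28] <- 2L; lab[31:44, 20:28] <- 3L
  img <- matrix(0.2, 48, 48); img[lab > 0] <- 0.8
  m <- background_subtraction_mask(make_label_map(lab), radiograph(img))
  expect_identical(unclass(m)[, , drop = TRUE], lab > 0)
})

test_that("Canny edges trace mask boundaries", {
  mask <- matrix(FALSE, 64, 64); mask[20:44, 25:39] <- TRUE
  e <- canny_edges(binary_mask(mask), sigma = 1)
  expect_true(any(e))
  # every edge pixel lies within 1 px of the mask boundary
  boundary <- mask & !(rbind(mask[-1, ], FALSE) & rbind(FALSE, mask[-64, ]) &
                       cbind(mask[, -1], FALSE) & cbind(FALSE, mask[, -64]))
  near <- boundary
  for (d in 1:2) {
    near <- near | rbind(near[-1, ], FALSE) | rbind(FALSE, near[-64, ]) |
            cbind(near[, -1], FALSE) | cbind(FALSE, near[, -64])
  }
  expect_true(all(near[e]))
  # interior rows show both walls
  expect_true(all(vapply(24:40, function(r) sum(e[r, ]) >= 2, logical(1))))

  # full-frame mask: edges only at the frame border
  ef <- canny_edges(binary_mask(matrix(TRUE, 32, 32)), sigma = 1)
  interior <- ef[4:29, 4:29]
  expect_false(any(interior))
  expect_true(any(ef))

  expect_error(canny_edges(binary_mask(matrix(FALSE, 4, 4))), "non-empty")
})

test_that("center curve is the wall midline with interpolated gaps", {
  e <- matrix(FALSE, 60, 200)
  e[10:50, 101] <- TRUE; e[10:50, 141] <- TRUE
  cv <- extract_center_curve(e, smooth_window = 0)
  expect_equal(cv$row, 9:49)
  expect_true(all(abs(cv$col - 120) < 1e-12))

  # slanted band with walls at col = r + 10 and r + 30 (0-based)
  e2 <- matrix(FALSE, 80, 200)
  for (r in 5:70) { e2[r + 1, r + 11] <- TRUE; e2[r + 1, r + 31] <- TRUE }
  cv2 <- extract_center_curve(e2, smooth_window = 3)
  expect_true(all(abs(cv2$col - (cv2$row + 20)) < 1e-9))  # MA keeps lines exact

  # three empty interior rows are filled on the line joining the neighbors
  e3 <- e
  e3[25:27, ] <- FALSE
  cv3 <- extract_center_curve(e3, smooth_window = 0)
  expect_equal(cv3$col[cv3$row %in% 24:26], rep(120, 3))

  expect_error(extract_center_curve(matrix(FALSE, 5, 5)), "2 rows")
})

test_that("a mirror-symmetric mask yields a center curve on its axis", {
  mask <- matrix(FALSE, 64, 65)
  for (r in 10:54) {
    w <- 8 + round(4 * sin((r - 10) / 10))
    mask[r, (33 - w):(33 + w)] <- TRUE
  }
  cv <- extract_center_curve(canny_edges(binary_mask(mask), 1), 0)
  expect_true(all(abs(cv$col - 32) <= 0.5))
})

test_that("smoothing never exceeds the local deviation within its window", {
  set.seed(2)
  x <- cumsum(rnorm(100))
  w <- 5
  sm <- spinecobb:::moving_average(x, w)
  for (i in seq_along(x)) {
    win <- x[max(1, i - w):min(length(x), i + w)]
    expect_lte(abs(sm[i] - x[i]), max(abs(win - x[i])) + 1e-12)
  }
})

test_that("tip repair brings the phantom mask curve within 1 px RMS of truth", {
  sp <- phantom_spec(curve_kind = "circular_arc", arc_central_angle_deg = 40,
                     noise_sigma = 0)
  b <- generate_phantom(sp)
  e <- canny_edges(b$truth_mask, 1)
  cv <- smooth_center_curve(repair_curve_tips(extract_center_curve(e, 0)), 5)
  truth_col <- approx(b$truth_curve$row, b$truth_curve$col, xout = cv$row,
                      rule = 2)$y
  rms <- sqrt(mean((cv$col - truth_col)^2))
  expect_lt(rms, 1.0)
})
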