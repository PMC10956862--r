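test_that("scanline families cover the image at every orientation", {
  sl <- orientation_scanlines(c(4, 4), orientation_set(1))
  expect_length(sl, 1)
  expect_length(sl[[1]], 4)
  expect_true(all(vapply(sl[[1]], nrow, integer(1)) == 4))
  expect_equal(sl[[1]][[1]][, "row"], rep(0, 4))

  sl2 <- orientation_scanlines(c(5, 7), orientation_set(2))
  expect_length(sl2, 2)
  # family at 0 deg runs along rows, family at 90 deg along columns
  expect_length(sl2[[1]], 5)
  expect_length(sl2[[2]], 7)

  # oblique: the 45-degree sample lattice leaves no pixel farther than one
  # lattice half-diagonal from a sample, and no pixel farther than half the
  # line spacing from a line
  sl45 <- orientation_scanlines(c(8, 8), orientation_set(4))[[2]]
  pts <- do.call(rbind, sl45)
  nv <- c(cospi(0.25), -sinpi(0.25))
  line_s <- vapply(sl45, function(m) (m[1, 1] - 3.5) * nv[1] +
                                     (m[1, 2] - 3.5) * nv[2], numeric(1))
  for (r in 0:7) for (cl in 0:7) {
    d2 <- (pts[, 1] - r)^2 + (pts[, 2] - cl)^2
    expect_lt(min(d2), 0.75^2)
    # perpendicular distance to the nearest scan line
    s <- (r - 3.5) * nv[1] + (cl - 3.5) * nv[2]
    expect_lte(min(abs(s - line_s)), 0.5 + 1e-9)
  }
})

test_that("displacement field pulls toward centers of mass", {
  # constant image: every line's CM is its midpoint, field points inward
  V <- lcm_displacement_field(matrix(0.5, 33, 33), orientation_set(4),
                              lcm_params(100, 1))
  ctr <- c(16, 16)
  for (p in list(c(5, 5), c(5, 28), c(28, 5), c(28, 28))) {
    v <- c(V$vr[p[1] + 1, p[2] + 1], V$vc[p[1] + 1, p[2] + 1])
    expect_gt(sum(v * (ctr - p)), 0)
  }
  # center pixel barely moves
  expect_lt(sqrt(V$vr[17, 17]^2 + V$vc[17, 17]^2), 0.5)

  # vertical bright stripe, horizontal scan: interior points pull to the
  # stripe's central column and stay within half-width + 0.5
  img <- matrix(0, 32, 32); img[, 13:21] <- 1
  V1 <- lcm_displacement_field(img, orientation_set(1), lcm_params(100, 1))
  inside <- V1$vc[, 13:21]
  expect_true(all(abs(inside) < 4.5 + 0.5))
  expect_true(all(V1$vc[, 13] > 0))   # left wall pulls right
  expect_true(all(V1$vc[, 21] < 0))   # right wall pulls left
  expect_true(all(abs(V1$vc[, 17]) < 0.5))
})

test_that("tracker convergence and clustering follow the field structure", {
  V0 <- list(vr = matrix(0, 16, 16), vc = matrix(0, 16, 16))
  lab0 <- converge_and_cluster(V0, iteration_schedule(10, 0, 2, 0.5))
  expect_identical(lab0$n_regions, 256L)

  # all trackers sent to one fixed point
  H <- 16
  V1 <- list(vr = 8 - matrix(0:(H - 1), H, H),
             vc = 8 - matrix(0:(H - 1), H, H, byrow = TRUE))
  lab1 <- converge_and_cluster(V1, iteration_schedule(30, 5, 2, 1))
  expect_identical(lab1$n_regions, 1L)

  # two attractors: labels match basin membership exactly
  W <- 32
  tc <- matrix(8, 16, W); tc[, 17:32] <- 24
  V2 <- list(vr = 8 - matrix(0:15, 16, W),
             vc = tc - matrix(0:(W - 1), 16, W, byrow = TRUE))
  lab2 <- converge_and_cluster(V2, iteration_schedule(30, 5, 2, 1))
  expect_identical(lab2$n_regions, 2L)
  expect_true(all(lab2$labels[, 1:16] == lab2$labels[1, 1]))
  expect_true(all(lab2$labels[, 17:32] == lab2$labels[1, 17]))

  expect_error(converge_and_cluster(list(vr = matrix(NaN, 2, 2),
                                         vc = matrix(0, 2, 2)),
                                    iteration_schedule(5, 0, 2, 1)),
               "finite")
})

test_that("a two-level image segments into exactly two regions at the step", {
  img <- cbind(matrix(0.2, 64, 32), matrix(0.8, 64, 32))
  lab <- segment_image(img, orientation_set(8), lcm_params(100, 1),
                       desk_schedule())
  expect_identical(lab$n_regions, 2L)
  boundary <- unlist(apply(lab$labels, 1, function(r) which(diff(r) != 0)))
  expect_true(all(abs(boundary - 32) <= 1))

  expect_identical(segment_image(matrix(0.5, 32, 32), orientation_set(4),
                                 lcm_params(100, 1),
                                 desk_schedule())$n_regions, 1L)
})

test_that("segmentation is deterministic and rotation-consistent", {
  img <- matrix(0.1, 32, 32)
  img[6:14, 8:16] <- 0.9; img[20:28, 18:26] <- 0.9
  o <- orientation_set(4); p <- lcm_params(300, 1)
  s <- iteration_schedule(50, 0, 2, 1)
  a <- segment_image(img, o, p, s)
  b <- segment_image(img, o, p, s)
  expect_identical(a$labels, b$labels)

  rot <- t(img)[ncol(img):1, ]
  lr <- segment_image(rot, o, p, s)
  ar <- t(a$labels)[ncol(a$labels):1, ]
  tab <- table(ar, lr$labels)
  expect_identical(a$n_regions, lr$n_regions)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("region count does not increase with looser merge or linkage scales", {
  img <- matrix(0.1, 32, 32)
  img[6:14, 8:16] <- 0.9; img[20:28, 18:26] <- 0.9
  o <- orientation_set(4); p <- lcm_params(300, 1)
  V <- lcm_displacement_field(img, o, p)
  n_eps <- vapply(c(0.5, 1, 2, 4), function(e)
    converge_and_cluster(V, iteration_schedule(50, 12, 2, e))$n_regions,
    integer(1))
  expect_true(all(diff(n_eps) <= 0))
  n_mr <- vapply(c(1, 2, 4), function(mr)
    converge_and_cluster(V, iteration_schedule(50, 12, mr, 1))$n_regions,
    integer(1))
  expect_true(all(diff(n_mr) <= 0))
})
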