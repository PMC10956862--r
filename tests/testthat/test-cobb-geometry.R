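test_that("curve endpoints are the topmost and bottommost samples", {
  cv <- center_curve(10:200, rep(50, 191))
  ep <- curve_endpoints(cv)
  expect_equal(ep$U, c(10, 50))
  expect_equal(ep$L, c(200, 50))

  cv3 <- center_curve(c(1, 5, 9), c(3, 4, 5))
  ep3 <- curve_endpoints(cv3)
  expect_equal(ep3$U, c(1, 3)); expect_equal(ep3$L, c(9, 5))

  expect_error(curve_endpoints(center_curve(1:2, c(0, 0))), "at least 3")
  expect_error(center_curve(c(1, 3, 2), c(0, 0, 0)), "increasing")
})

test_that("chord intersections record interior crossings", {
  arc <- arc_curve(40)
  ep <- curve_endpoints(arc)
  ch <- chord_intersections(arc, ep$U, ep$L)
  expect_equal(ch$M, ep$U); expect_equal(ch$N, ep$L)
  expect_length(ch$crossings, 0)

  # S-curve crosses its chord once mid-way
  r <- seq(0, 100, length.out = 201)
  scv <- center_curve(r, 50 + 10 * sinpi(r / 50))
  eps <- curve_endpoints(scv)
  chs <- chord_intersections(scv, eps$U, eps$L)
  expect_length(chs$crossings, 1)

  straight <- center_curve(r, rep(50, 201))
  eps2 <- curve_endpoints(straight)
  ch2 <- chord_intersections(straight, eps2$U, eps2$L)
  expect_true(all(ch2$offsets == 0))
})

test_that("the apex sits at the maximum deviation (and min_x agrees here)", {
  # symmetric arc: apex at the midpoint row
  arc <- arc_curve(40, chord = 200, r0 = 10)
  ep <- curve_endpoints(arc)
  C <- find_apex(arc, ep$U, ep$L)
  expect_equal(C[1], 110)

  # sinusoid with known extremum
  r <- 10:200
  cv <- center_curve(r, 120 - 20 * sin(pi * (r - 10) / 190))
  epc <- curve_endpoints(cv)
  Cc <- find_apex(cv, epc$U, epc$L)
  expect_equal(Cc, c(105, 100))
  expect_equal(find_apex(cv, epc$U, epc$L, rule = "min_x"), c(105, 100))

  straight <- center_curve(r, rep(120, length(r)))
  eps <- curve_endpoints(straight)
  expect_null(find_apex(straight, eps$U, eps$L))
})

test_that("perpendiculars from M and N intersect where the algebra says", {
  # worked case, points as (row, col) = (y, x): M=(0,0), N=(10,0) in x stays
  # on the chord row, apex offset -2
  M <- c(0, 0); N <- c(0, 10); C <- c(-2, 5)
  O <- perpendicular_intersection(M, N, C)
  expect_equal(O, c(12.5, 5), tolerance = 1e-12)

  # on a circle the intersection is the apex antipode
  th <- seq(-0.6, 0.6, length.out = 201)
  Mc <- c(sin(-0.6), cos(-0.6)); Nc <- c(sin(0.6), cos(0.6)); Cc <- c(0, 1)
  Oc <- perpendicular_intersection(Mc, Nc, Cc)
  expect_equal(Oc, c(0, -1), tolerance = 1e-9)

  expect_null(perpendicular_intersection(c(0, 0), c(0, 10), c(0, 5)))
})

test_that("the worked construction yields 43.60 and 136.40 degrees", {
  cons <- cobb_construction(L = c(0, 10), U = c(0, 0), M = c(0, 0),
                            N = c(0, 10), C = c(-2, 5), O = c(12.5, 5),
                            P = NULL, theta = NA)
  mon <- cobb_from_construction(cons, "mon")
  eq5 <- cobb_from_construction(cons, "eq5_printed")
  expect_equal(round(mon, 2), 43.60)
  expect_equal(round(eq5, 2), 136.40)
  expect_equal(mon + eq5, 180, tolerance = 1e-12)
})

test_that("the two printed conventions are exact supplements", {
  set.seed(31)
  for (k in 1:20) {
    arc <- arc_curve(runif(1, 10, 80), x0 = 150)
    res <- classify_scoliosis(arc, 1, "mon")
    res2 <- classify_scoliosis(arc, 1, "eq5_printed")
    expect_equal(res$angle_deg + res2$angle_deg, 180, tolerance = 1e-9)
  }
})

test_that("continuous circular arcs measure half their central angle", {
  for (phi in c(5, 15, 30, 45, 60, 75, 90)) {
    res <- classify_scoliosis(arc_curve(phi), min_dev_px = 0)
    expect_equal(res$angle_deg, phi / 2, tolerance = 1e-6)
  }
})

test_that("the measured angle is invariant to similarity transforms and mirroring", {
  arc <- arc_curve(50)
  base <- classify_scoliosis(arc, 1)$angle_deg
  # translation and uniform scaling
  t1 <- center_curve(arc$row * 2.5 + 40, arc$col * 2.5 - 13)
  expect_lt(abs(classify_scoliosis(t1, 1)$angle_deg - base), 1e-9)
  # small rotation (keeps rows increasing)
  a <- 4 * pi / 180
  rr <- cos(a) * (arc$row - 110) - sin(a) * (arc$col - 130) + 110
  cc <- sin(a) * (arc$row - 110) + cos(a) * (arc$col - 130) + 130
  expect_lt(abs(classify_scoliosis(center_curve(rr, cc), 1)$angle_deg - base),
            1e-9)
  # mirror about the (vertical) chord
  ep <- curve_endpoints(arc)
  expect_lt(abs(classify_scoliosis(
    center_curve(arc$row, 2 * ep$U[2] - arc$col), 1)$angle_deg - base), 1e-9)
})

test_that("larger apex deviation gives a strictly larger angle", {
  r <- seq(10, 200, length.out = 381)
  angles <- vapply(c(10, 20, 30, 40), function(d) {
    cv <- center_curve(r, 120 - d * sinpi((r - 10) / 190))
    classify_scoliosis(cv, 1)$angle_deg
  }, numeric(1))
  expect_true(all(diff(angles) > 0))
})

test_that("the no-scoliosis branch reports a zero angle", {
  r <- 10:200
  straight <- center_curve(r, rep(120, length(r)))
  res <- classify_scoliosis(straight, 3)
  expect_false(res$is_scoliosis)
  expect_identical(res$angle_deg, 0)
  expect_null(res$construction)

  bowed <- center_curve(r, 120 - 20 * sinpi((r - 10) / 190))
  resb <- classify_scoliosis(bowed, 3)
  expect_true(resb$is_scoliosis)
  expect_gt(resb$angle_deg, 0)

  slight <- center_curve(r, 120 - 2 * sinpi((r - 10) / 190))
  expect_false(classify_scoliosis(slight, 3)$is_scoliosis)
})
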