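# Geometric Cobb-angle construction on a center curve.
#
# All points are c(row, col) in the 0-based image frame. The construction:
# U and L are the curve's topmost and bottommost points; the chord UL
# intersects the curve at M (top) and N (bottom); the apex C is the curve
# point of maximum perpendicular deviation from the chord; perpendiculars
# to MC at M and to NC at N meet at O; P is the foot of the perpendicular
# from O onto line MN. The half-angle at O in right triangle MOP, doubled,
# is the reported angle (convention "mon", the angle MON); the alternative
# convention "eq5_printed" doubles the complementary half-angle
# atan(|OP|/|MP|) instead, and the two always sum to 180 degrees.

dot2 <- function(a, b) sum(a * b)
norm2 <- function(a) sqrt(sum(a * a))

# signed perpendicular distance of points (r, c) from the line a -> b
signed_offsets <- function(r, c, a, b) {
  d <- b - a
  len <- norm2(d)
  if (len == 0) stop("degenerate chord: identical endpoints")
  ((r - a[1]) * d[2] - (c - a[2]) * d[1]) / len
}

#' Endpoints of a center curve
#'
#' @param curve a `center_curve` (rows strictly increasing, >= 3 points).
#' @return list with `U` (topmost point) and `L` (bottommost point), each
#'   `c(row, col)`.
#' @export
curve_endpoints <- function(curve) {
  if (nrow(curve) < 3) stop("center curve must have at least 3 points")
  if (any(diff(curve$row) <= 0)) stop("center curve rows must be strictly increasing")
  list(U = c(curve$row[1], curve$col[1]),
       L = c(curve$row[nrow(curve)], curve$col[nrow(curve)]))
}

#' Chord-curve intersection points
#'
#' Computes the signed perpendicular offset of every curve point from the
#' chord UL. The endpoints themselves are exact zeros, so the topmost
#' crossing M coincides with U and the bottommost crossing N with L;
#' interior sign changes (an S-shaped curve crossing its own chord) are
#' recorded in the `"crossings"` attribute for diagnostics.
#'
#' @param curve a `center_curve`.
#' @param U,L endpoints from [curve_endpoints].
#' @return list with `M`, `N` and attribute-style entry `crossings`
#'   (0-based indices into the curve where the offset changes sign).
#' @export
chord_intersections <- function(curve, U, L) {
  off <- signed_offsets(curve$row, curve$col, U, L)
  s <- sign(off)
  n <- length(s)
  zeros <- which(s == 0)
  zeros <- zeros[zeros > 1 & zeros < n]
  flips <- which(s[-1] * s[-n] < 0)
  list(M = U, N = L, offsets = off,
       crossings = sort(unique(c(zeros, flips))))
}

#' Apex of the curve between M and N
#'
#' Default rule `max_dev`: the curve point maximizing the absolute
#' perpendicular deviation from the chord MN (ties broken by smaller row).
#' Rule `min_x`: the literal smallest-column point (appropriate only for
#' curves bowing toward lower column values).
#'
#' @param curve a `center_curve`.
#' @param M,N chord points.
#' @param rule `"max_dev"` (default) or `"min_x"`.
#' @param refine if `TRUE`, relocate the apex to the vertex of a parabola
#'   fitted to the deviation profile around the raw maximum. The deviation
#'   profile of a smooth bow is flat near its peak, so the raw argmax
#'   wanders by many rows under sub-pixel midline noise while the fitted
#'   vertex stays put; the returned point is the curve sample nearest the
#'   vertex row.
#' @param refine_window half-width (in curve samples) of the refinement fit.
#' @return apex point `c(row, col)`, or `NULL` when the curve is straight
#'   (zero maximum deviation).
#' @export
find_apex <- function(curve, M, N, rule = c("max_dev", "min_x"),
                      refine = FALSE, refine_window = 20) {
  rule <- match.arg(rule)
  if (rule == "max_dev") {
    off <- abs(signed_offsets(curve$row, curve$col, M, N))
    if (max(off) == 0) return(NULL)
    i <- which(off == max(off))[1]        # earliest row on ties
    if (refine) {
      idx <- max(1, i - refine_window):min(length(off), i + refine_window)
      if (length(idx) >= 5) {
        r0 <- curve$row[i]
        fit <- stats::lm.fit(cbind(1, curve$row[idx] - r0,
                                   (curve$row[idx] - r0)^2), off[idx])
        cf <- fit$coefficients
        if (is.finite(cf[3]) && cf[3] < 0) {
          vertex <- r0 - cf[2] / (2 * cf[3])
          vertex <- min(max(vertex, curve$row[idx[1]]),
                        curve$row[idx[length(idx)]])
          i <- which.min(abs(curve$row - vertex))
        }
      }
    }
  } else {
    i <- which(curve$col == min(curve$col))[1]
  }
  c(curve$row[i], curve$col[i])
}

#' Intersection of the perpendiculars raised at M and N
#'
#' O is the unique point with (O - M) perpendicular to (C - M) and
#' (O - N) perpendicular to (C - N).
#'
#' @param M,N,C pairwise distinct, non-collinear points `c(row, col)`.
#' @return point O, or `NULL` when M, C, N are collinear (parallel
#'   perpendiculars: the straight-spine signal).
#' @export
perpendicular_intersection <- function(M, N, C) {
  a <- rbind(C - M, C - N)
  b <- c(dot2(C - M, M), dot2(C - N, N))
  det <- a[1, 1] * a[2, 2] - a[1, 2] * a[2, 1]
  if (abs(det) < 1e-12 * max(1, norm2(C - M) * norm2(C - N))) return(NULL)
  as.vector(solve(a, b))
}

#' Cobb construction container
#'
#' @param L,U,M,N,C,O,P construction points `c(row, col)`.
#' @param theta half-angle at O in degrees.
#' @export
cobb_construction <- function(L, U, M, N, C, O, P, theta) {
  structure(list(L = L, U = U, M = M, N = N, C = C, O = O, P = P,
                 theta = theta), class = "cobb_construction")
}

#' Cobb angle from a construction
#'
#' P is the foot of the perpendicular from O onto line MN. Convention
#' `"mon"` (default) reports the angle MON as `2 * atan(|MP| / |OP|)`;
#' convention `"eq5_printed"` reports `2 * atan(|OP| / |MP|)`, its
#' supplement.
#'
#' @param cons a [cobb_construction] (the `theta`/`P` slots are recomputed).
#' @param convention `"mon"` or `"eq5_printed"`.
#' @return angle in degrees.
#' @export
cobb_from_construction <- function(cons, convention = c("mon", "eq5_printed")) {
  convention <- match.arg(convention)
  M <- cons$M; N <- cons$N; O <- cons$O
  d <- (N - M) / norm2(N - M)
  t <- dot2(O - M, d)
  P <- M + t * d
  MP <- norm2(P - M)
  OP <- norm2(O - P)
  if (OP == 0) stop("degenerate construction: O lies on the chord MN")
  ang <- if (convention == "mon") 2 * atan2(MP, OP) else 2 * atan2(OP, MP)
  ang * 180 / pi
}

#' Classify a center curve and measure its Cobb angle
#'
#' When the maximum perpendicular deviation of the curve from its chord UL
#' is below `min_dev_px` the image is labelled "no scoliosis" and the angle
#' is reported as 0 without building the construction; otherwise the full
#' chord / apex / perpendicular construction is carried out.
#'
#' @param curve a `center_curve`.
#' @param min_dev_px deviation threshold in pixels (default 3 at 256x256).
#' @param convention angle convention, `"mon"` (default) or `"eq5_printed"`.
#' @param apex_rule apex rule passed to [find_apex].
#' @param apex_refine parabolic apex refinement (see [find_apex]); on by
#'   default, which stabilizes the angle on curves with flat deviation
#'   peaks measured from noisy masks.
#' @return a `cobb_result`: list with `angle_deg`, `is_scoliosis`,
#'   `convention`, `construction` (a [cobb_construction] or `NULL`) and
#'   `chord_crossings` (interior crossing count, S-curve diagnostic).
#' @export
classify_scoliosis <- function(curve, min_dev_px = 3,
                               convention = c("mon", "eq5_printed"),
                               apex_rule = c("max_dev", "min_x"),
                               apex_refine = TRUE) {
  convention <- match.arg(convention)
  apex_rule <- match.arg(apex_rule)
  ep <- curve_endpoints(curve)
  off <- signed_offsets(curve$row, curve$col, ep$U, ep$L)
  no_sc <- function() {
    structure(list(angle_deg = 0, is_scoliosis = FALSE,
                   convention = convention, construction = NULL,
                   chord_crossings = 0L), class = "cobb_result")
  }
  if (max(abs(off)) < min_dev_px) return(no_sc())
  ch <- chord_intersections(curve, ep$U, ep$L)
  C <- find_apex(curve, ch$M, ch$N, rule = apex_rule, refine = apex_refine)
  if (is.null(C)) return(no_sc())
  O <- perpendicular_intersection(ch$M, ch$N, C)
  if (is.null(O)) return(no_sc())
  d <- (ch$N - ch$M) / norm2(ch$N - ch$M)
  P <- ch$M + dot2(O - ch$M, d) * d
  cons <- cobb_construction(L = ep$L, U = ep$U, M = ch$M, N = ch$N,
                            C = C, O = O, P = P, theta = NA_real_)
  ang <- cobb_from_construction(cons, convention)
  cons$theta <- ang / 2
  structure(list(angle_deg = ang, is_scoliosis = TRUE,
                 convention = convention, construction = cons,
                 chord_crossings = length(ch$crossings)),
            class = "cobb_result")
}

#' @export
print.cobb_result <- function(x, ...) {
  cat(sprintf("<cobb_result %s: %s, angle %.2f deg (%s)>\n",
              if (x$is_scoliosis) "scoliosis" else "no scoliosis",
              if (x$is_scoliosis) "measured" else "below deviation threshold",
              x$angle_deg, x$convention))
  invisible(x)
}
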