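#' Orientation set for 2D LCM segmentation
#'
#' K angles evenly spaced over \[0, 180) degrees (resolution 180/K). Angle 0
#' scans along rows (horizontal lines); angle 90 scans along columns.
#'
#' @param K number of orientations (default 180, i.e. 1 degree resolution;
#'   K = 8 is the documented desk-scale configuration).
#' @return object of class `orientation_set` with `angles` (degrees) and a
#'   K x 2 matrix `units` of (d_row, d_col) unit vectors.
#' @export
orientation_set <- function(K = 180) {
  stopifnot(K >= 1)
  angles <- (seq_len(K) - 1) * 180 / K
  units <- cbind(d_row = sinpi(angles / 180), d_col = cospi(angles / 180))
  structure(list(K = as.integer(K), angles = angles, units = units),
            class = "orientation_set")
}

# Rotated sampling grid covering the image for one scan angle.
# u = unit vector along the scanline, nv = unit normal (line spacing axis).
# Sample (i, j) of the grid lies at cc + s_i * nv + t_j * u, with s and t on
# unit-step ladders spanning the projections of the image corners; for
# axis-aligned angles the samples coincide exactly with the pixel grid.
rotated_grid <- function(shape, angle_deg) {
  H <- shape[1]; W <- shape[2]
  u  <- c(sinpi(angle_deg / 180), cospi(angle_deg / 180))
  nv <- c(cospi(angle_deg / 180), -sinpi(angle_deg / 180))
  cc <- c((H - 1) / 2, (W - 1) / 2)
  corners <- rbind(c(0, 0), c(0, W - 1), c(H - 1, 0), c(H - 1, W - 1))
  corners <- sweep(corners, 2, cc)
  tp <- corners %*% u
  sp <- corners %*% nv
  # unit-step ladders centered on the projection origin, so the sample set
  # is symmetric under image rotation/reflection; for axis-aligned angles
  # they coincide exactly with the pixel grid
  ladder <- function(lo, hi) {
    off <- (hi - lo - floor(hi - lo)) / 2
    seq(lo + off, hi, by = 1)
  }
  t_vals <- ladder(min(tp), max(tp))
  s_vals <- ladder(min(sp), max(sp))
  list(u = u, nv = nv, cc = cc, t_vals = t_vals, s_vals = s_vals)
}

#' Scanline geometry per orientation
#'
#' Materializes, for each angle, the family of parallel lines at unit pixel
#' spacing covering the image; each line is a matrix of (row, col) sample
#' points (0-based, possibly off-grid for oblique angles).
#'
#' @param shape `c(rows, cols)` of the image.
#' @param orient an [orientation_set].
#' @return list (one element per angle) of lists of n x 2 sample matrices.
#' @export
orientation_scanlines <- function(shape, orient = orientation_set()) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  lapply(orient$angles, function(a) {
    g <- rotated_grid(shape, a)
    lapply(g$s_vals, function(s) {
      r <- g$cc[1] + s * g$nv[1] + g$t_vals * g$u[1]
      c <- g$cc[2] + s * g$nv[2] + g$t_vals * g$u[2]
      keep <- r > -0.5 & r < shape[1] - 0.5 & c > -0.5 & c < shape[2] - 0.5
      cbind(row = r[keep], col = c[keep])
    })
  })
}

# Vectorized bilinear sampling of matrix `mat` at 0-based coordinates (r, c).
# Points outside [0, H-1] x [0, W-1] get `fill`.
bilinear_sample <- function(mat, r, c, fill = NA_real_) {
  H <- nrow(mat); W <- ncol(mat)
  inside <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
  r <- pmin(pmax(r, 0), H - 1)
  c <- pmin(pmax(c, 0), W - 1)
  r0 <- pmin(floor(r), H - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(c), W - 2); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + 1 + c0 * H
  v <- (1 - fr) * (1 - fc) * mat[i00] +
       fr       * (1 - fc) * mat[i00 + 1] +
       (1 - fr) * fc       * mat[i00 + H] +
       fr       * fc       * mat[i00 + H + 1]
  v[!inside] <- fill
  v
}

#' Per-pixel LCM displacement field
#'
#' For each orientation, intensities are sampled bilinearly along every
#' scanline, the linear-time 1D LCM is run on the in-image segment of each
#' line, and `C - n` becomes a signed displacement along the line's unit
#' vector, mapped back to the pixel grid. The field is the mean of the K
#' per-orientation displacement vectors.
#'
#' @param img a [radiograph] or \[0,1\] matrix.
#' @param orient an [orientation_set].
#' @param params an [lcm_params].
#' @return list with `vr`, `vc`: numeric matrices (rows x cols) holding the
#'   row/col components of the displacement field (pixels).
#' @export
lcm_displacement_field <- function(img, orient = orientation_set(),
                                   params = lcm_params()) {
  px <- as_pixel_matrix(img)
  H <- nrow(px); W <- ncol(px)
  vr <- matrix(0, H, W); vc <- matrix(0, H, W)
  pix_r <- matrix(0:(H - 1), H, W)
  pix_c <- matrix(0:(W - 1), H, W, byrow = TRUE)
  for (k in seq_len(orient$K)) {
    g <- rotated_grid(c(H, W), orient$angles[k])
    ns <- length(g$s_vals); nt <- length(g$t_vals)
    gr <- g$cc[1] + outer(g$s_vals * g$nv[1], g$t_vals * g$u[1], "+")
    gc <- g$cc[2] + outer(g$s_vals * g$nv[2], g$t_vals * g$u[2], "+")
    F <- matrix(bilinear_sample(px, as.vector(gr), as.vector(gc)), ns, nt)
    disp <- matrix(0, ns, nt)
    for (i in seq_len(ns)) {
      ok <- which(is.finite(F[i, ]))
      if (length(ok) >= 2) {
        a <- ok[1]; b <- ok[length(ok)]
        D <- cumulative_edge_energy(F[i, a:b], params)
        disp[i, a:b] <- lcm_from_energy(D) - seq_len(b - a + 1)
      }
    }
    # map pixels back into the rotated frame and sample the displacement
    tp <- (pix_r - g$cc[1]) * g$u[1]  + (pix_c - g$cc[2]) * g$u[2]
    sp <- (pix_r - g$cc[1]) * g$nv[1] + (pix_c - g$cc[2]) * g$nv[2]
    d <- bilinear_sample(disp, as.vector(sp - g$s_vals[1]),
                         as.vector(tp - g$t_vals[1]), fill = 0)
    d <- matrix(d, H, W)
    vr <- vr + d * g$u[1]
    vc <- vc + d * g$u[2]
  }
  list(vr = vr / orient$K, vc = vc / orient$K)
}

#' Iteration schedule for tracker convergence
#'
#' @param t_total total iterations (default 1000, the reported optimum).
#' @param t_phase2 trailing iterations run in phase-2 consolidation mode
#'   (default 250, as reported).
#' @param merge_radius phase-2 neighborhood radius in pixels (default 2).
#' @param cluster_eps single-linkage distance for final labelling (default 1).
#' @export
iteration_schedule <- function(t_total = 1000, t_phase2 = 250,
                               merge_radius = 2, cluster_eps = 1) {
  stopifnot(t_phase2 >= 0, t_phase2 <= t_total, merge_radius > 0,
            cluster_eps >= 0)
  structure(list(t_total = as.integer(t_total), t_phase2 = as.integer(t_phase2),
                 merge_radius = merge_radius, cluster_eps = cluster_eps),
            class = "iteration_schedule")
}

#' Desk-scale iteration schedule
#'
#' Reduced configuration (paired with K = 8 orientations) for interactive
#' use and testing; fewer orientations and iterations are the documented
#' route to runtime reduction.
#' @export
desk_schedule <- function() iteration_schedule(t_total = 50, t_phase2 = 12,
                                               merge_radius = 2, cluster_eps = 1)

# collapse tracker positions on a grid of pitch `res` to weighted unique
# points; returns unique coords, weights, and the tracker -> unique map
collapse_points <- function(pr, pc, w = NULL, res = 1e-3) {
  kr <- round(pr / res); kc <- round(pc / res)
  key <- kr + (kc - min(kc)) * (max(kr) - min(kr) + 1)
  uk <- unique(key)
  f <- match(key, uk)
  if (is.null(w)) w <- rep(1, length(pr))
  ws <- as.vector(rowsum(w, f))
  ur <- as.vector(rowsum(w * pr, f)) / ws
  uc <- as.vector(rowsum(w * pc, f)) / ws
  list(r = ur, c = uc, w = ws, map = f)
}

# all index pairs (i, j) with distance <= radius, via integer cell hashing
radius_pairs <- function(x, y, radius) {
  cell <- max(radius, 1e-9)
  cx <- floor(x / cell) - floor(min(x) / cell) + 1L
  cy <- floor(y / cell) - floor(min(y) / cell) + 1L
  nx <- max(cx) + 2L
  key <- cx + cy * nx
  o <- order(key)
  ks <- key[o]
  starts <- c(1L, which(diff(ks) != 0) + 1L)
  uk <- ks[starts]
  lens <- diff(c(starts, length(ks) + 1L))
  acc <- vector("list", 9); t <- 0
  for (dx in -1:1) for (dy in -1:1) {
    t <- t + 1
    m <- match(key + dx + dy * nx, uk)
    ok <- which(!is.na(m))
    if (!length(ok)) next
    li <- lens[m[ok]]
    i <- rep(ok, li)
    j <- o[sequence(li, from = starts[m[ok]])]
    keep <- (x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2
    acc[[t]] <- cbind(i[keep], j[keep])
  }
  mm <- do.call(rbind, acc)
  list(i = mm[, 1], j = mm[, 2])
}

#' Converge tracker points through a displacement field and cluster them
#'
#' Phase 1: one tracker per pixel follows `x <- x + V(x)` (bilinear field
#' interpolation, positions clamped to the image) for `t_total - t_phase2`
#' steps. Phase 2: for `t_phase2` steps each tracker moves to the weighted
#' mean of all trackers within `merge_radius` of it (mode-seeking
#' consolidation; near-coincident trackers are pooled at `merge_radius/4`
#' resolution first, which keeps the step exact to a quarter cell while
#' bounding its cost). Labelling is single linkage constrained to the
#' pixel grid: 4-adjacent pixels whose converged trackers lie within
#' `cluster_eps` of each other share a label, so a spatially connected
#' region whose trackers settle along a chain of nearby modes (the medial
#' structure of an elongated region) stays one label, while neighbors
#' whose trackers diverge to distant attractors are separated.
#'
#' @param V field as returned by [lcm_displacement_field].
#' @param sched an [iteration_schedule].
#' @return a `label_map`: list with `labels` (integer matrix, labels are
#'   consecutive integers starting at 0) and `n_regions`.
#' @export
converge_and_cluster <- function(V, sched = iteration_schedule()) {
  if (!all(is.finite(V$vr)) || !all(is.finite(V$vc)))
    stop("displacement field must be finite")
  H <- nrow(V$vr); W <- ncol(V$vr)
  pr <- as.vector(matrix(0:(H - 1), H, W))
  pc <- as.vector(matrix(0:(W - 1), H, W, byrow = TRUE))
  for (it in seq_len(sched$t_total - sched$t_phase2)) {
    dr <- bilinear_sample(V$vr, pr, pc, fill = 0)
    dc <- bilinear_sample(V$vc, pr, pc, fill = 0)
    pr <- pmin(pmax(pr + dr, 0), H - 1)
    pc <- pmin(pmax(pc + dc, 0), W - 1)
  }
  if (sched$t_phase2 > 0) {
    res <- sched$merge_radius / 4
    cp <- collapse_points(pr, pc, res = res)
    assign <- cp$map
    for (it in seq_len(sched$t_phase2)) {
      pp <- radius_pairs(cp$r, cp$c, sched$merge_radius)
      wj <- cp$w[pp$j]
      denom <- as.vector(rowsum(wj, pp$i))
      nr <- as.vector(rowsum(wj * cp$r[pp$j], pp$i)) / denom
      nc <- as.vector(rowsum(wj * cp$c[pp$j], pp$i)) / denom
      cp2 <- collapse_points(nr, nc, cp$w, res = res)
      assign <- cp2$map[assign]
      cp <- cp2
      if (length(cp$r) == 1) break
    }
    pr <- cp$r[assign]
    pc <- cp$c[assign]
  }
  label_map(spatial_linkage_labels(pr, pc, H, W, sched$cluster_eps))
}

# label pixels by single linkage over the 4-neighbor grid graph, linking
# two adjacent pixels when their tracker endpoints are within eps
spatial_linkage_labels <- function(er, ec, H, W, eps) {
  n <- H * W
  idx <- seq_len(n)
  eps2 <- eps^2
  # vertical neighbors (within a column of the column-major layout)
  k <- idx[(idx - 1) %% H < H - 1]
  okv <- (er[k] - er[k + 1])^2 + (ec[k] - ec[k + 1])^2 <= eps2
  # horizontal neighbors
  k2 <- idx[idx <= H * (W - 1)]
  okh <- (er[k2] - er[k2 + H])^2 + (ec[k2] - ec[k2 + H])^2 <= eps2
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(c(k[okv], k2[okh]),
                                  c(k[okv] + 1L, k2[okh] + H)))
  comp <- igraph::components(g)$membership
  lab <- match(comp, unique(comp)) - 1L
  matrix(as.integer(lab), H, W)
}

#' Label map constructor
#' @param labels integer matrix of 0-based region labels (consecutive).
#' @export
label_map <- function(labels) {
  stopifnot(is.matrix(labels))
  structure(list(labels = labels, n_regions = length(unique(as.vector(labels)))),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map %d x %d, %d regions>\n",
              nrow(x$labels), ncol(x$labels), x$n_regions))
  invisible(x)
}

#' Unsupervised 2D LCM segmentation
#'
#' Composition of [lcm_displacement_field] and [converge_and_cluster]:
#' per-orientation 1D local centers of mass define a displacement field,
#' tracker points converge through it, and converged trackers are clustered
#' into a label map. Fully deterministic (no randomness anywhere).
#'
#' @param img a [radiograph] or \[0,1\] matrix.
#' @param orient an [orientation_set].
#' @param params an [lcm_params].
#' @param sched an [iteration_schedule].
#' @return a `label_map`.
#' @export
segment_image <- function(img, orient = orientation_set(),
                          params = lcm_params(),
                          sched = iteration_schedule()) {
  V <- lcm_displacement_field(img, orient, params)
  converge_and_cluster(V, sched)
}
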