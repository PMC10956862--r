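#' Select the spine region from a label map
#'
#' The spinal column in an AP radiograph is bright and centered, so each
#' label is scored by (mean intensity) x (fraction of its pixels inside the
#' central third of the columns); the highest score wins and score ties are
#' broken by larger area. A manual override is accepted.
#'
#' @param labels a `label_map`.
#' @param img the [radiograph] the labels were computed from.
#' @param override optional label id to use directly.
#' @return integer label id.
#' @export
select_spine_label <- function(labels, img, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  lab <- labels$labels
  px <- as_pixel_matrix(img)
  stopifnot(all(dim(lab) == dim(px)))
  W <- ncol(lab)
  band_lo <- W / 3; band_hi <- 2 * W / 3
  colidx <- matrix(0:(W - 1), nrow(lab), W, byrow = TRUE)
  central <- colidx >= band_lo & colidx < band_hi
  ids <- sort(unique(as.vector(lab)))
  stats <- vapply(ids, function(id) {
    sel <- lab == id
    c(score = mean(px[sel]) * mean(central[sel]), area = sum(sel))
  }, numeric(2))
  best <- which(stats["score", ] == max(stats["score", ]))
  if (length(best) > 1) best <- best[which.max(stats["area", best])]
  ids[best]
}

#' Binary spine mask from a label map
#'
#' Keeps the pixels carrying `spine_label` and then only the largest
#' 4-connected component (the background-subtraction step: multiplying the
#' mask by the cropped image isolates the spinal region).
#'
#' @param labels a `label_map`.
#' @param spine_label label id of the spine region.
#' @return a logical matrix of class `binary_mask` with attribute `area`.
#' @export
spine_binary_mask <- function(labels, spine_label) {
  lab <- labels$labels
  if (!spine_label %in% lab) stop("spine label ", spine_label, " absent from label map")
  m <- lab == spine_label
  cc <- EBImage::bwlabel(m * 1)           # 4-connected labelling
  cc <- EBImage::imageData(cc)
  if (max(cc) >= 1) {
    sizes <- tabulate(cc[cc > 0])
    m <- cc == which.max(sizes)
  }
  if (!any(m)) stop("empty spine mask")
  binary_mask(m)
}

#' @param mask logical matrix.
#' @rdname spine_binary_mask
#' @export
binary_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(mask, area = sum(mask), class = c("binary_mask", "matrix", "array"))
}

#' Spine mask by background subtraction
#'
#' Identifies the background labels of a segmentation -- those whose mean
#' image intensity falls below a threshold (Otsu's threshold of the image
#' by default) -- subtracts them, and keeps the largest 4-connected
#' component of what remains. Because the subtraction is defined by the
#' background rather than by a single foreground label, the spinal column
#' survives as one mask even when the segmentation resolves individual
#' vertebrae and discs as separate regions.
#'
#' @param labels a `label_map`.
#' @param img the [radiograph] (or matrix) the labels were computed from.
#' @param threshold intensity threshold separating background label means;
#'   `NULL` (default) uses Otsu's threshold of `img`.
#' @return a `binary_mask`.
#' @export
background_subtraction_mask <- function(labels, img, threshold = NULL) {
  lab <- labels$labels
  px <- as_pixel_matrix(img)
  stopifnot(all(dim(lab) == dim(px)))
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(px))
  means <- tapply(px, lab, mean)
  fg_ids <- as.integer(names(means))[means >= threshold]
  if (!length(fg_ids)) stop("empty spine mask: every label is background")
  m <- matrix(lab %in% fg_ids, nrow(lab), ncol(lab))
  cc <- label_components(m, connectivity = 4)
  sizes <- tabulate(cc[cc > 0])
  if (!length(sizes)) stop("empty spine mask")
  binary_mask(cc == which.max(sizes))
}

# 2D Gaussian blur with replicate-free zero padding handled by the caller
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

#' Canny edge detection on a binary mask
#'
#' Gaussian smoothing, central-difference gradients, non-maximum suppression
#' along the quantized gradient direction, and hysteresis thresholding
#' (weak edges kept only when 8-connected to a strong edge). The mask is
#' zero-padded first, so the image frame itself is an edge when the mask
#' touches it.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @param sigma Gaussian smoothing scale in pixels (default 1).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude (defaults 0.1 and 0.2).
#' @return logical edge map, same shape as `mask`.
#' @export
canny_edges <- function(mask, sigma = 1, low = 0.1, high = 0.2) {
  if (!any(mask)) stop("canny_edges requires a non-empty mask")
  pad <- as.integer(ceiling(3 * sigma) + 1)
  H <- nrow(mask); W <- ncol(mask)
  m <- matrix(0, H + 2 * pad, W + 2 * pad)
  m[pad + (1:H), pad + (1:W)] <- mask * 1
  g <- gaussian_blur(m, sigma)
  Hp <- nrow(g); Wp <- ncol(g)
  gr <- matrix(0, Hp, Wp); gc <- matrix(0, Hp, Wp)
  gr[2:(Hp - 1), ] <- (g[3:Hp, ] - g[1:(Hp - 2), ]) / 2
  gc[, 2:(Wp - 1)] <- (g[, 3:Wp] - g[, 1:(Wp - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  if (max(mag) == 0) return(matrix(FALSE, H, W))
  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(gr, gc)              # direction of the gradient
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  off <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  shift2 <- function(mt, dr, dc) {
    out <- matrix(0, Hp, Wp)
    rs <- (1 + max(0, dr)):(Hp + min(0, dr))
    cs <- (1 + max(0, dc)):(Wp + min(0, dc))
    out[rs - dr, cs - dc] <- mt[rs, cs]
    out
  }
  nms <- matrix(FALSE, Hp, Wp)
  tol <- 1e-9 * max(mag)   # keep plateau ties; breaks them symmetrically
  for (s in 0:3) {
    d <- off[[as.character(s)]]
    sel <- sector == s
    ge <- mag >= shift2(mag, d[1], d[2]) - tol &
          mag >= shift2(mag, -d[1], -d[2]) - tol
    nms <- nms | (sel & ge)
  }
  strong <- nms & mag >= high * max(mag)
  weak <- nms & mag >= low * max(mag)
  # hysteresis: keep weak components that contain a strong pixel (8-conn)
  lab <- label_components(weak, connectivity = 8)
  keep_ids <- unique(lab[strong])
  edges <- weak & matrix(lab %in% setdiff(keep_ids, 0L), Hp, Wp)
  edges[pad + (1:H), pad + (1:W), drop = FALSE]
}

# connected-component labelling of a logical matrix (0 = background)
label_components <- function(mask, connectivity = 4) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  idx <- which(mask)
  if (!length(idx)) return(out)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  r <- (idx - 1L) %% H; cl <- (idx - 1L) %/% H
  deltas <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) deltas <- c(deltas, list(c(1, 1), c(1, -1)))
  ef <- integer(0); et <- integer(0)
  for (d in deltas) {
    nr <- r + d[1]; nc <- cl + d[2]
    ok <- nr >= 0 & nr < H & nc >= 0 & nc < W
    nidx <- nr[ok] + nc[ok] * H + 1L
    hit <- mask[nidx]
    ef <- c(ef, pos[idx[ok][hit]])
    et <- c(et, pos[nidx[hit]])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et), directed = FALSE,
    vertices = data.frame(name = seq_along(idx)))
  out[idx] <- as.integer(igraph::components(g)$membership)
  out
}

#' Extract the smoothed center curve from an edge map
#'
#' Per row, the midline column is the midpoint of the leftmost and rightmost
#' edge pixels (`method = "wall_midpoint"`, robust to interior texture
#' edges) or the mean of all edge pixels in the row (`method = "mean"`).
#' Rows inside the span with no edges are filled by linear interpolation,
#' then a centered moving average of width `2 * smooth_window + 1` (window
#' shrinking at the ends) is applied.
#'
#' @param edges logical edge map.
#' @param smooth_window smoothing half-width in rows (default 5; 0 disables).
#' @param method `"wall_midpoint"` (default) or `"mean"`.
#' @return a `center_curve`: data.frame with 0-based `row` (strictly
#'   increasing) and real-valued `col`, plus attributes `smoothed`, `window`.
#' @export
extract_center_curve <- function(edges, smooth_window = 5,
                                 method = c("wall_midpoint", "mean")) {
  method <- match.arg(method)
  rows_with <- which(rowSums(edges) > 0)
  if (length(rows_with) < 2) stop("edge map must populate at least 2 rows")
  span <- rows_with[1]:rows_with[length(rows_with)]
  col0 <- vapply(span, function(r) {
    e <- which(edges[r, ])
    if (!length(e)) return(NA_real_)
    if (method == "wall_midpoint") (min(e) + max(e)) / 2 - 1 else mean(e) - 1
  }, numeric(1))
  if (anyNA(col0)) {
    ok <- which(!is.na(col0))
    col0 <- approx(span[ok], col0[ok], xout = span)$y
  }
  sm <- moving_average(col0, smooth_window)
  spans <- vapply(span, function(r) {
    e <- which(edges[r, ])
    if (length(e) < 2) NA_real_ else diff(range(e))
  }, numeric(1))
  out <- center_curve(span - 1L, sm, smoothed = smooth_window > 0,
                      window = smooth_window)
  attr(out, "row_span") <- spans
  out
}

#' Repair the tips of a center curve distorted by mask end caps
#'
#' The first and last rows of a spine mask cut the end vertebrae obliquely,
#' so their left/right-edge midpoints drift off the column midline. Rows at
#' either end whose edge span falls below `frac` times the median span are
#' treated as partial cross-sections and their columns are replaced by a
#' straight-line extrapolation of the adjacent `fit_rows` trusted rows.
#'
#' A tilted end cap of width w reaches `w * sin(tilt)` rows into the mask,
#' so the trim depth is set from the column width (median row span) and the
#' end tilt estimated on interior rows: a conservative first fit (one full
#' width in from the tip) supplies the tilt, the trim is recomputed from
#' it, the overhang rows beyond the column's true end (`w/2 * sin(tilt)`)
#' are cut, and the remaining trimmed rows are replaced by a
#' constant-curvature continuation of the trusted section (slope and
#' curvature from a local quadratic fit; exact for a circular arc,
#' a straight line in the zero-curvature limit).
#'
#' @param curve a `center_curve` carrying the `row_span` attribute set by
#'   [extract_center_curve].
#' @param fit_rows number of trusted rows used for the extrapolation fit.
#' @param pad extra safety rows added to the computed trim depth.
#' @return the repaired `center_curve`.
#' @export
repair_curve_tips <- function(curve, fit_rows = 30, pad = 2) {
  spans <- attr(curve, "row_span")
  if (is.null(spans)) return(curve)
  n <- nrow(curve)
  w <- stats::median(spans, na.rm = TRUE)
  if (!is.finite(w) || n < ceiling(w) + 2 * fit_rows) return(curve)
  col <- curve$col
  basis <- function(r) cbind(1, r, r^2)
  fit_at <- function(fit_idx) {
    r0 <- mean(curve$row[fit_idx])
    coef <- stats::lm.fit(basis(curve$row[fit_idx] - r0), col[fit_idx])$coefficients
    list(r0 = r0, coef = coef)
  }
  slope_at <- function(f, idx) f$coef[2] + 2 * f$coef[3] * (curve$row[idx] - f$r0)
  sin_of <- function(s) abs(s) / sqrt(1 + s^2)
  # continue the curve from the trusted edge row with the constant curvature
  # and slope estimated there by the local quadratic fit
  circle_extrap <- function(f, edge_idx, idx) {
    u <- curve$row[edge_idx] - f$r0
    ce <- sum(f$coef * c(1, u, u^2))
    m <- f$coef[2] + 2 * f$coef[3] * u
    kap <- 2 * f$coef[3] / (1 + m^2)^1.5
    r <- curve$row[idx]
    if (abs(kap) < 1e-6) return(ce + m * (r - curve$row[edge_idx]))
    nrm <- c(-m, 1) / sqrt(1 + m^2)
    ctr_r <- curve$row[edge_idx] + nrm[1] / kap
    ctr_c <- ce + nrm[2] / kap
    disc <- pmax(1 / kap^2 - (r - ctr_r)^2, 0)
    ctr_c - sign(ctr_c - ce) * sqrt(disc)
  }
  t0 <- ceiling(w)
  # top tip: the cap's upper corner overhangs the curve end by (w/2) sin(tilt)
  # rows (cut), and biases midpoints down to w sin(tilt) rows in (extrapolate)
  f <- fit_at((t0 + 1):(t0 + fit_rows))
  s <- sin_of(slope_at(f, t0 + 1))
  cut_top <- min(ceiling(w / 2 * s), floor(n / 4))
  t1 <- min(ceiling(w * s) + pad, floor(n / 3))
  if (t1 > cut_top) {
    f <- fit_at((t1 + 1):(t1 + fit_rows))
    col[(cut_top + 1):t1] <- circle_extrap(f, t1 + 1, (cut_top + 1):t1)
  }
  # bottom tip
  f <- fit_at((n - t0 - fit_rows + 1):(n - t0))
  s <- sin_of(slope_at(f, n - t0))
  cut_bot <- min(ceiling(w / 2 * s), floor(n / 4))
  t1 <- min(ceiling(w * s) + pad, floor(n / 3))
  if (t1 > cut_bot) {
    f <- fit_at((n - t1 - fit_rows + 1):(n - t1))
    col[(n - t1 + 1):(n - cut_bot)] <-
      circle_extrap(f, n - t1, (n - t1 + 1):(n - cut_bot))
  }
  keep <- (cut_top + 1):(n - cut_bot)
  out <- center_curve(curve$row[keep], col[keep],
                      smoothed = attr(curve, "smoothed"),
                      window = attr(curve, "window"))
  attr(out, "row_span") <- spans[keep]
  out
}

#' Smooth a center curve with a centered moving average
#'
#' @param curve a `center_curve`.
#' @param window smoothing half-width in rows; the window shrinks at the
#'   curve ends.
#' @export
smooth_center_curve <- function(curve, window = 5) {
  out <- center_curve(curve$row, moving_average(curve$col, window),
                      smoothed = window > 0, window = window)
  attr(out, "row_span") <- attr(curve, "row_span")
  out
}

# centered moving average; the window shrinks symmetrically near the ends
# so a linear sequence is reproduced exactly everywhere
moving_average <- function(x, w) {
  if (w <= 0) return(x)
  n <- length(x)
  i <- seq_len(n)
  wi <- pmin(w, i - 1, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + wi + 1] - cs[i - wi]) / (2 * wi + 1)
}

#' Center-curve container
#' @param row numeric vector of 0-based row coordinates, strictly increasing.
#' @param col numeric vector of real-valued column coordinates.
#' @param smoothed,window smoothing metadata.
#' @export
center_curve <- function(row, col, smoothed = FALSE, window = 0) {
  stopifnot(length(row) == length(col))
  if (any(diff(row) <= 0)) stop("center curve rows must be strictly increasing")
  structure(data.frame(row = as.numeric(row), col = as.numeric(col)),
            smoothed = smoothed, window = window,
            class = c("center_curve", "data.frame"))
}
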