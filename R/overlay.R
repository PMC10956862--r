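# Overlay renderer: draws the measured geometry over the working-frame
# image as an RGB raster -- center curve in red, chord in green, apex
# lines MC / NC in blue (dotted), the two perpendiculars in yellow, and
# the angle value stamped near O with a small built-in digit font.

draw_segment <- function(rgb, p0, p1, color, dotted = FALSE) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  n <- max(2, ceiling(2 * sqrt(sum((p1 - p0)^2))))
  t <- seq(0, 1, length.out = n)
  if (dotted) t <- t[(seq_along(t) %/% 4) %% 2 == 0]
  r <- round(p0[1] + t * (p1[1] - p0[1])) + 1
  c <- round(p0[2] + t * (p1[2] - p0[2])) + 1
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  for (k in 1:3) rgb[cbind(r[ok], c[ok], k)] <- color[k]
  rgb
}

# 3x5 digit glyphs (plus '.', '-') as bit rows
GLYPHS <- list(
  "0" = c(7,5,5,5,7), "1" = c(2,6,2,2,7), "2" = c(7,1,7,4,7),
  "3" = c(7,1,7,1,7), "4" = c(5,5,7,1,1), "5" = c(7,4,7,1,7),
  "6" = c(7,4,7,5,7), "7" = c(7,1,1,1,1), "8" = c(7,5,7,5,7),
  "9" = c(7,5,7,1,7), "." = c(0,0,0,0,2), "-" = c(0,0,7,0,0))

draw_text <- function(rgb, text, at, color, scale = 2) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  x <- at[2]
  for (ch in strsplit(text, "")[[1]]) {
    gl <- GLYPHS[[ch]]
    if (!is.null(gl)) {
      for (i in 1:5) for (j in 1:3) {
        if (bitwAnd(gl[i], bitwShiftL(1, 3 - j)) > 0) {
          rr <- round(at[1] + (i - 1) * scale) + 1:scale
          cc <- round(x + (j - 1) * scale) + 1:scale
          rr <- rr[rr >= 1 & rr <= H]; cc <- cc[cc >= 1 & cc <= W]
          for (k in 1:3) rgb[rr, cc, k] <- color[k]
        }
      }
    }
    x <- x + 4 * scale
  }
  rgb
}

#' Render a measurement overlay
#'
#' @param img working-frame [radiograph] (grayscale backdrop).
#' @param curve working-frame `center_curve`.
#' @param result a `cobb_result`.
#' @return H x W x 3 RGB array in \[0, 1\] suitable for [png::writePNG].
#' @export
render_overlay <- function(img, curve, result) {
  px <- as_pixel_matrix(img)
  rgb <- array(rep(px, 3), c(dim(px), 3))
  red <- c(1, 0.1, 0.1); green <- c(0.1, 1, 0.1)
  blue <- c(0.2, 0.4, 1); yellow <- c(1, 1, 0.2)
  for (i in seq_len(nrow(curve) - 1)) {
    rgb <- draw_segment(rgb, c(curve$row[i], curve$col[i]),
                        c(curve$row[i + 1], curve$col[i + 1]), red)
  }
  cons <- result$construction
  if (!is.null(cons)) {
    rgb <- draw_segment(rgb, cons$U, cons$L, green)
    rgb <- draw_segment(rgb, cons$M, cons$C, blue, dotted = TRUE)
    rgb <- draw_segment(rgb, cons$N, cons$C, blue, dotted = TRUE)
    rgb <- draw_segment(rgb, cons$M, cons$O, yellow)
    rgb <- draw_segment(rgb, cons$N, cons$O, yellow)
    at <- c(min(max(cons$O[1], 2), dim(px)[1] - 14),
            min(max(cons$O[2], 2), dim(px)[2] - 40))
    rgb <- draw_text(rgb, sprintf("%.1f", result$angle_deg), at, yellow)
  }
  rgb
}
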