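#' Specification of a synthetic AP-spine phantom
#'
#' A phantom is a bright column of vertebra-like blocks on a darker noisy
#' background: `n_vertebrae` rectangles of width `vertebra_width_px`,
#' centered on and locally perpendicular to a parametric center curve of
#' known construction angle, separated by `gap_px` along the curve.
#'
#' Curve kinds: `circular_arc` (central angle `arc_central_angle_deg`,
#' bowing toward lower columns; its construction angle is exactly half the
#' central angle), `cosine` (half-sine lateral deviation with apex
#' `apex_deviation_px`), or `straight`.
#'
#' @param image_side frame side in pixels (default 256, the working frame).
#' @param curve_kind `"circular_arc"`, `"cosine"` or `"straight"`.
#' @param arc_central_angle_deg central angle phi in (0, 120\].
#' @param apex_deviation_px apex deviation for the cosine curve.
#' @param n_vertebrae number of blocks (default 12).
#' @param vertebra_width_px,gap_px block geometry in pixels.
#' @param fg_level,bg_level block/background intensities in \[0, 1\].
#' @param gap_level intensity of the inter-vertebral gap (disc) segments,
#'   between `bg_level` and `fg_level`; discs in an AP radiograph are less
#'   opaque than bone but well above the soft-tissue background.
#' @param noise_sigma additive Gaussian noise sd (default 0.02).
#' @param margin_px top/bottom margin of the curve inside the frame.
#' @param seed RNG seed (Mersenne-Twister) for the noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_side = 256,
                         curve_kind = c("circular_arc", "cosine", "straight"),
                         arc_central_angle_deg = 40,
                         apex_deviation_px = 20,
                         n_vertebrae = 12,
                         vertebra_width_px = 28,
                         gap_px = 3,
                         fg_level = 0.8,
                         bg_level = 0.2,
                         gap_level = 0.65,
                         noise_sigma = 0.02,
                         margin_px = 20,
                         seed = 1L) {
  curve_kind <- match.arg(curve_kind)
  stopifnot(fg_level > bg_level, gap_level >= bg_level, gap_level <= fg_level,
            image_side >= 64,
            n_vertebrae >= 1, vertebra_width_px > 0, gap_px >= 0,
            noise_sigma >= 0)
  if (curve_kind == "circular_arc")
    stopifnot(arc_central_angle_deg > 0, arc_central_angle_deg <= 120)
  structure(list(image_side = as.integer(image_side), curve_kind = curve_kind,
                 arc_central_angle_deg = arc_central_angle_deg,
                 apex_deviation_px = apex_deviation_px,
                 n_vertebrae = as.integer(n_vertebrae),
                 vertebra_width_px = vertebra_width_px, gap_px = gap_px,
                 fg_level = fg_level, bg_level = bg_level,
                 gap_level = gap_level,
                 noise_sigma = noise_sigma, margin_px = margin_px,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# continuous center curve of a spec: function row -> col plus endpoints.
# For the circular arc the chord is vertical at column x0 and the arc bows
# toward lower columns with sagitta R * (1 - cos(phi/2)).
phantom_curve <- function(spec) {
  side <- spec$image_side
  r0 <- spec$margin_px
  r1 <- side - 1 - spec$margin_px
  chord <- r1 - r0
  if (spec$curve_kind == "circular_arc") {
    phi <- spec$arc_central_angle_deg * pi / 180
    R <- chord / (2 * sin(phi / 2))
    sagitta <- R * (1 - cos(phi / 2))
    x0 <- (side - 1) / 2 + sagitta / 2
    yc <- (r0 + r1) / 2
    xc <- x0 + R * cos(phi / 2)
    col_of_row <- function(r) xc - sqrt(pmax(R^2 - (r - yc)^2, 0))
  } else if (spec$curve_kind == "cosine") {
    d <- spec$apex_deviation_px
    x0 <- (side - 1) / 2 + d / 2
    col_of_row <- function(r) x0 - d * sinpi((r - r0) / chord)
  } else {
    x0 <- (side - 1) / 2
    col_of_row <- function(r) rep(x0, length(r))
  }
  list(r0 = r0, r1 = r1, col_of_row = col_of_row)
}

# dense arclength parameterization of the curve (row, col, cumulative s)
phantom_curve_samples <- function(spec, n = 4001) {
  cv <- phantom_curve(spec)
  r <- seq(cv$r0, cv$r1, length.out = n)
  cl <- cv$col_of_row(r)
  ds <- c(0, sqrt(diff(r)^2 + diff(cl)^2))
  list(row = r, col = cl, s = cumsum(ds))
}

#' Generate a synthetic spine phantom
#'
#' Renders the vertebra blocks, adds Gaussian noise (deterministic per
#' seed), and returns the image together with its analytic ground truth.
#'
#' @param spec a [phantom_spec].
#' @return a `phantom_bundle`: list with `image` (a [radiograph]),
#'   `truth_mask` (noiseless foreground, `binary_mask`), `truth_curve`
#'   (continuous center-curve samples, data.frame row/col), `truth_angle_deg`
#'   (construction angle of the continuous curve) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  side <- spec$image_side
  cs <- phantom_curve_samples(spec)
  total_s <- cs$s[length(cs$s)]
  n <- spec$n_vertebrae
  block_h <- (total_s - (n - 1) * spec$gap_px) / n
  if (block_h <= 0) stop("phantom spec error: gaps longer than the curve")
  blocks <- matrix(FALSE, side, side)
  discs <- matrix(FALSE, side, side)
  pr <- matrix(0:(side - 1), side, side)
  pc <- matrix(0:(side - 1), side, side, byrow = TRUE)
  at_s <- function(s) {
    i <- findInterval(s, cs$s, all.inside = TRUE)
    f <- (s - cs$s[i]) / max(cs$s[i + 1] - cs$s[i], 1e-12)
    c(cs$row[i] + f * (cs$row[i + 1] - cs$row[i]),
      cs$col[i] + f * (cs$col[i + 1] - cs$col[i]))
  }
  rect_at <- function(s_mid, h, half_w) {
    ctr <- at_s(s_mid)
    a <- at_s(max(s_mid - 1, 0)); b <- at_s(min(s_mid + 1, total_s))
    tg <- b - a; tg <- tg / sqrt(sum(tg^2))
    nv <- c(-tg[2], tg[1])
    ext_r <- abs(tg[1]) * h / 2 + abs(nv[1]) * half_w
    ext_c <- abs(tg[2]) * h / 2 + abs(nv[2]) * half_w
    if (ctr[1] - ext_r < 0 || ctr[1] + ext_r > side - 1 ||
        ctr[2] - ext_c < 0 || ctr[2] + ext_c > side - 1)
      stop("phantom spec error: curve (with blocks) exits the frame")
    lt <- (pr - ctr[1]) * tg[1] + (pc - ctr[2]) * tg[2]
    ln <- (pr - ctr[1]) * nv[1] + (pc - ctr[2]) * nv[2]
    abs(lt) <= h / 2 & abs(ln) <= half_w
  }
  half_w <- spec$vertebra_width_px / 2
  for (k in seq_len(n)) {
    s_mid <- (k - 1) * (block_h + spec$gap_px) + block_h / 2
    blocks <- blocks | rect_at(s_mid, block_h, half_w)
    if (k < n && spec$gap_px > 0 && spec$gap_level > spec$bg_level)
      discs <- discs | rect_at(s_mid + (block_h + spec$gap_px) / 2,
                               spec$gap_px + 2, half_w)
  }
  discs <- discs & !blocks
  mask <- blocks | discs
  img <- matrix(spec$bg_level, side, side)
  img[discs] <- spec$gap_level
  img[blocks] <- spec$fg_level
  if (spec$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(spec$seed, kind = "Mersenne-Twister")
    img <- img + matrix(rnorm(side * side, 0, spec$noise_sigma), side, side)
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = radiograph(img, "png", c(side, side)),
                 truth_mask = binary_mask(mask),
                 truth_curve = data.frame(row = cs$row, col = cs$col),
                 truth_angle_deg = truth_angle(spec),
                 spec = spec),
            class = "phantom_bundle")
}

#' Ground-truth construction angle of a phantom's continuous curve
#'
#' Applies the chord / apex / perpendicular construction (mon convention)
#' to the continuous center curve sampled at 10x the pixel row density
#' (an odd sample count keeps the apex of symmetric curves exact). For a
#' circular arc of central angle phi this equals phi/2 analytically.
#'
#' @param spec a [phantom_spec].
#' @param supersample samples per pixel row (default 10).
#' @return angle in degrees (0 for a straight curve).
#' @export
truth_angle <- function(spec, supersample = 10) {
  if (spec$curve_kind == "straight") return(0)
  cv <- phantom_curve(spec)
  n <- supersample * round(cv$r1 - cv$r0)
  if (n %% 2 == 0) n <- n + 1                  # odd: middle sample at apex
  r <- seq(cv$r0, cv$r1, length.out = n)
  curve <- center_curve(r, cv$col_of_row(r))
  res <- classify_scoliosis(curve, min_dev_px = 0, convention = "mon")
  res$angle_deg
}
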