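#' Radiograph image container
#'
#' A `radiograph` is a plain 2D numeric matrix of intensities in \[0, 1\]
#' (rows x columns, origin top-left) carrying provenance attributes:
#' `source_format` (one of `"dicom"`, `"png"`, `"jpg"`) and `original_shape`
#' (the pre-resize `c(rows, cols)`), so that measurements made in the working
#' frame can be mapped back to the acquisition frame.
#'
#' @param pixels numeric matrix with all values in \[0, 1\].
#' @param source_format character scalar, one of `"dicom"`, `"png"`, `"jpg"`.
#' @param original_shape integer vector `c(rows, cols)` of the image as read.
#' @return an object of class `radiograph`.
#' @export
radiograph <- function(pixels, source_format = "png", original_shape = dim(pixels)) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 1))
    stop("radiograph intensities must be finite and in [0, 1]")
  structure(pixels,
            source_format = source_format,
            original_shape = as.integer(original_shape),
            class = c("radiograph", "matrix", "array"))
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph %d x %d, source %s, original %s, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), attr(x, "source_format"),
              paste(attr(x, "original_shape"), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

# strip class/attributes down to a bare matrix
as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  m
}

# Rec.601 luminance for <=3-channel inputs; equal channels map to themselves.
luminance <- function(arr) {
  nch <- dim(arr)[3]
  w <- c(0.299, 0.587, 0.114)[seq_len(nch)]
  w <- w / sum(w)
  out <- matrix(0, nrow(arr), ncol(arr))
  for (k in seq_len(nch)) out <- out + w[k] * arr[, , k]
  out
}

#' Read a radiograph from DICOM, PNG or JPG
#'
#' Multi-channel inputs with at most 3 channels are converted to grayscale by
#' luminance weighting; inputs with more than 3 channels are rejected (the
#' channel-dimension filter applied before segmentation). Raw integer bit
#' depths are rescaled to \[0, 1\] by the maximum representable value of the
#' stored sample type.
#'
#' @param path path to a `.dcm`, `.png`, `.jpg`/`.jpeg` or `.tif`/`.tiff` file.
#' @return a [radiograph].
#' @export
read_radiograph <- function(path) {
  if (!file.exists(path)) stop("cannot read radiograph: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom") || is_dicom_file(path)) {
    px <- read_dicom_pixels(path)
    return(radiograph(px, "dicom", dim(px)))
  }
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else {
    a <- tryCatch(EBImage::imageData(EBImage::readImage(path)),
                  error = function(e) stop("unreadable image file: ", path,
                                           " (", conditionMessage(e), ")"))
    # EBImage stores x (columns) first; transpose spatial dims to row-major
    if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] > 3)
      stop("rejected: image has ", dim(arr)[3], " channels (more than 3)")
    arr <- luminance(arr)
  }
  px <- pmin(pmax(arr, 0), 1)
  fmt <- if (ext %in% c("jpg", "jpeg")) "jpg" else "png"
  radiograph(px, fmt, dim(px))
}

#' Write a radiograph (or any \[0,1\] matrix) as 8-bit grayscale PNG
#'
#' @param img matrix of intensities in \[0, 1\].
#' @param path output path.
#' @export
write_radiograph <- function(img, path) {
  png::writePNG(as_pixel_matrix(img), path)
  invisible(path)
}

#' Resize a radiograph to the square working frame
#'
#' Bilinear resize to `side` x `side`. Idempotent when the image is already
#' at the target size. The original acquisition shape is preserved in the
#' `original_shape` attribute so results can be mapped back.
#'
#' @param img a [radiograph].
#' @param side target side length in pixels (default 256).
#' @return a [radiograph] of size `side` x `side`.
#' @export
to_working_frame <- function(img, side = 256) {
  if (side < 16) stop("working-frame side must be at least 16 pixels")
  orig <- attr(img, "original_shape")
  if (is.null(orig)) orig <- dim(img)
  fmt <- attr(img, "source_format") %||% "png"
  if (all(dim(img) == c(side, side)))
    return(radiograph(as_pixel_matrix(img), fmt, orig))
  r <- EBImage::resize(EBImage::Image(as_pixel_matrix(img)), w = side, h = side)
  px <- pmin(pmax(EBImage::imageData(r), 0), 1)
  radiograph(px, fmt, orig)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement on the working-frame grayscale image.
#' Deterministic for fixed parameters; a constant image is returned
#' unchanged (there is no contrast to equalize).
#'
#' @param img a [radiograph] (or \[0,1\] matrix).
#' @param clip_limit contrast clip limit as a fraction (default 0.01).
#' @param tiles number of tiles per side of the contextual grid (default 8).
#' @return a [radiograph] with intensities in \[0, 1\].
#' @export
clahe_enhance <- function(img, clip_limit = 0.01, tiles = 8) {
  px <- as_pixel_matrix(img)
  if (diff(range(px)) == 0)
    return(radiograph(px, attr(img, "source_format") %||% "png",
                      attr(img, "original_shape") %||% dim(px)))
  # clip_limit is a fraction of the tile histogram mass; the underlying
  # routine expects a multiple of the average bin height (bins = 256)
  out <- EBImage::clahe(EBImage::Image(px), nx = tiles, ny = tiles,
                        limit = max(clip_limit * 256, 1))
  out <- pmin(pmax(EBImage::imageData(out), 0), 1)
  radiograph(out, attr(img, "source_format") %||% "png",
             attr(img, "original_shape") %||% dim(px))
}

#' Region-of-interest box
#'
#' Half-open pixel-index box, 0-based: rows `[row_start, row_end)`,
#' columns `[col_start, col_end)`.
#'
#' @param row_start,row_end,col_start,col_end 0-based half-open bounds.
#' @export
roi_box <- function(row_start, row_end, col_start, col_end) {
  stopifnot(row_start >= 0, col_start >= 0,
            row_end > row_start, col_end > col_start)
  structure(list(row_start = as.integer(row_start), row_end = as.integer(row_end),
                 col_start = as.integer(col_start), col_end = as.integer(col_end)),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box rows [%d, %d) cols [%d, %d)>\n",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

#' Crop the spine region of interest by projection histograms
#'
#' Computes row-sum and column-sum intensity projections and keeps the
#' bounding box of rows/columns whose projection is at least
#' `proj_threshold` times the maximum projection on that axis.
#'
#' @param img a [radiograph].
#' @param proj_threshold fraction of the maximum projection (default 0.25).
#' @return `list(image = cropped radiograph, box = roi_box)`.
#' @export
crop_spine_roi <- function(img, proj_threshold = 0.25) {
  px <- as_pixel_matrix(img)
  rs <- rowSums(px)
  cs <- colSums(px)
  if (max(rs) <= 0 || max(cs) <= 0)
    stop("empty ROI: no projection bin exceeds the threshold")
  rkeep <- which(rs >= proj_threshold * max(rs))
  ckeep <- which(cs >= proj_threshold * max(cs))
  if (!length(rkeep) || !length(ckeep))
    stop("empty ROI: no projection bin exceeds the threshold")
  box <- roi_box(min(rkeep) - 1L, max(rkeep), min(ckeep) - 1L, max(ckeep))
  cropped <- px[(box$row_start + 1L):box$row_end,
                (box$col_start + 1L):box$col_end, drop = FALSE]
  list(image = radiograph(cropped, attr(img, "source_format") %||% "png",
                          attr(img, "original_shape") %||% dim(px)),
       box = box)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
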