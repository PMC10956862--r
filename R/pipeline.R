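#' Pipeline configuration
#'
#' Bundles every stage parameter of the measurement pipeline. Defaults
#' follow the reported optima for radiograph segmentation (alpha = 2000,
#' K = 180 orientations, 1000 total iterations of which 250 are phase-2);
#' `desk_profile()` switches to the reduced configuration (K = 8, 50
#' iterations) documented for interactive use and testing.
#'
#' The pipeline-level edge exponent default is `p = 2` with a small
#' Gaussian pre-smoothing (`denoise_sigma`) before the displacement field:
#' with a linear exponent, per-pixel noise accumulates edge energy at a
#' rate of roughly `alpha * E|df|` per pixel, which at alpha = 2000
#' collapses the LCM weighting window to sub-pixel size; the quadratic
#' exponent suppresses small noise differences while true region
#' boundaries keep an overwhelming energy barrier.
#'
#' @param side working-frame side (default 256).
#' @param clahe_clip,clahe_tiles CLAHE parameters.
#' @param proj_threshold ROI projection threshold (fraction of max).
#' @param denoise_sigma Gaussian pre-smoothing before segmentation (px).
#' @param alpha,p LCM edge-weight scale and exponent for segmentation.
#' @param K number of scan orientations.
#' @param t_total,t_phase2,merge_radius,cluster_eps iteration schedule.
#' @param canny_sigma Canny smoothing scale on the binary mask.
#' @param smooth_window center-curve smoothing half-width (rows).
#' @param curve_method `"wall_midpoint"` or `"mean"`.
#' @param min_dev_px no-scoliosis deviation threshold (px).
#' @param convention Cobb angle convention (`"mon"` or `"eq5_printed"`).
#' @param apex_rule `"max_dev"` or `"min_x"`.
#' @param input_dir,output_dir batch directories.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(side = 256,
                            clahe_clip = 0.01, clahe_tiles = 8,
                            proj_threshold = 0.25,
                            denoise_sigma = 1.5,
                            alpha = 2000, p = 2,
                            K = 180,
                            t_total = 1000, t_phase2 = 250,
                            merge_radius = 2, cluster_eps = 1,
                            canny_sigma = 1,
                            smooth_window = 5,
                            curve_method = "wall_midpoint",
                            min_dev_px = 3,
                            convention = "mon",
                            apex_rule = "max_dev",
                            input_dir = NULL, output_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Desk-scale pipeline profile
#'
#' @param ... overrides passed on to [pipeline_config].
#' @export
desk_profile <- function(...) {
  cfg <- pipeline_config(...)
  over <- names(list(...))
  if (!"K" %in% over) cfg$K <- 8
  if (!"t_total" %in% over) cfg$t_total <- 50
  if (!"t_phase2" %in% over) cfg$t_phase2 <- 12
  cfg
}

# embed an ROI-frame matrix back into the full working frame
embed_roi <- function(m, box, side, fill = FALSE) {
  out <- matrix(fill, side, side)
  out[(box$row_start + 1):box$row_end, (box$col_start + 1):box$col_end] <- m
  out
}

#' Measure the Cobb angle of one radiograph
#'
#' Full pipeline: read, resize to the working frame, CLAHE, ROI crop,
#' Gaussian denoising, 2D LCM segmentation, spine-label selection, binary
#' mask (largest component), Canny edges, smoothed center curve, scoliosis
#' classification and Cobb construction. On a degenerate image a
#' structured failure record is returned instead of an error.
#'
#' @param input a file path or a [radiograph].
#' @param cfg a [pipeline_config].
#' @return list with `status` (`"ok"` or `"failed"`), `reason` (on
#'   failure), and on success `result` (a `cobb_result`), `curve`
#'   (working-frame `center_curve`), `spine_mask` (working-frame logical
#'   matrix), `label_map`, `roi` and `working` (the enhanced image).
#' @export
measure_image <- function(input, cfg = pipeline_config()) {
  out <- tryCatch({
    img <- if (inherits(input, "radiograph")) input else read_radiograph(input)
    wf <- to_working_frame(img, cfg$side)
    enh <- clahe_enhance(wf, cfg$clahe_clip, cfg$clahe_tiles)
    roi <- crop_spine_roi(enh, cfg$proj_threshold)
    seg_in <- as_pixel_matrix(roi$image)
    if (cfg$denoise_sigma > 0) seg_in <- gaussian_blur(seg_in, cfg$denoise_sigma)
    labs <- segment_image(seg_in,
                          orient = orientation_set(cfg$K),
                          params = lcm_params(cfg$alpha, cfg$p),
                          sched = iteration_schedule(cfg$t_total, cfg$t_phase2,
                                                     cfg$merge_radius,
                                                     cfg$cluster_eps))
    mask <- background_subtraction_mask(labs, roi$image)
    edges <- canny_edges(mask, cfg$canny_sigma)
    # extract the raw midline, repair the end-cap rows, then smooth, so the
    # moving average cannot drag cap bias into the trusted interior
    curve_roi <- extract_center_curve(edges, 0, cfg$curve_method)
    curve_roi <- repair_curve_tips(curve_roi)
    curve_roi <- smooth_center_curve(curve_roi, cfg$smooth_window)
    curve <- center_curve(curve_roi$row + roi$box$row_start,
                          curve_roi$col + roi$box$col_start,
                          smoothed = attr(curve_roi, "smoothed"),
                          window = attr(curve_roi, "window"))
    res <- classify_scoliosis(curve, cfg$min_dev_px, cfg$convention,
                              cfg$apex_rule)
    list(status = "ok", reason = NA_character_, result = res, curve = curve,
         spine_mask = embed_roi(unclass(mask)[, , drop = FALSE], roi$box, cfg$side),
         label_map = labs, roi = roi$box, working = enh)
  }, error = function(e) {
    list(status = "failed", reason = conditionMessage(e), result = NULL)
  })
  out
}

#' Batch-measure a directory of radiographs
#'
#' Processes every readable image in `cfg$input_dir` (sorted by filename),
#' routes each into `output_dir/scoliosis`, `output_dir/no_scoliosis` or
#' records it as a failure, writes an overlay PNG and result JSON per
#' image, a `summary.csv` of angles and the resolved configuration. A
#' failing image never interrupts the batch.
#'
#' @param cfg a [pipeline_config] with `input_dir` (and optionally
#'   `output_dir`) set.
#' @return invisibly, the summary data.frame (file, status, is_scoliosis,
#'   angle_deg, reason).
#' @export
batch_directory <- function(cfg) {
  stopifnot(!is.null(cfg$input_dir), dir.exists(cfg$input_dir))
  files <- sort(list.files(cfg$input_dir,
                           pattern = "\\.(png|jpg|jpeg|dcm|dicom|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) warning("no input images found in ", cfg$input_dir)
  outdir <- cfg$output_dir
  if (!is.null(outdir)) {
    for (d in c("scoliosis", "no_scoliosis", "failures"))
      dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
    cfg_out <- cfg; cfg_out$input_dir <- NULL
    jsonlite::write_json(unclass(cfg_out),
                         file.path(outdir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  rows <- lapply(files, function(f) {
    m <- measure_image(f, cfg)
    if (m$status == "failed") {
      dest <- "failures"
      row <- data.frame(file = basename(f), status = "failed",
                        is_scoliosis = NA, angle_deg = NA_real_,
                        reason = m$reason)
    } else {
      dest <- if (m$result$is_scoliosis) "scoliosis" else "no_scoliosis"
      row <- data.frame(file = basename(f), status = "ok",
                        is_scoliosis = m$result$is_scoliosis,
                        angle_deg = m$result$angle_deg, reason = NA_character_)
    }
    if (!is.null(outdir)) {
      stem <- tools::file_path_sans_ext(basename(f))
      if (m$status == "ok") {
        write_result_json(m, file.path(outdir, dest, paste0(stem, ".json")))
        ov <- render_overlay(m$working, m$curve, m$result)
        png::writePNG(ov, file.path(outdir, dest, paste0(stem, "_overlay.png")))
      } else {
        jsonlite::write_json(list(status = "failed", reason = m$reason),
                             file.path(outdir, dest, paste0(stem, ".json")),
                             auto_unbox = TRUE)
      }
    }
    row
  })
  summary <- do.call(rbind, rows)
  if (!is.null(outdir))
    write.csv(summary, file.path(outdir, "summary.csv"), row.names = FALSE)
  invisible(summary)
}

write_result_json <- function(m, path) {
  res <- m$result
  pts <- if (is.null(res$construction)) NULL else
    lapply(res$construction[c("L", "U", "M", "N", "C", "O", "P")],
           function(p) list(row = p[1], col = p[2]))
  jsonlite::write_json(list(angle_deg = res$angle_deg,
                            convention = res$convention,
                            is_scoliosis = res$is_scoliosis,
                            chord_crossings = res$chord_crossings,
                            points = pts),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a label map as an indexed PNG with a JSON sidecar
#'
#' @param labs a `label_map`.
#' @param path output PNG path; the sidecar is `<path>.json`.
#' @param params optional parameter list recorded in the sidecar.
#' @export
write_label_map <- function(labs, path, params = NULL) {
  n <- max(labs$n_regions, 2)
  png::writePNG(labs$labels / (n - 1), path)
  jsonlite::write_json(list(n_regions = labs$n_regions, parameters = params),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Evaluate a predicted mask against a ground-truth mask
#'
#' Both masks are read as grayscale PNGs and thresholded at 0.5.
#'
#' @param pred_path,truth_path PNG file paths.
#' @return list of segmentation scores (fractions).
#' @export
evaluate_masks <- function(pred_path, truth_path) {
  pred <- as_pixel_matrix(read_radiograph(pred_path)) > 0.5
  truth <- as_pixel_matrix(read_radiograph(truth_path)) > 0.5
  segmentation_scores(confusion_counts(pred, truth))
}

#' Materialize the standard phantom fixture set
#'
#' Writes three phantoms (straight; circular arcs with construction truths
#' of 20 and 35 degrees, i.e. central angles 40 and 70 degrees) as PNGs
#' with their truth masks, truth-curve CSVs and spec JSONs.
#'
#' @param dir output directory.
#' @param noise_sigma noise level (default 0.02).
#' @param seed base RNG seed.
#' @return invisibly, the written image paths.
#' @export
write_fixture_set <- function(dir, noise_sigma = 0.02, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    straight = phantom_spec(curve_kind = "straight", noise_sigma = noise_sigma,
                            seed = seed),
    arc40 = phantom_spec(curve_kind = "circular_arc", arc_central_angle_deg = 40,
                         noise_sigma = noise_sigma, seed = seed + 1L),
    arc70 = phantom_spec(curve_kind = "circular_arc", arc_central_angle_deg = 70,
                         noise_sigma = noise_sigma, seed = seed + 2L))
  paths <- character(0)
  for (nm in names(specs)) {
    b <- generate_phantom(specs[[nm]])
    p <- file.path(dir, paste0(nm, ".png"))
    write_radiograph(b$image, p)
    write_radiograph(unclass(b$truth_mask) * 1, file.path(dir, paste0(nm, "_truth_mask.png")))
    write.csv(b$truth_curve, file.path(dir, paste0(nm, "_truth_curve.csv")),
              row.names = FALSE)
    jsonlite::write_json(c(unclass(specs[[nm]]),
                           list(truth_angle_deg = b$truth_angle_deg)),
                         file.path(dir, paste0(nm, "_spec.json")),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
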