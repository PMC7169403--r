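#' @importFrom generics glance
#' @export
generics::glance

#' Pipeline configuration
#'
#' Every parameter has a default; an empty call yields a configuration that
#' runs end-to-end on a phantom of the given size.  The canonical template
#' axes follow the image proportions unless a template file is supplied.
#'
#' @param image_size `(H, W)` used to size the default template.
#' @param ... overrides as named nested values, e.g.
#'   `gabor = list(wavelengths = c(8))`, `ght = list(n_bins = 18)`.
#' @return a `pipeline_config` (nested list).
#' @export
pipeline_config <- function(image_size = c(256, 256), ...) {
  h <- image_size[1]; w <- image_size[2]
  cfg <- list(
    version = 1L,
    gabor = list(orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                 wavelengths = c(8, 16), gamma = 0.5, bandwidth = 1),
    roi = list(enabled = TRUE, margin = 8),
    edge = list(threshold_quantile = 0.8),
    template = list(path = NULL, axes = c(0.14 * w, 0.22 * h),
                    lateral_halfwidth = 6),
    ght = list(n_bins = 36,
               sx = seq(0.85, 1.15, by = 0.05),
               sy = seq(0.85, 1.15, by = 0.05),
               theta = seq(-pi / 6, pi / 6, by = pi / 18),
               k = 10, suppression_radius = 5, smooth_radius = 1,
               verify = TRUE),
    band = list(beta = 0.1),
    confidence = list(model_path = NULL),
    seed = 1L)
  over <- list(...)
  for (nm in names(over))
    cfg[[nm]] <- if (is.list(cfg[[nm]])) modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Flat nested YAML; serialize-parse-serialize is idempotent.
#'
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @param image_size passed to [pipeline_config()] for defaults the file
#'   does not set.
#' @export
read_config <- function(path, image_size = c(256, 256)) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(image_size = image_size)
  merge_keep <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_keep(base[[nm]], upd[[nm]])
      else base[nm] <- list(upd[[nm]])  # keeps explicit NULLs in place
    }
    base
  }
  structure(merge_keep(unclass(cfg), raw), class = "pipeline_config")
}

#' Read an 8-bit grayscale image
#'
#' PNG (and single-channel TIFF via the tiff-capable readers of png files)
#' input; multi-channel images are averaged to gray.  Returns intensities on
#' the 0-255 scale, rows = y.
#'
#' @param path PNG file path.
#' @return numeric matrix.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) lv_error("lvmark_unreadable", paste("cannot read", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  img * 255
}

#' Run the full marking pipeline on one image
#'
#' Stages: Gabor filter bank and ROI extraction (on failure the search
#' degrades to the full image and the result is flagged), Sobel edge
#' extraction restricted to the ROI, R-table voting of the guided template
#' over the pose grid, ranking of the ten best recognition positions by
#' accumulator rate, gradient verification of those candidates to choose
#' the marking pose, deformation of the lateral band at that pose, and
#' (when a model is configured) an SVM confidence score from the restricted
#' accumulator's features.
#'
#' @param image file path or numeric matrix (0-255 grayscale).
#' @param cfg a [pipeline_config()].
#' @param keep_accumulators also return the full-image and ROI-restricted
#'   accumulators (needed for confidence training; costs memory).
#' @return an `lv_marking`: detections tibble, chosen index, septal/lateral
#'   polylines, ROI bbox, optional confidence, the report string and flags.
#' @export
run_pipeline <- function(image, cfg = NULL, keep_accumulators = FALSE) {
  img <- if (is.character(image)) read_gray(image) else image
  assert_gray(img)
  if (is.null(cfg)) cfg <- pipeline_config(image_size = dim(img))

  t0 <- Sys.time()
  roi <- NULL
  if (isTRUE(cfg$roi$enabled)) {
    bank <- default_gabor_bank(cfg$gabor$orientations, cfg$gabor$wavelengths,
                               cfg$gabor$gamma, cfg$gabor$bandwidth)
    roi <- tryCatch(extract_roi(filter_bank_response(img, bank),
                                cfg$roi$margin),
                    lvmark_no_roi = function(e) NULL)
    if (is.null(roi))
      warning("ROI extraction failed; falling back to a full-image search",
              call. = FALSE)
  }
  roi_fallback <- is.null(roi)
  if (roi_fallback)
    roi <- roi_from_mask(matrix(TRUE, nrow(img), ncol(img)), 0)
  lv_log("gabor_roi", t0,
         sprintf("enabled %s, margin %d", cfg$roi$enabled, cfg$roi$margin))

  t0 <- Sys.time()
  edges <- detect_edges(img, roi, cfg$edge$threshold_quantile)
  if (nrow(edges) == 0) lv_error("lvmark_no_edges", "no edge points detected")
  lv_log("detect_edges", t0, sprintf("%d edges, quantile %.2f", nrow(edges),
                                     cfg$edge$threshold_quantile))

  gt <- if (!is.null(cfg$template$path)) read_template(cfg$template$path)
  else guided_template(canonical_lv_template(cfg$template$axes,
                                             center = c(0, 0)),
                       lateral_halfwidth = cfg$template$lateral_halfwidth)
  rt <- build_rtable(gt, cfg$ght$n_bins)

  t0 <- Sys.time()
  grid <- grid_from_roi(roi, sx = cfg$ght$sx, sy = cfg$ght$sy,
                        theta = cfg$ght$theta)
  acc <- accumulate_ght(edges, rt, grid)
  det <- top_candidates(acc, cfg$ght$k, cfg$ght$suppression_radius,
                        cfg$ght$smooth_radius)
  if (nrow(det) == 0) lv_error("lvmark_no_detection", "accumulator is empty")
  lv_log("ght", t0, sprintf("%d x %d x %d pose cells, top rate %d",
                            length(grid$sx), length(grid$sy),
                            length(grid$theta), det$rate[1]))

  # hypothesis verification: among the rate-ranked candidates, pick the pose
  # whose full posed boundary lies on the strongest image gradient
  verif <- rep(NA_real_, nrow(det))
  chosen <- 1L
  if (isTRUE(cfg$ght$verify)) {
    gmag <- sobel_gradient(img)$mag
    verif <- vapply(seq_len(nrow(det)), function(i) {
      p <- pose_params(position = c(det$x[i], det$y[i]),
                       scale = c(det$sx[i], det$sy[i]), rotation = det$theta[i])
      pts <- apply_pose(gt$points, p, gt$reference)
      g <- sample_bilinear(gmag, pts[, 1], pts[, 2])
      mean(ifelse(is.na(g), 0, g))
    }, numeric(1))
    chosen <- which.max(verif)
  }
  best <- det[chosen, ]
  pose <- pose_params(position = c(best$x, best$y),
                      scale = c(best$sx, best$sy), rotation = best$theta)
  t0 <- Sys.time()
  lateral <- deform_band(img, gt, pose, cfg$band$beta)
  septal <- apply_pose(gt$points, pose, gt$reference)[gt$septal_idx, , drop = FALSE]
  lv_log("deform_band", t0, sprintf("beta %.3g, chosen %d", cfg$band$beta,
                                    chosen))

  confidence <- NULL
  acc_full <- NULL
  if (keep_accumulators || !is.null(cfg$confidence$model_path)) {
    if (isTRUE(cfg$roi$enabled)) {
      edges_full <- detect_edges(img, NULL, cfg$edge$threshold_quantile)
      grid_full <- ght_grid(sx = cfg$ght$sx, sy = cfg$ght$sy,
                            theta = cfg$ght$theta,
                            xlim = c(0, ncol(img)), ylim = c(0, nrow(img)))
      acc_full <- accumulate_ght(edges_full, rt, grid_full)
    } else {
      acc_full <- acc  # the search already spanned the whole image
    }
  }
  if (!is.null(cfg$confidence$model_path)) {
    model <- read_confidence(cfg$confidence$model_path)
    confidence <- as.numeric(score_confidence(model, featurize(acc, source = "restricted")))
  }

  res <- list(detections = det, chosen = as.integer(chosen),
              verification = verif,
              septal_polyline = septal,
              lateral_polyline = as.matrix(lateral[, c("x", "y")]),
              lateral_offsets = lateral$offset,
              roi = roi$bbox,
              roi_fallback = roi_fallback && isTRUE(cfg$roi$enabled),
              confidence = confidence,
              report = format_report(best),
              template = gt, config = cfg)
  if (keep_accumulators) {
    res$acc_full <- acc_full
    res$acc_restricted <- acc
  }
  structure(res, class = "lv_marking")
}

#' Full marked boundary of a pipeline result
#'
#' The septal limb at the detected pose followed by the deformed lateral
#' polyline, in template point order.
#'
#' @param res an `lv_marking`.
#' @return n x 2 matrix of `(x, y)` points.
#' @export
marking_boundary <- function(res) {
  stopifnot(inherits(res, "lv_marking"))
  unname(rbind(res$septal_polyline, res$lateral_polyline))
}

#' The paper-style one-line match report
#'
#' Formats a detection as
#' `"The best matching was found for scale %.6f and angle %.3f in position
#' (%d, %d) with rate %d"`.  When the two scales differ, the leading scale
#' is their arithmetic mean and both values are appended as
#' `" (scales %.6f, %.6f)"`.
#'
#' @param d one detection row (`rate`, `sx`, `sy`, `theta`, `x`, `y`).
#' @return character scalar.
#' @export
format_report <- function(d) {
  iso <- d$sx == d$sy
  s <- if (iso) d$sx else (d$sx + d$sy) / 2
  txt <- sprintf(
    "The best matching was found for scale %.6f and angle %.3f in position (%d, %d) with rate %d",
    s, d$theta, as.integer(d$x), as.integer(d$y), as.integer(d$rate))
  if (!iso) txt <- paste0(txt, sprintf(" (scales %.6f, %.6f)", d$sx, d$sy))
  txt
}

#' @export
print.lv_marking <- function(x, ...) {
  cat(x$report, "\n")
  if (!is.null(x$confidence)) cat(sprintf("Confidence: %.3f\n", x$confidence))
  if (x$roi_fallback) cat("(ROI extraction failed; full-image search)\n")
  invisible(x)
}

#' Detections table of a marking
#'
#' @param x an `lv_marking`.
#' @param ... unused.
#' @return the ranked detections tibble.
#' @exportS3Method tibble::as_tibble
as_tibble.lv_marking <- function(x, ...) x$detections

#' Serialize a marking result to JSON
#'
#' Deterministic full-precision JSON: detections, chosen index, polylines,
#' ROI, confidence and the report string.
#'
#' @param res an `lv_marking`.
#' @param path output path.
#' @export
write_marking <- function(res, path) {
  stopifnot(inherits(res, "lv_marking"))
  pts <- function(m) unname(apply(m, 1, as.numeric, simplify = FALSE))
  obj <- list(report = res$report,
              chosen = res$chosen,
              detections = as.data.frame(res$detections),
              septal_polyline = pts(res$septal_polyline),
              lateral_polyline = pts(res$lateral_polyline),
              roi = as.list(res$roi),
              roi_fallback = res$roi_fallback,
              confidence = res$confidence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write the marking overlay image
#'
#' The input image with the marked border drawn as a thin red line.
#'
#' @param res an `lv_marking`.
#' @param img the image the marking came from (0-255 matrix).
#' @param path PNG output path.
#' @export
write_overlay <- function(res, img, path) {
  g <- pmin(pmax(img / 255, 0), 1)  # argument order keeps the matrix dim
  rgb <- array(rep(g, 3), c(nrow(g), ncol(g), 3))
  b <- round(marking_boundary(res))
  ok <- b[, 1] >= 0 & b[, 1] < ncol(g) & b[, 2] >= 0 & b[, 2] < nrow(g)
  b <- b[ok, , drop = FALSE]
  rgb[cbind(b[, 2] + 1, b[, 1] + 1, 1)] <- 1
  rgb[cbind(b[, 2] + 1, b[, 1] + 1, 2)] <- 0
  rgb[cbind(b[, 2] + 1, b[, 1] + 1, 3)] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}

#' Plot a marking over its image
#'
#' @param object an `lv_marking`.
#' @param img the source image (0-255 matrix); required for the backdrop.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lv_marking <- function(object, img = NULL, ...) {
  sep <- as.data.frame(object$septal_polyline)
  lat <- as.data.frame(object$lateral_polyline)
  names(sep) <- names(lat) <- c("x", "y")
  p <- ggplot2::ggplot()
  if (!is.null(img)) {
    df <- expand.grid(x = seq_len(ncol(img)) - 1, y = seq_len(nrow(img)) - 1)
    df$v <- as.vector(t(img))
    p <- p + ggplot2::geom_raster(data = df, ggplot2::aes(x, y, fill = v)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p + ggplot2::geom_path(data = sep, ggplot2::aes(x, y), color = "red",
                         linewidth = 0.4) +
    ggplot2::geom_path(data = lat, ggplot2::aes(x, y), color = "red",
                       linewidth = 0.4, linetype = "22") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
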