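# Intensity levels of the synthetic scan (8-bit): background, in-sector
# tissue backscatter, cavity blood pool, myocardial wall peak, and the
# dimmer walls of the neighboring chambers.
.lv_levels <- c(bg = 0, sector = 40, cavity = 15, wall = 200, distractor = 130)

#' Specification of a synthetic echocardiography-like phantom
#'
#' Describes a single still frame: a dark fan-shaped scan sector on a black
#' background containing an elliptical dark cavity (the LV blood pool)
#' bounded by a brighter myocardial wall, whose lateral side can be dimmed
#' to emulate a poor acoustic window, with seeded multiplicative
#' speckle-like noise and a known affine pose of the ground-truth boundary.
#'
#' @param image_size `(H, W)` pixels.
#' @param sector_apex `(x, y)` of the transducer apex; default top center.
#' @param sector_angle full opening angle of the fan, radians.
#' @param cavity_center `(x, y)` of the canonical cavity ellipse.
#' @param cavity_axes `(a, b)` semi-axes, pixels.
#' @param wall_thickness myocardial band width outward of the border, px.
#' @param pose [pose_params()] applied to the canonical boundary.
#' @param speckle_scale multiplicative noise amplitude, `>= 0`; `0` gives a
#'   deterministic noise-free image.
#' @param lateral_attenuation in `[0, 1]`; `1` makes the lateral wall
#'   indistinguishable from the sector backscatter.
#' @param distractors paint the neighboring chambers of an apical
#'   four-chamber view (right ventricle, both atria) as dimmer cavity/ring
#'   structures around the LV?  They provide the off-target clutter a real
#'   scan presents to a full-image search.
#' @param seed integer; all stochastic draws derive from it.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(image_size = c(256, 256), sector_apex = NULL,
                         sector_angle = 1.8, cavity_center = NULL,
                         cavity_axes = NULL, wall_thickness = 10,
                         pose = pose_params(), speckle_scale = 0.3,
                         lateral_attenuation = 0.5, distractors = TRUE,
                         seed = 1L) {
  if (any(image_size < 16)) lv_error("lvmark_invalid_spec", "image too small")
  if (speckle_scale < 0) lv_error("lvmark_invalid_spec", "speckle_scale must be >= 0")
  if (lateral_attenuation < 0 || lateral_attenuation > 1)
    lv_error("lvmark_invalid_spec", "lateral_attenuation must be in [0, 1]")
  h <- image_size[1]; w <- image_size[2]
  if (is.null(sector_apex)) sector_apex <- c(w / 2, h * 0.02)
  if (is.null(cavity_center)) cavity_center <- c(w / 2, h * 0.48)
  if (is.null(cavity_axes)) cavity_axes <- c(0.14 * w, 0.22 * h)
  structure(list(image_size = as.integer(image_size), sector_apex = sector_apex,
                 sector_angle = sector_angle, cavity_center = cavity_center,
                 cavity_axes = cavity_axes, wall_thickness = wall_thickness,
                 pose = pose, speckle_scale = speckle_scale,
                 lateral_attenuation = lateral_attenuation,
                 distractors = isTRUE(distractors),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "Phantom spec: %dx%d, cavity axes (%.1f, %.1f), speckle %.2f, lat. att. %.2f, seed %d\n",
    x$image_size[1], x$image_size[2], x$cavity_axes[1], x$cavity_axes[2],
    x$speckle_scale, x$lateral_attenuation, x$seed))
  invisible(x)
}

in_sector <- function(px, py, spec) {
  dx <- px - spec$sector_apex[1]
  dy <- py - spec$sector_apex[2]
  r <- sqrt(dx^2 + dy^2)
  rmax <- 0.98 * (spec$image_size[1] - spec$sector_apex[2])
  # fan axis points straight down (+y)
  ang <- abs(atan2(dx, dy))
  ang <= spec$sector_angle / 2 & r <= rmax & dy >= 0
}

#' Generate a synthetic phantom with ground truth
#'
#' Paints the scan sector, cavity and tapered myocardial wall implied by the
#' spec, applies the pose to the canonical U-shaped boundary, optionally
#' multiplies in smoothed speckle-like noise, and returns the 8-bit image
#' with the matching ground truth.  Identical specs yield bit-identical
#' images.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (integer matrix, 0-255) and `truth` (list with
#'   subpixel `boundary`, `septal_polyline`, `lateral_polyline` matrices and
#'   the `pose`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  tpl <- canonical_lv_template(spec$cavity_axes, spec$cavity_center)
  posed <- apply_pose(tpl$points, spec$pose, tpl$reference)
  wt <- spec$wall_thickness
  margin_pts <- cbind(
    c(posed[, 1] + wt, posed[, 1] - wt, posed[, 1], posed[, 1]),
    c(posed[, 2], posed[, 2], posed[, 2] + wt, posed[, 2] - wt))
  if (!all(in_sector(margin_pts[, 1], margin_pts[, 2], spec)))
    lv_error("lvmark_invalid_spec",
             "posed boundary (plus wall) is not fully inside the scan sector")

  px <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  py <- matrix(seq_len(h) - 1, h, w)
  img <- matrix(.lv_levels["bg"], h, w)
  sector <- matrix(in_sector(as.vector(px), as.vector(py), spec), h, w)
  img[sector] <- .lv_levels["sector"]

  if (spec$distractors)
    img <- paint_distractors(img, sector, px, py, spec, tpl)

  # cavity: pixels mapping inside the canonical ellipse under the inverse pose
  pos <- if (is.null(spec$pose$position)) tpl$reference else spec$pose$position
  ct <- cos(-spec$pose$rotation); st <- sin(-spec$pose$rotation)
  qx <- ((px - pos[1]) * ct - (py - pos[2]) * st) / spec$pose$scale[1] +
    tpl$reference[1]
  qy <- ((px - pos[1]) * st + (py - pos[2]) * ct) / spec$pose$scale[2] +
    tpl$reference[2]
  cavity <- ((qx - spec$cavity_center[1]) / spec$cavity_axes[1])^2 +
    ((qy - spec$cavity_center[2]) / spec$cavity_axes[2])^2 < 1
  img[cavity & sector] <- .lv_levels["cavity"]

  # myocardial band: outward of the border, intensity tapering to sector level
  pd <- polyline_dist_cpp(posed[, 1], posed[, 2], w, h)
  septal <- attr(tpl, "septal_idx")
  wallpeak <- ifelse(matrix(pd$index, h, w) %in% septal,
                     .lv_levels["wall"],
                     .lv_levels["wall"] - spec$lateral_attenuation *
                       (.lv_levels["wall"] - .lv_levels["sector"]))
  wallpeak <- matrix(wallpeak, h, w)
  band <- !cavity & sector & pd$dist <= spec$wall_thickness
  taper <- pd$dist / spec$wall_thickness
  img[band] <- wallpeak[band] - (wallpeak[band] - .lv_levels["sector"]) * taper[band]

  set.seed(spec$seed)
  if (spec$speckle_scale > 0) {
    n <- matrix(rnorm(h * w), h, w)
    n <- as.matrix(EBImage::gblur(EBImage::Image(n), sigma = 1))
    n <- (n - mean(n)) / sd(n)
    img <- img * (1 + spec$speckle_scale * n)
  }
  img <- matrix(as.integer(pmax(0, pmin(255, round(img)))), h, w)

  truth <- list(boundary = posed,
                septal_polyline = posed[septal, , drop = FALSE],
                lateral_polyline = posed[attr(tpl, "lateral_idx"), , drop = FALSE],
                pose = spec$pose)
  list(image = img, truth = truth)
}

# Neighboring chambers of the four-chamber layout, placed relative to the
# posed LV: right ventricle beside the septum, the atria beyond the mitral
# plane.  Dimmer walls, no taper; painted before the LV so the LV cavity and
# band override any overlap.
paint_distractors <- function(img, sector, px, py, spec, tpl) {
  ctr <- apply_pose(matrix(spec$cavity_center, 1), spec$pose, tpl$reference)
  a <- spec$cavity_axes[1] * spec$pose$scale[1]
  b <- spec$cavity_axes[2] * spec$pose$scale[2]
  th <- spec$pose$rotation
  ct <- cos(th); st <- sin(th)
  chambers <- list(
    rv = list(off = c(-2.25 * a, -0.15 * b), axes = c(0.75 * a, 0.80 * b)),
    la = list(off = c(0.15 * a, 1.50 * b), axes = c(0.85 * a, 0.55 * b)),
    ra = list(off = c(-2.05 * a, 1.45 * b), axes = c(0.65 * a, 0.50 * b)))
  for (ch in chambers) {
    cx <- ctr[1] + ct * ch$off[1] - st * ch$off[2]
    cy <- ctr[2] + st * ch$off[1] + ct * ch$off[2]
    ux <- (px - cx) * ct + (py - cy) * st
    uy <- -(px - cx) * st + (py - cy) * ct
    f <- sqrt((ux / ch$axes[1])^2 + (uy / ch$axes[2])^2)
    ring_w <- 0.7 * spec$wall_thickness / sqrt(prod(ch$axes))
    img[sector & f < 1] <- .lv_levels["cavity"]
    img[sector & f >= 1 & f <= 1 + ring_w] <- .lv_levels["distractor"]
  }
  img
}

#' Boundary discrepancy between two point lists
#'
#' Symmetric nearest-neighbor statistics: `mean_dist` is the average of the
#' two directed mean nearest-neighbor distances, `hausdorff` the larger of
#' the two directed maxima.
#'
#' @param detected,truth non-empty n x 2 matrices (or data frames with
#'   `x`, `y`) of boundary points.
#' @return a one-row tibble with `mean_dist` and `hausdorff`, pixels.
#' @export
boundary_error <- function(detected, truth) {
  as_pts <- function(p) {
    if (is.data.frame(p)) p <- cbind(p$x, p$y)
    p <- as.matrix(p)
    if (nrow(p) == 0) lv_error("lvmark_domain", "empty point list")
    p
  }
  a <- as_pts(detected); b <- as_pts(truth)
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  da <- sqrt(apply(d2, 1, min))
  db <- sqrt(apply(d2, 2, min))
  tibble::tibble(mean_dist = (mean(da) + mean(db)) / 2,
                 hausdorff = max(max(da), max(db)))
}

#' Write a phantom image and its ground truth
#'
#' The image goes to an 8-bit grayscale PNG, the ground truth to a sidecar
#' JSON with the point lists as `[[x, y], ...]` and the pose fields by name.
#'
#' @param phantom result of [generate_phantom()].
#' @param image_path PNG output path.
#' @param truth_path JSON output path (default: image path with `.json`).
#' @export
write_phantom <- function(phantom, image_path,
                          truth_path = sub("\\.png$", ".json", image_path)) {
  png::writePNG(phantom$image / 255, image_path)
  tr <- phantom$truth
  pts <- function(m) unname(apply(m, 1, as.numeric, simplify = FALSE))
  pose <- tr$pose
  obj <- list(boundary = pts(tr$boundary),
              septal_polyline = pts(tr$septal_polyline),
              lateral_polyline = pts(tr$lateral_polyline),
              pose = list(position = pose$position, scale = pose$scale,
                          rotation = pose$rotation))
  jsonlite::write_json(obj, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(image_path, truth_path))
}
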