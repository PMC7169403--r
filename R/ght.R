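# Sobel gradient of an image: components, magnitude and orientation mod pi.
sobel_gradient <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2_reflect(img, kx)   # d/dx (columns)
  gy <- conv2_reflect(img, t(kx))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2), phi = mod_pi(atan2(gy, gx)))
}

#' Extract edge points and their gradient orientations
#'
#' Computes the 3x3 Sobel gradient and keeps the pixels whose gradient
#' magnitude reaches a threshold, by default the 80th percentile of the
#' nonzero magnitudes (adapting to image contrast).  With an ROI, both the
#' percentile and the selection are restricted to the ROI bounding box.
#'
#' @param img numeric matrix image.
#' @param roi optional `roi_mask`; edges are restricted to its bounding box.
#' @param threshold_quantile quantile of nonzero gradient magnitudes.
#' @param threshold absolute magnitude threshold; overrides the quantile.
#' @return an `edge_points` tibble with columns `x`, `y` (0-based pixel
#'   coordinates), `phi` (orientation mod pi) and `mag`.
#' @export
detect_edges <- function(img, roi = NULL, threshold_quantile = 0.8,
                         threshold = NULL) {
  assert_gray(img)
  g <- sobel_gradient(img)
  keep <- matrix(TRUE, nrow(img), ncol(img))
  if (!is.null(roi)) {
    bb <- roi$bbox
    keep[] <- FALSE
    keep[(bb["y0"] + 1):bb["y1"], (bb["x0"] + 1):bb["x1"]] <- TRUE
  }
  mag <- g$mag
  mag[!keep] <- 0
  # FFT convolution leaves ~1e-13 residue on flat regions; treat anything
  # negligible on the image's own intensity scale as zero gradient
  eps <- 1e-8 * max(1, max(abs(img)))
  nz <- mag[mag > eps]
  if (length(nz) == 0)
    return(structure(tibble::tibble(x = integer(0), y = integer(0),
                                    phi = numeric(0), mag = numeric(0)),
                     class = c("edge_points", class(tibble::tibble()))))
  if (is.null(threshold)) threshold <- quantile(nz, threshold_quantile)
  sel <- which(mag >= pmax(threshold, eps) & mag > 0, arr.ind = TRUE)
  out <- tibble::tibble(x = sel[, 2] - 1L, y = sel[, 1] - 1L,
                        phi = g$phi[sel], mag = g$mag[sel])
  structure(out, class = c("edge_points", class(out)))
}

#' Build the R-table of a boundary template
#'
#' The straight angle is discretized into `n_bins` subintervals of width
#' `pi / n_bins`; each template point contributes the displacement
#' `reference - point`, stored in polar form `(rho, alpha)` in the bin of
#' its gradient orientation mod pi.
#'
#' @param template a [boundary_template()] (or `guided_template`).
#' @param n_bins number of orientation bins (default 36, i.e. 5 degrees).
#' @return an `rtable`: list with `n_bins` and an `entries` tibble
#'   (`bin`, `rho`, `alpha`).
#' @export
build_rtable <- function(template, n_bins = 36) {
  if (n_bins < 1) lv_error("lvmark_domain", "n_bins must be >= 1")
  pts <- template$points
  ori <- template$orientations
  dt <- pi / n_bins
  bin <- pmin(floor(ori / dt), n_bins - 1) + 1L
  rx <- template$reference[1] - pts[, 1]
  ry <- template$reference[2] - pts[, 2]
  entries <- tibble::tibble(bin = as.integer(bin),
                            rho = sqrt(rx^2 + ry^2),
                            alpha = atan2(ry, rx))
  structure(list(n_bins = as.integer(n_bins), entries = entries),
            class = "rtable")
}

#' @export
print.rtable <- function(x, ...) {
  cat(sprintf("R-table: %d entries in %d orientation bins\n",
              nrow(x$entries), x$n_bins))
  invisible(x)
}

#' Write / read an R-table as JSON
#'
#' The reader validates that entries are conserved (one per template point
#' recorded at write time).
#'
#' @param rt an `rtable`.
#' @param path file path.
#' @export
write_rtable <- function(rt, path) {
  stopifnot(inherits(rt, "rtable"))
  obj <- list(format = "lvmark-rtable", version = 1L, n_bins = rt$n_bins,
              n_entries = nrow(rt$entries),
              bins = lapply(seq_len(rt$n_bins), function(b) {
                e <- rt$entries[rt$entries$bin == b, ]
                unname(Map(c, e$rho, e$alpha))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rtable
#' @export
read_rtable <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "lvmark-rtable")
    lv_error("lvmark_bad_rtable", "not an lvmark R-table file")
  rows <- list()
  for (b in seq_along(obj$bins))
    for (e in obj$bins[[b]])
      rows[[length(rows) + 1L]] <- c(b, e[[1]], e[[2]])
  m <- do.call(rbind, rows)
  if (is.null(m) || nrow(m) != obj$n_entries)
    lv_error("lvmark_bad_rtable", "R-table entry count does not match header")
  structure(list(n_bins = as.integer(obj$n_bins),
                 entries = tibble::tibble(bin = as.integer(m[, 1]),
                                          rho = m[, 2], alpha = m[, 3])),
            class = "rtable")
}

#' Save / load an accumulator
#'
#' Compressed single-file bundle (votes array plus grid axes) for handing
#' accumulator spaces to the confidence tooling; reloads identically.
#'
#' @param acc a `ght_accumulator`.
#' @param path file path.
#' @export
write_accumulator <- function(acc, path) {
  stopifnot(inherits(acc, "ght_accumulator"))
  saveRDS(acc, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_accumulator
#' @export
read_accumulator <- function(path) {
  acc <- readRDS(path)
  if (!inherits(acc, "ght_accumulator"))
    lv_error("lvmark_bad_accumulator", "not an lvmark accumulator file")
  acc
}

#' Search grid for the anisotropic GHT
#'
#' Axes of the five-dimensional pose space: the two orthogonal scales, the
#' rotation, and the pixel position window (`x`, `y` half-open 0-based
#' ranges, e.g. an ROI bounding box).
#'
#' @param sx,sy scale axis values (`> 0`).
#' @param theta rotation axis values, radians.
#' @param xlim,ylim `(lo, hi)` half-open pixel ranges for the reference
#'   position.
#' @return a `ght_grid` object.
#' @export
ght_grid <- function(sx = seq(0.85, 1.15, by = 0.05),
                     sy = seq(0.85, 1.15, by = 0.05),
                     theta = seq(-pi / 6, pi / 6, by = pi / 18),
                     xlim, ylim) {
  if (any(sx <= 0) || any(sy <= 0))
    lv_error("lvmark_domain", "scale axes must be positive")
  if (length(sx) == 0 || length(sy) == 0 || length(theta) == 0)
    lv_error("lvmark_domain", "grid axes must be non-empty")
  structure(list(sx = as.numeric(sx), sy = as.numeric(sy),
                 theta = as.numeric(theta),
                 x0 = as.integer(xlim[1]), x1 = as.integer(xlim[2]),
                 y0 = as.integer(ylim[1]), y1 = as.integer(ylim[2])),
            class = "ght_grid")
}

grid_from_roi <- function(roi, ...) {
  ght_grid(..., xlim = c(roi$bbox["x0"], roi$bbox["x1"]),
           ylim = c(roi$bbox["y0"], roi$bbox["y1"]))
}

#' Anisotropic generalized Hough transform accumulation
#'
#' Every edge point looks up the R-table bin of its orientation shifted by
#' the candidate rotation (`phi - theta`, mod pi) and casts one vote per
#' entry: the stored displacement is scaled per axis, rotated, and added to
#' the edge position,
#' \deqn{y_{vote} = x_B + Rot(\theta)\, diag(S_x, S_y)\, r.}
#' Votes landing inside the position window increment the 5-D integer
#' accumulator indexed `(Sx, Sy, theta, y, x)`.
#'
#' @param edges an `edge_points` tibble from [detect_edges()] (or any data
#'   frame with `x`, `y`, `phi`).
#' @param rtable an [build_rtable()] result.
#' @param grid a [ght_grid()].
#' @return a `ght_accumulator`: list with the integer `votes` array (dims
#'   `nSx, nSy, ntheta, ny, nx`) and the grid axes.
#' @export
accumulate_ght <- function(edges, rtable, grid) {
  stopifnot(inherits(rtable, "rtable"), inherits(grid, "ght_grid"))
  nx <- grid$x1 - grid$x0
  ny <- grid$y1 - grid$y0
  if (nx < 1 || ny < 1) lv_error("lvmark_domain", "empty position window")
  e <- rtable$entries[order(rtable$entries$bin), ]
  counts <- tabulate(e$bin, nbins = rtable$n_bins)
  bin_start <- c(0L, cumsum(counts))
  votes <- ght_vote_cpp(as.numeric(edges$x), as.numeric(edges$y),
                        as.numeric(edges$phi),
                        e$rho, e$alpha, as.integer(bin_start), rtable$n_bins,
                        grid$sx, grid$sy, grid$theta,
                        grid$x0, grid$y0, nx, ny)
  structure(list(votes = votes, sx = grid$sx, sy = grid$sy,
                 theta = grid$theta,
                 x = seq(grid$x0, length.out = nx),
                 y = seq(grid$y0, length.out = ny)),
            class = "ght_accumulator")
}

#' @export
print.ght_accumulator <- function(x, ...) {
  d <- dim(x$votes)
  cat(sprintf(
    "GHT accumulator: %d x %d x %d pose cells over %d x %d positions, max rate %d\n",
    d[1], d[2], d[3], d[5], d[4], max(x$votes)))
  invisible(x)
}

# Linear cell index -> (isx, isy, ith, iy, ix) plus tie key ordering columns.
acc_cell_info <- function(acc, cells) {
  d <- dim(acc$votes)
  ai <- arrayInd(cells, d)
  data.frame(sx_bin = ai[, 1], sy_bin = ai[, 2], theta_bin = ai[, 3],
             iy = ai[, 4], ix = ai[, 5])
}

#' Ranked pose candidates from an accumulator
#'
#' Returns up to `k` detections ranked by accumulator support (descending);
#' each detection's `rate` is the raw vote count at its cell.  With
#' `smooth_radius > 0` the ranking key is the summed votes in the
#' `(2r+1)^2` positional neighborhood of the cell (same pose), which
#' consolidates votes smeared over adjacent positions by edge-pixel
#' quantization; raw cell votes break support ties, then the lexicographic
#' order on ascending `(theta bin, Sx bin, Sy bin, y, x)`.  With
#' `smooth_radius = 0` the ranking is exactly by raw rate.  Greedy
#' non-maximum suppression removes candidates within `suppression_radius`
#' pixels (Euclidean, in position) of an already accepted detection.
#'
#' @param acc a `ght_accumulator`.
#' @param k number of candidates (default 10, the usual short list).
#' @param suppression_radius pixels; `0` disables suppression.
#' @param smooth_radius positional consolidation radius, pixels.
#' @return a `ght_detections` tibble: `rate`, `sx`, `sy`, `theta`, `x`, `y`
#'   plus bin indices and the ranking `support`.  Empty for an all-zero
#'   accumulator.
#' @export
top_candidates <- function(acc, k = 10, suppression_radius = 5,
                           smooth_radius = 1) {
  stopifnot(inherits(acc, "ght_accumulator"))
  if (k < 1) lv_error("lvmark_domain", "k must be >= 1")
  v <- acc$votes
  empty <- tibble::tibble(rate = integer(0), sx = numeric(0), sy = numeric(0),
                          theta = numeric(0), x = integer(0), y = integer(0),
                          sx_bin = integer(0), sy_bin = integer(0),
                          theta_bin = integer(0), support = integer(0))
  if (max(v) == 0L)
    return(structure(empty, class = c("ght_detections", class(empty))))
  s <- if (smooth_radius > 0) box_support_cpp(v, as.integer(smooth_radius)) else v
  # restrict the exact sort to a generous head of the support distribution
  m <- min(length(s), max(5000L, 50L * k))
  thr <- if (m < length(s)) -sort(-as.vector(s), partial = m)[m] else 1L
  cells <- which(s >= max(thr, 1L) & v >= 1L)
  info <- acc_cell_info(acc, cells)
  rate <- v[cells]
  supp <- s[cells]
  o <- order(-supp, -rate, info$theta_bin, info$sx_bin, info$sy_bin,
             info$iy, info$ix)
  cells <- cells[o]; info <- info[o, ]; rate <- rate[o]; supp <- supp[o]
  px <- acc$x[info$ix]; py <- acc$y[info$iy]
  keep <- integer(0)
  for (i in seq_along(cells)) {
    if (length(keep) > 0 && suppression_radius > 0 &&
        any((px[i] - px[keep])^2 + (py[i] - py[keep])^2 <= suppression_radius^2))
      next
    keep <- c(keep, i)
    if (length(keep) >= k) break
  }
  out <- tibble::tibble(rate = as.integer(rate[keep]),
                        sx = acc$sx[info$sx_bin[keep]],
                        sy = acc$sy[info$sy_bin[keep]],
                        theta = acc$theta[info$theta_bin[keep]],
                        x = as.integer(px[keep]), y = as.integer(py[keep]),
                        sx_bin = info$sx_bin[keep], sy_bin = info$sy_bin[keep],
                        theta_bin = info$theta_bin[keep],
                        support = as.integer(supp[keep]))
  structure(out, class = c("ght_detections", class(out)))
}

#' Stamp a template's edge set at a pose
#'
#' Produces the edge-point set an ideal detector would return for a
#' template instance at the given pose: posed point positions (subpixel)
#' with orientations shifted by the pose rotation (mod pi).  Useful for
#' self-detection checks: accumulating these edges with the template's own
#' R-table puts `n_points` votes at the pose.
#'
#' @param template a [boundary_template()] or `guided_template`.
#' @param pose a [pose_params()].
#' @return an `edge_points` tibble.
#' @export
stamp_edges <- function(template, pose = pose_params()) {
  posed <- apply_pose(template$points, pose, template$reference)
  out <- tibble::tibble(x = posed[, 1], y = posed[, 2],
                        phi = mod_pi(template$orientations + pose$rotation),
                        mag = 1)
  structure(out, class = c("edge_points", class(out)))
}
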