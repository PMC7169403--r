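#' Boundary template
#'
#' An ordered set of boundary points with a reference point (the barycenter
#' by default) and a gradient orientation per point, reduced mod pi to
#' `[0, pi)`.  Orientations are the contour normals: local tangents rotated
#' by pi/2.
#'
#' @param points n x 2 matrix of ordered `(x, y)` points.
#' @param reference `(x, y)`; defaults to the barycenter of `points`.
#' @param orientations radians per point; computed from the point ordering
#'   when omitted.
#' @param closed is the contour closed (affects tangent estimation at the
#'   ends)?
#' @return a `boundary_template` object.
#' @export
boundary_template <- function(points, reference = NULL, orientations = NULL,
                              closed = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 2 || ncol(points) != 2)
    lv_error("lvmark_domain", "template needs at least two (x, y) points")
  colnames(points) <- c("x", "y")
  if (is.null(reference)) reference <- colMeans(points)
  if (is.null(orientations))
    orientations <- contour_orientations(points, closed = closed)
  orientations <- mod_pi(orientations)
  structure(list(points = points, reference = as.numeric(reference),
                 orientations = orientations, closed = closed),
            class = "boundary_template")
}

#' @export
print.boundary_template <- function(x, ...) {
  cat(sprintf("Boundary template: %d points, reference (%.1f, %.1f)\n",
              nrow(x$points), x$reference[1], x$reference[2]))
  invisible(x)
}

# Normal orientation (tangent + pi/2, mod pi) from ordered points, with a
# short running-mean smoothing of the coordinates to damp pixel jaggies.
contour_orientations <- function(points, closed = FALSE) {
  n <- nrow(points)
  sm <- function(v) {
    if (n < 7) return(v)
    k <- stats::filter(if (closed) c(tail(v, 2), v, head(v, 2)) else v,
                       rep(1 / 5, 5), sides = 2)
    k <- as.numeric(k)
    if (closed) k <- k[3:(n + 2)]
    ifelse(is.na(k), v, k)
  }
  xs <- sm(points[, 1]); ys <- sm(points[, 2])
  ip <- if (closed) c(2:n, 1) else c(2:n, n)
  im <- if (closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  mod_pi(atan2(ys[ip] - ys[im], xs[ip] - xs[im]) + pi / 2)
}

# Resample an ordered polyline at (approximately) unit arc-length spacing.
resample_polyline <- function(points, spacing = 1, closed = FALSE) {
  if (closed) points <- rbind(points, points[1, , drop = FALSE])
  seg <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(points[1, , drop = FALSE])
  t <- seq(0, total, by = spacing)
  cbind(x = approx(s, points[, 1], xout = t, ties = "ordered")$y,
        y = approx(s, points[, 2], xout = t, ties = "ordered")$y)
}

#' Canonical left-ventricle boundary template
#'
#' A U-shaped open contour modelling the endocardial border in an
#' apical-view frame: an elliptical arc with a gap at the mitral (bottom)
#' side, sampled at ~1-px arc-length spacing.  In image coordinates
#' (y down) the closed end — the LV apex — points up.  The first half of the
#' arc (left limb, x < center) is the septal wall, the second half the
#' lateral wall.
#'
#' @param axes `(a, b)` ellipse semi-axes, pixels.
#' @param center `(x, y)` ellipse center.
#' @param gap_halfangle half-width of the mitral-plane opening, radians.
#' @return a `boundary_template` with `septal_idx`/`lateral_idx` attributes.
#' @export
canonical_lv_template <- function(axes = c(36, 56), center = c(0, 0),
                                  gap_halfangle = pi / 9) {
  # arc from just past the gap (bottom-left) over the apex (top) back down;
  # bottom of the screen is t = pi/2 since y increases downward
  t0 <- pi / 2 + gap_halfangle
  t1 <- 2 * pi + pi / 2 - gap_halfangle
  tt <- seq(t0, t1, length.out = 2048)
  pts <- cbind(x = center[1] + axes[1] * cos(tt),
               y = center[2] + axes[2] * sin(tt))
  pts <- resample_polyline(pts)
  # analytic normals: tangent of the ellipse arc, rotated by pi/2
  n <- nrow(pts)
  ang <- atan2((pts[, 2] - center[2]) / axes[2], (pts[, 1] - center[1]) / axes[1])
  tang <- atan2(axes[2] * cos(ang), -axes[1] * sin(ang))
  tpl <- boundary_template(pts, orientations = mod_pi(tang + pi / 2))
  apex_i <- which.min(pts[, 2])  # closed end (smallest y)
  attr(tpl, "septal_idx") <- seq_len(apex_i)
  attr(tpl, "lateral_idx") <- seq(apex_i + 1L, n)
  tpl
}

#' Extract a boundary template from a binary sketch
#'
#' Keeps the largest connected foreground component, thins it to a 1-px
#' skeleton (Zhang-Suen), orders the skeleton pixels into a path, resamples
#' at unit arc length, and derives per-point orientations from the local
#' tangent.  The reference point is the barycenter.
#'
#' @param sketch logical or 0/1 numeric matrix (rows = y), or the path of a
#'   binary PNG drawing.
#' @return a `boundary_template`.
#' @export
template_from_sketch <- function(sketch) {
  if (is.character(sketch)) sketch <- read_gray(sketch)
  mask <- sketch > 0
  if (!any(mask)) lv_error("lvmark_empty_sketch", "sketch has no foreground pixels")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- tabulate(as.integer(lab))
  mask <- matrix(as.integer(lab) == which.max(areas), nrow(mask), ncol(mask))
  skel <- zs_thin(mask)
  path <- order_skeleton(skel)
  closed <- sqrt(sum((path[1, ] - path[nrow(path), ])^2)) <= 1.8
  pts <- resample_polyline(path, closed = closed)
  boundary_template(pts, closed = closed)
}

# Zhang-Suen morphological thinning of a logical mask.
zs_thin <- function(mask) {
  m <- mask
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(p, dy, dx) p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1);  p6 <- shift(pad, 1, 0);  p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(as.vector(p2), as.vector(p3), as.vector(p4), as.vector(p5),
                    as.vector(p6), as.vector(p7), as.vector(p8), as.vector(p9),
                    as.vector(p2))
      a <- matrix(rowSums(seqs[, 1:8, drop = FALSE] < seqs[, 2:9, drop = FALSE]),
                  h, w)
      cur <- pad[2:(h + 1), 2:(w + 1)]
      if (step == 1) {
        cond <- cur & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cur & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        cur[cond] <- FALSE
        pad[2:(h + 1), 2:(w + 1)] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)]
}

# Order skeleton pixels into a path by greedy nearest-neighbor walking from
# an endpoint (degree-1 pixel) when one exists, else from an arbitrary pixel
# (closed curves).
order_skeleton <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  n <- nrow(pts)
  if (n == 1) return(pts)
  key <- pts[, 1] * 1e6 + pts[, 2]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  nb_off <- expand.grid(dx = -1:1, dy = -1:1)
  nb_off <- nb_off[!(nb_off$dx == 0 & nb_off$dy == 0), ]
  neighbors <- function(i) {
    ks <- as.character((pts[i, 1] + nb_off$dx) * 1e6 + (pts[i, 2] + nb_off$dy))
    out <- integer(0)
    for (k in ks) if (exists(k, envir = lookup, inherits = FALSE))
      out <- c(out, get(k, envir = lookup))
    out
  }
  deg <- vapply(seq_len(n), function(i) length(neighbors(i)), integer(1))
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  visited <- rep(FALSE, n)
  path <- integer(n)
  cur <- start
  for (step in seq_len(n)) {
    path[step] <- cur
    visited[cur] <- TRUE
    nb <- neighbors(cur)
    nb <- nb[!visited[nb]]
    if (length(nb) == 0) { path <- path[seq_len(step)]; break }
    if (length(nb) > 1) {  # prefer 4-connected continuation
      d <- abs(pts[nb, 1] - pts[cur, 1]) + abs(pts[nb, 2] - pts[cur, 2])
      nb <- nb[order(d)]
    }
    cur <- nb[1]
  }
  pts[path, , drop = FALSE]
}

#' Guided deformable template
#'
#' Couples a thin septal limb, used for pose localization because the septal
#' wall is the better-visualized side, with a thick lateral band inside
#' which the lateral border is allowed to deform to the image evidence.
#' Both limbs share the template's reference point.
#'
#' @param template a [boundary_template()]; segment index attributes are
#'   honored when present (as set by [canonical_lv_template()]).
#' @param septal_idx,lateral_idx integer indices into the template points.
#' @param lateral_halfwidth half-width of the deformable band, pixels at unit
#'   scale (`> 1`).
#' @param septal_halfwidth half-width of the guidance limb (`<= 1`).
#' @return a `guided_template` object.
#' @export
guided_template <- function(template,
                            septal_idx = attr(template, "septal_idx"),
                            lateral_idx = attr(template, "lateral_idx"),
                            lateral_halfwidth = 6, septal_halfwidth = 1) {
  stopifnot(inherits(template, "boundary_template"))
  n <- nrow(template$points)
  if (is.null(septal_idx) || is.null(lateral_idx)) {
    septal_idx <- seq_len(floor(n / 2))
    lateral_idx <- seq(floor(n / 2) + 1L, n)
  }
  if (lateral_halfwidth <= septal_halfwidth)
    lv_error("lvmark_domain", "lateral band must be wider than the septal limb")
  ori <- template$orientations[lateral_idx]
  structure(list(points = template$points, reference = template$reference,
                 orientations = template$orientations,
                 septal_idx = as.integer(septal_idx),
                 lateral_idx = as.integer(lateral_idx),
                 lateral_halfwidth = lateral_halfwidth,
                 septal_halfwidth = septal_halfwidth,
                 normals = cbind(cos(ori), sin(ori))),
            class = "guided_template")
}

#' @export
print.guided_template <- function(x, ...) {
  cat(sprintf(
    "Guided template: %d septal + %d lateral points, band halfwidth %.1f px\n",
    length(x$septal_idx), length(x$lateral_idx), x$lateral_halfwidth))
  invisible(x)
}

#' Deform the lateral band to the image gradient
#'
#' Each posed lateral point may slide along its posed normal by an integer
#' offset bounded by the band half-width times the local scale.  The offsets
#' maximize the summed gradient magnitude at the displaced points minus a
#' smoothness penalty `beta * (d_i - d_{i+1})^2` between neighbors, solved
#' exactly by dynamic programming.  Ties prefer the smaller absolute offset,
#' then the negative one, so a gradient-free image returns the posed
#' polyline unchanged.
#'
#' @param img numeric matrix image.
#' @param gt a [guided_template()].
#' @param pose a [pose_params()] placing the template in the image.
#' @param beta smoothness weight per px^2.
#' @return tibble with columns `x`, `y` (deformed lateral polyline) and
#'   `offset` (signed px along the posed normal).
#' @export
deform_band <- function(img, gt, pose, beta = 0.1) {
  assert_gray(img)
  stopifnot(inherits(gt, "guided_template"))
  posed <- apply_pose(gt$points, pose, gt$reference)[gt$lateral_idx, , drop = FALSE]
  ori <- gt$orientations[gt$lateral_idx]
  # posed normal = perpendicular of the posed tangent
  nu <- pose_tangent(ori - pi / 2, pose) + pi / 2
  nx <- cos(nu); ny <- sin(nu)
  # orient normals consistently outward (away from the posed reference)
  ref <- if (is.null(pose$position)) gt$reference else pose$position
  flip <- sign((posed[, 1] - ref[1]) * nx + (posed[, 2] - ref[2]) * ny)
  flip[flip == 0] <- 1
  nx <- nx * flip; ny <- ny * flip
  # band half-length scales with the template normal under diag(S)
  sloc <- sqrt((pose$scale[1] * cos(ori))^2 + (pose$scale[2] * sin(ori))^2)
  lim <- pmax(0L, floor(gt$lateral_halfwidth * sloc))
  K <- max(lim)
  offs <- seq(-K, K)
  npt <- nrow(posed)

  g <- sobel_gradient(img)$mag
  score <- matrix(-Inf, npt, length(offs))
  inside_any <- FALSE
  for (s in seq_along(offs)) {
    d <- offs[s]
    px <- posed[, 1] + d * nx
    py <- posed[, 2] + d * ny
    v <- sample_bilinear(g, px, py)
    ok <- !is.na(v) & abs(d) <= lim
    if (any(!is.na(v))) inside_any <- TRUE
    # tiny bias implements the deterministic tie rule
    score[ok, s] <- v[ok] - 1e-9 * abs(d) - 5e-10 * (d > 0)
  }
  if (!inside_any)
    lv_error("lvmark_band_outside", "posed lateral band lies entirely outside the image")
  # an individual point whose whole band is outside keeps zero offset
  dead <- rowSums(is.finite(score)) == 0
  score[dead, offs == 0] <- 0

  V <- score[1, ]
  back <- matrix(0L, npt, length(offs))
  for (i in seq(2, length.out = npt - 1)) {
    # trans[t, s] = V[t] - beta (offs[s] - offs[t])^2
    trans <- V - beta * outer(offs, offs, function(t, s) (s - t)^2)
    best <- apply(trans, 2, which.max)
    V <- trans[cbind(best, seq_along(offs))] + score[i, ]
    back[i, ] <- best
  }
  state <- which.max(V)
  states <- integer(npt)
  states[npt] <- state
  for (i in seq(npt, 2)) states[i - 1] <- back[i, states[i]]
  d <- offs[states]
  tibble::tibble(x = posed[, 1] + d * nx, y = posed[, 2] + d * ny, offset = d)
}

# Bilinear interpolation at continuous 0-based (x, y); NA outside the image.
sample_bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  out[ok] <- img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
  out
}

#' Write / read a guided template as JSON
#'
#' Full-precision JSON serialization; `read_template()` round-trips the
#' object exactly.
#'
#' @param gt a `guided_template`.
#' @param path file path.
#' @export
write_template <- function(gt, path) {
  stopifnot(inherits(gt, "guided_template"))
  obj <- list(format = "lvmark-template", version = 1L,
              points = unname(apply(gt$points, 1, as.numeric, simplify = FALSE)),
              reference = gt$reference, orientations = gt$orientations,
              septal_idx = gt$septal_idx, lateral_idx = gt$lateral_idx,
              lateral_halfwidth = gt$lateral_halfwidth,
              septal_halfwidth = gt$septal_halfwidth)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "lvmark-template")
    lv_error("lvmark_bad_template", "not an lvmark template file")
  pts <- if (is.matrix(obj$points)) obj$points else
    matrix(unlist(obj$points), ncol = 2, byrow = TRUE)
  dimnames(pts) <- list(NULL, c("x", "y"))
  tpl <- boundary_template(pts, reference = obj$reference,
                           orientations = obj$orientations)
  guided_template(tpl, septal_idx = obj$septal_idx,
                  lateral_idx = obj$lateral_idx,
                  lateral_halfwidth = obj$lateral_halfwidth,
                  septal_halfwidth = obj$septal_halfwidth)
}
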