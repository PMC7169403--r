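#' Pose parameters of a template instance
#'
#' A pose is the reference-point position together with two orthogonal scale
#' factors and a rotation: a point `p` of a template with reference `ref`
#' maps to `position + Rot(rotation) diag(scale) (p - ref)`.
#'
#' @param position `(x, y)` of the posed reference point; `NULL` means "at the
#'   template's own reference" (pure scale/rotation about it).
#' @param scale `(Sx, Sy)`, both `> 0`.
#' @param rotation radians.
#' @return a `pose_params` object.
#' @export
pose_params <- function(position = NULL, scale = c(1, 1), rotation = 0) {
  if (length(scale) == 1) scale <- rep(scale, 2)
  if (any(scale <= 0)) lv_error("lvmark_domain", "scales must be positive")
  structure(list(position = position, scale = as.numeric(scale),
                 rotation = as.numeric(rotation)),
            class = "pose_params")
}

#' @export
print.pose_params <- function(x, ...) {
  pos <- if (is.null(x$position)) "(template reference)" else
    sprintf("(%.1f, %.1f)", x$position[1], x$position[2])
  cat(sprintf("Pose: position %s, scale (%.3f, %.3f), rotation %.3f rad\n",
              pos, x$scale[1], x$scale[2], x$rotation))
  invisible(x)
}

#' Apply a pose to template points
#'
#' @param points n x 2 matrix of `(x, y)` points.
#' @param pose a [pose_params()] object.
#' @param reference the template reference point the pose pivots about.
#' @return n x 2 matrix of posed points.
#' @export
apply_pose <- function(points, pose, reference) {
  pos <- if (is.null(pose$position)) reference else pose$position
  ct <- cos(pose$rotation); st <- sin(pose$rotation)
  dx <- (points[, 1] - reference[1]) * pose$scale[1]
  dy <- (points[, 2] - reference[2]) * pose$scale[2]
  cbind(x = pos[1] + ct * dx - st * dy,
        y = pos[2] + st * dx + ct * dy)
}

# Tangent direction under a pose: scale the tangent vector per axis, rotate,
# and renormalize.  Used to carry template normals into the image.
pose_tangent <- function(tangents, pose) {
  tx <- cos(tangents) * pose$scale[1]
  ty <- sin(tangents) * pose$scale[2]
  atan2(ty, tx) + pose$rotation
}
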