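.lv_feature_names <- c("max_rate", "mean_rate", "var_rate", "peak_ratio",
                       "entropy", "pos_sx", "pos_sy", "pos_theta",
                       "pos_x", "pos_y", "peak_mass")

#' Summary features of an accumulator space
#'
#' A fixed-length descriptor of the vote distribution, independent of the
#' grid size: maximum rate, mean and population variance of the cells,
#' peak-to-second-peak ratio (second peak taken outside `radius` pixels of
#' the peak position, capped at `1e6` when it is zero), Shannon entropy
#' (natural log) of the normalized vote histogram, the argmax pose
#' coordinates normalized to their grid ranges, and the fraction of all
#' votes within `radius` pixels of the peak position.
#'
#' @param acc a `ght_accumulator`.
#' @param radius pixels; positional neighborhood of the peak.
#' @param source `"full"` or `"restricted"`, recorded alongside the features.
#' @return one-row tibble with the 11 feature columns plus `source`.
#' @export
featurize <- function(acc, radius = 5, source = "full") {
  stopifnot(inherits(acc, "ght_accumulator"))
  v <- acc$votes
  tot <- sum(as.numeric(v))
  if (tot <= 0) lv_error("lvmark_degenerate_acc", "all-zero accumulator")
  p <- as.numeric(v) / tot
  p <- p[p > 0]
  entropy <- -sum(p * log(p))
  mx <- max(v)
  # argmax with the candidate-ranking tie order
  cells <- which(v == mx)
  info <- acc_cell_info(acc, cells)
  o <- order(info$theta_bin, info$sx_bin, info$sy_bin, info$iy, info$ix)
  peak <- info[o[1], ]
  pxv <- acc$x[peak$ix]; pyv <- acc$y[peak$iy]
  d <- dim(v)
  # positional distance of every cell from the peak
  ddx <- outer(rep(1, d[4]), (acc$x - pxv)^2)
  ddy <- outer((acc$y - pyv)^2, rep(1, d[5]))
  near_pos <- (ddx + ddy) <= radius^2  # ny x nx
  per_pos <- apply(v, c(4, 5), sum)
  peak_mass <- sum(per_pos[near_pos]) / tot
  vmat <- matrix(v, nrow = d[1] * d[2] * d[3])
  second <- suppressWarnings(max(vmat[, !as.vector(near_pos), drop = FALSE]))
  if (!is.finite(second)) second <- 0
  ratio <- if (second <= 0) 1e6 else mx / second
  norm01 <- function(axis, i) {
    rng <- range(axis)
    if (diff(rng) == 0) 0.5 else (axis[i] - rng[1]) / diff(rng)
  }
  out <- tibble::tibble(max_rate = as.numeric(mx),
                        mean_rate = mean(as.numeric(v)),
                        var_rate = mean((as.numeric(v) - mean(as.numeric(v)))^2),
                        peak_ratio = min(ratio, 1e6),
                        entropy = entropy,
                        pos_sx = norm01(acc$sx, peak$sx_bin),
                        pos_sy = norm01(acc$sy, peak$sy_bin),
                        pos_theta = norm01(acc$theta, peak$theta_bin),
                        pos_x = norm01(acc$x, peak$ix),
                        pos_y = norm01(acc$y, peak$iy),
                        peak_mass = peak_mass,
                        source = source)
  structure(out, class = c("acc_features", class(out)))
}

feature_matrix <- function(features) {
  as.matrix(as.data.frame(features)[, .lv_feature_names, drop = FALSE])
}

#' Train the marking-confidence classifier
#'
#' Fits a support vector machine with a cubic polynomial kernel
#' `(x . x' / s^2 + 1)^3` on standardized accumulator features, where the
#' automatic kernel scale `s` is the median pairwise Euclidean distance
#' between the (standardized) training vectors.  Reports leave-one-out
#' cross-validated accuracy, with the standardization and kernel scale
#' recomputed inside every fold.
#'
#' @param features data frame of accumulator features ([featurize()] rows).
#' @param labels logical (or `"correct"`/`"incorrect"`) per row; `TRUE`
#'   means the marking was correct.
#' @param seed integer; training is deterministic given it.
#' @param kernel `"cubic"` (default) or `"linear"` (diagnostic).
#' @param cost SVM cost parameter.
#' @return a `confidence_model` with a `loocv_accuracy` field.
#' @export
train_confidence <- function(features, labels, seed = 1L,
                             kernel = c("cubic", "linear"), cost = 1) {
  kernel <- match.arg(kernel)
  x <- feature_matrix(features)
  y <- normalize_labels(labels, nrow(x))
  if (length(unique(y)) < 2)
    lv_error("lvmark_single_class", "need both correct and incorrect samples")
  if (min(table(y)) < 2)
    lv_error("lvmark_single_class", "need at least 2 samples per class")
  set.seed(seed)
  fit <- fit_svm(x, y, kernel, cost)
  n <- nrow(x)
  hits <- logical(n)
  for (i in seq_len(n)) {
    f <- fit_svm(x[-i, , drop = FALSE], y[-i], kernel, cost)
    hits[i] <- (svm_margin(f, x[i, , drop = FALSE]) > 0) == (y[i] == "correct")
  }
  structure(c(fit, list(loocv_accuracy = mean(hits), n = n, seed = seed,
                        kernel = kernel,
                        source = unique(as.character(features$source %||% NA)),
                        feature_names = .lv_feature_names)),
            class = "confidence_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_labels <- function(labels, n) {
  if (is.logical(labels)) labels <- ifelse(labels, "correct", "incorrect")
  labels <- as.character(labels)
  if (length(labels) != n || !all(labels %in% c("correct", "incorrect")))
    lv_error("lvmark_domain", "labels must be logical or 'correct'/'incorrect'")
  factor(labels, levels = c("incorrect", "correct"))
}

fit_svm <- function(x, y, kernel, cost) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- scale(x, ctr, scl)
  s <- median(dist(z))
  if (!is.finite(s) || s <= 0) s <- 1
  svm_args <- if (kernel == "cubic")
    list(kernel = "polynomial", degree = 3, gamma = 1 / s^2, coef0 = 1)
  else list(kernel = "linear")
  fit <- do.call(e1071::svm, c(list(x = z, y = y, cost = cost, scale = FALSE),
                               svm_args))
  # orient the margin so that positive means "correct"
  dv <- attr(predict(fit, z, decision.values = TRUE), "decision.values")
  sign_flip <- if (grepl("^incorrect", colnames(dv)[1])) -1 else 1
  list(fit = fit, center = ctr, scale = scl, kernel_scale = s,
       sign_flip = sign_flip)
}

svm_margin <- function(model, x) {
  z <- scale(x, model$center, model$scale)
  dv <- attr(predict(model$fit, z, decision.values = TRUE), "decision.values")
  model$sign_flip * as.numeric(dv)
}

#' Confidence of a marking from its accumulator features
#'
#' Maps the signed SVM margin through a logistic squashing into `[0, 1]`;
#' `0.5` sits exactly on the decision boundary and larger values mean the
#' marking is more likely correct.
#'
#' @param model a [train_confidence()] result.
#' @param features one or more feature rows ([featurize()] output).
#' @return numeric vector of confidences in `[0, 1]`.
#' @export
score_confidence <- function(model, features) {
  stopifnot(inherits(model, "confidence_model"))
  x <- feature_matrix(features)
  if (ncol(x) != length(model$feature_names))
    lv_error("lvmark_domain", "feature length does not match the trained model")
  stats::plogis(svm_margin(model, x))
}

#' @export
print.confidence_model <- function(x, ...) {
  cat(sprintf(
    "Confidence model: %s kernel (scale %.3g), n = %d, LOOCV accuracy %.1f%%\n",
    x$kernel, x$kernel_scale, x$n, 100 * x$loocv_accuracy))
  invisible(x)
}

#' One-row model summary
#'
#' @param x a `confidence_model`.
#' @param ... unused.
#' @return tibble with sample size, kernel, kernel scale, support-vector
#'   count and LOOCV accuracy.
#' @exportS3Method generics::glance
glance.confidence_model <- function(x, ...) {
  tibble::tibble(n = x$n, kernel = x$kernel, kernel_scale = x$kernel_scale,
                 n_support = nrow(x$fit$SV), loocv_accuracy = x$loocv_accuracy)
}

#' Save / load a confidence model
#'
#' Single-file RDS bundle; reloading reproduces scores exactly.
#'
#' @param model a `confidence_model`.
#' @param path file path.
#' @export
write_confidence <- function(model, path) {
  stopifnot(inherits(model, "confidence_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_confidence
#' @export
read_confidence <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "confidence_model"))
    lv_error("lvmark_bad_model", "not an lvmark confidence model")
  model
}

#' Phantom benchmark for the confidence classifier
#'
#' Generates a seeded set of phantoms spanning benign to hostile imaging
#' conditions (speckle up to 1.8, lateral attenuation up to 1, poses off
#' the search grid) and runs two pipelines on each: the full procedure with
#' the Gabor ROI, and the same procedure searching the whole image (the
#' ROI stage disabled).  Each pipeline's accumulator is featurized and its
#' sample labelled by whether that pipeline's own marking has mean boundary
#' error at most `label_px` pixels — the restricted and full feature sets
#' each describe the accumulator space that produced their marking.
#'
#' @param seed integer; drives phantom poses and noise.
#' @param n number of phantoms.
#' @param image_size `(H, W)`; the default keeps the bench fast.
#' @param label_px labelling threshold on mean boundary error, pixels.
#' @return list with tibbles `full` and `restricted` (features + `label`)
#'   and the per-phantom, per-pipeline `errors`.
#' @export
confidence_bench <- function(seed = 1L, n = 24, image_size = c(128, 128),
                             label_px = 3) {
  set.seed(seed)
  h <- image_size[1]; w <- image_size[2]
  rows_full <- list(); rows_restr <- list()
  err_full <- err_restr <- numeric(n)
  lab_full <- lab_restr <- logical(n)
  cfg_roi <- pipeline_config(image_size = image_size)
  # the "full" arm is the direct GHT: whole-image search without the ROI
  # restriction, peak consolidation or candidate verification
  cfg_all <- pipeline_config(image_size = image_size,
                             roi = list(enabled = FALSE),
                             ght = list(smooth_radius = 0, verify = FALSE))
  ref <- canonical_lv_template(c(0.14 * w, 0.22 * h),
                               c(w / 2, 0.52 * h))$reference
  one <- function(ph, cfg, source) {
    res <- tryCatch(suppressWarnings(run_pipeline(ph$image, cfg,
                                                  keep_accumulators = TRUE)),
                    lvmark_error = function(e) NULL)
    if (is.null(res))  # no usable detection: maximally wrong marking
      return(list(err = NA_real_, label = FALSE, row = NULL))
    err <- boundary_error(marking_boundary(res), ph$truth$boundary)$mean_dist
    list(err = err, label = err <= label_px,
         row = cbind(featurize(res$acc_restricted, source = source),
                     label = err <= label_px))
  }
  for (i in seq_len(n)) {
    hostile <- (i %% 2 == 0)
    spec <- phantom_spec(
      image_size = image_size,
      cavity_center = c(w / 2, 0.52 * h),
      wall_thickness = 8,
      pose = pose_params(
        position = ref + runif(2, -4, 4),
        scale = c(runif(1, 0.9, 1.1), runif(1, 0.9, 1.1)),
        rotation = runif(1, -0.35, 0.35)),
      speckle_scale = if (hostile) runif(1, 0.8, 1.8) else runif(1, 0, 0.35),
      lateral_attenuation = if (hostile) runif(1, 0.8, 1) else runif(1, 0, 0.5),
      seed = seed * 1000L + i)
    ph <- generate_phantom(spec)
    r <- one(ph, cfg_roi, "restricted")
    f <- one(ph, cfg_all, "full")
    err_restr[i] <- r$err; lab_restr[i] <- r$label
    err_full[i] <- f$err; lab_full[i] <- f$label
    if (!is.null(r$row)) rows_restr[[length(rows_restr) + 1L]] <- r$row
    if (!is.null(f$row)) rows_full[[length(rows_full) + 1L]] <- f$row
  }
  list(full = tibble::as_tibble(do.call(rbind, rows_full)),
       restricted = tibble::as_tibble(do.call(rbind, rows_restr)),
       errors = tibble::tibble(phantom = seq_len(n),
                               restricted_dist = err_restr,
                               restricted_label = lab_restr,
                               full_dist = err_full,
                               full_label = lab_full))
}
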