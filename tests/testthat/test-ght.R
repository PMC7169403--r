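test_that("edge detection finds step edges with the right orientation", {
  expect_equal(nrow(detect_edges(matrix(7, 32, 32))), 0)
  img <- matrix(0, 48, 48)
  img[, 25:48] <- 200  # vertical step between x = 23 and x = 24
  e <- detect_edges(img)
  expect_gt(nrow(e), 0)
  expect_true(all(abs(e$x - 23.5) <= 1))
  # gradient is horizontal: orientation ~ 0 mod pi
  expect_true(all(pmin(e$phi, pi - e$phi) < 0.05))
  # ROI restriction picks exactly the sub-box subset
  roi <- lvmark:::roi_from_mask(rbind(matrix(TRUE, 24, 48),
                                      matrix(FALSE, 24, 48)))
  e_top <- detect_edges(img, roi, threshold = 1)
  e_all <- detect_edges(img, threshold = 1)
  expect_equal(as.data.frame(e_top),
               as.data.frame(e_all[e_all$y < 24, ]))
})

test_that("the R-table stores one polar displacement per template point", {
  circ <- circle_template(r = 15)
  rt <- build_rtable(circ, 36)
  # for a circle every displacement has the circle's radius
  expect_true(all(abs(rt$entries$rho - 15) < 1.5))
  expect_equal(nrow(rt$entries), nrow(circ$points))
  # degenerate binning: one bin holds everything
  rt1 <- build_rtable(circ, 1)
  expect_true(all(rt1$entries$bin == 1))
  # conservation for an arbitrary template
  tpl <- canonical_lv_template(c(20, 30))
  rt2 <- build_rtable(tpl, 36)
  expect_equal(nrow(rt2$entries), nrow(tpl$points))
  expect_true(all(rt2$entries$bin >= 1 & rt2$entries$bin <= 36))
})

test_that("R-table JSON round-trips and validates conservation", {
  rt <- build_rtable(circle_template(), 12)
  path <- tempfile(fileext = ".json")
  write_rtable(rt, path)
  rt2 <- read_rtable(path)
  expect_equal(rt2$n_bins, rt$n_bins)
  expect_equal(nrow(rt2$entries), nrow(rt$entries))
  expect_equal(sort(rt2$entries$rho), sort(rt$entries$rho), tolerance = 1e-12)
  # a corrupted header fails the conservation check
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$n_entries <- obj$n_entries + 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_rtable(path), class = "lvmark_bad_rtable")
})

test_that("stamping a template at a pose is recovered with rate = n points", {
  tpl <- canonical_lv_template(c(24, 36), c(0, 0))
  grid <- ght_grid(sx = seq(0.85, 1.15, by = 0.05),
                   sy = seq(0.85, 1.15, by = 0.05),
                   theta = seq(-pi / 6, pi / 6, by = pi / 18),
                   xlim = c(0, 160), ylim = c(0, 160))
  rt <- build_rtable(tpl, 36)
  cases <- list(
    pose_params(position = c(80, 80)),
    pose_params(position = c(70, 90), scale = c(0.9, 1.1), rotation = pi / 18),
    pose_params(position = c(85, 75), scale = c(1.15, 0.85), rotation = -pi / 6))
  for (pose in cases) {
    acc <- accumulate_ght(stamp_edges(tpl, pose), rt, grid)
    top <- top_candidates(acc, k = 3)[1, ]
    expect_equal(top$rate, nrow(tpl$points))
    expect_equal(c(top$sx, top$sy), pose$scale)
    expect_equal(top$theta, pose$rotation)
    expect_equal(c(top$x, top$y), pose$position)
  }
})

test_that("rotating the stamp by one grid step moves the maximum with it", {
  tpl <- canonical_lv_template(c(24, 36), c(0, 0))
  rt <- build_rtable(tpl, 36)
  grid <- ght_grid(sx = 1, sy = 1, theta = c(0, pi / 18),
                   xlim = c(0, 160), ylim = c(0, 160))
  a0 <- top_candidates(accumulate_ght(
    stamp_edges(tpl, pose_params(position = c(80, 80))), rt, grid), 1)
  a1 <- top_candidates(accumulate_ght(
    stamp_edges(tpl, pose_params(position = c(80, 80), rotation = pi / 18)),
    rt, grid), 1)
  expect_equal(a0$theta, 0)
  expect_equal(a1$theta, pi / 18)
  expect_equal(a1$rate, a0$rate)
  expect_equal(c(a1$x, a1$y), c(a0$x, a0$y))
})

test_that("accumulation equals the brute-force oracle on small instances", {
  for (seed in 1:5) {
    inst <- random_ght_instance(seed)
    acc <- accumulate_ght(inst$edges, inst$rt, inst$grid)
    expect_identical(acc$votes, ght_oracle(inst$edges, inst$rt, inst$grid))
  }
})

test_that("deleting edges never increases votes; translation shifts argmax", {
  inst <- random_ght_instance(42)
  acc <- accumulate_ght(inst$edges, inst$rt, inst$grid)
  sub <- accumulate_ght(inst$edges[1:50, ], inst$rt, inst$grid)
  expect_true(all(sub$votes <= acc$votes))
  # translation equivariance on a stamped template
  tpl <- canonical_lv_template(c(20, 30), c(0, 0))
  rt <- build_rtable(tpl, 36)
  grid <- ght_grid(sx = 1, sy = 1, theta = 0, xlim = c(0, 200), ylim = c(0, 200))
  e0 <- stamp_edges(tpl, pose_params(position = c(90, 90)))
  e1 <- e0
  e1$x <- e1$x + 13; e1$y <- e1$y - 9
  t0 <- top_candidates(accumulate_ght(e0, rt, grid), 1)
  t1 <- top_candidates(accumulate_ght(e1, rt, grid), 1)
  expect_equal(c(t1$x - t0$x, t1$y - t0$y), c(13, -9))
  expect_equal(t1$rate, t0$rate)
})

test_that("candidate ranking sorts by rate with the documented tie order", {
  # single nonzero cell
  v <- array(0L, c(2, 2, 2, 6, 6))
  v[2, 1, 2, 3, 4] <- 7L
  acc <- make_acc(v)
  d <- top_candidates(acc, k = 5)
  expect_equal(nrow(d), 1)
  expect_equal(d$rate, 7L)
  expect_equal(c(d$sx_bin, d$sy_bin, d$theta_bin), c(2, 1, 2))
  expect_equal(c(d$x, d$y), c(3, 2))  # 0-based axes from make_acc
  # two equal maxima: smaller theta bin wins
  v[1, 2, 1, 5, 5] <- 7L
  d2 <- top_candidates(make_acc(v), k = 2, suppression_radius = 0)
  expect_equal(d2$theta_bin, c(1, 2))
  # all-zero accumulator yields an empty list
  expect_equal(nrow(top_candidates(make_acc(array(0L, c(2, 2, 2, 4, 4))))), 0)
})

test_that("ranking without suppression equals an independent full sort", {
  set.seed(7)
  v <- array(sample(0:9, 4 * 4 * 4 * 16 * 16, replace = TRUE),
             c(4, 4, 4, 16, 16))
  acc <- make_acc(v)
  k <- 200
  d <- top_candidates(acc, k = k, suppression_radius = 0, smooth_radius = 0)
  # independent sort over all nonzero cells
  idx <- which(v > 0)
  ai <- arrayInd(idx, dim(v))
  o <- order(-v[idx], ai[, 3], ai[, 1], ai[, 2], ai[, 4], ai[, 5])
  top <- head(o, k)
  expect_equal(d$rate, as.integer(v[idx][top]))
  expect_equal(d$sx_bin, ai[top, 1])
  expect_equal(d$sy_bin, ai[top, 2])
  expect_equal(d$theta_bin, ai[top, 3])
  expect_equal(d$y, acc$y[ai[top, 4]])
  expect_equal(d$x, acc$x[ai[top, 5]])
})

test_that("non-maximum suppression enforces the positional radius", {
  v <- array(0L, c(1, 1, 1, 20, 20))
  v[1, 1, 1, 5, 5] <- 10L
  v[1, 1, 1, 5, 8] <- 9L   # within radius 5 of the peak
  v[1, 1, 1, 5, 15] <- 8L  # outside
  d <- top_candidates(make_acc(v), k = 5, suppression_radius = 5)
  expect_equal(d$rate, c(10L, 8L))
})

test_that("ROI restriction cannot raise the maximum accumulator rate", {
  spec <- phantom_spec(image_size = c(128, 128), speckle_scale = 0.2,
                       cavity_center = c(64, 0.52 * 128),
                       wall_thickness = 8, seed = 3)
  ph <- generate_phantom(spec)
  tpl <- guided_template(canonical_lv_template(c(0.14 * 128, 0.22 * 128)))
  rt <- build_rtable(tpl, 36)
  e_full <- detect_edges(ph$image, threshold = 100)
  roi <- lvmark:::roi_from_mask(
    rbind(matrix(TRUE, 96, 128), matrix(FALSE, 32, 128)))
  e_roi <- detect_edges(ph$image, roi, threshold = 100)
  mk <- function(e, xlim, ylim)
    max(accumulate_ght(e, rt, ght_grid(sx = c(0.9, 1, 1.1), sy = c(0.9, 1, 1.1),
                                       theta = 0, xlim = xlim, ylim = ylim))$votes)
  expect_lte(mk(e_roi, c(0, 128), c(0, 96)), mk(e_full, c(0, 128), c(0, 128)))
})
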