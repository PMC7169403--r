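# Independent oracles and small fixture builders shared across tests.

# Same rounding rule as the voting kernel: half away from zero.
r_half_away <- function(v) trunc(v + sign(v) * 0.5)

# Brute-force GHT accumulation: an explicit loop over pose cells and edge
# points (vectorized only over the R-table entries of the matched bin).
# Deliberately independent of the package's voting path.
ght_oracle <- function(edges, rt, grid) {
  nx <- grid$x1 - grid$x0
  ny <- grid$y1 - grid$y0
  votes <- array(0L, c(length(grid$sx), length(grid$sy), length(grid$theta),
                       ny, nx))
  dt <- pi / rt$n_bins
  ent <- split(rt$entries, rt$entries$bin)
  for (it in seq_along(grid$theta)) {
    th <- grid$theta[it]
    ct <- cos(th); st <- sin(th)
    bins <- pmin(floor(((edges$phi - th) %% pi) / dt), rt$n_bins - 1) + 1
    for (is in seq_along(grid$sx)) for (js in seq_along(grid$sy)) {
      for (e in seq_len(nrow(edges))) {
        b <- ent[[as.character(bins[e])]]
        if (is.null(b)) next
        rx <- b$rho * cos(b$alpha) * grid$sx[is]
        ry <- b$rho * sin(b$alpha) * grid$sy[js]
        ix <- r_half_away(edges$x[e] + ct * rx - st * ry) - grid$x0 + 1
        iy <- r_half_away(edges$y[e] + st * rx + ct * ry) - grid$y0 + 1
        ok <- which(ix >= 1 & ix <= nx & iy >= 1 & iy <= ny)
        for (q in ok)
          votes[is, js, it, iy[q], ix[q]] <- votes[is, js, it, iy[q], ix[q]] + 1L
      }
    }
  }
  votes
}

# Random GHT instance within the documented small-instance envelope.
random_ght_instance <- function(seed) {
  set.seed(seed)
  ne <- sample(30:200, 1)
  edges <- tibble::tibble(x = sample(0:63, ne, replace = TRUE),
                          y = sample(0:63, ne, replace = TRUE),
                          phi = runif(ne, 0, pi), mag = 1)
  n_bins <- sample(c(4, 8, 12), 1)
  nent <- sample(20:60, 1)
  ori <- runif(nent, 0, pi)
  pts <- cbind(x = runif(nent, 10, 50), y = runif(nent, 10, 50))
  tpl <- boundary_template(pts, orientations = ori)
  rt <- build_rtable(tpl, n_bins)
  naxis <- function() sample(2:5, 1)
  grid <- ght_grid(sx = sort(runif(naxis(), 0.7, 1.3)),
                   sy = sort(runif(naxis(), 0.7, 1.3)),
                   theta = sort(runif(sample(2:8, 1), -pi / 3, pi / 3)),
                   xlim = c(0, 64), ylim = c(0, 64))
  list(edges = edges, rt = rt, grid = grid)
}

# Circle boundary template with analytically known orientations.  The phase
# offset keeps orientations away from exact R-table bin edges, where a
# one-ulp rounding difference could move a point to the neighboring bin.
circle_template <- function(r = 20, center = c(32, 32), n = 120) {
  t <- 0.0123 + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- cbind(x = center[1] + r * cos(t), y = center[2] + r * sin(t))
  boundary_template(pts, orientations = (t %% pi), closed = TRUE)
}

# A feature row that varies only in max_rate; the rest of the descriptor is
# held fixed so classifiers see a 1-D problem.
make_features <- function(v, source = "full") {
  tibble::tibble(max_rate = v, mean_rate = 1, var_rate = 1, peak_ratio = 2,
                 entropy = 3, pos_sx = 0.5, pos_sy = 0.5, pos_theta = 0.5,
                 pos_x = 0.5, pos_y = 0.5, peak_mass = 0.1, source = source)
}

# Hand-built accumulator object (featurize and top_candidates only touch the
# votes array and the axis vectors).
make_acc <- function(votes, sx = NULL, sy = NULL, theta = NULL,
                     x0 = 0, y0 = 0) {
  d <- dim(votes)
  structure(list(votes = votes,
                 sx = if (is.null(sx)) seq(0.8, length.out = d[1], by = 0.1) else sx,
                 sy = if (is.null(sy)) seq(0.8, length.out = d[2], by = 0.1) else sy,
                 theta = if (is.null(theta)) seq(0, length.out = d[3], by = 0.2) else theta,
                 x = seq(x0, length.out = d[5]),
                 y = seq(y0, length.out = d[4])),
            class = "ght_accumulator")
}

# Grid-pose phantom at 256x256 used by the recovery tests.
grid_pose_phantom <- function(seed, speckle = 0) {
  set.seed(seed)
  cfg <- pipeline_config(image_size = c(256, 256))
  ref <- canonical_lv_template(cfg$template$axes, c(128, 0.48 * 256))$reference
  pose <- pose_params(position = round(ref) + c(sample(-6:6, 1), sample(-6:6, 1)),
                      scale = c(sample(cfg$ght$sx, 1), sample(cfg$ght$sy, 1)),
                      rotation = sample(cfg$ght$theta, 1))
  spec <- phantom_spec(image_size = c(256, 256), pose = pose,
                       speckle_scale = speckle, seed = seed)
  list(spec = spec, phantom = generate_phantom(spec), cfg = cfg)
}
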