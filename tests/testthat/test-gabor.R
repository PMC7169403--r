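test_that("bandwidth-sigma coupling matches the closed forms", {
  # at unit bandwidth sigma = 0.56 lambda
  expect_equal(sigma_from_bandwidth(1, 10), 5.6, tolerance = 0.05 / 5.6)
  expect_equal(sigma_from_bandwidth(1, 1), 0.56, tolerance = 0.005 / 0.56)
  expect_equal(bandwidth_from_sigma(0.56, 1), 1, tolerance = 0.01)
  # frozen high-precision evaluation at b = 2
  expect_equal(sigma_from_bandwidth(2, 1), 0.31231770854879598,
               tolerance = 1e-14)
  # sigma is linear in lambda at fixed b
  expect_equal(sigma_from_bandwidth(1.3, 7) / 7, sigma_from_bandwidth(1.3, 1),
               tolerance = 1e-12)
  expect_error(sigma_from_bandwidth(0, 1), class = "lvmark_domain")
  expect_error(sigma_from_bandwidth(1, -2), class = "lvmark_domain")
  # below the pole of the inverse relation the bandwidth is undefined
  expect_error(bandwidth_from_sigma(sqrt(log(2) / 2) / pi, 1),
               class = "lvmark_domain")
})

test_that("bandwidth and sigma conversions are mutual inverses", {
  for (b in c(0.25, 0.5, 1, 2, 3, 4))
    expect_equal(bandwidth_from_sigma(sigma_from_bandwidth(b, 1), 1), b,
                 tolerance = 1e-9)
  # sigma strictly decreasing in b; b strictly decreasing in sigma/lambda
  bs <- seq(0.25, 4, by = 0.25)
  expect_true(all(diff(sigma_from_bandwidth(bs, 1)) < 0))
  rs <- seq(0.3, 5, by = 0.1)
  expect_true(all(diff(bandwidth_from_sigma(rs, 1)) < 0))
})

test_that("the Gabor kernel has the analytic center, symmetry and samples", {
  for (th in c(0, 0.7, 2)) {
    k <- gabor_kernel(gabor_params(8, theta = th, phase = 0, gamma = 0.6))
    r <- (nrow(k) - 1) / 2
    expect_equal(k[r + 1, r + 1], 1.0)
    # even symmetry at zero phase: k(x, y) = k(-x, -y)
    expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))],
                 tolerance = 1e-12)
  }
  # cos(phase) at the center for a nonzero phase
  k <- gabor_kernel(gabor_params(8, phase = 1.1))
  expect_equal(k[(nrow(k) + 1) / 2, (ncol(k) + 1) / 2], cos(1.1))
  # hand-evaluated sample at (x, y) = (lambda/2, 0), theta = 0, gamma = 1:
  # the cosine is at a half cycle, the envelope at exp(-lambda^2 / (8 sigma^2))
  p <- gabor_params(8, theta = 0, phase = 0, gamma = 1)
  k <- gabor_kernel(p)
  r <- (nrow(k) - 1) / 2
  expect_equal(k[r + 1, r + 1 + 4], -0.67332777192582449, tolerance = 1e-12)
  # rotating theta by pi gives the point reflection at zero phase
  k2 <- gabor_kernel(gabor_params(8, theta = 0.4), radius = 10)
  k3 <- gabor_kernel(gabor_params(8, theta = 0.4 + pi), radius = 10)
  expect_equal(k3, k2[rev(1:21), rev(1:21)], tolerance = 1e-12)
})

test_that("filter bank response behaves like rectified convolution energy", {
  const <- matrix(5, 32, 32)
  odd <- list(gabor_params(8, phase = pi / 2))
  expect_lt(max(filter_bank_response(const, odd)), 1e-6 * 5)
  # a singleton bank is the absolute convolution
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- gabor_params(6, theta = 0.3)
  resp <- filter_bank_response(img, list(p))
  expect_equal(resp, abs(lvmark:::conv2_reflect(img, gabor_kernel(p))),
               tolerance = 1e-12)
  # non-negative and image-shaped
  expect_true(all(resp >= 0))
  expect_identical(dim(resp), dim(img))
})

test_that("an aligned kernel out-responds the orthogonal one on a grating", {
  x <- matrix(seq_len(64) - 1, 64, 64, byrow = TRUE)
  grating <- 128 + 100 * sin(2 * pi * x / 8)  # vertical stripes, normal = x
  aligned <- filter_bank_response(grating, list(gabor_params(8, theta = 0),
                                                gabor_params(8, theta = 0, phase = pi / 2)))
  ortho <- filter_bank_response(grating, list(gabor_params(8, theta = pi / 2),
                                              gabor_params(8, theta = pi / 2, phase = pi / 2)))
  interior <- 20:45
  expect_true(all(aligned[interior, interior] >= ortho[interior, interior]))
})

test_that("adding a constant does not change a zero-DC bank's response", {
  set.seed(2)
  img <- matrix(runif(48 * 48, 0, 200), 48, 48)
  bank <- list(gabor_params(8, phase = pi / 2),
               gabor_params(8, theta = pi / 3, phase = pi / 2))
  r1 <- filter_bank_response(img, bank)
  r2 <- filter_bank_response(img + 60, bank)
  expect_lt(max(abs(r1 - r2)), 1e-6 * max(img))
})

test_that("ROI extraction keeps the largest component with a padded box", {
  resp <- matrix(0, 64, 64)
  resp[21:40, 11:30] <- 10  # rows = y in [20, 40), cols = x in [10, 30)
  roi <- extract_roi(resp, margin = 0)
  expect_equal(unname(roi$bbox), c(10, 20, 30, 40))
  roi5 <- extract_roi(resp, margin = 5)
  expect_equal(unname(roi5$bbox), c(5, 15, 35, 45))
  # margin clips at the image edge
  resp2 <- matrix(0, 64, 64)
  resp2[1:20, 1:20] <- 10
  expect_equal(unname(extract_roi(resp2, margin = 5)$bbox), c(0, 0, 25, 25))
  # two components: only the larger one survives
  resp3 <- matrix(0, 64, 64)
  resp3[5:9, 5:14] <- 10          # 50 px
  resp3[30:49, 30:49] <- 10       # 400 px
  roi3 <- extract_roi(resp3, margin = 0)
  expect_equal(unname(roi3$bbox), c(29, 29, 49, 49))
  expect_false(any(roi3$mask[5:9, 5:14]))
  expect_error(extract_roi(matrix(0, 8, 8)), class = "lvmark_no_roi")
})
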