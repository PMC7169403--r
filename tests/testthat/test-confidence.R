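test_that("accumulator features match their definitions", {
  # single nonzero cell: capped peak ratio, zero entropy
  v <- array(0L, c(2, 2, 2, 8, 8))
  v[1, 2, 1, 4, 5] <- 9L
  f <- featurize(make_acc(v))
  expect_equal(f$max_rate, 9)
  expect_equal(f$peak_ratio, 1e6)
  expect_equal(f$entropy, 0)
  expect_equal(f$peak_mass, 1)
  # uniform accumulator: entropy log(n cells), unit peak ratio
  u <- array(3L, c(2, 2, 2, 8, 8))
  fu <- featurize(make_acc(u))
  expect_equal(fu$entropy, log(length(u)))
  expect_equal(fu$peak_ratio, 1)
  expect_error(featurize(make_acc(array(0L, c(1, 1, 1, 4, 4)))),
               class = "lvmark_degenerate_acc")
})

test_that("features agree with a naive independent recomputation", {
  set.seed(13)
  v <- array(sample(0:6, 3 * 2 * 4 * 9 * 8, replace = TRUE), c(3, 2, 4, 9, 8))
  acc <- make_acc(v)
  f <- featurize(acc, radius = 3)
  expect_equal(f$max_rate, max(v))
  expect_equal(f$mean_rate, mean(v))
  expect_equal(f$var_rate, sum((v - mean(v))^2) / length(v))
  p <- as.numeric(v) / sum(v); p <- p[p > 0]
  expect_equal(f$entropy, -sum(p * log(p)))
  # peak cell under the lexicographic tie order
  idx <- which(v == max(v))
  ai <- arrayInd(idx, dim(v))
  pk <- ai[order(ai[, 3], ai[, 1], ai[, 2], ai[, 4], ai[, 5])[1], ]
  expect_equal(f$pos_theta, (acc$theta[pk[3]] - min(acc$theta)) /
                 diff(range(acc$theta)))
  expect_equal(f$pos_x, (acc$x[pk[5]] - min(acc$x)) / diff(range(acc$x)))
  # second peak outside the positional radius, and peak mass inside it
  px <- acc$x[pk[5]]; py <- acc$y[pk[4]]
  near <- outer((acc$y - py)^2, (acc$x - px)^2, `+`) <= 9
  vm <- matrix(v, nrow = prod(dim(v)[1:3]))
  expect_equal(f$peak_ratio, max(v) / max(vm[, !as.vector(near)]))
  expect_equal(f$peak_mass, sum(vm[, as.vector(near)]) / sum(v))
})

test_that("scale-free features ignore vote rescaling; moments scale", {
  set.seed(14)
  v <- array(sample(0:5, 2 * 2 * 3 * 8 * 8, replace = TRUE), c(2, 2, 3, 8, 8))
  f1 <- featurize(make_acc(v))
  f3 <- featurize(make_acc(v * 3L))
  for (nm in c("peak_ratio", "entropy", "pos_sx", "pos_sy", "pos_theta",
               "pos_x", "pos_y", "peak_mass"))
    expect_equal(f3[[nm]], f1[[nm]])
  expect_equal(f3$max_rate, 3 * f1$max_rate)
  expect_equal(f3$mean_rate, 3 * f1$mean_rate)
  expect_equal(f3$var_rate, 9 * f1$var_rate)
})

test_that("perfectly separated clusters reach 100% LOOCV accuracy", {
  set.seed(15)
  feats <- make_features(c(rnorm(10, 0), rnorm(10, 20)))
  labels <- rep(c(FALSE, TRUE), each = 10)
  m <- train_confidence(feats, labels, seed = 1)
  expect_equal(m$loocv_accuracy, 1)
  expect_error(train_confidence(feats, rep(TRUE, 20), seed = 1),
               class = "lvmark_single_class")
  expect_error(train_confidence(feats[1:3, ], c(TRUE, TRUE, FALSE), seed = 1),
               class = "lvmark_single_class")
})

test_that("shuffled labels drive LOOCV accuracy to chance", {
  set.seed(16)
  feats <- make_features(c(rnorm(20, 0), rnorm(20, 8)))
  accs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    lab <- sample(rep(c(TRUE, FALSE), each = 20))
    train_confidence(feats, lab, seed = s)$loocv_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("confidence is a sign-consistent deterministic margin transform", {
  set.seed(17)
  feats <- make_features(c(rnorm(10, 0), rnorm(10, 10)))
  labels <- rep(c(FALSE, TRUE), each = 10)
  m <- train_confidence(feats, labels, seed = 1)
  far_pos <- make_features(12)
  far_neg <- make_features(-2)
  expect_gt(score_confidence(m, far_pos), 0.5)
  expect_lt(score_confidence(m, far_neg), 0.5)
  expect_identical(score_confidence(m, far_pos), score_confidence(m, far_pos))
  expect_true(all(score_confidence(m, feats) >= 0 &
                    score_confidence(m, feats) <= 1))
})

test_that("mirror points across a linear decision boundary sum to one", {
  set.seed(18)
  feats <- make_features(c(rnorm(10, 0, 0.5), rnorm(10, 10, 0.5)))
  labels <- rep(c(FALSE, TRUE), each = 10)
  m <- train_confidence(feats, labels, seed = 1, kernel = "linear")
  margin <- function(v) score_confidence(m, make_features(v)) - 0.5
  vstar <- uniroot(margin, c(0, 10), tol = 1e-12)$root
  for (v0 in c(1.5, 3, 8)) {
    s <- score_confidence(m, make_features(v0)) +
      score_confidence(m, make_features(2 * vstar - v0))
    expect_equal(s, 1, tolerance = 1e-6)
  }
})

test_that("a serialized model reloads and scores identically", {
  set.seed(19)
  feats <- make_features(c(rnorm(8, 0), rnorm(8, 15)))
  labels <- rep(c(FALSE, TRUE), each = 8)
  m <- train_confidence(feats, labels, seed = 2)
  path <- tempfile(fileext = ".rds")
  write_confidence(m, path)
  m2 <- read_confidence(path)
  probe <- make_features(seq(-5, 20, length.out = 13))
  expect_identical(score_confidence(m, probe), score_confidence(m2, probe))
  g <- glance(m2)
  expect_equal(g$n, 16)
  expect_equal(g$loocv_accuracy, m$loocv_accuracy)
})
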