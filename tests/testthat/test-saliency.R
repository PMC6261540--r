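test_that("gradient map of a linear scorer recovers its weights exactly", {
  set.seed(10)
  w <- matrix(rnorm(3721), 61, 61)
  model <- linear_scorer(w)
  vi <- matrix(rnorm(3721), 61, 61)
  g <- gradient_map(model, vi)
  expect_equal(dim(g$values), dim(vi))
  expect_equal(g$values, w, tolerance = 1e-12)
  expect_false(g$normalized)
})

test_that("CNN input gradients agree with central finite differences", {
  net <- build_cnn(model_spec("CNN", seed = 21))
  set.seed(22)
  vi <- matrix(rnorm(3721, sd = 3), 61, 61)
  g <- gradient_map(net, vi)$values
  h <- 1e-3
  fd_at <- function(i, h) {
    xp <- as.vector(vi); xm <- as.vector(vi)
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (vorofield:::predict_network(net, matrix(xp, ncol = 1)) -
       vorofield:::predict_network(net, matrix(xm, ncol = 1))) / (2 * h)
  }
  checked <- 0
  for (i in sample(3721, 40)) {
    fd1 <- fd_at(i, h)
    fd2 <- fd_at(i, h / 2)
    # the difference quotient is only a valid oracle away from ReLU/max-pool
    # kinks; require the oracle to be self-consistent before using it
    if (abs(fd1 - fd2) > 1e-4 * max(abs(fd1), 1e-8)) next
    expect_equal(g[i], fd1, tolerance = 1e-4)
    checked <- checked + 1
    if (checked >= 5) break
  }
  expect_gte(checked, 5)
})

test_that("SmoothGrad degenerates to the plain gradient without noise", {
  net <- build_cnn(model_spec("CNN", seed = 30))
  set.seed(31)
  vi <- matrix(rnorm(3721), 61, 61)
  g <- gradient_map(net, vi)
  expect_equal(smoothgrad(net, vi, n = 1, sigma_r = 0)$values, g$values)
  expect_equal(smoothgrad(net, vi, n = 25, sigma_r = 0)$values, g$values)
  # a constant image gives sigma = 0 and also degenerates to the gradient
  vc <- matrix(1.5, 61, 61)
  expect_equal(smoothgrad(net, vc, n = 10, sigma_r = 0.05)$values,
               gradient_map(net, vc)$values)
})

test_that("SmoothGrad on a linear scorer equals the weight map for any noise level", {
  set.seed(40)
  w <- matrix(rnorm(3721), 61, 61)
  model <- linear_scorer(w)
  vi <- matrix(rnorm(3721, sd = 5), 61, 61)
  # the gradient of a linear functional is constant, so the Monte-Carlo
  # average is exact for any sigma and any n
  sg <- smoothgrad(model, vi, n = 50, sigma_r = 0.1, seed = 7)
  expect_equal(sg$values, w, tolerance = 1e-10)
})

test_that("SmoothGrad is bit-reproducible under a fixed seed", {
  net <- build_cnn(model_spec("CNN", seed = 44))
  set.seed(45)
  vi <- matrix(rnorm(3721, sd = 4), 61, 61)
  a <- smoothgrad(net, vi, n = 60, sigma_r = 0.05, seed = 9)
  b <- smoothgrad(net, vi, n = 60, sigma_r = 0.05, seed = 9)
  d <- smoothgrad(net, vi, n = 60, sigma_r = 0.05, seed = 10)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, d$values))
})

test_that("piece-wise averaging matches brute force, is idempotent and region-constant", {
  p <- toy_pattern(L = 3, seed = 50)
  rmap <- region_assignment(p)
  set.seed(51)
  raw <- vorofield:::as_saliency(matrix(rnorm(3721), 61, 61), "smoothgrad")
  pw <- piecewise_map(raw, rmap)
  expect_equal(pw$values, oracle_region_average(raw$values, rmap$assignment))
  for (l in unique(as.vector(rmap$assignment)))
    expect_length(unique(pw$values[rmap$assignment == l]), 1)
  expect_equal(piecewise_map(pw, rmap)$values, pw$values)

  # a constant map is a fixed point
  cm <- vorofield:::as_saliency(matrix(2, 61, 61), "smoothgrad")
  expect_equal(piecewise_map(cm, rmap)$values, cm$values)

  bad <- vorofield:::as_saliency(matrix(0, 10, 10), "smoothgrad")
  expect_error(piecewise_map(bad, rmap), "dimensions")
})

test_that("normalization is a min-max rescale with the constant-map convention", {
  m <- vorofield:::as_saliency(matrix(c(-2, 0, 2, 2), 2, 2), "gradient")
  nm <- normalize_map(m)
  expect_equal(sort(unique(as.vector(nm$values))), c(0, 0.5, 1))
  expect_true(nm$normalized)

  const <- vorofield:::as_saliency(matrix(7, 61, 61), "gradient")
  expect_true(all(normalize_map(const)$values == 0))

  # affine invariance for positive scale
  set.seed(52)
  v <- matrix(rnorm(100), 10, 10)
  m1 <- normalize_map(vorofield:::as_saliency(v, "gradient"))
  m2 <- normalize_map(vorofield:::as_saliency(3.2 * v - 5, "gradient"))
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("the full pipeline on a linear scorer recovers the region-averaged weights", {
  p <- toy_pattern(L = 6, seed = 60)
  rmap <- region_assignment(p)
  set.seed(61)
  w <- matrix(rnorm(3721), 61, 61)
  model <- linear_scorer(w)
  vi <- matrix(rnorm(3721, sd = 3), 61, 61)
  maps <- saliency_maps(model, vi, rmap, n = 30, sigma_r = 0.05, seed = 3)
  # hand-computed oracle: region-average w, then min-max to [0, 1]
  ref <- oracle_region_average(w, rmap$assignment)
  ref <- (ref - min(ref)) / (max(ref) - min(ref))
  expect_equal(maps$piecewise$values, ref, tolerance = 1e-10)
  expect_equal(range(maps$smoothgrad$values), c(0, 1))
})
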