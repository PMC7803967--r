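# Row/null-space split, PCA reduction, weighted combination and overlay.

stack_from_matrix <- function(X, h, w, A) {
  # X is D x (h*w), locations column-major
  feature_stack(aperm(array(X, dim = c(nrow(X), h, w)), c(2, 3, 1)), A)
}

test_that("row_null_split: hand case and full-rank trivial null space", {
  # A = [1, 0], x = (3, 4): row space keeps (3, 0), null space (0, 4)
  st <- stack_from_matrix(matrix(c(3, 4), 2, 1), 1, 1,
                          matrix(c(1, 0), 1, 2))
  sp <- row_null_split(st)
  expect_equal(as.numeric(sp$x_r), c(3, 0))
  expect_equal(as.numeric(sp$x_n), c(0, 4))

  # square full-rank operator: x_n = 0
  set.seed(60)
  A <- matrix(rnorm(16), 4, 4)
  X <- matrix(rnorm(4 * 6), 4, 6)
  sp2 <- row_null_split(stack_from_matrix(X, 2, 3, A))
  expect_lt(max(abs(sp2$x_n)), 1e-10)
  expect_equal(matrix(aperm(sp2$x_r, c(3, 1, 2)), 4), X, tolerance = 1e-10)

  expect_error(row_null_split(feature_stack(array(1, c(2, 2, 3)),
                                            matrix(1, 1, 3))), NA)
  expect_error(feature_stack(array(1, c(2, 2, 3)), matrix(1, 1, 4)),
               "match")
})

test_that("subspace identities hold against the pseudoinverse oracle", {
  set.seed(61)
  for (rep in 1:25) {
    d <- sample(4:10, 1)
    m <- sample(1:(d - 1), 1)
    A <- matrix(rnorm(m * d), m, d)
    if (runif(1) < 0.3) A[sample(m, 1), ] <- 0   # rank-deficient case
    X <- matrix(rnorm(d * 12), d, 12)
    sp <- row_null_split(stack_from_matrix(X, 3, 4, A))
    XR <- matrix(aperm(sp$x_r, c(3, 1, 2)), d)
    XN <- matrix(aperm(sp$x_n, c(3, 1, 2)), d)
    expect_lt(max(abs(XR + XN - X)), 1e-10)
    expect_lt(max(abs(A %*% XN)), 1e-8)
    expect_lt(max(abs(colSums(XR * XN))), 1e-8)
    # oracle: projection through the pseudoinverse
    P <- t(A) %*% pinv(A %*% t(A)) %*% A
    expect_lt(max(abs(XR - P %*% X)), 1e-8)
  }
})

test_that("pca_reduce: degenerate spectrum, isotropy, sign convention", {
  # variance along a single axis: V1 carries everything
  set.seed(62)
  h <- 6; w <- 6; d <- 5
  dir1 <- rnorm(d)
  coef <- rnorm(h * w, sd = 3)
  X <- outer(dir1, coef)
  p1 <- pca_reduce(aperm(array(X, c(d, h, w)), c(2, 3, 1)))
  expect_gt(p1$explained[1], 0.999999)
  expect_lt(max(abs(p1$V2)), 1e-8)
  expect_true(all(diff(p1$explained) <= 1e-12))

  # isotropic data: roughly equal leading ratios
  Xi <- matrix(rnorm(8 * 40 * 40), 8)
  pi_ <- pca_reduce(aperm(array(Xi, c(8, 40, 40)), c(2, 3, 1)))
  expect_lt(pi_$explained[1] / pi_$explained[3], 1.5)

  # deterministic output: rerun gives identical fields
  p2 <- pca_reduce(aperm(array(X, c(d, h, w)), c(2, 3, 1)))
  expect_identical(p1$V1, p2$V1)
  expect_error(pca_reduce(array(1, c(1, 2, 5))), "3 grid locations")
  expect_error(pca_reduce(array(1, c(4, 4, 2))), "dimension")
})

test_that("weighted_combine applies the grayscale weights exactly", {
  M <- matrix(rnorm(12), 3, 4)
  expect_equal(weighted_combine(M, M, M), M)   # weights sum to 1
  one <- matrix(1, 2, 2); zero <- matrix(0, 2, 2)
  expect_equal(weighted_combine(one, zero, zero), matrix(0.7152, 2, 2))
  expect_equal(weighted_combine(zero, one, zero), matrix(0.2126, 2, 2))
  expect_equal(weighted_combine(zero, zero, one), matrix(0.0722, 2, 2))
  expect_equal(weighted_combine(zero, zero, zero), zero)
  expect_error(weighted_combine(one, zero, matrix(0, 3, 3)), "mismatch")
})

test_that("overlay_map: constant flag, alpha identity, argmax preservation", {
  img <- generate_background(64, 64, seed = 63)
  expect_warning(res <- overlay_map(matrix(1, 4, 4), img), "constant")
  expect_true(res$constant_field)

  V <- matrix(0, 8, 8); V[3, 5] <- 1
  res0 <- overlay_map(V, img, alpha = 0)
  expect_equal(res0$image, img)

  res1 <- overlay_map(V, img, alpha = 1)
  # the overlay's yellow peak sits at the upsampled hot-cell location
  diffsum <- abs(res1$image[, , 1] - img[, , 1]) # not meaningful; use colormap
  pal_top <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")[256])
  hot <- which(res1$image[, , 1] == pal_top[1] &
                 res1$image[, , 2] == pal_top[2], arr.ind = TRUE)
  expect_true(all(hot[, 1] >= 17 & hot[, 1] <= 24))   # row cell 3 of 8
  expect_true(all(hot[, 2] >= 33 & hot[, 2] <= 40))   # col cell 5 of 8
})

test_that("feature-stack JSON container round-trips exactly", {
  fs <- simulate_feature_stack(seed = 66, h = 4, w = 5, d = 8, out_dim = 3)
  st <- feature_stack(fs$features, fs$A)
  p <- withr::local_tempfile(fileext = ".json")
  write_feature_stack(st, p)
  back <- read_feature_stack(p)
  expect_equal(back$features, st$features)
  expect_equal(back$A, st$A)
})

test_that("pipeline is invariant to positive feature scaling", {
  fs <- simulate_feature_stack(seed = 64, h = 10, w = 10, d = 12, out_dim = 4)
  img <- generate_background(80, 80, seed = 64)
  v1 <- featuremap_visualize(feature_stack(fs$features, fs$A), img)
  v2 <- featuremap_visualize(feature_stack(fs$features * 3.7, fs$A), img)
  expect_equal(v1$overlay$image, v2$overlay$image, tolerance = 1e-9)
})

test_that("split denoises the planted bump", {
  fs <- simulate_feature_stack(seed = 65, h = 12, w = 12, d = 24,
                               out_dim = 6, noise_sd = 2)
  sp <- row_null_split(feature_stack(fs$features, fs$A))
  # row-space magnitude tracks the planted bump
  mag <- sqrt(apply(sp$x_r^2, c(1, 2), sum))
  expect_gt(stats::cor(as.numeric(mag), as.numeric(fs$signal)), 0.999)
  # the removed component carries the noise, not the bump
  magn <- sqrt(apply(sp$x_n^2, c(1, 2), sum))
  expect_lt(abs(stats::cor(as.numeric(magn), as.numeric(fs$signal))), 0.5)
})
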