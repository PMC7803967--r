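# Feature-map denoising and visualization.
#
# A spatial grid of feature vectors x is split against the affine operator
# A that consumes them downstream: solving A A^T xhat = A x gives the
# row-space component x_r = A^T xhat (the part the operator can see) and
# the null-space component x_n = x - x_r (annihilated by A, hence noise
# for the network). The row-space field is reduced to three dimensions by
# PCA, combined with the RGB-to-grayscale weights, and overlaid with the
# viridis colormap.

#' Build a feature stack
#'
#' @param features numeric array `[H, W, D]` of feature vectors.
#' @param A affine operator matrix (`out_dim x D`).
#' @return list of class `feature_stack`.
#' @export
feature_stack <- function(features, A) {
  assert_that(length(dim(features)) == 3, "features must be a [H, W, D] array")
  assert_that(ncol(A) == dim(features)[3],
              "operator columns must match the feature dimension")
  assert_that(all(is.finite(features)) && all(is.finite(A)),
              "features and operator must be finite")
  structure(list(features = features, A = A), class = "feature_stack")
}

#' Row/null-space split of a feature stack
#'
#' Per grid location solves `A A^T xhat = A x` (minimum-norm via the
#' pseudoinverse when `A A^T` is singular), then `x_r = A^T xhat` and
#' `x_n = x - x_r`. By construction `x_r + x_n = x`, `A x_n = 0`, and
#' `<x_r, x_n> = 0` to floating-point tolerance.
#'
#' @param stack a [feature_stack()] (or a list with `features` and `A`).
#' @return list of class `subspace_split` with arrays `x_hat`
#'   (`[H, W, out_dim]`), `x_r`, `x_n` (both `[H, W, D]`).
#' @export
row_null_split <- function(stack) {
  A <- stack$A
  feats <- stack$features
  assert_that(nrow(A) >= 1 && ncol(A) >= 1, "operator must be non-empty")
  hh <- dim(feats)[1]; ww <- dim(feats)[2]; d <- dim(feats)[3]
  X <- matrix(aperm(feats, c(3, 1, 2)), nrow = d)   # D x (H*W)
  AX <- A %*% X
  G <- A %*% t(A)
  ev <- eigen(G, symmetric = TRUE)
  tol <- max(dim(A)) * .Machine$double.eps * max(ev$values, 0)
  pos <- ev$values > tol
  # minimum-norm solve of G xhat = A x  (pseudoinverse of G)
  Ginv_ax <- ev$vectors[, pos, drop = FALSE] %*%
    ((t(ev$vectors[, pos, drop = FALSE]) %*% AX) / ev$values[pos])
  XR <- t(A) %*% Ginv_ax
  XN <- X - XR
  to_arr <- function(m) aperm(array(m, dim = c(nrow(m), hh, ww)), c(2, 3, 1))
  structure(list(x_hat = to_arr(Ginv_ax), x_r = to_arr(XR), x_n = to_arr(XN)),
            class = "subspace_split")
}

#' PCA reduction of a feature field to three components
#'
#' Treats grid locations as observations, centers the features, and
#' returns the first three principal-component score fields with their
#' explained-variance ratios. Component signs are fixed so each score
#' field has non-negative skewness (deterministic output).
#'
#' @param field numeric array `[H, W, D]` (e.g. `x_r` from
#'   [row_null_split()]).
#' @return list with `V1`, `V2`, `V3` (`H x W` matrices) and
#'   `explained` (length-3 ratios, non-increasing).
#' @export
pca_reduce <- function(field) {
  hh <- dim(field)[1]; ww <- dim(field)[2]; d <- dim(field)[3]
  assert_that(hh * ww >= 3, "need at least 3 grid locations")
  assert_that(d >= 3, "need feature dimension >= 3")
  M <- matrix(aperm(field, c(3, 1, 2)), nrow = d)   # D x n
  pc <- stats::prcomp(t(M), center = TRUE, scale. = FALSE)
  assert_that(sum(pc$sdev > 1e-12) >= 1, "degenerate feature field")
  scores <- pc$x[, 1:3, drop = FALSE]
  if (ncol(scores) < 3) stop_ew("fewer than 3 non-degenerate dimensions")
  flip_sign <- function(v) {
    sk <- mean((v - mean(v))^3)
    if (sk < 0) -v else v
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(V1 = matrix(flip_sign(scores[, 1]), hh, ww),
       V2 = matrix(flip_sign(scores[, 2]), hh, ww),
       V3 = matrix(flip_sign(scores[, 3]), hh, ww),
       explained = expl[1:3])
}

#' Combine the three PCA fields with the grayscale weights
#'
#' `V = 0.7152 V1 + 0.2126 V2 + 0.0722 V3` pointwise; the weights are the
#' RGB-to-grayscale conversion coefficients and sum to 1, so equal inputs
#' are reproduced unchanged.
#'
#' @param V1,V2,V3 matrices of identical shape.
#' @return the weighted matrix.
#' @export
weighted_combine <- function(V1, V2, V3) {
  assert_that(all(dim(V1) == dim(V2)) && all(dim(V1) == dim(V3)),
              "shape mismatch")
  0.7152 * V1 + 0.2126 * V2 + 0.0722 * V3
}

#' Overlay a scalar response map on an image
#'
#' Min-max normalizes `V` to `[0, 1]`, bilinearly upsamples it to the
#' image size, maps it through the viridis colormap (yellow = strongest
#' response) and alpha-blends it over the image. A constant `V` renders a
#' uniform mid-colormap overlay and sets a warning flag.
#'
#' @param V scalar response matrix.
#' @param image RGB array (values 0-255).
#' @param alpha overlay opacity in `[0, 1]`.
#' @param n_colors colormap resolution.
#' @return list with `image` (the blended RGB array) and `constant_field`
#'   flag.
#' @export
overlay_map <- function(V, image, alpha = 0.5, n_colors = 256L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  rng <- range(V)
  constant <- !(rng[2] > rng[1])
  Vn <- if (constant) matrix(0.5, nrow(V), ncol(V)) else
    (V - rng[1]) / (rng[2] - rng[1])
  up <- clamp(bilinear_resize(Vn, H, W), 0, 1)
  pal <- grDevices::hcl.colors(n_colors, palette = "viridis")
  rgbm <- grDevices::col2rgb(pal)                       # 3 x n_colors
  idx <- pmin(pmax(1L, as.integer(up * (n_colors - 1)) + 1L), n_colors)
  out <- image
  for (ch in 1:3) {
    layer <- matrix(rgbm[ch, idx], H, W)
    out[, , ch] <- (1 - alpha) * image[, , ch] + alpha * layer
  }
  if (constant) warning("constant response field; overlay is uniform")
  list(image = out, constant_field = constant)
}

#' End-to-end feature-map visualization
#'
#' Row/null-space split, PCA to three components, grayscale-weighted
#' combination and viridis overlay, in one call.
#'
#' @param stack a [feature_stack()].
#' @param image RGB array to overlay on.
#' @param alpha overlay opacity.
#' @return list with `V`, `overlay`, `split`, `pca`.
#' @export
featuremap_visualize <- function(stack, image, alpha = 0.5) {
  split <- row_null_split(stack)
  pca <- pca_reduce(split$x_r)
  V <- weighted_combine(pca$V1, pca$V2, pca$V3)
  ov <- overlay_map(V, image, alpha = alpha)
  list(V = V, overlay = ov, split = split, pca = pca)
}
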