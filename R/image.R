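# Image primitives. Images are numeric arrays [H, W, C] with values in
# [0, 255]; C = 3 (RGB) or 4 (RGBA). Pixel (row r, col c) covers the
# half-open square [c-1, c) x [r-1, r) in 0-based continuous coordinates,
# with center (c - 0.5, r - 0.5).

blank_image <- function(height, width, channels = 3L, value = 0) {
  array(value, dim = c(height, width, channels))
}

img_height <- function(img) dim(img)[1]
img_width <- function(img) dim(img)[2]

#' Mirror an image left-right.
#' @keywords internal
mirror_image <- function(img) {
  img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

#' Write an RGB(A) array as PNG (values in [0, 255]).
#' @param img numeric array `[H, W, 3|4]` with values in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, target = path)
  invisible(path)
}

#' Read a PNG into a `[H, W, C]` array scaled to [0, 255].
#' @param path PNG file path.
#' @return numeric array.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  x * 255
}

#' Separable Gaussian blur of a single-channel matrix.
#'
#' Kernel is truncated at 4 sigma and renormalized; sigma = 0 returns the
#' input unchanged. Edges use zero padding, appropriate for alpha masks
#' embedded in a transparent canvas.
#' @keywords internal
gaussian_blur <- function(m, sigma) {
  if (sigma < 0) stop_ew("sigma must be >= 0")
  if (sigma == 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(mat) {
    # zero-pad convolve along columns of mat
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      out[keep, ] <- out[keep, ] + k[i] * mat[src[keep], , drop = FALSE]
    }
    out
  }
  t(blur_axis(t(blur_axis(m))))
}

#' Bilinear sample of a single-channel matrix at continuous coords.
#'
#' `x`, `y` are 0-based continuous coordinates (pixel centers at
#' half-integers). Points outside the canvas return 0.
#' @keywords internal
bilinear_sample <- function(m, x, y, pad = c("zero", "clamp")) {
  pad <- match.arg(pad)
  H <- nrow(m); W <- ncol(m)
  # convert to fractional pixel-center index space
  cx <- x - 0.5
  cy <- y - 0.5
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  get_px <- function(col0, row0) {
    if (pad == "clamp") {
      col0 <- clamp(col0, 0, W - 1)
      row0 <- clamp(row0, 0, H - 1)
    }
    ok <- col0 >= 0 & col0 <= W - 1 & row0 >= 0 & row0 <= H - 1
    v <- numeric(length(col0))
    if (any(ok)) v[ok] <- m[cbind(row0[ok] + 1L, col0[ok] + 1L)]
    v
  }
  v00 <- get_px(x0, y0)
  v10 <- get_px(x0 + 1, y0)
  v01 <- get_px(x0, y0 + 1)
  v11 <- get_px(x0 + 1, y0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' Bilinear upsample of a matrix to a target size.
#' @keywords internal
bilinear_resize <- function(m, out_h, out_w) {
  sx <- ncol(m) / out_w
  sy <- nrow(m) / out_h
  xs <- (seq_len(out_w) - 0.5) * sx
  ys <- (seq_len(out_h) - 0.5) * sy
  grid <- expand.grid(y = ys, x = xs)
  matrix(bilinear_sample(m, grid$x, grid$y, pad = "clamp"),
         nrow = out_h, ncol = out_w)
}
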