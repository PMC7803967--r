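# Poisson (gradient-domain) paste.
#
# The opaque sprite region Omega is blended by solving, per RGB channel,
# the discrete Poisson equation
#   4 f_p - sum_{q in N(p) & Omega} f_q =
#     sum_{q in N(p) & Omega} (g_p - g_q) + sum_{q in N(p) \ Omega} bg_q
# where g is the light-scaled sprite and the Dirichlet boundary is the
# background, so the seam is invisible by construction. Guidance gradients
# across the region boundary are set to zero (the blend continues the
# background smoothly rather than importing the sprite's fringe, whose RGB
# is undefined outside the alpha mask).

# Conjugate gradients for the SPD sparse system; errors out if the
# relative residual has not reached tol within maxit iterations.
cg_solve <- function(A, b, x0, tol = 1e-10, maxit = 10000L) {
  x <- x0
  r <- b - as.numeric(A %*% x)
  p <- r
  rs <- sum(r * r)
  b2 <- max(sum(b * b), .Machine$double.eps)
  for (it in seq_len(maxit)) {
    if (sqrt(rs / b2) <= tol) return(x)
    Ap <- as.numeric(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (sqrt(rs / b2) > tol)
    stop_ew("Poisson solver did not converge within tolerance")
  x
}

# Core blend operating on a transformed sprite canvas (`tr` from
# transform_sprite) pasted at an integer offset.
poisson_blend <- function(background, tr, offset, light,
                          solver = c("direct", "cg"),
                          tol = 1e-10, maxit = 20000L) {
  solver <- match.arg(solver)
  mask <- tr$mask
  if (!any(mask)) return(background)
  H <- dim(background)[1]; W <- dim(background)[2]
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  fr <- offset["top"] + c(min(rows), max(rows))
  fc <- offset["left"] + c(min(cols), max(cols))
  assert_that(fr[1] >= 2 && fr[2] <= H - 1 && fc[1] >= 2 && fc[2] <= W - 1,
              "Poisson paste region must lie strictly inside the frame")

  # local window = mask bbox expanded by 1 px, in frame coordinates
  wr <- (fr[1] - 1L):(fr[2] + 1L)
  wc <- (fc[1] - 1L):(fc[2] + 1L)
  nh <- length(wr); nw <- length(wc)
  mloc <- matrix(FALSE, nh, nw)
  # canvas rows/cols overlapping the window
  cr <- wr - offset["top"]; cccols <- wc - offset["left"]
  in_canvas_r <- cr >= 1 & cr <= nrow(mask)
  in_canvas_c <- cccols >= 1 & cccols <= ncol(mask)
  mloc[in_canvas_r, in_canvas_c] <- mask[cr[in_canvas_r], cccols[in_canvas_c]]

  idx <- matrix(0L, nh, nw)
  idx[mloc] <- seq_len(sum(mloc))
  n_unknown <- sum(mloc)
  shift <- function(m, dr, dc, fill = 0L) {
    out <- matrix(fill, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
    okr <- rs >= 1 & rs <= nrow(m); okc <- cs >= 1 & cs <= ncol(m)
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))

  ii <- list(); jj <- list()
  for (d in dirs) {
    nb <- shift(idx, d[1], d[2])
    both <- mloc & nb > 0L
    ii[[length(ii) + 1L]] <- idx[both]
    jj[[length(jj) + 1L]] <- nb[both]
  }
  A <- Matrix::sparseMatrix(
    i = c(idx[mloc], unlist(ii)), j = c(idx[mloc], unlist(jj)),
    x = c(rep(4, n_unknown), rep(-1, length(unlist(ii)))),
    dims = c(n_unknown, n_unknown))

  # guidance (light-scaled sprite RGB) and background on the window
  out <- background
  for (ch in 1:3) {
    g <- matrix(0, nh, nw)
    gcan <- tr$rgba[, , ch] * light
    g[in_canvas_r, in_canvas_c] <- gcan[cr[in_canvas_r], cccols[in_canvas_c]]
    bgw <- background[wr, wc, ch]
    b <- numeric(n_unknown)
    for (d in dirs) {
      nb_in <- shift(mloc, d[1], d[2])          # neighbor inside Omega?
      gq <- shift(g, d[1], d[2])
      bq <- shift(bgw, d[1], d[2])
      sel <- mloc & nb_in
      b[idx[sel]] <- b[idx[sel]] + (g[sel] - gq[sel])
      selb <- mloc & !nb_in
      b[idx[selb]] <- b[idx[selb]] + bq[selb]
    }
    x0 <- bgw[mloc]
    f <- if (solver == "cg") cg_solve(A, b, x0, tol = tol, maxit = maxit)
         else as.numeric(Matrix::solve(A, b))
    res <- bgw
    res[mloc] <- f
    out[wr, wc, ch] <- res
  }
  out
}

#' Poisson paste
#'
#' Gradient-domain blend of a sprite into the background: the discrete
#' Poisson equation is solved on the opaque sprite region with the sprite
#' gradients as guidance field and the background as Dirichlet boundary,
#' per channel, giving a seamless boundary by construction. A constant
#' sprite over a constant background reproduces the background exactly
#' (Laplace limit).
#'
#' @inheritParams direct_paste
#' @param solver `"cg"` (matrix-free conjugate gradients, the reference
#'   iterative route) or `"direct"` (sparse Cholesky). Both solve the same
#'   system and agree to the solver tolerance.
#' @param tol relative-residual convergence tolerance for `"cg"`.
#' @param maxit iteration cap for `"cg"`; exceeding it raises an error.
#' @return the blended RGB array.
#' @export
poisson_paste <- function(background, sprite, placement,
                          solver = c("cg", "direct"),
                          tol = 1e-10, maxit = 20000L) {
  solver <- match.arg(solver)
  tr <- transform_sprite(sprite, placement,
                         dim(background)[1] * dim(background)[2])
  off <- paste_offset(placement, dim(tr$rgba))
  poisson_blend(background, tr, off, placement$light_factor,
                solver = solver, tol = tol, maxit = maxit)
}
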