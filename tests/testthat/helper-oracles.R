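# Independent oracles and small fixtures used across the suite.

# Dense direct solve of the paste Poisson system: assemble the full linear
# system from a mask, background window and guidance window with plain
# loops and solve with base::solve. Independent of the package's sparse /
# CG route.
dense_poisson_oracle <- function(mask, bg, g) {
  n <- sum(mask)
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[mask] <- seq_len(n)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (!mask[r, cc]) next
    p <- idx[r, cc]
    A[p, p] <- 4
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      inside <- rr >= 1 && rr <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask)
      if (inside && mask[rr, c2]) {
        A[p, idx[rr, c2]] <- A[p, idx[rr, c2]] - 1
        b[p] <- b[p] + g[r, cc] - g[rr, c2]
      } else {
        # outside Omega: Dirichlet background, zero guidance gradient
        b[p] <- b[p] + bg[rr, c2]
      }
    }
  }
  solve(A, b)
}

# Brute-force all-point-interpolated AP via the per-true-positive route:
# each TP at rank k contributes max precision over prefixes >= k.
ap_oracle <- function(tp, n_gt) {
  if (!length(tp) || n_gt < 1) return(0)
  prec <- cumsum(tp) / seq_along(tp)
  s <- 0
  for (k in seq_along(tp)) {
    if (tp[k]) s <- s + max(prec[k:length(tp)])
  }
  s / n_gt
}

# Moore-Penrose pseudoinverse via SVD (oracle for the subspace split).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# A fully opaque rectangular white test sprite.
opaque_sprite <- function(h = 8L, w = 6L, value = 255) {
  rgba <- array(0, dim = c(h, w, 4))
  rgba[, , 1:3] <- value
  rgba[, , 4] <- 255
  structure(list(rgba = rgba, species = "great_egret",
                 box = c(0, 0, w, h)), class = "egret_sprite")
}

# Sprite with a smooth color ramp (non-constant gradients).
ramp_sprite <- function(h = 8L, w = 8L) {
  rgba <- array(0, dim = c(h, w, 4))
  ramp <- outer(seq_len(h), seq_len(w), function(r, cc) 60 + 10 * r + 5 * cc)
  for (ch in 1:3) rgba[, , ch] <- ramp + 10 * ch
  rgba[, , 4] <- 255
  structure(list(rgba = rgba, species = "great_egret",
                 box = c(0, 0, w, h)), class = "egret_sprite")
}

# Identity-transform placement for a sprite (scale 1, no pose change).
identity_placement <- function(sprite, frame_w, frame_h, cx, cy, light = 1) {
  structure(list(center = c(cx, cy),
                 area_fraction = sum(sprite$rgba[, , 4] > 0) / (frame_w * frame_h),
                 light_factor = light, rotation = 0, flip = FALSE, shear = 0),
            class = "placement")
}

# Detection records from per-frame counts: `counts[i]` birds at `times[i]`,
# boxes at a fixed location.
records_from_counts <- function(times, counts, species = "great_egret",
                                x = 100, y = 100, side = 50, score = 0.9) {
  n <- sum(counts)
  if (n == 0) {
    return(data.frame(timestamp = as.POSIXct(character(0), tz = "UTC"),
                      species = character(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), score = numeric(0)))
  }
  data.frame(timestamp = rep(times, counts), species = species,
             x_min = x, y_min = y, x_max = x + side, y_max = y + side,
             score = score)
}

utc <- function(s) as.POSIXct(s, tz = "UTC")

# Small simulation config for recovery tests (defaults otherwise).
desk_config <- function(n_days = 4L, frame_interval = 60,
                        count_noise = "none", seed = 11L, ...) {
  sim_config(day_span = seq(as.Date("2019-09-23"), by = "day",
                            length.out = n_days),
             frame_interval = frame_interval, count_noise = count_noise,
             rng_seed = seed, ...)
}
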