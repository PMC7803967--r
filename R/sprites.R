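# Procedural bird sprites and backgrounds.
#
# Sprites are 2D stand-ins for rendered 3D egret models: a body ellipse, a
# curved neck, a head disc and a beak wedge, drawn into an RGBA canvas and
# tight-cropped to the opaque pixels. The two egret species differ in a
# deterministic geometric attribute (neck curvature and beak length) so a
# downstream classifier could in principle separate them; the "other"
# category (night-heron-like) is darker with a short neck.

SPRITE_CANVAS <- 96L

sprite_palette <- list(
  great_egret  = list(body = c(238, 238, 232), beak = c(228, 196, 64)),
  little_egret = list(body = c(244, 244, 240), beak = c(45, 45, 45)),
  other        = list(body = c(118, 128, 148), beak = c(60, 60, 60))
)

# species-level shape parameters (fractions of canvas side)
sprite_shape <- list(
  great_egret  = list(neck_len = 0.46, neck_curve = 0.22, beak_len = 0.17,
                      body_a = 0.26, body_b = 0.155),
  little_egret = list(neck_len = 0.34, neck_curve = 0.08, beak_len = 0.10,
                      body_a = 0.22, body_b = 0.145),
  other        = list(neck_len = 0.18, neck_curve = 0.04, beak_len = 0.09,
                      body_a = 0.27, body_b = 0.19)
)

draw_bird <- function(species, pose_angle, pose_stretch) {
  S <- SPRITE_CANVAS
  shp <- sprite_shape[[species]]
  pal <- sprite_palette[[species]]
  xs <- matrix(rep(seq_len(S) - 0.5, each = S), nrow = S)   # x per column
  ys <- matrix(rep(seq_len(S) - 0.5, times = S), nrow = S)  # y per row

  alpha <- matrix(FALSE, S, S)
  rgb <- array(0, dim = c(S, S, 3))
  paint <- function(mask, col) {
    for (ch in 1:3) {
      m <- rgb[, , ch]
      m[mask] <- col[ch]
      rgb[, , ch] <<- m
    }
    alpha <<- alpha | mask
  }

  # body ellipse, slightly tilted
  bx <- 0.40 * S; by <- 0.62 * S
  th <- -10 * pi / 180
  dx <- xs - bx; dy <- ys - by
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  body <- (u / (shp$body_a * S))^2 + (v / (shp$body_b * S))^2 <= 1
  paint(body, pal$body)

  # neck: quadratic Bezier from body shoulder to head, curvature per species
  phi <- pose_angle
  p0 <- c(bx + 0.16 * S, by - 0.10 * S)
  p2 <- p0 + shp$neck_len * S * pose_stretch * c(cos(phi), -sin(phi))
  # control point bows backwards; magnitude is the species' curvature cue
  nrm <- c(-sin(phi), -cos(phi))
  p1 <- (p0 + p2) / 2 + shp$neck_curve * S * nrm
  tt <- seq(0, 1, length.out = 48)
  bez <- function(i) (1 - tt)^2 * p0[i] + 2 * tt * (1 - tt) * p1[i] + tt^2 * p2[i]
  cxs <- bez(1); cys <- bez(2)
  rn <- 0.034 * S
  neck <- matrix(FALSE, S, S)
  for (k in seq_along(tt)) {
    neck <- neck | ((xs - cxs[k])^2 + (ys - cys[k])^2 <= rn^2)
  }
  paint(neck, pal$body)

  # head disc at neck end
  head <- (xs - p2[1])^2 + (ys - p2[2])^2 <= (0.048 * S)^2
  paint(head, pal$body)

  # beak wedge pointing along the head direction
  bl <- shp$beak_len * S
  tip <- p2 + bl * c(cos(phi * 0.5), -sin(phi * 0.5))
  dirv <- (tip - p2) / sqrt(sum((tip - p2)^2))
  perp <- c(-dirv[2], dirv[1])
  proj <- (xs - p2[1]) * dirv[1] + (ys - p2[2]) * dirv[2]
  off <- (xs - p2[1]) * perp[1] + (ys - p2[2]) * perp[2]
  beak <- proj >= 0 & proj <= bl & abs(off) <= 0.030 * S * (1 - proj / bl)
  paint(beak, pal$beak)

  # shading: darken the belly a little so sprites are not flat-colored
  shade <- clamp(1 - 0.15 * (ys - by) / (0.2 * S), 0.82, 1)
  for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] * shade

  out <- array(0, dim = c(S, S, 4))
  out[, , 1:3] <- rgb
  out[, , 4] <- ifelse(alpha, 255, 0)
  out
}

tight_crop <- function(rgba) {
  op <- rgba[, , 4] > 0
  rows <- which(rowSums(op) > 0)
  cols <- which(colSums(op) > 0)
  rgba[min(rows):max(rows), min(cols):max(cols), , drop = FALSE]
}

#' Generate procedural bird sprites
#'
#' Draws `n_poses` bird-like RGBA sprites for each species
#' (`great_egret`, `little_egret`, `other`). Poses vary the neck angle and
#' extension deterministically from `seed`, so the same seed always yields
#' byte-identical sprites. Species differ in neck curvature and beak
#' length, the field cues used to tell the two egrets apart.
#'
#' @param seed integer RNG seed.
#' @param n_poses number of poses per species (>= 1).
#' @return A list of sprites. Each sprite is a list with elements
#'   `rgba` (numeric array `[h, w, 4]`, values 0-255, tight-cropped so the
#'   opaque bounding box is the full canvas), `species`, and `box`
#'   (`c(x_min, y_min, x_max, y_max)`, 0-based half-open, equal to the
#'   sprite extent).
#' @examples
#' sp <- generate_sprites(seed = 1, n_poses = 2)
#' length(sp)  # 6
#' @export
generate_sprites <- function(seed, n_poses = 1L) {
  assert_that(n_poses >= 1, "n_poses must be >= 1")
  with_seed(child_seed(seed, "sprites"), {
    out <- list()
    for (species in SPECIES) {
      for (p in seq_len(n_poses)) {
        ang <- runif(1, 55, 100) * pi / 180
        stretch <- runif(1, 0.85, 1.1)
        rgba <- tight_crop(draw_bird(species, ang, stretch))
        out[[length(out) + 1L]] <- structure(
          list(rgba = rgba, species = species,
               box = c(0, 0, ncol(rgba), nrow(rgba))),
          class = "egret_sprite")
      }
    }
    out
  })
}

#' Generate a textured background image
#'
#' Deterministic stand-in for a real monitoring-camera frame with no birds:
#' a vertical sky gradient, soft tree-crown blobs over the lower half and
#' fine per-pixel noise. Contains no sprite content.
#'
#' @param width,height frame size in pixels (>= 64).
#' @param seed integer RNG seed; the same seed reproduces the image exactly.
#' @return numeric RGB array `[height, width, 3]`, values in 0-255.
#' @export
generate_background <- function(width, height, seed) {
  assert_that(width >= 64 && height >= 64, "width and height must be >= 64")
  with_seed(child_seed(seed, "background"), {
    img <- array(0, dim = c(height, width, 3))
    # sky gradient
    tgrad <- (seq_len(height) - 1) / (height - 1)
    top <- c(132, 186, 232); bot <- c(208, 222, 230)
    for (ch in 1:3) {
      img[, , ch] <- matrix((1 - tgrad) * top[ch] + tgrad * bot[ch],
                            nrow = height, ncol = width)
    }
    # tree-crown blobs
    n_blob <- 12L + as.integer(width * height / 3e4)
    for (b in seq_len(n_blob)) {
      cx <- runif(1, 0, width)
      cy <- runif(1, 0.35 * height, 0.95 * height)
      r <- runif(1, 0.03, 0.1) * min(width, height)
      col <- c(runif(1, 30, 70), runif(1, 80, 125), runif(1, 35, 70))
      c0 <- max(1L, floor(cx - 1.3 * r)); c1 <- min(width, ceiling(cx + 1.3 * r))
      r0 <- max(1L, floor(cy - 1.3 * r)); r1 <- min(height, ceiling(cy + 1.3 * r))
      if (c0 > c1 || r0 > r1) next
      wx <- (c0:c1) - 0.5 - cx
      wy <- (r0:r1) - 0.5 - cy
      d <- sqrt(outer(wy^2, wx^2, `+`))
      w <- clamp(1.25 - d / r, 0, 1)
      for (ch in 1:3) {
        sub <- img[r0:r1, c0:c1, ch]
        img[r0:r1, c0:c1, ch] <- (1 - w) * sub + w * col[ch]
      }
    }
    # fine texture noise
    noise <- matrix(runif(height * width, -7, 7), nrow = height)
    for (ch in 1:3) img[, , ch] <- clamp(img[, , ch] + noise, 0, 255)
    img
  })
}
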