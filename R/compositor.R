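# Domain-randomization compositor: paste sprites onto backgrounds with the
# direct / Gaussian / Poisson paste operators under randomized placement,
# and emit COCO-style annotations.

#' Compositor randomization configuration
#'
#' Ranges of the placement randomization. Bird size is uniform in
#' 0.04%-0.56% of the background *area*; light is a uniform multiplicative
#' factor in 0.6-1.0; the camera-viewpoint variation of a 3D renderer is
#' proxied in 2D by rotation, horizontal flip and shear.
#'
#' @param area_range uniform range of sprite area as a fraction of frame
#'   area.
#' @param light_range uniform range of the multiplicative light factor.
#' @param rotation_range uniform rotation range in degrees.
#' @param shear_range uniform horizontal shear range.
#' @param flip_prob probability of a horizontal flip.
#' @param margin_frac placement margin from the frame border, as a
#'   fraction of the frame diagonal (keeps pasted sprites inside).
#' @return list of class `placement_config`.
#' @export
placement_config <- function(area_range = c(0.0004, 0.0056),
                             light_range = c(0.6, 1.0),
                             rotation_range = c(-15, 15),
                             shear_range = c(-0.2, 0.2),
                             flip_prob = 0.5,
                             margin_frac = 0.06) {
  structure(list(area_range = area_range, light_range = light_range,
                 rotation_range = rotation_range, shear_range = shear_range,
                 flip_prob = flip_prob, margin_frac = margin_frac),
            class = "placement_config")
}

#' Sample one randomized paste decision
#'
#' Draws area fraction, light factor, 2D pose (rotation, flip, shear) and a
#' center uniform over the allowed region. Consumes the global RNG stream,
#' so a fixed RNG state reproduces the sample.
#'
#' @param frame_size `c(width, height)` in pixels.
#' @param config a [placement_config()].
#' @param allowed_mask optional logical `[height, width]` matrix of allowed
#'   center pixels; defaults to the frame inset by the margin.
#' @return list of class `placement`: `center` (x, y in 0-based continuous
#'   pixels), `area_fraction`, `light_factor`, `rotation`, `flip`, `shear`.
#' @export
sample_placement <- function(frame_size, config = placement_config(),
                             allowed_mask = NULL) {
  W <- frame_size[1]; H <- frame_size[2]
  area_fraction <- runif(1, config$area_range[1], config$area_range[2])
  light_factor <- runif(1, config$light_range[1], config$light_range[2])
  rotation <- runif(1, config$rotation_range[1], config$rotation_range[2])
  flip <- runif(1) < config$flip_prob
  shear <- runif(1, config$shear_range[1], config$shear_range[2])
  if (is.null(allowed_mask)) {
    m <- config$margin_frac * sqrt(W^2 + H^2)
    assert_that(W - 2 * m > 1 && H - 2 * m > 1, "frame too small for margin")
    center <- c(runif(1, m, W - m), runif(1, m, H - m))
  } else {
    idx <- which(allowed_mask)
    assert_that(length(idx) > 0, "allowed-region mask is empty")
    pick <- idx[sample.int(length(idx), 1L)]
    r <- (pick - 1L) %% nrow(allowed_mask) + 1L
    cc <- (pick - 1L) %/% nrow(allowed_mask) + 1L
    center <- c(cc - 0.5, r - 0.5)
  }
  structure(list(center = center, area_fraction = area_fraction,
                 light_factor = light_factor, rotation = rotation,
                 flip = flip, shear = shear),
            class = "placement")
}

# Transform a sprite for a placement: flip, scale to the target area,
# rotate and shear, resampling bilinearly (premultiplied alpha). Returns
# the transformed RGBA canvas plus the binary paste mask (alpha >= 0.5).
transform_sprite <- function(sprite, placement, frame_area) {
  rgba <- sprite$rgba
  if (placement$flip) rgba <- rgba[, rev(seq_len(ncol(rgba))), , drop = FALSE]
  opaque_area <- sum(rgba[, , 4] > 0)
  if (opaque_area == 0) {
    # fully transparent sprite: compositing is the identity
    empty <- array(0, dim = c(2L, 2L, 4L))
    return(list(rgba = empty, mask = matrix(FALSE, 2L, 2L)))
  }
  scale <- sqrt(placement$area_fraction * frame_area / opaque_area)
  th <- placement$rotation * pi / 180
  sh <- placement$shear
  # forward map (centered coords): rotate %*% shear %*% scale
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, sh, 1), 2, 2)
  M <- R %*% Sh %*% diag(c(scale, scale))
  h0 <- nrow(rgba); w0 <- ncol(rgba)
  corners <- M %*% rbind(c(-w0, w0, w0, -w0) / 2, c(-h0, -h0, h0, h0) / 2)
  wt <- ceiling(max(corners[1, ]) - min(corners[1, ]))
  ht <- ceiling(max(corners[2, ]) - min(corners[2, ]))
  if (wt < 2 || ht < 2) stop_ew("degenerate scaled sprite (< 2 px side)")
  Minv <- solve(M)
  xs <- rep(seq_len(wt) - 0.5 - wt / 2, each = ht)
  ys <- rep(seq_len(ht) - 0.5 - ht / 2, times = wt)
  src <- Minv %*% rbind(xs, ys)
  sx <- src[1, ] + w0 / 2
  sy <- src[2, ] + h0 / 2
  a <- rgba[, , 4] / 255
  alpha_t <- matrix(bilinear_sample(a, sx, sy), ht, wt)
  out <- array(0, dim = c(ht, wt, 4))
  out[, , 4] <- alpha_t * 255
  for (ch in 1:3) {
    pm <- matrix(bilinear_sample(rgba[, , ch] * a, sx, sy), ht, wt)
    out[, , ch] <- ifelse(alpha_t > 0, pm / pmax(alpha_t, 1e-12), 0)
  }
  list(rgba = out, mask = alpha_t >= 0.5)
}

# Integer top-left offset (0-based) aligning the transformed canvas center
# with the placement center.
paste_offset <- function(placement, canvas_dim) {
  c(left = round(placement$center[1] - canvas_dim[2] / 2),
    top = round(placement$center[2] - canvas_dim[1] / 2))
}

# Composite a transformed sprite canvas over the background with a given
# continuous alpha matrix (same size as the canvas), applying the light
# factor to the sprite RGB. Regions falling outside the frame are clipped.
composite_canvas <- function(background, canvas, alpha, offset, light) {
  H <- dim(background)[1]; W <- dim(background)[2]
  ht <- dim(canvas)[1]; wt <- dim(canvas)[2]
  r0 <- max(1L, offset["top"] + 1L); r1 <- min(H, offset["top"] + ht)
  c0 <- max(1L, offset["left"] + 1L); c1 <- min(W, offset["left"] + wt)
  if (r0 > r1 || c0 > c1) return(background)
  sr <- (r0:r1) - offset["top"]; sc <- (c0:c1) - offset["left"]
  a <- alpha[sr, sc, drop = FALSE]
  for (ch in 1:3) {
    bg <- background[r0:r1, c0:c1, ch]
    background[r0:r1, c0:c1, ch] <-
      (1 - a) * bg + a * canvas[sr, sc, ch] * light
  }
  background
}

#' Direct paste
#'
#' Scales, pose-transforms and light-scales the sprite, then hard
#' alpha-composites it over the background: pixels under the binary mask
#' take the sprite value, all others are unchanged.
#'
#' @param background RGB array `[H, W, 3]`, values 0-255.
#' @param sprite a sprite from [generate_sprites()].
#' @param placement a [sample_placement()] result.
#' @return the composited RGB array.
#' @export
direct_paste <- function(background, sprite, placement) {
  tr <- transform_sprite(sprite, placement,
                         dim(background)[1] * dim(background)[2])
  off <- paste_offset(placement, dim(tr$rgba))
  composite_canvas(background, tr$rgba, tr$mask * 1, off,
                   placement$light_factor)
}

#' Gaussian paste
#'
#' As [direct_paste()], but the binary paste mask is Gaussian-blurred with
#' standard deviation `sigma` (pixels) before compositing, feathering the
#' sprite edges. `sigma = 0` reduces exactly to the direct paste.
#'
#' @inheritParams direct_paste
#' @param sigma blur standard deviation in pixels (>= 0).
#' @return the composited RGB array.
#' @export
gaussian_paste <- function(background, sprite, placement, sigma = 2) {
  assert_that(sigma >= 0, "sigma must be >= 0")
  tr <- transform_sprite(sprite, placement,
                         dim(background)[1] * dim(background)[2])
  off <- paste_offset(placement, dim(tr$rgba))
  alpha <- gaussian_blur(tr$mask * 1, sigma)
  composite_canvas(background, tr$rgba, alpha, off, placement$light_factor)
}

#' Compose a randomized scene
#'
#' Samples `n_birds` sprites from the pool (species mix configurable),
#' pastes them back-to-front with the requested paste operator, and returns
#' the image together with one annotation per pasted bird. Placements whose
#' box overlaps an accepted box beyond `max_iou` are resampled up to
#' `max_retries` times.
#'
#' @param background RGB array.
#' @param sprite_pool list of sprites from [generate_sprites()].
#' @param n_birds number of birds to paste (>= 0).
#' @param paste_mode one of `"direct"`, `"gaussian"`, `"poisson"`.
#' @param config a [placement_config()].
#' @param species_probs named sampling probabilities over species present
#'   in the pool.
#' @param max_iou maximum allowed pairwise box IoU between pasted birds.
#' @param max_retries placement resampling budget per bird.
#' @param sigma Gaussian-paste blur, in pixels.
#' @param render if `FALSE`, skip pixel compositing and return only the
#'   annotations (placements and boxes are computed identically).
#' @return list with `image` (RGB array, or the untouched background when
#'   `render = FALSE`) and `annotations` (data.frame `species`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, 0-based half-open, clipped to the frame).
#' @export
compose_scene <- function(background, sprite_pool, n_birds,
                          paste_mode = c("direct", "gaussian", "poisson"),
                          config = placement_config(),
                          species_probs = c(great_egret = 0.45,
                                            little_egret = 0.45,
                                            other = 0.10),
                          max_iou = 0.3, max_retries = 50L,
                          sigma = 2, render = TRUE) {
  paste_mode <- match.arg(paste_mode)
  assert_that(n_birds >= 0, "n_birds must be >= 0")
  H <- dim(background)[1]; W <- dim(background)[2]
  pool_species <- vapply(sprite_pool, `[[`, character(1), "species")
  img <- background
  ann <- list()
  boxes <- matrix(numeric(0), ncol = 4)
  for (b in seq_len(n_birds)) {
    sp <- sample(names(species_probs), 1L, prob = species_probs)
    cand <- which(pool_species == sp)
    assert_that(length(cand) > 0, paste("no sprite for species", sp))
    sprite <- sprite_pool[[cand[sample.int(length(cand), 1L)]]]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      placement <- sample_placement(c(W, H), config)
      tr <- transform_sprite(sprite, placement, W * H)
      off <- paste_offset(placement, dim(tr$rgba))
      bb <- mask_bbox(tr$mask, off, W, H)
      if (is.null(bb)) next
      ok <- TRUE
      if (nrow(boxes) > 0) {
        for (k in seq_len(nrow(boxes))) {
          if (iou(bb, boxes[k, ]) > max_iou) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      if (render) {
        pasted <- tryCatch(switch(paste_mode,
          direct = composite_canvas(img, tr$rgba, tr$mask * 1, off,
                                    placement$light_factor),
          gaussian = composite_canvas(img, tr$rgba,
                                      gaussian_blur(tr$mask * 1, sigma), off,
                                      placement$light_factor),
          poisson = poisson_blend(img, tr, off, placement$light_factor)),
          error = function(e) NULL)
        if (is.null(pasted)) next   # e.g. Poisson region touching the border
        img <- pasted
      }
      boxes <- rbind(boxes, bb)
      ann[[length(ann) + 1L]] <- data.frame(
        species = sp, x_min = bb[1], y_min = bb[2],
        x_max = bb[3], y_max = bb[4])
      placed <- TRUE
      break
    }
    if (!placed) stop_ew("placement retries exhausted under the overlap policy")
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(species = character(0), x_min = numeric(0), y_min = numeric(0),
               x_max = numeric(0), y_max = numeric(0))
  rownames(annotations) <- NULL
  list(image = img, annotations = annotations)
}

# Bounding box (0-based half-open, clipped) of a mask pasted at an offset;
# NULL when the mask is empty or fully outside the frame.
mask_bbox <- function(mask, offset, W, H) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (!length(rows)) return(NULL)
  x0 <- max(0, offset["left"] + min(cols) - 1)
  x1 <- min(W, offset["left"] + max(cols))
  y0 <- max(0, offset["top"] + min(rows) - 1)
  y1 <- min(H, offset["top"] + max(rows))
  if (x1 <= x0 || y1 <= y0) return(NULL)
  unname(c(x0, y0, x1, y1))
}

#' Generate a synthetic detection-training dataset
#'
#' Composes `n_images` randomized scenes (paste operator chosen uniformly
#' per image by default) and writes COCO-format annotations plus a
#' manifest recording the seed and configuration hash. Rerunning with the
#' same seed reproduces the annotation file exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param n_images number of images (default 1000, the size of the
#'   synthetic pretraining set this generator emulates).
#' @param frame_width,frame_height frame size in pixels.
#' @param seed integer seed.
#' @param n_birds_range inclusive range of birds per image.
#' @param paste_modes paste operators mixed uniformly per image.
#' @param n_backgrounds size of the generated background pool.
#' @param n_poses sprite poses per species.
#' @param config a [placement_config()].
#' @param write_images write each composited frame as PNG (heavy at full
#'   resolution; annotations are always written).
#' @param render compute pixel composites even when not writing images.
#' @return invisibly, a list with the COCO annotation structure, the
#'   per-image annotation data.frames and the manifest.
#' @export
generate_dataset <- function(out_dir, n_images = 1000L,
                             frame_width = 2139L, frame_height = 1281L,
                             seed = 7L, n_birds_range = c(1L, 6L),
                             paste_modes = c("direct", "gaussian", "poisson"),
                             n_backgrounds = 5L, n_poses = 4L,
                             config = placement_config(),
                             write_images = FALSE, render = write_images) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), "output path is not writable")
  pool <- generate_sprites(seed, n_poses)
  backgrounds <- lapply(seq_len(n_backgrounds), function(i)
    generate_background(frame_width, frame_height, child_seed(seed, paste0("bg", i))))
  per_image <- vector("list", n_images)
  modes <- character(n_images)
  with_seed(child_seed(seed, "dataset"), {
    for (i in seq_len(n_images)) {
      modes[i] <- sample(paste_modes, 1L)
      n_birds <- sample(seq(n_birds_range[1], n_birds_range[2]), 1L)
      bg <- backgrounds[[(i - 1L) %% n_backgrounds + 1L]]
      scene <- compose_scene(bg, pool, n_birds, paste_mode = modes[i],
                             config = config, render = render)
      per_image[[i]] <- scene$annotations
      if (write_images) {
        write_image(scene$image,
                    file.path(out_dir, sprintf("img_%04d.png", i)))
      }
    }
  })
  coco <- annotations_to_coco(per_image, frame_width, frame_height)
  jsonlite::write_json(coco, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_echo <- list(n_images = n_images, frame = c(frame_width, frame_height),
                   seed = seed, n_birds_range = n_birds_range,
                   paste_modes = paste_modes, config = unclass(config))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg_echo, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = seed, n_images = n_images,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   paste_mode_counts = as.list(table(modes)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(coco = coco, annotations = per_image, manifest = manifest))
}

COCO_CATEGORIES <- data.frame(
  id = 1:3, name = c("great_egret", "little_egret", "other"))

annotations_to_coco <- function(per_image, width, height) {
  images <- lapply(seq_along(per_image), function(i)
    list(id = i, file_name = sprintf("img_%04d.png", i),
         width = width, height = height))
  anns <- list()
  aid <- 0L
  for (i in seq_along(per_image)) {
    df <- per_image[[i]]
    for (k in seq_len(nrow(df))) {
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = i,
        category_id = match(df$species[k], COCO_CATEGORIES$name),
        bbox = c(df$x_min[k], df$y_min[k],
                 df$x_max[k] - df$x_min[k], df$y_max[k] - df$y_min[k]),
        area = (df$x_max[k] - df$x_min[k]) * (df$y_max[k] - df$y_min[k]),
        iscrowd = 0L)
    }
  }
  list(images = images, annotations = anns,
       categories = lapply(seq_len(nrow(COCO_CATEGORIES)), function(i)
         list(id = COCO_CATEGORIES$id[i], name = COCO_CATEGORIES$name[i])))
}
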