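# Placement randomization and the three paste operators.

test_that("sample_placement: ranges, mean light, determinism, empty mask", {
  set.seed(42)
  n <- 10000L
  s <- replicate(n, unclass(sample_placement(c(640, 480))), simplify = FALSE)
  af <- vapply(s, `[[`, numeric(1), "area_fraction")
  lf <- vapply(s, `[[`, numeric(1), "light_factor")
  expect_true(all(af >= 0.0004 & af <= 0.0056))
  expect_true(all(lf >= 0.6 & lf <= 1.0))
  expect_equal(mean(lf), 0.8, tolerance = 0.01 / 0.8)
  cx <- vapply(s, function(p) p$center[1], numeric(1))
  cy <- vapply(s, function(p) p$center[2], numeric(1))
  expect_true(all(cx >= 0 & cx <= 640 & cy >= 0 & cy <= 480))

  set.seed(7); a <- sample_placement(c(640, 480))
  set.seed(7); b <- sample_placement(c(640, 480))
  expect_identical(a, b)

  empty <- matrix(FALSE, 480, 640)
  expect_error(sample_placement(c(640, 480), allowed_mask = empty), "empty")
})

test_that("direct_paste: opaque copy, transparent identity, light scaling", {
  bg <- generate_background(200, 160, seed = 1)
  spr <- opaque_sprite(8, 6)
  pl <- identity_placement(spr, 200, 160, cx = 100.0, cy = 80.0, light = 1)
  out <- direct_paste(bg, spr, pl)
  # pasted block equals the sprite exactly (identity transform, light 1)
  r0 <- 80 - 4 + 1; c0 <- 100 - 3 + 1
  expect_equal(out[r0:(r0 + 7), c0:(c0 + 5), 1:3],
               spr$rgba[, , 1:3], tolerance = 1e-12)
  # all other pixels untouched
  touched <- array(FALSE, dim = dim(bg))
  touched[r0:(r0 + 7), c0:(c0 + 5), ] <- TRUE
  expect_identical(out[!touched], bg[!touched])

  transparent <- opaque_sprite(8, 6)
  transparent$rgba[, , 4] <- 0
  expect_identical(direct_paste(bg, transparent, pl), bg)

  white <- opaque_sprite(8, 6, value = 255)
  pl06 <- identity_placement(white, 200, 160, 100, 80, light = 0.6)
  out3 <- direct_paste(bg, white, pl06)
  expect_equal(unique(as.numeric(out3[r0:(r0 + 7), c0:(c0 + 5), 1:3])), 153)
})

test_that("gaussian_paste: sigma 0 limit, feathering, convexity", {
  bg <- generate_background(200, 160, seed = 2)
  spr <- ramp_sprite(10, 10)
  pl <- identity_placement(spr, 200, 160, 100, 80, light = 0.9)
  expect_equal(gaussian_paste(bg, spr, pl, sigma = 0),
               direct_paste(bg, spr, pl))
  expect_error(gaussian_paste(bg, spr, pl, sigma = -1), "sigma")

  out <- gaussian_paste(bg, spr, pl, sigma = 2)
  # center of the mask keeps (nearly) full sprite value; far pixels keep bg
  expect_equal(out[81, 101, 1], spr$rgba[6, 6, 1] * 0.9, tolerance = 0.05)
  expect_identical(out[1:40, 1:40, ], bg[1:40, 1:40, ])
  # convexity: every pixel between background and (light-scaled) sprite canvas
  canvas <- array(0, dim = dim(bg))
  r0 <- 80 - 5 + 1; c0 <- 100 - 5 + 1
  canvas[r0:(r0 + 9), c0:(c0 + 9), ] <- spr$rgba[, , 1:3] * 0.9
  lo <- pmin(bg, canvas); hi <- pmax(bg, canvas)
  expect_true(all(out >= lo - 1e-9 & out <= hi + 1e-9))
})

test_that("poisson_paste: Laplace limit, Dirichlet untouched outside, solvers agree", {
  # constant sprite into constant background reproduces the background
  bg <- blank_image(64, 64, 3, value = 120)
  spr <- opaque_sprite(10, 8, value = 200)
  pl <- identity_placement(spr, 64, 64, 32, 32)
  out <- poisson_paste(bg, spr, pl, solver = "cg")
  expect_equal(out, bg, tolerance = 1e-8)

  # non-trivial sprite: pixels outside the opaque region unchanged
  bg2 <- generate_background(64, 64, seed = 3)
  spr2 <- ramp_sprite(10, 10)
  pl2 <- identity_placement(spr2, 64, 64, 32, 32)
  out_cg <- poisson_paste(bg2, spr2, pl2, solver = "cg")
  out_dir <- poisson_paste(bg2, spr2, pl2, solver = "direct")
  expect_equal(out_cg, out_dir, tolerance = 1e-7)
  touched <- array(FALSE, dim = dim(bg2))
  r0 <- 32 - 5 + 1; c0 <- 32 - 5 + 1
  touched[r0:(r0 + 9), c0:(c0 + 9), ] <- TRUE
  expect_identical(out_cg[!touched], bg2[!touched])

  # region touching the border is rejected
  ple <- identity_placement(spr2, 64, 64, 4, 4)
  expect_error(poisson_paste(bg2, spr2, ple), "strictly inside")
})

test_that("poisson_paste matches the dense direct-solve oracle", {
  set.seed(10)
  for (rep in 1:3) {
    h <- sample(c(6L, 8L, 10L, 12L), 1); w <- sample(c(6L, 8L, 10L, 12L), 1)
    spr <- ramp_sprite(h, w)
    # carve an irregular opaque region (keep it connected-ish)
    a <- matrix(255, h, w)
    a[sample(h * w, round(0.2 * h * w))] <- 0
    spr$rgba[, , 4] <- a
    bg <- generate_background(64, 64, seed = rep)
    pl <- identity_placement(spr, 64, 64, 30, 30)
    pl$area_fraction <- sum(a > 0) / (64 * 64)   # keep scale exactly 1
    out <- poisson_paste(bg, spr, pl, solver = "cg", tol = 1e-12)
    # oracle on the same window
    r0 <- 30 - floor(h / 2) + 1; c0 <- 30 - floor(w / 2) + 1
    wr <- (r0 - 1):(r0 + h); wc <- (c0 - 1):(c0 + w)
    mask <- matrix(FALSE, length(wr), length(wc))
    mask[2:(h + 1), 2:(w + 1)] <- a > 0
    for (ch in 1:3) {
      g <- matrix(0, length(wr), length(wc))
      g[2:(h + 1), 2:(w + 1)] <- spr$rgba[, , ch]
      ref <- dense_poisson_oracle(mask, bg[wr, wc, ch], g)
      got <- out[wr, wc, ch][mask]
      expect_lt(max(abs(got - ref)), 1e-6)
    }
  }
})

test_that("paste operators commute with horizontal mirroring", {
  bg <- generate_background(128, 96, seed = 4)
  spr <- ramp_sprite(9, 7)
  pl <- structure(list(center = c(60.3, 47.2), area_fraction = 0.004,
                       light_factor = 0.8, rotation = 9, flip = FALSE,
                       shear = 0.12), class = "placement")
  mirror_pl <- function(p, W) {
    p$center[1] <- W - p$center[1]
    p$rotation <- -p$rotation
    p$shear <- -p$shear
    p$flip <- !p$flip
    p
  }
  mir <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  W <- 128
  for (op in list(
    function(b, s, p) direct_paste(b, s, p),
    function(b, s, p) gaussian_paste(b, s, p, sigma = 1.5),
    function(b, s, p) poisson_paste(b, s, p, solver = "direct"))) {
    a <- mir(op(bg, spr, pl))
    b <- op(mir(bg), spr, mirror_pl(pl, W))
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("compose_scene: counts, in-frame boxes, annotation-pixel consistency", {
  bg <- generate_background(320, 240, seed = 5)
  pool <- generate_sprites(3, 2)
  set.seed(1)
  empty <- compose_scene(bg, pool, 0, "direct")
  expect_identical(empty$image, bg)
  expect_equal(nrow(empty$annotations), 0L)

  set.seed(2)
  sc <- compose_scene(bg, pool, 5, "direct")
  ann <- sc$annotations
  expect_equal(nrow(ann), 5L)
  expect_true(all(ann$x_min >= 0 & ann$x_max <= 320 &
                    ann$y_min >= 0 & ann$y_max <= 240))
  expect_true(all(ann$x_max > ann$x_min & ann$y_max > ann$y_min))
  for (k in seq_len(nrow(ann))) {
    rr <- (floor(ann$y_min[k]) + 1):ceiling(ann$y_max[k])
    cc <- (floor(ann$x_min[k]) + 1):ceiling(ann$x_max[k])
    expect_gt(sum(sc$image[rr, cc, ] != bg[rr, cc, ]), 0)
  }
})

test_that("compose_scene balances the two egret species over many scenes", {
  bg <- generate_background(320, 240, seed = 6)
  pool <- generate_sprites(4, 1)
  set.seed(3)
  tab <- c(great_egret = 0, little_egret = 0, other = 0)
  for (i in 1:600) {
    sc <- compose_scene(bg, pool, 4, "direct", render = FALSE)
    t2 <- table(sc$annotations$species)
    tab[names(t2)] <- tab[names(t2)] + t2
  }
  # ~2400 birds: the 45/45/10 species mix keeps the egrets balanced
  ratio <- tab[["great_egret"]] / tab[["little_egret"]]
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
  expect_lt(tab[["other"]] / sum(tab), 0.2)
})

test_that("generate_dataset writes n images worth of reproducible annotations", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- generate_dataset(d1, n_images = 3, frame_width = 320,
                           frame_height = 240, seed = 9, write_images = TRUE)
  expect_length(list.files(d1, pattern = "^img_.*png$"), 3L)
  expect_true(file.exists(file.path(d1, "annotations.json")))
  expect_length(res1$coco$images, 3L)
  res2 <- generate_dataset(d2, n_images = 3, frame_width = 320,
                           frame_height = 240, seed = 9, write_images = FALSE)
  expect_identical(readLines(file.path(d1, "annotations.json")),
                   readLines(file.path(d2, "annotations.json")))
})
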