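# Cell grid, spatial/temporal smoothing and period heatmaps.

rec_at <- function(x, y, species = "great_egret", t = utc("2019-09-23 08:00:00")) {
  data.frame(timestamp = t, species = species, x_min = x - 10, y_min = y - 10,
             x_max = x + 10, y_max = y + 10, score = 0.9)
}

test_that("cell_grid tiles the frame with partial edge cells", {
  g <- cell_grid(2139, 1281, 200)
  expect_equal(g$n_cols, 11L)
  expect_equal(g$n_rows, 7L)
  expect_equal(dim(g$dist), c(77L, 77L))
  expect_true(isSymmetric(g$dist))
  expect_true(all(diag(g$dist) == 0))
  # last column cell is partial: center at (2000 + 2139)/2
  expect_equal(max(g$centers[, "x"]), (2000 + 2139) / 2)
})

test_that("assign_counts: center assignment, boundary convention, conservation", {
  g <- cell_grid(1000, 800, 200)
  r <- rec_at(450, 650)   # cell col 3 (400-600), row 4 (600-800)
  cts <- assign_counts(r, g, "great_egret")
  m <- field_matrix(cts, g)
  expect_equal(m[4, 3], 1)
  expect_equal(sum(cts), 1)
  # center exactly on a cell boundary: belongs to the half-open cell
  # starting there
  rb <- rec_at(400, 200)
  mb <- field_matrix(assign_counts(rb, g, "great_egret"), g)
  expect_equal(mb[2, 3], 1)
  # conservation over a random batch
  set.seed(5)
  batch <- do.call(rbind, lapply(1:50, function(i)
    rec_at(runif(1, 15, 985), runif(1, 15, 785))))
  expect_equal(sum(assign_counts(batch, g, "great_egret")), 50)
  expect_equal(sum(assign_counts(batch, g, "little_egret")), 0)
})

test_that("spatial_smooth: kernel limits and closed-form neighbor value", {
  g <- cell_grid(1000, 800, 200)
  n <- g$n_rows * g$n_cols
  cts <- integer(n); cts[7] <- 3
  # beta = 0: every cell equals the total count
  expect_equal(spatial_smooth(cts, g, beta = 0), rep(3, n))
  # neighbor at distance 200 px with beta = 0.01 receives c0 * exp(-2)
  x <- spatial_smooth(cts, g, beta = 0.01)
  nb <- which(abs(g$dist[7, ] - 200) < 1e-9)[1]
  expect_equal(x[nb], 3 * exp(-2))
  expect_equal(x[7], 3)   # own cell: e^0
  # large beta leaves the raw counts
  expect_equal(spatial_smooth(cts, g, beta = 10), as.numeric(cts),
               tolerance = 1e-12)
  expect_error(spatial_smooth(cts, g, beta = -1), "beta")
})

test_that("spatial_smooth matches the double-loop oracle on small grids", {
  g <- cell_grid(8 * 50, 8 * 50, 50)   # 8 x 8 cells
  n <- 64
  set.seed(6)
  for (beta in c(0, 0.003, 0.02, 0.3)) {
    cts <- rpois(n, 2)
    x <- spatial_smooth(cts, g, beta)
    oracle <- numeric(n)
    for (i in 1:n) for (j in 1:n) {
      oracle[i] <- oracle[i] + exp(-beta * sqrt(sum((g$centers[i, ] -
                                                       g$centers[j, ])^2))) * cts[j]
    }
    expect_lt(max(abs(x - oracle)), 1e-10)
    # mass inflation identity
    expect_equal(sum(x), sum(cts * colSums(exp(-beta * g$dist))),
                 tolerance = 1e-10)
    # x dominates the raw counts (all kernel terms nonnegative, e^0 own cell)
    expect_true(all(x >= cts - 1e-12))
  }
})

test_that("temporal_smooth: lambda limits, fixed point, bounds", {
  set.seed(7)
  x <- matrix(rpois(5 * 20, 4), 5, 20)
  expect_equal(temporal_smooth(x, lam = 1), x * 1.0)
  s0 <- temporal_smooth(x, lam = 0)
  expect_true(all(s0 == x[, 1]))
  expect_equal(temporal_smooth(x, lam = 0, s0_policy = "zero"),
               matrix(0, 5, 20))
  # constant input is a fixed point
  cst <- matrix(3, 4, 10)
  expect_equal(temporal_smooth(cst, lam = 0.3), cst)
  # bounded by the running min/max of (s0, x_1..t)
  s <- temporal_smooth(x, lam = 0.25)
  for (t in seq_len(ncol(x))) {
    expect_true(all(s[, t] >= apply(cbind(x[, 1], x[, 1:t]), 1, min) - 1e-12))
    expect_true(all(s[, t] <= apply(cbind(x[, 1], x[, 1:t]), 1, max) + 1e-12))
  }
  expect_error(temporal_smooth(x, lam = 1.2), "lambda")
})

test_that("period_heatmap recovers planted hotspots and stratification", {
  cfg <- desk_config(n_days = 2, count_noise = "poisson", seed = 40,
                     hotspot_centers = c(0.25, 0.75),
                     hotspot_sds = c(0.03, 0.03),
                     hotspot_weights = c(0.5, 0.5))
  sim <- simulate_detections(cfg)
  g <- cell_grid(cfg$frame_width, cfg$frame_height, 200)
  hm_g <- period_heatmap(sim$records, g, "great_egret", beta = 0.005,
                         lam = 0.1)
  expect_true(all(hm_g$field >= 0))
  # top cells concentrate at the two planted horizontal hotspots
  m <- field_matrix(hm_g$field, g)
  col_mass <- colSums(m)
  top2 <- order(col_mass, decreasing = TRUE)[1:2]
  hot_cols <- sort(unique(pmin(floor(cfg$hotspot_centers * cfg$frame_width /
                                       200), g$n_cols - 1) + 1))
  expect_setequal(sort(top2), hot_cols)

  # vertical stratification: with a fine grid and near-local kernel the
  # occupied row span of the great egret strictly contains the little's
  # (bands [0.10, 0.70] vs [0.35, 0.65] of frame height)
  g50 <- cell_grid(cfg$frame_width, cfg$frame_height, 50)
  row_span <- function(sp) {
    hm <- period_heatmap(sim$records, g50, sp, beta = 10, lam = 1)
    rm <- rowSums(field_matrix(hm$field, g50))
    range(which(rm > 0))
  }
  sg <- row_span("great_egret"); sl <- row_span("little_egret")
  expect_lt(sg[1], sl[1])
  expect_gt(sg[2], sl[2])

  # time-constant field: mean equals the field; empty period errors
  expect_error(period_heatmap(sim$records, g, "great_egret",
                              period = utc(c("2030-01-01", "2030-01-02"))),
               "empty")
})

test_that("render_heatmap maps species to colors and handles zero fields", {
  g <- cell_grid(400, 400, 200)
  bg <- blank_image(400, 400, 3, value = 100)
  fg <- c(1, 0, 0, 0); fl <- c(0, 0, 0, 1)
  out <- render_heatmap(fg, fl, g, bg, alpha = 0.5)
  # great egret cell (top-left) pushed toward red, little (bottom-right)
  # toward blue
  expect_gt(out[50, 50, 1], out[50, 50, 3])
  expect_gt(out[350, 350, 3], out[350, 350, 1])
  blank <- render_heatmap(rep(0, 4), rep(0, 4), g, bg)
  expect_equal(blank, bg)
})
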