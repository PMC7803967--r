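# Spatio-temporal occupancy heatmaps: the frame is tiled with 200 x 200 px
# cells; per-frame per-cell counts are smoothed spatially with an
# exponential-distance kernel over all cells,
#   x[t, i, k] = sum_j exp(-beta * d(p_i, p_j)) * c(t, j, k),
# then recursively in time,
#   s[t, i, k] = lambda * x[t, i, k] + (1 - lambda) * s[t-1, i, k],
# and averaged over a period for display.

#' Build the cell grid of a frame
#'
#' Cells tile the frame (the last row/column may be partial); cell centers
#' are the centers of the actual, possibly clipped cell rectangles, and
#' the Euclidean distance table between centers is precomputed.
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param cell_size cell side in pixels (default 200).
#' @return list of class `cell_grid`: `n_rows`, `n_cols`, `cell_size`,
#'   `centers` (n x 2 matrix, x then y), `dist` (n x n), frame size.
#' @export
cell_grid <- function(frame_width, frame_height, cell_size = 200) {
  assert_that(cell_size > 0, "cell_size must be > 0")
  n_cols <- ceiling(frame_width / cell_size)
  n_rows <- ceiling(frame_height / cell_size)
  ix <- rep(seq_len(n_cols), each = n_rows)
  iy <- rep(seq_len(n_rows), times = n_cols)
  x0 <- (ix - 1) * cell_size; x1 <- pmin(ix * cell_size, frame_width)
  y0 <- (iy - 1) * cell_size; y1 <- pmin(iy * cell_size, frame_height)
  centers <- cbind(x = (x0 + x1) / 2, y = (y0 + y1) / 2)
  d <- as.matrix(stats::dist(centers))
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 frame_width = frame_width, frame_height = frame_height,
                 centers = centers, dist = d),
            class = "cell_grid")
}

# cell index (column-major over rows) of box centers; half-open cells, so
# a center exactly on a boundary goes to the higher cell start, i.e. the
# cell whose half-open interval contains it.
cell_index <- function(grid, x, y) {
  cx <- pmin(floor(x / grid$cell_size), grid$n_cols - 1)
  cy <- pmin(floor(y / grid$cell_size), grid$n_rows - 1)
  cx * grid$n_rows + cy + 1
}

#' Assign detections of one frame to grid cells
#'
#' Each detection is assigned to the cell containing its box center
#' (half-open cells, lower-index side on exact boundaries).
#'
#' @param records detection records of one frame (any data.frame with the
#'   box columns); rows outside the species are ignored when `species` is
#'   given.
#' @param grid a [cell_grid()].
#' @param species optional species filter.
#' @return integer vector of length `n_rows * n_cols` of per-cell counts;
#'   sums to the number of assigned detections.
#' @export
assign_counts <- function(records, grid, species = NULL) {
  if (!is.null(species)) records <- records[records$species == species, ,
                                            drop = FALSE]
  n <- grid$n_rows * grid$n_cols
  if (!nrow(records)) return(integer(n))
  xc <- (records$x_min + records$x_max) / 2
  yc <- (records$y_min + records$y_max) / 2
  tabulate(cell_index(grid, xc, yc), nbins = n)
}

#' Spatial smoothing of per-cell counts
#'
#' `x_i = sum_j exp(-beta * d(p_i, p_j)) * c_j` over all cells. With
#' `beta = 0` every cell receives the total count; large `beta` leaves the
#' raw counts.
#'
#' @param counts per-cell count vector (or matrix, cells x times).
#' @param grid a [cell_grid()].
#' @param beta spatial smoothing constant, per pixel, >= 0.
#' @return smoothed vector (or matrix) with the same shape.
#' @export
spatial_smooth <- function(counts, grid, beta = 0.01) {
  assert_that(beta >= 0, "beta must be >= 0")
  K <- exp(-beta * grid$dist)
  if (is.matrix(counts)) K %*% counts else as.numeric(K %*% counts)
}

#' Exponential temporal smoothing
#'
#' `s_t = lambda * x_t + (1 - lambda) * s_{t-1}` per cell; `s_0` is the
#' first observation by default (`s0_policy = "first"`) or zero
#' (`"zero"`).
#'
#' @param x matrix of spatially smoothed fields, cells x times.
#' @param lam smoothing constant in `[0, 1]`.
#' @param s0_policy initialization policy.
#' @return matrix of the same shape with the recursively smoothed fields.
#' @export
temporal_smooth <- function(x, lam = 0.1, s0_policy = c("first", "zero")) {
  assert_that(lam >= 0 && lam <= 1, "lambda must be in [0, 1]")
  s0_policy <- match.arg(s0_policy)
  x <- as.matrix(x)
  s <- matrix(0, nrow(x), ncol(x))
  prev <- if (s0_policy == "first") x[, 1] else numeric(nrow(x))
  for (t in seq_len(ncol(x))) {
    prev <- lam * x[, t] + (1 - lam) * prev
    s[, t] <- prev
  }
  s
}

#' Period-averaged heatmap field
#'
#' Builds the per-frame per-cell counts of a species over a time period,
#' applies the spatial and temporal smoothing, and averages the smoothed
#' fields over time.
#'
#' @param records detection records.
#' @param grid a [cell_grid()].
#' @param species species label.
#' @param beta,lam smoothing constants.
#' @param period optional `c(start, end)` POSIXct filter (half-open).
#' @param score_threshold minimum confidence.
#' @return list with `field` (per-cell time-mean, length n cells), `x`
#'   and `s` matrices (cells x frames), and the frame timestamps.
#' @export
period_heatmap <- function(records, grid, species, beta = 0.01, lam = 0.1,
                           period = NULL, score_threshold = 0.5) {
  keep <- records$score >= score_threshold
  if (!is.null(period)) {
    keep <- keep & records$timestamp >= period[1] & records$timestamp < period[2]
  }
  rec <- records[keep, , drop = FALSE]
  frames <- sort(unique(rec$timestamp))
  assert_that(length(frames) > 0, "empty period")
  n <- grid$n_rows * grid$n_cols
  counts <- matrix(0, n, length(frames))
  recs_sp <- rec[rec$species == species, , drop = FALSE]
  if (nrow(recs_sp)) {
    fi <- match(recs_sp$timestamp, frames)
    xc <- (recs_sp$x_min + recs_sp$x_max) / 2
    yc <- (recs_sp$y_min + recs_sp$y_max) / 2
    ci <- cell_index(grid, xc, yc)
    for (k in seq_along(fi)) counts[ci[k], fi[k]] <- counts[ci[k], fi[k]] + 1
  }
  x <- spatial_smooth(counts, grid, beta)
  s <- temporal_smooth(x, lam)
  list(field = rowMeans(s), x = x, s = s, frames = frames)
}

#' Field vector to a cell matrix
#' @param field per-cell vector in grid order.
#' @param grid a [cell_grid()].
#' @return `n_rows x n_cols` matrix.
#' @export
field_matrix <- function(field, grid) {
  matrix(field, nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Render a two-species heatmap overlay
#'
#' Normalizes each species field to `[0, 1]` (max-normalization; an
#' all-zero field stays blank), maps the great egret to red and the little
#' egret to blue, upsamples to the frame size and alpha-blends over the
#' background.
#'
#' @param field_g,field_l per-cell fields (great and little egret).
#' @param grid a [cell_grid()].
#' @param background RGB array of the frame (values 0-255).
#' @param alpha maximal overlay opacity.
#' @return RGB array of the overlay image.
#' @export
render_heatmap <- function(field_g, field_l, grid, background, alpha = 0.6) {
  H <- dim(background)[1]; W <- dim(background)[2]
  norm01 <- function(f) if (max(f) > 0) f / max(f) else f
  mg <- bilinear_resize(field_matrix(norm01(field_g), grid), H, W)
  ml <- bilinear_resize(field_matrix(norm01(field_l), grid), H, W)
  out <- background
  cov <- clamp(mg + ml, 0, 1) * alpha
  red <- c(220, 30, 30); blue <- c(30, 60, 220)
  tot <- pmax(mg + ml, 1e-12)
  for (ch in 1:3) {
    colmix <- (mg * red[ch] + ml * blue[ch]) / tot
    out[, , ch] <- (1 - cov) * background[, , ch] + cov * colmix
  }
  out
}
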