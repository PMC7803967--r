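# Detection evaluation: IoU matching, precision-recall curves, AP and mAP
# (all at a fixed IoU threshold, the protocol behind "mAP (IoU = 0.5)").

#' Intersection over union of two boxes
#'
#' Boxes are `c(x_min, y_min, x_max, y_max)` with `x_max > x_min` and
#' `y_max > y_min` (half-open pixel coordinates).
#'
#' @param a,b numeric boxes.
#' @return the ratio area(a intersect b) / area(a union b), in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  stopifnot(a[3] > a[1], a[4] > a[2], b[3] > b[1], b[4] > b[2])
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Greedily match detections to ground truth
#'
#' Detections are processed in descending confidence (ties broken by input
#' order, stable); each matches the highest-IoU not-yet-matched ground
#' truth of the same class with IoU at or above the threshold. Unmatched
#' detections are false positives; unmatched ground truths are false
#' negatives.
#'
#' @param dets data.frame with columns `label`, `score`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @param gts data.frame with columns `label`, `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @param iou_threshold matching threshold in (0, 1].
#' @return list with `order` (detection indices in evaluation order),
#'   `tp` (logical per detection, in evaluation order), and `gt_matched`
#'   (logical per ground truth).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  assert_that(iou_threshold > 0 && iou_threshold <= 1,
              "iou_threshold must be in (0, 1]")
  ord <- order(-dets$score)
  tp <- logical(length(ord))
  gt_matched <- logical(nrow(gts))
  for (k in seq_along(ord)) {
    d <- dets[ord[k], ]
    best <- 0; best_j <- 0L
    for (j in seq_len(nrow(gts))) {
      if (gt_matched[j] || gts$label[j] != d$label) next
      v <- iou(c(d$x_min, d$y_min, d$x_max, d$y_max),
               c(gts$x_min[j], gts$y_min[j], gts$x_max[j], gts$y_max[j]))
      if (v >= iou_threshold && v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0L) { tp[k] <- TRUE; gt_matched[best_j] <- TRUE }
  }
  list(order = ord, tp = tp, gt_matched = gt_matched)
}

#' Cumulative precision-recall curve
#'
#' One point per detection prefix in descending-confidence order; recall is
#' non-decreasing along the curve.
#'
#' @param tp logical vector of per-detection true-positive flags, already
#'   in descending-confidence order.
#' @param n_gt number of ground-truth objects (>= 1).
#' @return data.frame with columns `recall` and `precision` (zero rows for
#'   no detections).
#' @export
pr_curve <- function(tp, n_gt) {
  assert_that(n_gt >= 1, "n_gt must be >= 1")
  if (!length(tp)) {
    return(data.frame(recall = numeric(0), precision = numeric(0)))
  }
  ctp <- cumsum(tp)
  k <- seq_along(tp)
  data.frame(recall = ctp / n_gt, precision = ctp / k)
}

#' Average precision from a precision-recall curve
#'
#' Area under the precision-envelope-recall curve: precision is replaced by
#' its running maximum from the right (the envelope), then integrated over
#' recall from 0 to 1 with all-point interpolation. A 101-point
#' interpolation variant is available.
#'
#' @param curve data.frame from [pr_curve()].
#' @param method `"all_points"` (default) or `"101_point"`.
#' @return AP in `[0, 1]`; 0 for an empty curve.
#' @export
average_precision <- function(curve, method = c("all_points", "101_point")) {
  method <- match.arg(method)
  if (!nrow(curve)) return(0)
  r <- c(0, curve$recall)
  p <- c(0, curve$precision)
  # envelope: max precision at any recall >= r
  penv <- rev(cummax(rev(p)))
  if (method == "101_point") {
    grid <- seq(0, 1, length.out = 101)
    pv <- vapply(grid, function(g) {
      ok <- curve$recall >= g
      if (any(ok)) max(curve$precision[ok]) else 0
    }, numeric(1))
    return(mean(pv))
  }
  sum(diff(r) * penv[-1])
}

#' Mean average precision over classes
#'
#' Unweighted mean of per-class AP over classes with at least one ground
#' truth; classes without ground truth are skipped.
#'
#' @param dets,gts as in [match_detections()].
#' @param iou_threshold matching threshold.
#' @param method AP interpolation, see [average_precision()].
#' @return list with `per_class` (named AP vector) and `map`.
#' @export
mean_ap <- function(dets, gts, iou_threshold = 0.5,
                    method = "all_points") {
  classes <- unique(gts$label)
  assert_that(length(classes) > 0, "no class has ground truth")
  aps <- vapply(classes, function(cl) {
    d <- dets[dets$label == cl, , drop = FALSE]
    g <- gts[gts$label == cl, , drop = FALSE]
    m <- match_detections(d, g, iou_threshold)
    average_precision(pr_curve(m$tp, nrow(g)), method = method)
  }, numeric(1))
  names(aps) <- classes
  list(per_class = aps, map = mean(aps))
}

#' Read COCO-format ground truth or detection results
#'
#' @param path JSON file. Ground-truth files carry `images`/`annotations`/
#'   `categories`; results files are arrays of `image_id`, `category_id`,
#'   `bbox`, `score` objects.
#' @param categories data.frame with `id` and `name` used to label
#'   results files (which carry no category table); defaults to the
#'   package's three-species scheme.
#' @return data.frame with `image_id`, `label`, box columns, and `score`
#'   for results.
#' @export
read_coco <- function(path, categories = COCO_CATEGORIES) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$annotations)) {
    cats <- vapply(x$categories, function(cc) cc$name, character(1))
    ids <- vapply(x$categories, function(cc) cc$id, numeric(1))
    rows <- lapply(x$annotations, function(a) data.frame(
      image_id = a$image_id,
      label = cats[match(a$category_id, ids)],
      x_min = a$bbox[[1]], y_min = a$bbox[[2]],
      x_max = a$bbox[[1]] + a$bbox[[3]], y_max = a$bbox[[2]] + a$bbox[[4]]))
    return(do.call(rbind, rows))
  }
  rows <- lapply(x, function(a) data.frame(
    image_id = a$image_id,
    label = categories$name[match(a$category_id, categories$id)],
    x_min = a$bbox[[1]], y_min = a$bbox[[2]],
    x_max = a$bbox[[1]] + a$bbox[[3]], y_max = a$bbox[[2]] + a$bbox[[4]],
    score = a$score))
  do.call(rbind, rows)
}

#' Evaluate detections over a set of images
#'
#' Pools matching decisions across images per class before building the
#' PR curve (standard multi-image protocol).
#'
#' @param dets data.frame with `image_id`, `label`, `score` and box
#'   columns.
#' @param gts data.frame with `image_id`, `label` and box columns.
#' @param iou_threshold matching threshold.
#' @return list with `per_class` AP, `map`, and per-class PR curves.
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5) {
  classes <- unique(gts$label)
  assert_that(length(classes) > 0, "no class has ground truth")
  out_ap <- numeric(0); curves <- list()
  for (cl in classes) {
    scores <- numeric(0); tps <- logical(0)
    n_gt <- 0L
    for (im in unique(c(dets$image_id, gts$image_id))) {
      d <- dets[dets$label == cl & dets$image_id == im, , drop = FALSE]
      g <- gts[gts$label == cl & gts$image_id == im, , drop = FALSE]
      n_gt <- n_gt + nrow(g)
      if (nrow(d)) {
        m <- match_detections(d, g, iou_threshold)
        scores <- c(scores, d$score[m$order])
        tps <- c(tps, m$tp)
      }
    }
    if (n_gt == 0L) next
    ord <- order(-scores)
    curve <- pr_curve(tps[ord], n_gt)
    curves[[cl]] <- curve
    out_ap[cl] <- average_precision(curve)
  }
  list(per_class = out_ap, map = mean(out_ap), curves = curves)
}
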