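as_box_matrix <- function(x, arg = "box") {
  if (is.data.frame(x)) {
    need <- c("x1", "y1", "x2", "y2")
    if (!all(need %in% names(x))) {
      abort(sprintf("%s must have columns x1, y1, x2, y2", arg))
    }
    x <- as.matrix(x[, need])
  } else if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 4L) abort(sprintf("%s must be a length-4 box", arg))
    x <- matrix(x, ncol = 4L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 4L) abort(sprintf("%s must have 4 columns", arg))
  }
  storage.mode(x) <- "double"
  unname(x)
}

#' Pairwise and elementwise intersection-over-union
#'
#' @param a,b Boxes as `(x1, y1, x2, y2)` rows (matrix, data frame with
#'   those columns, or a single length-4 vector).
#' @param pairwise If `TRUE` (default) `a` and `b` are matched row by row;
#'   otherwise the full `nrow(a) x nrow(b)` IoU matrix is returned.
#' @return Numeric vector (row-matched) or matrix of IoU values in
#'   `[0, 1]`.
#' @export
box_iou <- function(a, b, pairwise = TRUE) {
  a <- as_box_matrix(a, "a"); b <- as_box_matrix(b, "b")
  if (!pairwise) {
    out <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(nrow(b))) {
      out[, j] <- box_iou(a, matrix(b[j, ], nrow(a), 4, byrow = TRUE))
    }
    return(out)
  }
  stopifnot(nrow(a) == nrow(b))
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  union <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  ifelse(union > 0, inter / union, 0)
}

ciou_terms <- function(p, g) {
  iou <- box_iou(p, g)
  pcx <- (p[, 1] + p[, 3]) / 2; pcy <- (p[, 2] + p[, 4]) / 2
  gcx <- (g[, 1] + g[, 3]) / 2; gcy <- (g[, 2] + g[, 4]) / 2
  rho2 <- (pcx - gcx)^2 + (pcy - gcy)^2
  cw <- pmax(p[, 3], g[, 3]) - pmin(p[, 1], g[, 1])
  ch <- pmax(p[, 4], g[, 4]) - pmin(p[, 2], g[, 2])
  c2 <- cw^2 + ch^2
  pw <- p[, 3] - p[, 1]; ph <- p[, 4] - p[, 2]
  gw <- g[, 3] - g[, 1]; gh <- g[, 4] - g[, 2]
  dth <- atan(gw / gh) - atan(pw / ph)
  v <- 4 / pi^2 * dth^2
  alpha <- ifelse(v > 0, v / ((1 - iou) + v), 0)
  list(iou = iou, rho2 = rho2, c2 = c2, v = v, alpha = alpha, dth = dth,
       pw = pw, ph = ph)
}

#' Complete-IoU bounding-box regression loss
#'
#' `1 - IoU + rho^2/c^2 + alpha * v`: the IoU deficit, plus the squared
#' centroid distance `rho^2` normalized by the squared diagonal `c^2` of the
#' smallest enclosing box, plus an aspect-ratio consistency term where
#' `v = (4/pi^2) (atan(w_gt/h_gt) - atan(w/h))^2` and
#' `alpha = v / ((1 - IoU) + v)`. Zero exactly when the boxes coincide.
#'
#' @param pred,truth Predicted and ground-truth boxes as `(x1, y1, x2, y2)`
#'   rows (see [box_iou()] for accepted shapes). Rows are matched.
#' @return Non-negative numeric vector, one loss per box pair.
#' @export
#' @examples
#' ciou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2))   # 0
#' ciou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3))   # 1 - 1/7 + 1/9
ciou_loss <- function(pred, truth) {
  p <- as_box_matrix(pred, "pred"); g <- as_box_matrix(truth, "truth")
  stopifnot(nrow(p) == nrow(g))
  if (any(p[, 3] <= p[, 1] | p[, 4] <= p[, 2]) ||
      any(g[, 3] <= g[, 1] | g[, 4] <= g[, 2])) {
    abort("degenerate (zero-area) box: need x2 > x1 and y2 > y1")
  }
  t <- ciou_terms(p, g)
  1 - t$iou + t$rho2 / t$c2 + t$alpha * t$v
}

# Analytic gradient of ciou_loss with respect to the predicted corners,
# with alpha treated as constant (the usual detached-alpha convention).
# Returns an n x 4 matrix. Verified against finite differences in the
# test-suite.
ciou_grad <- function(pred, truth) {
  p <- as_box_matrix(pred); g <- as_box_matrix(truth)
  n <- nrow(p)
  t <- ciou_terms(p, g)
  ap <- (p[, 3] - p[, 1]) * (p[, 4] - p[, 2])
  ag <- (g[, 3] - g[, 1]) * (g[, 4] - g[, 2])
  ix1 <- pmax(p[, 1], g[, 1]); iy1 <- pmax(p[, 2], g[, 2])
  ix2 <- pmin(p[, 3], g[, 3]); iy2 <- pmin(p[, 4], g[, 4])
  iw <- pmax(0, ix2 - ix1); ih <- pmax(0, iy2 - iy1)
  inter <- iw * ih
  uni <- ap + ag - inter
  overlap <- iw > 0 & ih > 0
  # d inter / d corner (sub-gradients at the boundary attribute to pred
  # whenever the pred corner is the active one)
  di <- matrix(0, n, 4)
  di[, 1] <- ifelse(overlap & p[, 1] >= g[, 1], -ih, 0)
  di[, 2] <- ifelse(overlap & p[, 2] >= g[, 2], -iw, 0)
  di[, 3] <- ifelse(overlap & p[, 3] <= g[, 3], ih, 0)
  di[, 4] <- ifelse(overlap & p[, 4] <= g[, 4], iw, 0)
  dap <- cbind(-(p[, 4] - p[, 2]), -(p[, 3] - p[, 1]),
               p[, 4] - p[, 2], p[, 3] - p[, 1])
  diou <- matrix(0, n, 4)
  for (j in 1:4) {
    duni <- dap[, j] - di[, j]
    diou[, j] <- ifelse(uni > 0, (di[, j] * uni - inter * duni) / uni^2, 0)
  }
  # centroid-distance term rho2 / c2
  pcx <- (p[, 1] + p[, 3]) / 2; pcy <- (p[, 2] + p[, 4]) / 2
  gcx <- (g[, 1] + g[, 3]) / 2; gcy <- (g[, 2] + g[, 4]) / 2
  cw <- pmax(p[, 3], g[, 3]) - pmin(p[, 1], g[, 1])
  ch <- pmax(p[, 4], g[, 4]) - pmin(p[, 2], g[, 2])
  drho <- cbind((pcx - gcx), (pcy - gcy), (pcx - gcx), (pcy - gcy))
  dc2 <- cbind(ifelse(p[, 1] <= g[, 1], -2 * cw, 0),
               ifelse(p[, 2] <= g[, 2], -2 * ch, 0),
               ifelse(p[, 3] >= g[, 3], 2 * cw, 0),
               ifelse(p[, 4] >= g[, 4], 2 * ch, 0))
  ddist <- (drho * t$c2 - t$rho2 * dc2) / t$c2^2
  # aspect term alpha * v, alpha detached
  pw <- t$pw; ph <- t$ph
  dv_dw <- -8 / pi^2 * t$dth * ph / (pw^2 + ph^2)
  dv_dh <- 8 / pi^2 * t$dth * pw / (pw^2 + ph^2)
  dasp <- t$alpha * cbind(-dv_dw, -dv_dh, dv_dw, dv_dh)
  unname(-diou + ddist + dasp)
}

#' Distribution focal loss
#'
#' Each box side is predicted as a discrete probability distribution over
#' integer bins; for a continuous target `y` bracketed by bins `y_i` and
#' `y_i + 1`, the loss `-( (y_{i+1} - y) log s_i + (y - y_i) log s_{i+1} )`
#' pulls probability mass onto the two bracketing bins, and is minimized
#' when the mass splits linearly (`s_i = y_{i+1} - y`,
#' `s_{i+1} = y - y_i`).
#'
#' @param bin_probs Probabilities over bins `0 .. reg_max-1`: a vector for
#'   one side, or a matrix with one row per side.
#' @param target Continuous target(s) in bin units, within
#'   `[0, reg_max - 1]`.
#' @param eps Probabilities are clamped to `[eps, 1]` before taking logs so
#'   saturated predictions stay finite.
#' @return Non-negative numeric vector of losses.
#' @export
#' @examples
#' dfl_loss(c(0, 0, 0.5, 0.5), 2.5)  # log 2 at the symmetric midpoint
dfl_loss <- function(bin_probs, target, eps = 1e-7) {
  if (is.null(dim(bin_probs))) bin_probs <- matrix(bin_probs, nrow = 1L)
  stopifnot(nrow(bin_probs) == length(target))
  nb <- ncol(bin_probs)
  if (any(target < 0 | target > nb - 1)) {
    abort(sprintf("target must lie within the bin range [0, %d]", nb - 1L))
  }
  if (any(bin_probs < -1e-9) || any(abs(rowSums(bin_probs) - 1) > 1e-6)) {
    abort("bin_probs rows must be non-negative and sum to 1")
  }
  lo <- pmin(floor(target), nb - 2)
  hi <- lo + 1
  wl <- hi - target
  wr <- target - lo
  idx <- cbind(seq_along(target), lo + 1L)
  sl <- pmax(bin_probs[idx], eps)
  sr <- pmax(bin_probs[cbind(seq_along(target), hi + 1L)], eps)
  -(wl * log(sl) + wr * log(sr))
}

#' Binary cross-entropy classification loss
#'
#' Mean over all label/prediction pairs of
#' `-(y log p + (1 - y) log(1 - p))`, with predictions clamped away from 0
#' and 1 before the logs.
#'
#' @param labels Targets in `[0, 1]` (vector or matrix).
#' @param probs Predicted probabilities, same shape as `labels`.
#' @param eps Clamping width.
#' @return A single non-negative number.
#' @export
#' @examples
#' bce_loss(c(1, 0), c(0.9, 0.2))
bce_loss <- function(labels, probs, eps = 1e-7) {
  if (length(labels) != length(probs)) abort("labels and probs must match in shape")
  if (length(labels) < 1L) abort("need at least one label")
  if (any(labels < 0 | labels > 1)) abort("labels must lie in [0, 1]")
  if (any(probs < 0 | probs > 1)) abort("probs must lie in [0, 1]")
  p <- pmin(pmax(probs, eps), 1 - eps)
  mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Grid anchor points of the three detection scales
#'
#' Anchor-free decoding predicts box offsets from the centers of the
#' feature-map cells. Cells are laid out at strides 8, 16 and 32 with a
#' half-cell offset.
#'
#' @param input_size Network input size in pixels (multiple of 32).
#' @param strides Detection strides.
#' @return A tibble with one row per anchor: `x`, `y` (pixel center),
#'   `stride`, `scale` (1-based scale index), `row`, `col` (0-based cell).
#' @export
anchor_points <- function(input_size, strides = c(8L, 16L, 32L)) {
  purrr::map_dfr(seq_along(strides), function(s) {
    st <- strides[s]
    n <- input_size %/% st
    g <- expand.grid(col = seq_len(n) - 1L, row = seq_len(n) - 1L)
    tibble::tibble(x = (g$col + 0.5) * st, y = (g$row + 0.5) * st,
                   stride = st, scale = s, row = g$row, col = g$col)
  })
}

#' Task-aligned assignment of ground truths to anchors
#'
#' For each ground-truth box, anchors whose centers fall inside the box are
#' ranked by the task-alignment metric `score^alpha * IoU^beta` (predicted
#' class score and predicted-box IoU with the ground truth) and the top `k`
#' become positives. An anchor claimed by several ground truths keeps the
#' one with the highest alignment.
#'
#' @param truths Ground-truth tibble with pixel columns `x1, y1, x2, y2`
#'   and `class_id` (0-based).
#' @param anchors Anchor tibble from [anchor_points()].
#' @param class_scores Matrix `n_anchors x n_classes` of predicted class
#'   probabilities.
#' @param pred_boxes Matrix `n_anchors x 4` of decoded predicted boxes
#'   (pixels).
#' @param topk Positives kept per ground truth.
#' @param alpha,beta Exponents of the alignment metric.
#' @return A list: `gt_index` (per anchor, `NA` or the row of the assigned
#'   truth), `positive_mask`, `normalizer` (number of positives, floored at
#'   one), `alignment` (per-anchor metric of the kept assignment).
#' @export
assign_targets <- function(truths, anchors, class_scores, pred_boxes,
                           topk = 10L, alpha = 0.5, beta = 6) {
  na <- nrow(anchors)
  gt_index <- rep(NA_integer_, na)
  best_align <- rep(-Inf, na)
  if (!is.null(truths) && nrow(truths) > 0) {
    pb <- as_box_matrix(pred_boxes, "pred_boxes")
    for (g in seq_len(nrow(truths))) {
      tb <- truths[g, ]
      inside <- anchors$x > tb$x1 & anchors$x < tb$x2 &
        anchors$y > tb$y1 & anchors$y < tb$y2
      cand <- which(inside)
      if (length(cand) == 0L) next
      iou <- box_iou(pb[cand, , drop = FALSE],
                     matrix(unlist(tb[c("x1", "y1", "x2", "y2")]),
                            length(cand), 4, byrow = TRUE))
      sc <- class_scores[cand, tb$class_id + 1L]
      align <- pmax(sc, 0)^alpha * pmax(iou, 0)^beta
      keep <- cand[order(align, decreasing = TRUE)[seq_len(min(topk, length(cand)))]]
      keep_align <- sort(align, decreasing = TRUE)[seq_len(length(keep))]
      better <- keep_align > best_align[keep]
      gt_index[keep[better]] <- g
      best_align[keep[better]] <- keep_align[better]
    }
  }
  positive <- !is.na(gt_index)
  list(gt_index = gt_index, positive_mask = positive,
       normalizer = max(1L, sum(positive)),
       alignment = ifelse(positive, best_align, 0))
}

#' Combine loss components with the training weights
#'
#' The training objective is the weighted sum of the CIoU box loss, the BCE
#' classification loss and the distribution focal loss, with default
#' weights 7.5, 0.5 and 1.5.
#'
#' @param box,cls,dfl Scalar loss components.
#' @param weights Named numeric vector of weights.
#' @return A one-row tibble with the components and the weighted `total`.
#' @export
#' @examples
#' combine_losses(1, 1, 1)  # total 9.0
combine_losses <- function(box, cls, dfl,
                           weights = c(box = 7.5, cls = 0.5, dfl = 1.5)) {
  tibble::tibble(box = box, cls = cls, dfl = dfl,
                 total = weights[["box"]] * box + weights[["cls"]] * cls +
                   weights[["dfl"]] * dfl)
}
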