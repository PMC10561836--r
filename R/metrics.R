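#' Match detections to ground truths
#'
#' Greedy one-to-one matching: detections are visited in order of
#' descending confidence (ties broken by higher best-IoU, then input
#' order); each claims the unconsumed same-class truth of highest IoU at
#' or above the threshold, in the same image when an `image` column is
#' present. Unclaimed truths are false negatives.
#'
#' @param detections Tibble with `x1, y1, x2, y2`, `class_id`,
#'   `confidence` (and optionally `image`).
#' @param truths Tibble with `x1, y1, x2, y2`, `class_id` (and optionally
#'   `image`).
#' @param iou_threshold Minimum IoU for a match.
#' @return A list: `flags` (one row per detection: `confidence`,
#'   `class_id`, `tp`), `fn` (count of unmatched truths), `n_truth`.
#' @export
match_detections <- function(detections, truths, iou_threshold = 0.5) {
  nd <- nrow(detections)
  if (!"image" %in% names(detections)) detections$image <- 1L
  if (!"image" %in% names(truths)) truths$image <- 1L
  tp <- logical(nd)
  used <- logical(nrow(truths))
  best_iou <- numeric(nd)
  if (nd > 0 && nrow(truths) > 0) {
    tb <- as_box_matrix(truths[, c("x1", "y1", "x2", "y2")])
    db <- as_box_matrix(detections[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(nd)) {
      cand <- which(truths$class_id == detections$class_id[i] &
                      truths$image == detections$image[i])
      if (length(cand)) {
        ious <- box_iou(matrix(db[i, ], length(cand), 4, byrow = TRUE),
                        tb[cand, , drop = FALSE])
        best_iou[i] <- max(ious)
      }
    }
    ord <- order(-detections$confidence, -best_iou, seq_len(nd))
    for (i in ord) {
      cand <- which(!used & truths$class_id == detections$class_id[i] &
                      truths$image == detections$image[i])
      if (length(cand) == 0L) next
      ious <- box_iou(matrix(db[i, ], length(cand), 4, byrow = TRUE),
                      tb[cand, , drop = FALSE])
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        tp[i] <- TRUE
        used[cand[j]] <- TRUE
      }
    }
  }
  list(flags = tibble::tibble(confidence = detections$confidence,
                              class_id = detections$class_id, tp = tp),
       fn = nrow(truths) - sum(used), n_truth = nrow(truths))
}

#' Cumulative precision-recall curve
#'
#' Sweeps the confidence threshold down through the flagged detections and
#' accumulates precision and recall; recall is non-decreasing along the
#' curve.
#'
#' @param flags Tibble with `confidence` and logical `tp` (from
#'   [match_detections()]).
#' @param n_truth Number of ground truths.
#' @return Tibble with `confidence`, `recall`, `precision`, one row per
#'   detection in descending confidence.
#' @export
pr_curve <- function(flags, n_truth) {
  if (nrow(flags) == 0L) {
    return(tibble::tibble(confidence = numeric(), recall = numeric(),
                          precision = numeric()))
  }
  ord <- order(-flags$confidence)
  tp <- cumsum(flags$tp[ord])
  fp <- cumsum(!flags$tp[ord])
  tibble::tibble(confidence = flags$confidence[ord],
                 recall = if (n_truth > 0) tp / n_truth else rep(0, length(tp)),
                 precision = tp / (tp + fp))
}

#' Average precision (area under the P(R) curve)
#'
#' 101-point interpolation: precision is first made monotone by taking, at
#' each recall level, the maximum precision at any equal-or-higher recall
#' (the monotone envelope), then averaged over the recall grid
#' `0, 0.01, ..., 1`. A `"trapezoid"` rule over the envelope is available
#' as an independent cross-check.
#'
#' @param curve A [pr_curve()] tibble.
#' @param method `"interp101"` (default) or `"trapezoid"`.
#' @return A scalar in `[0, 1]`.
#' @export
average_precision <- function(curve, method = c("interp101", "trapezoid")) {
  method <- match.arg(method)
  if (nrow(curve) == 0L) return(0)
  n <- nrow(curve)
  # monotone envelope from the right: max precision at >= this recall
  p_env <- rev(cummax(rev(curve$precision)))
  if (method == "interp101") {
    # exact grid; the tiny slack keeps recall values that equal a grid
    # point (k/n_truth vs j/100) from being excluded by rounding
    grid <- (0:100) / 100
    idx <- findInterval(grid - 1e-9, curve$recall, left.open = TRUE) + 1L
    vals <- ifelse(idx <= n, p_env[pmin(idx, n)], 0)
    mean(vals)
  } else {
    r <- c(0, curve$recall)
    sum(diff(r) * p_env)
  }
}

#' Mean average precision over classes
#'
#' @param aps Numeric vector of per-class average precisions.
#' @return Their unweighted mean.
#' @export
map_multiclass <- function(aps) {
  if (length(aps) == 0L) abort("need at least one class AP")
  mean(aps)
}

#' Evaluate detections against ground truth
#'
#' Computes, per class: true/false positives and false negatives from
#' greedy IoU matching, precision and recall at a fixed reporting
#' confidence, and average precision over the full confidence sweep; plus
#' mAP@50 (the mean AP over classes). Classes with no ground truths are
#' excluded from the mean and reported with a message.
#'
#' @param detections,truths See [match_detections()]. All detections (down
#'   to the lowest confidence) should be supplied; the AP sweep needs
#'   them.
#' @param iou_threshold Matching IoU (0.5 for mAP@50).
#' @param conf_threshold Confidence at which the tabulated P and R are
#'   reported.
#' @return A `metrics_report`: `per_class` tibble, `mAP50`, thresholds,
#'   and the per-class PR curves. `tidy()` returns the per-class table,
#'   `glance()` the one-row summary, `autoplot()` the PR curves.
#' @export
evaluate_detections <- function(detections, truths, iou_threshold = 0.5,
                                conf_threshold = 0.25) {
  classes <- sort(unique(c(detections$class_id, truths$class_id)))
  rows <- list(); curves <- list()
  for (cl in classes) {
    d <- detections[detections$class_id == cl, , drop = FALSE]
    t <- truths[truths$class_id == cl, , drop = FALSE]
    m <- match_detections(d, t, iou_threshold)
    curve <- pr_curve(m$flags, m$n_truth)
    ap <- if (m$n_truth > 0) average_precision(curve) else NA_real_
    keep <- m$flags$confidence >= conf_threshold
    tp <- sum(m$flags$tp[keep]); fp <- sum(keep) - tp
    fn_at_conf <- m$n_truth - tp
    rows[[length(rows) + 1L]] <- tibble::tibble(
      class_id = cl, n_truth = m$n_truth, n_det = nrow(d),
      tp = tp, fp = fp, fn = fn_at_conf,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (m$n_truth > 0) tp / m$n_truth else NA_real_,
      ap = ap)
    curves[[as.character(cl)]] <- curve
  }
  per_class <- dplyr::bind_rows(rows)
  empty <- per_class$class_id[per_class$n_truth == 0]
  if (length(empty)) {
    rlang::inform(sprintf(
      "classes with no ground truths excluded from mAP: %s",
      paste(empty, collapse = ", ")))
  }
  scored <- per_class$ap[per_class$n_truth > 0]
  structure(list(per_class = per_class,
                 mAP50 = if (length(scored)) map_multiclass(scored) else NA_real_,
                 iou_threshold = iou_threshold,
                 conf_threshold = conf_threshold,
                 curves = curves),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> mAP@%d = %.4f (P/R at conf %.2f)\n",
              round(x$iou_threshold * 100), x$mAP50, x$conf_threshold))
  print(x$per_class)
  invisible(x)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(mAP50 = x$mAP50,
                 precision = mean(x$per_class$precision, na.rm = TRUE),
                 recall = mean(x$per_class$recall, na.rm = TRUE),
                 classes = nrow(x$per_class),
                 n_truth = sum(x$per_class$n_truth))
}

#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- dplyr::bind_rows(purrr::imap(object$curves, function(cv, cl) {
    if (nrow(cv)) dplyr::mutate(cv, class_id = cl) else NULL
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$class_id)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "Class",
                  title = sprintf("Precision-recall at IoU %.2f (mAP %.3f)",
                                  object$iou_threshold, object$mAP50))
}
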