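# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops and first-principles geometry only.

# plain-geometry CIoU oracle
oracle_ciou <- function(p, g) {
  iw <- max(0, min(p[3], g[3]) - max(p[1], g[1]))
  ih <- max(0, min(p[4], g[4]) - max(p[2], g[2]))
  inter <- iw * ih
  ap <- (p[3] - p[1]) * (p[4] - p[2])
  ag <- (g[3] - g[1]) * (g[4] - g[2])
  iou <- inter / (ap + ag - inter)
  pc <- c((p[1] + p[3]) / 2, (p[2] + p[4]) / 2)
  gc <- c((g[1] + g[3]) / 2, (g[2] + g[4]) / 2)
  rho2 <- sum((pc - gc)^2)
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  ch <- max(p[4], g[4]) - min(p[2], g[2])
  v <- 4 / pi^2 * (atan((g[3] - g[1]) / (g[4] - g[2])) -
                     atan((p[3] - p[1]) / (p[4] - p[2])))^2
  alpha <- if (v > 0) v / ((1 - iou) + v) else 0
  1 - iou + rho2 / (cw^2 + ch^2) + alpha * v
}

# O(n^2) exhaustive NMS oracle
oracle_nms <- function(d, iou_threshold) {
  d <- d[order(-d$confidence), ]
  kept <- integer()
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (j in kept) {
      if (d$class_id[i] != d$class_id[j]) next
      iw <- max(0, min(d$x2[i], d$x2[j]) - max(d$x1[i], d$x1[j]))
      ih <- max(0, min(d$y2[i], d$y2[j]) - max(d$y1[i], d$y1[j]))
      inter <- iw * ih
      un <- (d$x2[i] - d$x1[i]) * (d$y2[i] - d$y1[i]) +
        (d$x2[j] - d$x1[j]) * (d$y2[j] - d$y1[j]) - inter
      if (inter / un > iou_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  d[kept, ]
}

# independent 101-point AP oracle: for each grid recall, scan all curve
# points for the maximum precision at equal-or-higher recall
oracle_ap101 <- function(recall, precision) {
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, function(r) {
    at <- precision[recall >= r - 1e-12]
    if (length(at)) max(at) else 0
  }, 0)
  mean(vals)
}

# naive direct convolution (stride s, zero padding p) on a C x H x W array
oracle_conv <- function(x, w_arr, stride, pad) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  O <- dim(w_arr)[1]; k <- dim(w_arr)[3]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(O, Ho, Wo))
  for (o in seq_len(O)) for (yo in seq_len(Ho)) for (xo in seq_len(Wo)) {
    acc <- 0
    for (c in seq_len(C)) for (ky in seq_len(k)) for (kx in seq_len(k)) {
      yi <- (yo - 1) * stride + ky - pad
      xi <- (xo - 1) * stride + kx - pad
      if (yi >= 1 && yi <= H && xi >= 1 && xi <= W) {
        acc <- acc + x[c, yi, xi] * w_arr[o, c, ky, kx]
      }
    }
    out[o, yo, xo] <- acc
  }
  out
}

random_box_vec <- function(size = 100) {
  as.numeric(unlist(random_boxes(1, size)))
}

random_boxes <- function(n, size = 100, min_side = 2) {
  x1 <- runif(n, 0, size - min_side)
  y1 <- runif(n, 0, size - min_side)
  tibble::tibble(x1 = x1, y1 = y1,
                 x2 = x1 + runif(n, min_side, size / 3),
                 y2 = y1 + runif(n, min_side, size / 3))
}

# tiny but structurally complete topology (concat, sppf, upsample, 3-scale
# head) for fast engine tests at a 32-pixel input
tiny_topology <- function(num_classes = 2L, reg_max = 4L) {
  blocks <- dplyr::bind_rows(
    layer_spec(0, "conv", 3, 2, in_channels = 3, out_channels = 4),
    layer_spec(1, "conv", 3, 2, in_channels = 4, out_channels = 6),
    layer_spec(2, "conv", 1, 1, in_channels = 6, out_channels = 6),
    layer_spec(3, "maxpool", 2, 2),
    layer_spec(4, "conv", 1, 1, in_channels = 6, out_channels = 8),
    layer_spec(5, "conv", 3, 1, in_channels = 8, out_channels = 8),
    layer_spec(6, "concat", sources = c(4, 5)),
    layer_spec(7, "sppf", 5, 1, in_channels = 16, out_channels = 8,
               hidden_channels = 4),
    layer_spec(8, "maxpool", 2, 2),
    layer_spec(9, "conv", 3, 1, in_channels = 8, out_channels = 8),
    layer_spec(10, "maxpool", 2, 2),
    layer_spec(11, "conv", 1, 1, in_channels = 8, out_channels = 8),
    layer_spec(12, "upsample"),
    layer_spec(13, "concat", sources = c(12, 9)),
    layer_spec(14, "conv", 1, 1, in_channels = 16, out_channels = 8))
  simplifruit:::new_fruit_topology(
    blocks, detect_scales = c(7L, 9L, 11L), num_classes = num_classes,
    input_size = 32L, reg_max = reg_max, head_width = 8L)
}
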