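test_that("CIoU reproduces hand-derived geometry", {
  expect_equal(ciou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2)), 0)
  # equal squares offset by one: IoU 1/7, centroid distance 2, diagonal 18
  expect_equal(ciou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 - 1 / 7 + 1 / 9,
               tolerance = 1e-9)
  # disjoint unit squares: rho2 = 32, c2 = 50
  expect_equal(ciou_loss(c(0, 0, 1, 1), c(4, 4, 5, 5)), 1 + 32 / 50,
               tolerance = 1e-9)
})

test_that("CIoU agrees with an independent geometric oracle", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_box_vec()
    g <- random_box_vec()
    expect_equal(ciou_loss(p, g), oracle_ciou(p, g), tolerance = 1e-10)
  }
})

test_that("CIoU is zero iff identical, positive otherwise, and invariant to joint shifts and scalings", {
  set.seed(12)
  for (i in 1:20) {
    p <- random_box_vec(); g <- random_box_vec()
    l <- ciou_loss(p, g)
    if (!isTRUE(all.equal(p, g))) expect_gt(l, 0)
    shift <- runif(1, -50, 50)
    expect_equal(ciou_loss(p + shift, g + shift), l, tolerance = 1e-9)
    k <- runif(1, 0.1, 10)
    expect_equal(ciou_loss(p * k, g * k), l, tolerance = 1e-9)
  }
  expect_error(ciou_loss(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("the analytic CIoU gradient matches finite differences", {
  # the training gradient freezes alpha (detached-alpha convention), so the
  # finite-difference oracle differentiates the loss with alpha held at its
  # base value, computed here from first-principles geometry
  detached <- function(p, g, alpha0) {
    iw <- max(0, min(p[3], g[3]) - max(p[1], g[1]))
    ih <- max(0, min(p[4], g[4]) - max(p[2], g[2]))
    inter <- iw * ih
    iou <- inter / ((p[3] - p[1]) * (p[4] - p[2]) +
                      (g[3] - g[1]) * (g[4] - g[2]) - inter)
    rho2 <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
      ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
    c2 <- (max(p[3], g[3]) - min(p[1], g[1]))^2 +
      (max(p[4], g[4]) - min(p[2], g[2]))^2
    v <- 4 / pi^2 * (atan((g[3] - g[1]) / (g[4] - g[2])) -
                       atan((p[3] - p[1]) / (p[4] - p[2])))^2
    1 - iou + rho2 / c2 + alpha0 * v
  }
  set.seed(13)
  for (i in 1:20) {
    p <- random_box_vec(); g <- random_box_vec()
    an <- simplifruit:::ciou_grad(p, g)[1, ]
    base <- oracle_ciou(p, g)
    l_plain <- detached(p, g, 0)
    v0 <- 4 / pi^2 * (atan((g[3] - g[1]) / (g[4] - g[2])) -
                        atan((p[3] - p[1]) / (p[4] - p[2])))^2
    alpha0 <- if (v0 > 0) (base - l_plain) / v0 else 0
    eps <- 1e-6
    for (j in 1:4) {
      ph <- p; ph[j] <- ph[j] + eps
      pl <- p; pl[j] <- pl[j] - eps
      fd <- (detached(ph, g, alpha0) - detached(pl, g, alpha0)) / (2 * eps)
      expect_lt(abs(an[j] - fd), 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("DFL reproduces its closed-form values", {
  one_hot <- c(0, 0, 1, 0, 0, 0)
  expect_equal(dfl_loss(one_hot, 2), 0, tolerance = 1e-9)
  expect_equal(dfl_loss(c(0, 0, 0.5, 0.5, 0, 0), 2.5), log(2),
               tolerance = 1e-9)
  probs <- c(0, 0, 0.4, 0.6, 0, 0)
  expect_equal(dfl_loss(probs, 2.6), -(0.4 * log(0.4) + 0.6 * log(0.6)),
               tolerance = 1e-9)
})

test_that("DFL respects the entropy lower bound of the bracketing weights", {
  set.seed(14)
  for (i in 1:30) {
    reg_max <- 8L
    y <- runif(1, 0, reg_max - 1)
    lo <- min(floor(y), reg_max - 2); wl <- lo + 1 - y; wr <- y - lo
    bound <- -(ifelse(wl > 0, wl * log(wl), 0) +
                 ifelse(wr > 0, wr * log(wr), 0))
    probs <- runif(reg_max); probs <- probs / sum(probs)
    expect_gte(dfl_loss(probs, y), bound - 1e-9)
    exact <- rep(0, reg_max); exact[lo + 1] <- wl; exact[lo + 2] <- wr
    if (wl > 0 && wr > 0) {
      expect_equal(dfl_loss(exact, y), bound, tolerance = 1e-9)
    }
  }
})

test_that("DFL clamps vanished probabilities and validates the target", {
  expect_true(is.finite(dfl_loss(c(1, 0, 0, 0), 2.5)))
  expect_error(dfl_loss(c(0.5, 0.5), 3), "bin range")
  expect_error(dfl_loss(c(0.9, 0.3), 0.5), "sum to 1")
})

test_that("BCE matches hand evaluation and is label-symmetric", {
  expect_equal(bce_loss(1, 1 - 1e-9), 0, tolerance = 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.2)),
               (-log(0.9) - log(0.8)) / 2, tolerance = 1e-9)
  set.seed(15)
  y <- round(runif(20)); p <- runif(20, 0.01, 0.99)
  expect_equal(bce_loss(y, p), bce_loss(1 - y, 1 - p), tolerance = 1e-12)
  expect_error(bce_loss(1, 1.2), "\\[0, 1\\]")
})

test_that("task-aligned assignment keeps top-k anchors inside their boxes", {
  anchors <- anchor_points(160)
  n <- nrow(anchors)
  set.seed(16)
  scores <- matrix(runif(n * 2, 0.1, 0.9), n, 2)
  jitter <- matrix(runif(n * 4, -2, 2), n, 4)
  pred <- cbind(anchors$x - 12, anchors$y - 12, anchors$x + 12,
                anchors$y + 12) + jitter
  big <- tibble::tibble(class_id = 0L, x1 = 20, y1 = 20, x2 = 140, y2 = 140)
  asn <- assign_targets(big, anchors, scores, pred, topk = 10L)
  expect_identical(sum(asn$positive_mask), 10L)
  expect_identical(asn$normalizer, 10L)
  inside <- anchors$x[asn$positive_mask] > 20 &
    anchors$x[asn$positive_mask] < 140 &
    anchors$y[asn$positive_mask] > 20 & anchors$y[asn$positive_mask] < 140
  expect_true(all(inside))

  none <- assign_targets(big[0, ], anchors, scores, pred)
  expect_false(any(none$positive_mask))
  expect_identical(none$normalizer, 1L)
})

test_that("disjoint truths get disjoint anchor sets, each inside its own box", {
  anchors <- anchor_points(160)
  n <- nrow(anchors)
  set.seed(17)
  scores <- matrix(runif(n * 2, 0.1, 0.9), n, 2)
  pred <- cbind(anchors$x - 10, anchors$y - 10, anchors$x + 10,
                anchors$y + 10)
  truths <- tibble::tibble(class_id = c(0L, 1L),
                           x1 = c(8, 96), y1 = c(8, 96),
                           x2 = c(64, 152), y2 = c(64, 152))
  asn <- assign_targets(truths, anchors, scores, pred)
  pos <- which(asn$positive_mask)
  for (a in pos) {
    g <- asn$gt_index[a]
    # brute-force inside-box predicate
    expect_true(anchors$x[a] > truths$x1[g] && anchors$x[a] < truths$x2[g] &&
                  anchors$y[a] > truths$y1[g] && anchors$y[a] < truths$y2[g])
  }
  sets <- split(pos, asn$gt_index[pos])
  expect_length(intersect(sets[["1"]], sets[["2"]]), 0)
})

test_that("loss components combine with the 7.5/0.5/1.5 weights", {
  expect_equal(combine_losses(1, 1, 1)$total, 9.5)
  set.seed(18)
  for (i in 1:10) {
    v <- runif(3)
    cl <- combine_losses(v[1], v[2], v[3])
    expect_equal(cl$total, 7.5 * v[1] + 0.5 * v[2] + 1.5 * v[3])
  }
})
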