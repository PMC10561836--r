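#' Training configuration
#'
#' Defaults are the published training recipe: 640x640x3 input, batch 9,
#' 100 epochs from scratch, SGD momentum 0.937, weight decay 0.0005, NMS
#' IoU 0.7, loss weights 7.5 (box) / 0.5 (cls) / 1.5 (DFL), and the
#' [augment_config()] mosaic/HSV/scale/translate recipe. The learning rate
#' (0.01 with linear decay and a short warmup) follows the reference
#' framework's default; the recipe does not state one.
#'
#' @param input_size Square network input (multiple of 32).
#' @param batch Batch size.
#' @param epochs Passes over the training set.
#' @param lr0,lrf Initial learning rate and final fraction of it.
#' @param warmup_iters Linear warmup iterations.
#' @param momentum,weight_decay SGD hyperparameters.
#' @param nms_iou IoU threshold of non-maximum suppression.
#' @param conf_threshold Default inference confidence threshold.
#' @param loss_weights Named weights of the box/cls/dfl components.
#' @param augment An [augment_config()].
#' @param use_augment Apply the augmentation pipeline during training
#'   (mosaic, HSV, scale/translate). Disable to fit fixed images exactly.
#' @param seed Seed for initialization, shuffling and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(input_size = 640L, batch = 9L, epochs = 100L,
                         lr0 = 0.01, lrf = 0.01, warmup_iters = 20L,
                         momentum = 0.937, weight_decay = 5e-4,
                         nms_iou = 0.7, conf_threshold = 0.25,
                         loss_weights = c(box = 7.5, cls = 0.5, dfl = 1.5),
                         augment = augment_config(size = input_size),
                         use_augment = TRUE, seed = 0L) {
  stopifnot(batch >= 1, epochs >= 1, nms_iou > 0, nms_iou < 1,
            input_size %% 32 == 0)
  structure(list(input_size = as.integer(input_size),
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 lr0 = lr0, lrf = lrf, warmup_iters = as.integer(warmup_iters),
                 momentum = momentum, weight_decay = weight_decay,
                 nms_iou = nms_iou, conf_threshold = conf_threshold,
                 loss_weights = loss_weights, augment = augment,
                 use_augment = use_augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Expected offset of a distribution-focal bin distribution
#'
#' Decoding inverts the binned box representation: each side's offset is
#' the expectation `sum_j j * softmax(z)_j` over the bin logits.
#'
#' @param logits Bin logits: a vector, or a `reg_max x n` matrix (one
#'   column per prediction).
#' @return Numeric vector of expected offsets in bin (cell) units.
#' @export
#' @examples
#' dfl_expectation(rep(0, 16))   # 7.5, the mean of 0..15
dfl_expectation <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, ncol = 1L)
  p <- col_softmax(logits)
  as.vector(crossprod(p, seq_len(nrow(logits)) - 1))
}

col_softmax <- function(m) {
  mx <- apply(m, 2, max)
  e <- exp(sweep(m, 2, mx))
  sweep(e, 2, colSums(e), `/`)
}

#' Encode a box-side distance as a two-bin focal distribution
#'
#' The exact encoding places mass `ceil(d) - d` on the lower bracketing
#' bin and `d - floor(d)` on the upper one; [dfl_expectation()] of its log
#' recovers the distance.
#'
#' @param distance Distances in cell units, clipped to
#'   `[0, reg_max - 1.01]`.
#' @param reg_max Number of bins.
#' @return A `reg_max x length(distance)` matrix of probabilities.
#' @export
encode_dfl <- function(distance, reg_max = 16L) {
  d <- pmin(pmax(distance, 0), reg_max - 1 - 0.01)
  lo <- floor(d)
  out <- matrix(0, reg_max, length(d))
  out[cbind(lo + 1L, seq_along(d))] <- 1 - (d - lo)
  out[cbind(lo + 2L, seq_along(d))] <- d - lo
  out
}

# anchors of one scale, in cell units, matching the engine's spatial layout
scale_anchor_centers <- function(n_cells) {
  j <- seq_len(n_cells * n_cells) - 1L
  list(x = (j %% n_cells) + 0.5, y = (j %/% n_cells) + 0.5)
}

# decode one image's raw head outputs into boxes (input pixels) and class
# probabilities; returns per-scale pieces plus flat concatenations
decode_raw <- function(box_outs, cls_outs, strides, reg_max) {
  pieces <- vector("list", length(strides))
  for (s in seq_along(strides)) {
    bo <- box_outs[[s]]
    hw <- ncol(bo)
    nc_cells <- as.integer(sqrt(hw))
    ac <- scale_anchor_centers(nc_cells)
    dist <- matrix(0, 4L, hw)
    probs <- vector("list", 4L)
    for (side in 1:4) {
      z <- bo[((side - 1L) * reg_max + 1L):(side * reg_max), , drop = FALSE]
      p <- col_softmax(z)
      probs[[side]] <- p
      dist[side, ] <- as.vector(crossprod(p, seq_len(reg_max) - 1))
    }
    st <- strides[s]
    boxes <- cbind(x1 = (ac$x - dist[1, ]) * st,
                   y1 = (ac$y - dist[2, ]) * st,
                   x2 = (ac$x + dist[3, ]) * st,
                   y2 = (ac$y + dist[4, ]) * st)
    pieces[[s]] <- list(boxes = boxes, scores = t(sigmoid(cls_outs[[s]])),
                        dist = dist, probs = probs, n = hw,
                        stride = st, cells = nc_cells,
                        acx = ac$x, acy = ac$y)
  }
  list(pieces = pieces,
       boxes = do.call(rbind, lapply(pieces, `[[`, "boxes")),
       scores = do.call(rbind, lapply(pieces, `[[`, "scores")))
}

anchors_from_pieces <- function(pieces) {
  dplyr::bind_rows(lapply(seq_along(pieces), function(s) {
    p <- pieces[[s]]
    tibble::tibble(x = p$acx * p$stride, y = p$acy * p$stride,
                   stride = p$stride, scale = s)
  }))
}

# loss + gradients w.r.t. the raw head outputs for one image.
# Returns components (sums, not yet normalized) plus per-scale gradient
# matrices and the positive count.
image_loss_grads <- function(decoded, truths_px, reg_max, weights) {
  pieces <- decoded$pieces
  anchors <- anchors_from_pieces(pieces)
  asn <- assign_targets(truths_px, anchors, decoded$scores, decoded$boxes)
  npos <- sum(asn$positive_mask)
  nc <- ncol(decoded$scores)
  gbox <- lapply(pieces, function(p) matrix(0, 4L * reg_max, p$n))
  gcls <- lapply(pieces, function(p) matrix(0, nc, p$n))
  # classification: BCE-with-logits over every anchor/class entry
  Y <- matrix(0, nrow(decoded$scores), nc)
  if (npos > 0) {
    pos <- which(asn$positive_mask)
    Y[cbind(pos, truths_px$class_id[asn$gt_index[pos]] + 1L)] <- 1
  }
  P <- pmin(pmax(decoded$scores, 1e-7), 1 - 1e-7)
  cls_sum <- -sum(Y * log(P) + (1 - Y) * log(1 - P))
  gcls_flat <- decoded$scores - Y
  offs <- c(0L, cumsum(vapply(pieces, `[[`, 0L, "n")))
  for (s in seq_along(pieces)) {
    gcls[[s]] <- t(gcls_flat[(offs[s] + 1L):offs[s + 1L], , drop = FALSE])
  }
  box_sum <- 0; dfl_sum <- 0
  if (npos > 0) {
    pos <- which(asn$positive_mask)
    gt <- truths_px[asn$gt_index[pos], , drop = FALSE]
    pb <- decoded$boxes[pos, , drop = FALSE]
    box_sum <- sum(ciou_loss(pb, gt[, c("x1", "y1", "x2", "y2")]))
    gcorners <- ciou_grad(pb, gt[, c("x1", "y1", "x2", "y2")])
    for (k in seq_along(pos)) {
      a <- pos[k]
      s <- findInterval(a, offs, left.open = TRUE)
      j <- a - offs[s]
      p <- pieces[[s]]
      st <- p$stride
      tgt_dist <- c(p$acx[j] - gt$x1[k] / st, p$acy[j] - gt$y1[k] / st,
                    gt$x2[k] / st - p$acx[j], gt$y2[k] / st - p$acy[j])
      tgt_dist <- pmin(pmax(tgt_dist, 0), reg_max - 1 - 0.01)
      # chain d(box loss)/d(corner) through corner = stride * (ac -/+ dist)
      ddist <- c(-st * gcorners[k, 1], -st * gcorners[k, 2],
                 st * gcorners[k, 3], st * gcorners[k, 4])
      for (side in 1:4) {
        rows <- ((side - 1L) * reg_max + 1L):(side * reg_max)
        pj <- pieces[[s]]$probs[[side]][, j]
        sj <- pieces[[s]]$dist[side, j]
        w <- encode_dfl(tgt_dist[side], reg_max)[, 1]
        dfl_sum <- dfl_sum - sum(w * log(pmax(pj, 1e-7))) / 4
        gbox[[s]][rows, j] <- gbox[[s]][rows, j] +
          weights[["box"]] * ddist[side] * pj * (seq_len(reg_max) - 1 - sj) +
          weights[["dfl"]] * (pj - w) / 4
      }
    }
  }
  for (s in seq_along(pieces)) gcls[[s]] <- weights[["cls"]] * gcls[[s]]
  list(box = box_sum, cls = cls_sum, dfl = dfl_sum, npos = npos,
       gbox = gbox, gcls = gcls)
}

prepare_batch_mats <- function(images, size) {
  mats <- lapply(images, image_to_mat)
  attr(mats, "height") <- as.integer(size)
  attr(mats, "width") <- as.integer(size)
  mats
}

#' Train the simplified detector
#'
#' Full from-scratch training: letterboxed (optionally mosaic/HSV/affine
#' augmented) batches are pushed through the network, targets are assigned
#' to anchors task-aligned, and the weighted CIoU + DFL + BCE objective is
#' backpropagated with SGD. All randomness flows from `config$seed`, so a
#' run is reproducible.
#'
#' @param data A list of samples (each `list(image, labels)`), or a path
#'   to a dataset manifest ([generate_dataset()]).
#' @param num_classes Number of classes.
#' @param config A [train_config()].
#' @param verbose Print a line every few iterations.
#' @return A `fruit_detector`: topology, trained parameters, per-iteration
#'   loss log (`tidy()`), and the config. `autoplot()` draws the loss
#'   curves.
#' @export
train_detector <- function(data, num_classes = 3L, config = train_config(),
                           verbose = FALSE) {
  if (is.character(data)) data <- read_dataset(data)
  if (length(data) == 0L) abort("empty training set")
  topology <- build_simplified(num_classes, config$input_size)
  plan <- compile_plan(topology)
  params <- init_params(plan, seed = config$seed)
  velocity <- sgd_init(params)
  set.seed(config$seed + 1L)
  size <- config$input_size
  fixed <- lapply(data, function(sm) letterbox(sm$image, sm$labels, size))
  fixed_mats <- prepare_batch_mats(lapply(fixed, `[[`, "image"), size)
  n <- length(data)
  batch <- min(config$batch, n)
  iters_per_epoch <- max(1L, n %/% batch)
  total_iters <- config$epochs * iters_per_epoch
  log <- vector("list", total_iters)
  it <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    for (bi in seq_len(iters_per_epoch)) {
      it <- it + 1L
      idx <- perm[((bi - 1L) * batch + 1L):min(bi * batch, n)]
      if (config$use_augment) {
        batch_samples <- lapply(idx, function(i) {
          sm <- data[[i]]
          if (runif(1) < config$augment$mosaic_prob) {
            others <- sample.int(n, 3L, replace = n < 4L)
            mcfg <- config$augment
            sm <- mosaic_augment(lapply(c(i, others), function(j) data[[j]]),
                                 mcfg)
          }
          sm <- scale_translate(list(
            image = resize_image_cpp(sm$image, size, size),
            labels = sm$labels), config$augment)
          sm$image <- hsv_jitter(sm$image, config$augment)
          sm
        })
        mats <- prepare_batch_mats(lapply(batch_samples, `[[`, "image"), size)
        truths <- lapply(batch_samples, function(sm)
          labels_to_boxes(sm$labels, size, size))
      } else {
        mats <- fixed_mats[idx]
        attr(mats, "height") <- size; attr(mats, "width") <- size
        truths <- lapply(fixed[idx], function(lb)
          labels_to_boxes(lb$labels, size, size))
      }
      lr <- lr_at(it, total_iters, config)
      fw <- forward_net(plan, params, mats, train = TRUE)
      params <- fw$params  # running BN stats updated
      per_img <- vector("list", length(mats))
      for (m in seq_along(mats)) {
        box_outs <- lapply(plan$head, function(h) fw$acts[[h$box]]$out[[m]])
        cls_outs <- lapply(plan$head, function(h) fw$acts[[h$cls]]$out[[m]])
        decoded <- decode_raw(box_outs, cls_outs, plan$strides,
                              topology$reg_max)
        per_img[[m]] <- image_loss_grads(decoded, truths[[m]],
                                         topology$reg_max,
                                         config$loss_weights)
      }
      norm <- max(1L, sum(vapply(per_img, `[[`, 0L, "npos")))
      seed_grads <- list()
      for (s in seq_along(plan$head)) {
        seed_grads[[length(seed_grads) + 1L]] <- list(
          node = plan$head[[s]]$box,
          grad = lapply(per_img, function(pi) pi$gbox[[s]] / norm))
        seed_grads[[length(seed_grads) + 1L]] <- list(
          node = plan$head[[s]]$cls,
          grad = lapply(per_img, function(pi) pi$gcls[[s]] / norm))
      }
      comp <- combine_losses(
        box = sum(vapply(per_img, `[[`, 0, "box")) / norm,
        cls = sum(vapply(per_img, `[[`, 0, "cls")) / norm,
        dfl = sum(vapply(per_img, `[[`, 0, "dfl")) / norm,
        weights = config$loss_weights)
      if (!is.finite(comp$total)) {
        abort(sprintf(
          "non-finite loss at iteration %d (box=%.3g cls=%.3g dfl=%.3g); training diverged",
          it, comp$box, comp$cls, comp$dfl))
      }
      pgrads <- backward_net(plan, params, fw$acts, seed_grads)
      upd <- sgd_step(params, pgrads, velocity, lr,
                      momentum = config$momentum,
                      weight_decay = config$weight_decay)
      params <- upd$params; velocity <- upd$velocity
      log[[it]] <- dplyr::mutate(comp, epoch = epoch, iter = it, lr = lr,
                                 npos = norm)
      if (verbose && (it %% 10L == 0L || it == 1L)) {
        cat(sprintf("iter %4d/%d  lr %.4f  box %.3f cls %.3f dfl %.3f total %.3f (n+ %d)\n",
                    it, total_iters, lr, comp$box, comp$cls, comp$dfl,
                    comp$total, norm))
      }
    }
  }
  structure(list(topology = topology, plan = plan, params = params,
                 log = dplyr::bind_rows(log), config = config,
                 num_classes = num_classes),
            class = "fruit_detector")
}

lr_at <- function(it, total, config) {
  warm <- min(config$warmup_iters, max(1L, total %/% 10L))
  if (it <= warm) return(config$lr0 * it / warm)
  frac <- (it - warm) / max(1L, total - warm)
  config$lr0 * (1 - frac * (1 - config$lrf))
}

#' @export
print.fruit_detector <- function(x, ...) {
  cat(sprintf("<fruit_detector> %d classes, input %d, %s parameters\n",
              x$num_classes, x$config$input_size,
              format(count_params(x$topology), big.mark = ",")))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("trained %d iterations; final loss %.3f (box %.3f, cls %.3f, dfl %.3f)\n",
                nrow(x$log), last$total, last$box, last$cls, last$dfl))
  }
  invisible(x)
}

#' @method tidy fruit_detector
#' @export
tidy.fruit_detector <- function(x, ...) {
  x$log[, c("epoch", "iter", "box", "cls", "dfl", "total", "lr", "npos")]
}

#' @method glance fruit_detector
#' @export
glance.fruit_detector <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(iterations = nrow(x$log), final_loss = last$total,
                 box = last$box, cls = last$cls, dfl = last$dfl,
                 params = count_params(x$topology))
}

#' @method autoplot fruit_detector
#' @export
autoplot.fruit_detector <- function(object, ...) {
  df <- tidyr_longer(tidy(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = "Loss",
                  title = "Training loss components")
}

# minimal long-format pivot (components only) to avoid a tidyr dependency
tidyr_longer <- function(log) {
  dplyr::bind_rows(lapply(c("box", "cls", "dfl", "total"), function(cmp) {
    tibble::tibble(iter = log$iter, component = cmp, value = log[[cmp]])
  }))
}

#' Export the per-epoch loss log as CSV
#'
#' @param model A `fruit_detector`.
#' @param path CSV path; columns `epoch, box, cls, dfl, total` (epoch
#'   means).
#' @return `path`, invisibly.
#' @export
write_loss_log <- function(model, path) {
  log <- tidy(model)
  by_epoch <- dplyr::summarise(
    dplyr::group_by(log, .data$epoch),
    box = mean(.data$box), cls = mean(.data$cls), dfl = mean(.data$dfl),
    total = mean(.data$total), .groups = "drop")
  utils::write.csv(by_epoch, path, row.names = FALSE)
  invisible(path)
}

#' Greedy non-maximum suppression
#'
#' Per class, keeps detections in descending confidence, suppressing any
#' remaining same-class box whose IoU with a kept box exceeds the
#' threshold.
#'
#' @param detections Tibble with `x1, y1, x2, y2`, `class_id`,
#'   `confidence`.
#' @param iou_threshold Suppression IoU.
#' @param conf_threshold Minimum confidence kept.
#' @return The kept subset, sorted by descending confidence.
#' @export
nms <- function(detections, iou_threshold = 0.7, conf_threshold = 0) {
  d <- detections[detections$confidence >= conf_threshold, , drop = FALSE]
  if (nrow(d) == 0L) return(d)
  d <- d[order(-d$confidence), , drop = FALSE]
  keep <- logical(nrow(d))
  b <- as_box_matrix(d[, c("x1", "y1", "x2", "y2")])
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    later <- which(alive & seq_len(nrow(d)) > i & d$class_id == d$class_id[i])
    if (length(later)) {
      ious <- box_iou(matrix(b[i, ], length(later), 4, byrow = TRUE),
                      b[later, , drop = FALSE])
      alive[later[ious > iou_threshold]] <- FALSE
    }
  }
  d[keep, , drop = FALSE]
}

#' Detect fruit in one image
#'
#' Letterboxes the image to the network input, runs the forward pass,
#' decodes the binned box offsets and class probabilities, applies
#' per-class NMS, and maps boxes back to original-image pixels (clipped to
#' the image bounds).
#'
#' @param model A trained `fruit_detector`.
#' @param image `H x W x 3` array, or a path to a PNG.
#' @param conf_threshold Minimum confidence reported.
#' @param iou_threshold NMS IoU (default: the model's config).
#' @return A detection tibble (`x1, y1, x2, y2, class_id, confidence`)
#'   with a [speed_report()] attached as attribute `"speed"`.
#' @export
predict_image <- function(model, image,
                          conf_threshold = model$config$conf_threshold,
                          iou_threshold = model$config$nms_iou) {
  if (is.character(image)) image <- read_image(image)
  t0 <- proc.time()[["elapsed"]]
  lb <- letterbox(image, target = model$config$input_size)
  mats <- prepare_batch_mats(list(lb$image), model$config$input_size)
  fw <- forward_net(model$plan, model$params, mats, train = FALSE,
                    keep_cache = FALSE)
  box_outs <- lapply(model$plan$head, function(h) fw$acts[[h$box]]$out[[1]])
  cls_outs <- lapply(model$plan$head, function(h) fw$acts[[h$cls]]$out[[1]])
  decoded <- decode_raw(box_outs, cls_outs, model$plan$strides,
                        model$topology$reg_max)
  conf <- apply(decoded$scores, 1, max)
  cls <- max.col(decoded$scores, ties.method = "first") - 1L
  keep <- which(conf >= conf_threshold)
  d <- tibble::tibble(x1 = decoded$boxes[keep, 1], y1 = decoded$boxes[keep, 2],
                      x2 = decoded$boxes[keep, 3], y2 = decoded$boxes[keep, 4],
                      class_id = cls[keep], confidence = conf[keep])
  d <- d[d$x2 > d$x1 & d$y2 > d$y1, , drop = FALSE]
  d <- nms(d, iou_threshold)
  d <- unletterbox(d, lb$meta)
  elapsed <- proc.time()[["elapsed"]] - t0
  attr(d, "speed") <- speed_report(1L, max(elapsed, 1e-9))
  d
}

#' Evaluate a detector on a set of samples
#'
#' Runs [predict_image()] over every sample at a low sweep threshold and
#' scores the pooled detections with [evaluate_detections()].
#'
#' @param model A trained `fruit_detector`.
#' @param samples List of samples (`image`, normalized `labels`).
#' @param iou_threshold Matching IoU (0.5 for mAP@50).
#' @param conf_threshold Sweep floor for the PR curve.
#' @param report_conf Confidence at which tabulated P/R are reported.
#' @return A `metrics_report`.
#' @export
evaluate_detector <- function(model, samples, iou_threshold = 0.5,
                              conf_threshold = 0.001, report_conf = 0.25) {
  dets <- list(); truths <- list()
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    d <- predict_image(model, sm$image, conf_threshold = conf_threshold)
    if (nrow(d)) { d$image <- i; dets[[length(dets) + 1L]] <- d }
    h <- dim(sm$image)[1]; w <- dim(sm$image)[2]
    t <- labels_to_boxes(sm$labels, w, h)
    if (nrow(t)) { t$image <- i; truths[[length(truths) + 1L]] <- t }
  }
  empty_det <- tibble::tibble(
    x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
    class_id = integer(), confidence = numeric(), image = integer())
  evaluate_detections(
    dplyr::bind_rows(c(list(empty_det), dets)),
    dplyr::bind_rows(c(list(empty_det[, -6]), truths)),
    iou_threshold = iou_threshold, conf_threshold = report_conf)
}
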