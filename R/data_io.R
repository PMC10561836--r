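#' Read and write images
#'
#' Images are `H x W x 3` double arrays with values in `[0, 1]` (RGB). PNG
#' is the supported on-disk format; grayscale and alpha channels are
#' normalized to plain RGB on read.
#'
#' @param path File path.
#' @param image An `H x W x 3` array in `[0, 1]`.
#' @return `read_image()` returns the image array; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

new_labels <- function(class_id = integer(), x_center = numeric(),
                       y_center = numeric(), width = numeric(),
                       height = numeric()) {
  tibble::tibble(class_id = as.integer(class_id), x_center = x_center,
                 y_center = y_center, width = width, height = height)
}

validate_labels <- function(labels, where = "labels") {
  cols <- c("x_center", "y_center", "width", "height")
  vals <- as.matrix(labels[, cols])
  if (any(vals < 0 | vals > 1)) {
    abort(sprintf("%s: coordinates must lie in [0, 1]", where))
  }
  if (any(labels$width <= 0 | labels$height <= 0)) {
    abort(sprintf("%s: box width and height must be positive", where))
  }
  if (any(labels$class_id < 0)) abort(sprintf("%s: class ids must be >= 0", where))
  labels
}

#' Read and write YOLO-format annotation files
#'
#' One text file per image, one row per box:
#' `class x_center y_center width height`, all coordinates normalized to
#' the image size. An empty (or absent) file means no objects.
#'
#' @param path Label file path.
#' @param labels A label tibble (`class_id`, `x_center`, `y_center`,
#'   `width`, `height`).
#' @return `read_yolo_labels()` returns the label tibble;
#'   `write_yolo_labels()` returns `path` invisibly. Values round-trip to
#'   six decimal places.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_yolo_labels(tibble::tibble(class_id = 0L, x_center = 0.5,
#'   y_center = 0.5, width = 0.2, height = 0.3), f)
#' read_yolo_labels(f)
read_yolo_labels <- function(path) {
  if (!file.exists(path)) return(new_labels())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(new_labels())
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 5L) {
      abort(sprintf("%s line %d: expected 5 fields, got %d", path, i, length(tok)))
    }
    vals <- suppressWarnings(as.numeric(tok))
    if (any(is.na(vals))) {
      abort(sprintf("%s line %d: non-numeric token", path, i))
    }
    if (any(vals[2:5] < 0 | vals[2:5] > 1)) {
      abort(sprintf("%s line %d: coordinate outside [0, 1]", path, i))
    }
    if (any(vals[4:5] <= 0)) {
      abort(sprintf("%s line %d: width/height must be positive", path, i))
    }
    new_labels(as.integer(vals[1]), vals[2], vals[3], vals[4], vals[5])
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_yolo_labels
#' @export
write_yolo_labels <- function(labels, path) {
  validate_labels(labels)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id,
                   labels$x_center, labels$y_center, labels$width,
                   labels$height)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write labels to %s", path))
  invisible(path)
}

#' Convert between normalized center and pixel corner boxes
#'
#' @param labels Normalized label tibble ([read_yolo_labels()] layout).
#' @param boxes Pixel-corner tibble/matrix with `x1, y1, x2, y2` (0-based,
#'   half-open) and optionally `class_id`.
#' @param width,height Image size in pixels.
#' @return `labels_to_boxes()`: tibble with `class_id, x1, y1, x2, y2`;
#'   `boxes_to_labels()`: a normalized label tibble.
#' @export
labels_to_boxes <- function(labels, width, height) {
  tibble::tibble(
    class_id = labels$class_id,
    x1 = (labels$x_center - labels$width / 2) * width,
    y1 = (labels$y_center - labels$height / 2) * height,
    x2 = (labels$x_center + labels$width / 2) * width,
    y2 = (labels$y_center + labels$height / 2) * height)
}

#' @rdname labels_to_boxes
#' @export
boxes_to_labels <- function(boxes, width, height) {
  cid <- if ("class_id" %in% names(boxes)) as.integer(boxes$class_id) else 0L
  new_labels(cid,
             (boxes$x1 + boxes$x2) / 2 / width,
             (boxes$y1 + boxes$y2) / 2 / height,
             (boxes$x2 - boxes$x1) / width,
             (boxes$y2 - boxes$y1) / height)
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving bilinear resize so the long side equals `target`,
#' then symmetric padding of the short side with neutral gray. The
#' recorded `scale`/`pad` metadata define the exact inverse transform used
#' to map predictions back to the original image ([unletterbox()]).
#'
#' @param image `H x W x 3` array.
#' @param labels Optional normalized label tibble for the input image; it
#'   is re-expressed relative to the letterboxed canvas.
#' @param target Output side length in pixels.
#' @return A list with `image` (target x target x 3), `labels`, and `meta`
#'   (`scale`, `pad_x`, `pad_y`, `orig_width`, `orig_height`, `target`).
#' @export
letterbox <- function(image, labels = NULL, target = 640L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  scale <- target / max(h, w)
  nh <- round(h * scale); nw <- round(w * scale)
  resized <- if (nh == h && nw == w) image else resize_image_cpp(image, nh, nw)
  pad_y <- (target - nh) %/% 2L
  pad_x <- (target - nw) %/% 2L
  canvas <- array(114 / 255, c(target, target, 3L))
  canvas[pad_y + seq_len(nh), pad_x + seq_len(nw), ] <- resized
  out_labels <- NULL
  if (!is.null(labels)) {
    out_labels <- new_labels(
      labels$class_id,
      (labels$x_center * nw + pad_x) / target,
      (labels$y_center * nh + pad_y) / target,
      labels$width * nw / target,
      labels$height * nh / target)
  }
  list(image = canvas, labels = out_labels,
       meta = list(scale = scale, pad_x = pad_x, pad_y = pad_y,
                   orig_width = w, orig_height = h, target = target,
                   resized_width = nw, resized_height = nh))
}

#' Map letterboxed pixel boxes back to original-image coordinates
#'
#' @param boxes Tibble/data frame of pixel-corner boxes in the letterboxed
#'   canvas.
#' @param meta The `meta` element returned by [letterbox()].
#' @return The boxes in original-image pixels, clipped to the image bounds.
#' @export
unletterbox <- function(boxes, meta) {
  sx <- meta$resized_width / meta$orig_width
  sy <- meta$resized_height / meta$orig_height
  out <- boxes
  out$x1 <- pmin(pmax((boxes$x1 - meta$pad_x) / sx, 0), meta$orig_width)
  out$x2 <- pmin(pmax((boxes$x2 - meta$pad_x) / sx, 0), meta$orig_width)
  out$y1 <- pmin(pmax((boxes$y1 - meta$pad_y) / sy, 0), meta$orig_height)
  out$y2 <- pmin(pmax((boxes$y2 - meta$pad_y) / sy, 0), meta$orig_height)
  out
}

#' Augmentation configuration
#'
#' Defaults are the training recipe of the detector: HSV jitter gains of
#' 0.015 (hue), 0.7 (saturation) and 0.4 (value/lightness), mosaic applied
#' with probability 1.0, random zoom of +/-0.5 and translation of +/-0.1
#' of the canvas.
#'
#' @param hue_gain,sat_gain,val_gain Half-ranges of the multiplicative HSV
#'   jitter (hue is additive, in turns).
#' @param mosaic_prob Probability of building a 4-image mosaic.
#' @param scale,translate Half-ranges of the random zoom factor and the
#'   fractional translation.
#' @param size Canvas side used by the mosaic, in pixels.
#' @return An `augment_config` list.
#' @export
augment_config <- function(hue_gain = 0.015, sat_gain = 0.7, val_gain = 0.4,
                           mosaic_prob = 1.0, scale = 0.5, translate = 0.1,
                           size = 640L) {
  stopifnot(mosaic_prob >= 0, mosaic_prob <= 1,
            hue_gain >= 0, sat_gain >= 0, val_gain >= 0)
  structure(list(hue_gain = hue_gain, sat_gain = sat_gain,
                 val_gain = val_gain, mosaic_prob = mosaic_prob,
                 scale = scale, translate = translate,
                 size = as.integer(size)),
            class = "augment_config")
}

# clip pixel boxes to a canvas, dropping boxes whose surviving area is
# below `min_frac` of their original area
clip_boxes_drop <- function(boxes, width, height, min_frac = 0.1) {
  if (nrow(boxes) == 0L) return(boxes)
  area0 <- (boxes$x2 - boxes$x1) * (boxes$y2 - boxes$y1)
  out <- boxes
  out$x1 <- pmin(pmax(boxes$x1, 0), width)
  out$x2 <- pmin(pmax(boxes$x2, 0), width)
  out$y1 <- pmin(pmax(boxes$y1, 0), height)
  out$y2 <- pmin(pmax(boxes$y2, 0), height)
  area <- (out$x2 - out$x1) * (out$y2 - out$y1)
  out[area > 0 & area / area0 >= min_frac, , drop = FALSE]
}

#' Four-image mosaic augmentation
#'
#' Builds a 2x2 collage: the four samples are resized to the configured
#' canvas side and placed in the quadrants around a random pivot; labels
#' are mapped to collage coordinates, clipped, and dropped when less than
#' 10% of the original box area survives the clip. Deterministic for a
#' fixed RNG state.
#'
#' @param samples List of exactly four samples, each a list with `image`
#'   and (normalized) `labels`.
#' @param config An [augment_config()].
#' @return A sample list (`image` of side `2 * config$size`, `labels`
#'   normalized to it).
#' @export
mosaic_augment <- function(samples, config = augment_config()) {
  if (length(samples) != 4L) abort("mosaic needs exactly 4 samples")
  s <- config$size
  canvas <- array(114 / 255, c(2L * s, 2L * s, 3L))
  px <- as.integer(round(runif(1, 0.5, 1.5) * s))
  py <- as.integer(round(runif(1, 0.5, 1.5) * s))
  offs <- list(c(px - s, py - s), c(px, py - s), c(px - s, py), c(px, py))
  all_boxes <- list()
  for (q in 1:4) {
    sm <- samples[[q]]
    img <- if (all(dim(sm$image)[1:2] == s)) sm$image
           else resize_image_cpp(sm$image, s, s)
    ox <- offs[[q]][1]; oy <- offs[[q]][2]
    xs <- max(1L, 1L + ox):min(2L * s, s + ox)
    ys <- max(1L, 1L + oy):min(2L * s, s + oy)
    canvas[ys, xs, ] <- img[ys - oy, xs - ox, , drop = FALSE]
    if (!is.null(sm$labels) && nrow(sm$labels) > 0) {
      b <- labels_to_boxes(sm$labels, s, s)
      b$x1 <- b$x1 + ox; b$x2 <- b$x2 + ox
      b$y1 <- b$y1 + oy; b$y2 <- b$y2 + oy
      all_boxes[[q]] <- b
    }
  }
  boxes <- dplyr::bind_rows(all_boxes)
  labels <- if (nrow(boxes) == 0L) new_labels() else {
    kept <- clip_boxes_drop(boxes, 2L * s, 2L * s)
    boxes_to_labels(kept, 2L * s, 2L * s)
  }
  list(image = canvas, labels = labels)
}

rgb_to_hsv_arr <- function(image) {
  d <- dim(image)
  m <- grDevices::rgb2hsv(
    matrix(aperm(image, c(3L, 1L, 2L)), nrow = 3L) * 255, maxColorValue = 255)
  aperm(array(m, c(3L, d[1], d[2])), c(2L, 3L, 1L))
}

hsv_to_rgb_arr <- function(hsv) {
  h <- (hsv[, , 1] %% 1) * 6
  s <- pmin(pmax(hsv[, , 2], 0), 1)
  v <- pmin(pmax(hsv[, , 3], 0), 1)
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim(hsv))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Random HSV color jitter
#'
#' Draws one gain per channel uniformly in the configured +/- ranges and
#' applies it in HSV space: hue is shifted (wrapping), saturation and
#' value are scaled. All-zero gains return the input bit-identically.
#'
#' @param image `H x W x 3` RGB array.
#' @param config An [augment_config()].
#' @return The jittered image; the drawn gains are attached as attribute
#'   `"gains"`.
#' @export
hsv_jitter <- function(image, config = augment_config()) {
  gains <- runif(3, -1, 1) * c(config$hue_gain, config$sat_gain,
                               config$val_gain)
  if (all(gains == 0)) return(structure(image, gains = gains))
  hsv <- rgb_to_hsv_arr(image)
  hsv[, , 1] <- hsv[, , 1] + gains[1]
  hsv[, , 2] <- hsv[, , 2] * (1 + gains[2])
  hsv[, , 3] <- hsv[, , 3] * (1 + gains[3])
  structure(hsv_to_rgb_arr(hsv), gains = gains)
}

#' Random zoom and translation
#'
#' Zooms the image by a factor drawn in `1 +/- scale` about the canvas
#' center and shifts it by up to `translate` of the canvas in each
#' direction, padding with neutral gray. Labels are transformed, clipped,
#' and dropped when less than 10% of the box area survives.
#'
#' @param sample A list with `image` and normalized `labels`.
#' @param config An [augment_config()].
#' @return The transformed sample.
#' @export
scale_translate <- function(sample, config = augment_config()) {
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  zoom <- runif(1, 1 - config$scale, 1 + config$scale)
  tx <- round(runif(1, -config$translate, config$translate) * w)
  ty <- round(runif(1, -config$translate, config$translate) * h)
  nh <- max(2L, as.integer(round(h * zoom)))
  nw <- max(2L, as.integer(round(w * zoom)))
  zimg <- resize_image_cpp(sample$image, nh, nw)
  canvas <- array(114 / 255, c(h, w, 3L))
  ox <- as.integer(round((w - nw) / 2)) + as.integer(tx)
  oy <- as.integer(round((h - nh) / 2)) + as.integer(ty)
  xs <- max(1L, 1L + ox):min(w, nw + ox)
  ys <- max(1L, 1L + oy):min(h, nh + oy)
  if (length(xs) > 0 && length(ys) > 0 && xs[1] <= w && ys[1] <= h) {
    canvas[ys, xs, ] <- zimg[ys - oy, xs - ox, , drop = FALSE]
  }
  labels <- sample$labels
  if (!is.null(labels) && nrow(labels) > 0) {
    b <- labels_to_boxes(labels, nw, nh)
    b$x1 <- b$x1 + ox; b$x2 <- b$x2 + ox
    b$y1 <- b$y1 + oy; b$y2 <- b$y2 + oy
    kept <- clip_boxes_drop(b, w, h)
    labels <- boxes_to_labels(kept, w, h)
  }
  list(image = canvas, labels = labels)
}

#' Stratified train/valid/test split
#'
#' Randomly partitions samples into train/valid/test with the given
#' fractions, stratified by class so each class is split in (about) the
#' same proportions.
#'
#' @param samples A tibble with one row per sample, including the stratum
#'   column.
#' @param fractions Named fractions summing to one (default the 80/15/5
#'   recipe).
#' @param seed Integer seed for the shuffle.
#' @param strata Name of the stratum column.
#' @return The input tibble with a `split` factor column added.
#' @export
#' @examples
#' df <- tibble::tibble(id = 1:100, class = rep(0:1, 50))
#' table(split_dataset(df, seed = 1)$split)
split_dataset <- function(samples,
                          fractions = c(train = 0.80, valid = 0.15, test = 0.05),
                          seed = 0L, strata = "class") {
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  if (!strata %in% names(samples)) {
    samples[[strata]] <- 0L
  }
  rng <- local_rng(seed)
  labels <- names(fractions)
  samples$split <- NA_character_
  for (cl in unique(samples[[strata]])) {
    idx <- which(samples[[strata]] == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    counts <- floor(fractions * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    stops <- cumsum(counts)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (k in seq_along(labels)) {
      if (counts[k] > 0) {
        samples$split[idx[starts[k]:stops[k]]] <- labels[k]
      }
    }
  }
  samples$split <- factor(samples$split, levels = labels)
  samples
}

# evaluate `expr`-style RNG use under a locally seeded, restored RNG state
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}
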