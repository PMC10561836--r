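#' Configuration for synthetic orchard scenes
#'
#' The generator emulates the conditions of dense-fruit field imagery:
#' elliptical fruit targets in clusters, partial occlusion by leaf/branch
#' shapes, background clutter, and lighting gradients (back/front/side
#' light). Labels are exact by construction and, like field annotation
#' practice, record the full unoccluded extent of each fruit.
#'
#' @param image_size Square canvas side in pixels.
#' @param n_targets Number of fruit targets per scene.
#' @param n_classes Number of fruit classes (default 3: strawberry-, jujube-
#'   and cherry-like palettes).
#' @param occlusion_prob Per-target probability of a partial leaf occlusion.
#' @param clutter_density Expected number of background distractor shapes.
#' @param lighting Amplitude of the illumination gradient in `[0, 1]`.
#' @param radius_range Fruit semi-axis range as a fraction of the canvas.
#' @param seed Integer seed; every draw is deterministic given it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = 320L, n_targets = 12L, n_classes = 3L,
                         occlusion_prob = 0.3, clutter_density = 8L,
                         lighting = 0.35, radius_range = c(0.04, 0.08),
                         seed = 1L) {
  stopifnot(n_targets >= 0, occlusion_prob >= 0, occlusion_prob <= 1,
            n_classes >= 1)
  structure(list(image_size = as.integer(image_size),
                 n_targets = as.integer(n_targets),
                 n_classes = as.integer(n_classes),
                 occlusion_prob = occlusion_prob,
                 clutter_density = clutter_density,
                 lighting = lighting, radius_range = radius_range,
                 seed = as.integer(seed)),
            class = "scene_config")
}

fruit_palette <- function(n_classes = 3L) {
  base <- rbind(c(0.85, 0.12, 0.18),   # strawberry-like red
                c(0.62, 0.30, 0.12),   # jujube-like russet
                c(0.45, 0.05, 0.28))   # cherry-like dark red
  if (n_classes <= 3L) return(base[seq_len(n_classes), , drop = FALSE])
  extra <- matrix(runif(3 * (n_classes - 3L), 0.2, 0.9),
                  ncol = 3L)
  rbind(base, extra)
}

# paint a shaded ellipse onto an image; returns the image
draw_ellipse <- function(img, cx, cy, rx, ry, theta, color, shade = 0.35) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ex <- sqrt((rx * cos(theta))^2 + (ry * sin(theta))^2)
  ey <- sqrt((rx * sin(theta))^2 + (ry * cos(theta))^2)
  ys <- max(1L, floor(cy - ey)):min(h, ceiling(cy + ey))
  xs <- max(1L, floor(cx - ex)):min(w, ceiling(cx + ex))
  if (length(ys) == 0L || length(xs) == 0L) return(img)
  dy <- matrix(ys - cy, length(ys), length(xs))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / rx
  v <- (-dx * sin(theta) + dy * cos(theta)) / ry
  r2 <- u^2 + v^2
  mask <- r2 <= 1
  if (!any(mask)) return(img)
  shading <- 1 - shade * r2 + shade * 0.6 * pmax(0, 0.4 - r2)
  for (c in 1:3) {
    plane <- img[ys, xs, c]
    plane[mask] <- pmin(1, pmax(0, color[c] * shading[mask]))
    img[ys, xs, c] <- plane
  }
  img
}

render_background <- function(config) {
  s <- config$image_size
  img <- array(0, c(s, s, 3L))
  base <- c(0.22, 0.42, 0.18)
  # smooth illumination gradient with a random direction (back/side light)
  ang <- runif(1, 0, 2 * pi)
  gx <- matrix(seq(-0.5, 0.5, length.out = s), s, s, byrow = TRUE)
  gy <- matrix(seq(-0.5, 0.5, length.out = s), s, s)
  grad <- config$lighting * (gx * cos(ang) + gy * sin(ang))
  # low-frequency foliage mottle from a few random sinusoids
  mottle <- matrix(0, s, s)
  for (k in 1:4) {
    fr <- runif(2, 1, 5); ph <- runif(2, 0, 2 * pi)
    mottle <- mottle + sin(2 * pi * fr[1] * gx + ph[1]) *
      sin(2 * pi * fr[2] * gy + ph[2])
  }
  mottle <- mottle / 8
  for (c in 1:3) {
    img[, , c] <- pmin(1, pmax(0, base[c] * (1 + grad + mottle) +
                                 rnorm(s * s, 0, 0.015)))
  }
  n_clutter <- rpois(1, config$clutter_density)
  for (i in seq_len(n_clutter)) {
    col <- c(runif(1, 0.1, 0.3), runif(1, 0.3, 0.55), runif(1, 0.05, 0.25))
    img <- draw_ellipse(img, runif(1, 0, s), runif(1, 0, s),
                        runif(1, 0.02, 0.08) * s, runif(1, 0.01, 0.03) * s,
                        runif(1, 0, pi), col, shade = 0.2)
  }
  img
}

sample_targets <- function(config) {
  s <- config$image_size
  n <- config$n_targets
  if (n == 0L) {
    return(tibble::tibble(class_id = integer(), cx = numeric(),
                          cy = numeric(), rx = numeric(), ry = numeric(),
                          theta = numeric(), occluded = logical(),
                          occ_dx = numeric(), occ_dy = numeric(),
                          occ_r = numeric()))
  }
  rmin <- config$radius_range[1] * s; rmax <- config$radius_range[2] * s
  placed <- list()
  tries <- 0L
  while (length(placed) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      abort(sprintf(
        "could not place %d targets without near-total overlap after %d tries",
        n, tries - 1L))
    }
    rx <- runif(1, rmin, rmax); ry <- runif(1, rmin, rmax)
    margin <- max(rx, ry) + 2
    cand <- list(cx = runif(1, margin, s - margin),
                 cy = runif(1, margin, s - margin), rx = rx, ry = ry)
    ok <- TRUE
    for (p in placed) {
      d <- sqrt((p$cx - cand$cx)^2 + (p$cy - cand$cy)^2)
      if (d < 0.6 * (max(p$rx, p$ry) + max(rx, ry))) { ok <- FALSE; break }
    }
    if (ok) placed[[length(placed) + 1L]] <- cand
  }
  tibble::tibble(
    class_id = sample.int(config$n_classes, n, replace = TRUE) - 1L,
    cx = vapply(placed, `[[`, 0, "cx"),
    cy = vapply(placed, `[[`, 0, "cy"),
    rx = vapply(placed, `[[`, 0, "rx"),
    ry = vapply(placed, `[[`, 0, "ry"),
    theta = runif(n, 0, pi),
    occluded = runif(n) < config$occlusion_prob,
    occ_dx = runif(n, -0.6, 0.6),
    occ_dy = runif(n, -0.6, 0.6),
    occ_r = runif(n, 0.5, 0.9))
}

render_targets <- function(img, targets, palette) {
  for (i in seq_len(nrow(targets))) {
    t <- targets[i, ]
    col <- pmin(1, pmax(0, palette[t$class_id + 1L, ] +
                          runif(3, -0.05, 0.05)))
    img <- draw_ellipse(img, t$cx, t$cy, t$rx, t$ry, t$theta, col)
  }
  # leaf occluders drawn after all fruits so clusters occlude naturally
  for (i in which(targets$occluded)) {
    t <- targets[i, ]
    r <- max(t$rx, t$ry)
    img <- draw_ellipse(img, t$cx + t$occ_dx * r, t$cy + t$occ_dy * r,
                        t$occ_r * r, 0.6 * t$occ_r * r, t$theta + pi / 3,
                        c(0.18, 0.45, 0.15), shade = 0.15)
  }
  img
}

targets_to_labels <- function(targets, size, min_visible = 0.25) {
  if (nrow(targets) == 0L) return(new_labels())
  ex <- sqrt((targets$rx * cos(targets$theta))^2 +
               (targets$ry * sin(targets$theta))^2)
  ey <- sqrt((targets$rx * sin(targets$theta))^2 +
               (targets$ry * cos(targets$theta))^2)
  b <- tibble::tibble(class_id = targets$class_id,
                      x1 = targets$cx - ex, y1 = targets$cy - ey,
                      x2 = targets$cx + ex, y2 = targets$cy + ey)
  kept <- clip_boxes_drop(b, size, size, min_frac = min_visible)
  boxes_to_labels(kept, size, size)
}

#' Generate one synthetic orchard scene
#'
#' Renders a deterministic scene (given `config$seed`): background with
#' lighting gradient, mottle and clutter; `n_targets` shaded fruit
#' ellipses placed with bounded-retry rejection of near-total overlap;
#' optional leaf occluders drawn over fruits. Labels are the tight
#' bounding boxes of the target ellipses *before* occlusion, mirroring
#' annotation practice of labeling the whole fruit.
#'
#' @param config A [scene_config()].
#' @return A sample list: `image` (size x size x 3), `labels` (normalized
#'   tibble), and `targets` (the exact ellipse parameters, one row per
#'   fruit — usable as an independent geometric oracle).
#' @export
#' @examples
#' sc <- generate_scene(scene_config(image_size = 96, n_targets = 3))
#' nrow(sc$labels)
generate_scene <- function(config = scene_config()) {
  set.seed(config$seed)
  img <- render_background(config)
  targets <- sample_targets(config)
  img <- render_targets(img, targets, fruit_palette(config$n_classes))
  list(image = img,
       labels = targets_to_labels(targets, config$image_size),
       targets = targets, config = config)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` scenes as PNG images with matching YOLO label files
#' and a dataset manifest (`manifest.yaml` with class names and paths).
#' Scene `i` uses seed `config$seed + i`, so regeneration is byte-stable.
#'
#' @param config A [scene_config()].
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @param class_names Class names for the manifest.
#' @return The manifest as a list (invisibly); also written as YAML.
#' @export
generate_dataset <- function(config, n_images, out_dir,
                             class_names = c("strawberry", "jujube", "cherry")) {
  stopifnot(n_images >= 1)
  class_names <- class_names[seq_len(config$n_classes)]
  img_dir <- file.path(out_dir, "images")
  lab_dir <- file.path(out_dir, "labels")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE) |
    dir.exists(img_dir)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || !dir.exists(lab_dir)) {
    abort(sprintf("cannot create dataset directories under %s", out_dir))
  }
  ids <- sprintf("scene_%04d", seq_len(n_images))
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- config$seed + i
    sc <- generate_scene(cfg)
    write_image(sc$image, file.path(img_dir, paste0(ids[i], ".png")))
    write_yolo_labels(sc$labels, file.path(lab_dir, paste0(ids[i], ".txt")))
  }
  manifest <- list(path = normalizePath(out_dir), images = "images",
                   labels = "labels", nc = length(class_names),
                   names = as.list(class_names), ids = as.list(ids))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a dataset manifest and its samples
#'
#' @param path A manifest YAML file or the directory containing one.
#' @return A list of samples (`image`, `labels`, `id`) plus the manifest as
#'   attribute `"manifest"`.
#' @export
read_dataset <- function(path) {
  mf <- if (dir.exists(path)) file.path(path, "manifest.yaml") else path
  if (!file.exists(mf)) abort(sprintf("no manifest at %s", path))
  manifest <- yaml::read_yaml(mf)
  root <- dirname(mf)
  samples <- lapply(manifest$ids, function(id) {
    list(image = read_image(file.path(root, manifest$images, paste0(id, ".png"))),
         labels = read_yolo_labels(file.path(root, manifest$labels,
                                             paste0(id, ".txt"))),
         id = id)
  })
  attr(samples, "manifest") <- manifest
  samples
}

#' Generate a synthetic video of moving fruit targets
#'
#' Targets from one scene translate rigidly by `motion` pixels per frame
#' (their occluders move with them); the background stays fixed. A target
#' is labeled in a frame while at least a quarter of its box is on the
#' canvas; `true_count` is the number of distinct targets ever labeled.
#'
#' @param config A [scene_config()].
#' @param n_frames Number of frames.
#' @param motion Length-2 pixels-per-frame displacement `(dx, dy)`.
#' @param out_dir Optional directory; if given, frames are written as
#'   `frame_%04d.png` with YOLO labels alongside (an image-sequence
#'   "video").
#' @return A list: `frames` (list of images), `labels` (list of label
#'   tibbles), `true_count`, `targets`, `motion`.
#' @export
generate_video <- function(config, n_frames, motion = c(3, 0),
                           out_dir = NULL) {
  stopifnot(n_frames >= 1, length(motion) == 2)
  set.seed(config$seed)
  bg <- render_background(config)
  targets0 <- sample_targets(config)
  palette <- fruit_palette(config$n_classes)
  frames <- vector("list", n_frames)
  labels <- vector("list", n_frames)
  ever <- logical(nrow(targets0))
  for (f in seq_len(n_frames)) {
    tg <- targets0
    tg$cx <- tg$cx + (f - 1L) * motion[1]
    tg$cy <- tg$cy + (f - 1L) * motion[2]
    on_canvas <- tg$cx > -2 * tg$rx & tg$cx < config$image_size + 2 * tg$rx &
      tg$cy > -2 * tg$ry & tg$cy < config$image_size + 2 * tg$ry
    frames[[f]] <- render_targets(bg, tg[on_canvas, ], palette)
    labels[[f]] <- targets_to_labels(tg, config$image_size)
    vis <- attr(targets_visible(tg, config$image_size), "visible")
    ever <- ever | vis
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_len(n_frames)) {
      write_image(frames[[f]], file.path(out_dir, sprintf("frame_%04d.png", f)))
      write_yolo_labels(labels[[f]],
                        file.path(out_dir, sprintf("frame_%04d.txt", f)))
    }
  }
  list(frames = frames, labels = labels, true_count = sum(ever),
       targets = targets0, motion = motion)
}

targets_visible <- function(targets, size, min_visible = 0.25) {
  if (nrow(targets) == 0L) {
    return(structure(targets, visible = logical()))
  }
  ex <- sqrt((targets$rx * cos(targets$theta))^2 +
               (targets$ry * sin(targets$theta))^2)
  ey <- sqrt((targets$rx * sin(targets$theta))^2 +
               (targets$ry * cos(targets$theta))^2)
  x1 <- targets$cx - ex; x2 <- targets$cx + ex
  y1 <- targets$cy - ey; y2 <- targets$cy + ey
  iw <- pmax(0, pmin(x2, size) - pmax(x1, 0))
  ih <- pmax(0, pmin(y2, size) - pmax(y1, 0))
  frac <- iw * ih / ((x2 - x1) * (y2 - y1))
  structure(targets, visible = frac >= min_visible)
}
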