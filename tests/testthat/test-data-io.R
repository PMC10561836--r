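test_that("YOLO label files parse and validate", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.2 0.3", f)
  lb <- read_yolo_labels(f)
  expect_equal(nrow(lb), 1L)
  expect_identical(lb$class_id, 0L)
  expect_equal(lb$x_center, 0.5)

  writeLines(character(), f)
  expect_equal(nrow(read_yolo_labels(f)), 0L)

  writeLines(c("0 0.5 0.5 0.2 0.3", "1 0.5 0.5 1.2 0.3"), f)
  expect_error(read_yolo_labels(f), "line 2")
  writeLines("0 0.5 oops 0.2 0.3", f)
  expect_error(read_yolo_labels(f), "line 1.*non-numeric")
  writeLines("0 0.5 0.5 0.2", f)
  expect_error(read_yolo_labels(f), "5 fields")
})

test_that("labels round-trip through files to six decimals", {
  set.seed(21)
  n <- 200L
  w <- runif(n, 0.01, 0.3); h <- runif(n, 0.01, 0.3)
  lb <- tibble::tibble(class_id = sample(0:2, n, TRUE),
                       x_center = runif(n, 0.2, 0.8),
                       y_center = runif(n, 0.2, 0.8), width = w, height = h)
  f <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(lb, f)
  expect_identical(length(readLines(f)), n)
  back <- read_yolo_labels(f)
  for (col in c("x_center", "y_center", "width", "height")) {
    expect_lt(max(abs(back[[col]] - lb[[col]])), 1e-6)
  }
  expect_identical(back$class_id, lb$class_id)
  write_yolo_labels(lb[0, ], f)
  expect_equal(nrow(read_yolo_labels(f)), 0L)
})

test_that("letterbox is the identity on already-square inputs", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  lb <- letterbox(img, target = 64L)
  expect_equal(lb$image, img)
  expect_equal(lb$meta$pad_x, 0L)
  expect_equal(lb$meta$pad_y, 0L)
  expect_equal(lb$meta$scale, 1)
})

test_that("letterbox scales by the long side and pads symmetrically", {
  # same 1904:4096 aspect as the capture resolution, at test scale
  img <- array(runif(119 * 256 * 3), c(119, 256, 3))
  lb <- letterbox(img, target = 64L)
  expect_equal(lb$meta$scale, 64 / 256)
  expect_equal(lb$meta$resized_height, round(119 * 64 / 256))
  expect_equal(dim(lb$image), c(64L, 64L, 3L))
  expect_equal(lb$meta$pad_y, (64L - lb$meta$resized_height) %/% 2L)
  # a centered box stays centered
  labels <- tibble::tibble(class_id = 0L, x_center = 0.5, y_center = 0.5,
                           width = 0.4, height = 0.4)
  lb2 <- letterbox(img, labels, target = 64L)
  expect_equal(lb2$labels$x_center, 0.5, tolerance = 1e-6)
  expect_equal(lb2$labels$y_center, 0.5, tolerance = 0.02)
})

test_that("de-letterboxing inverts the letterbox to sub-pixel accuracy", {
  set.seed(22)
  img <- array(runif(150 * 100 * 3), c(150, 100, 3))
  lb <- letterbox(img, target = 96L)
  orig <- random_boxes(20, size = 70)
  scaled <- orig
  sx <- lb$meta$resized_width / 100; sy <- lb$meta$resized_height / 150
  scaled$x1 <- orig$x1 * sx + lb$meta$pad_x
  scaled$x2 <- orig$x2 * sx + lb$meta$pad_x
  scaled$y1 <- orig$y1 * sy + lb$meta$pad_y
  scaled$y2 <- orig$y2 * sy + lb$meta$pad_y
  back <- unletterbox(scaled, lb$meta)
  expect_equal(as.matrix(back), as.matrix(orig), tolerance = 1e-8)
})

test_that("mosaic collages four samples deterministically", {
  set.seed(23)
  mk <- function(with_label) {
    img <- array(runif(48 * 48 * 3), c(48, 48, 3))
    labels <- if (with_label) {
      tibble::tibble(class_id = 0L, x_center = 0.5, y_center = 0.5,
                     width = 0.25, height = 0.25)
    } else {
      tibble::tibble(class_id = integer(), x_center = numeric(),
                     y_center = numeric(), width = numeric(),
                     height = numeric())
    }
    list(image = img, labels = labels)
  }
  cfg <- augment_config(size = 48L)
  empty4 <- replicate(4, mk(FALSE), simplify = FALSE)
  set.seed(1)
  m0 <- mosaic_augment(empty4, cfg)
  expect_equal(nrow(m0$labels), 0L)
  expect_equal(dim(m0$image), c(96L, 96L, 3L))

  full4 <- replicate(4, mk(TRUE), simplify = FALSE)
  set.seed(7); m1 <- mosaic_augment(full4, cfg)
  set.seed(7); m2 <- mosaic_augment(full4, cfg)
  expect_identical(m1, m2)
  expect_error(mosaic_augment(full4[1:3], cfg), "4 samples")
})

test_that("mosaic keeps surviving labels inside the canvas", {
  set.seed(24)
  for (rep in 1:10) {
    samples <- replicate(4, {
      n <- sample(0:3, 1)
      cx <- runif(n, 0.2, 0.8); cy <- runif(n, 0.2, 0.8)
      list(image = array(runif(32 * 32 * 3), c(32, 32, 3)),
           labels = tibble::tibble(class_id = rep(0L, n), x_center = cx,
                                   y_center = cy,
                                   width = runif(n, 0.05, 0.3),
                                   height = runif(n, 0.05, 0.3)))
    }, simplify = FALSE)
    m <- mosaic_augment(samples, augment_config(size = 32L))
    if (nrow(m$labels)) {
      b <- labels_to_boxes(m$labels, 64, 64)
      expect_true(all(b$x1 >= -1e-9 & b$y1 >= -1e-9 &
                        b$x2 <= 64 + 1e-9 & b$y2 <= 64 + 1e-9))
    }
  }
})

test_that("HSV jitter with zero gains is the identity and seeds reproduce", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  none <- augment_config(hue_gain = 0, sat_gain = 0, val_gain = 0)
  out <- hsv_jitter(img, none)
  expect_identical(unclass(out)[seq_along(img)], as.vector(img))
  cfg <- augment_config()
  set.seed(5); a <- hsv_jitter(img, cfg)
  set.seed(5); b <- hsv_jitter(img, cfg)
  expect_identical(a, b)
})

test_that("the value channel shifts by the drawn gain", {
  img <- array(0.5, c(40, 40, 3))
  img[, , 1] <- 0.45  # slightly unsaturated gray so value is well defined
  cfg <- augment_config(hue_gain = 0, sat_gain = 0, val_gain = 0.4)
  set.seed(6)
  out <- hsv_jitter(img, cfg)
  gain <- attr(out, "gains")[3]
  v_in <- pmax(img[, , 1], img[, , 2], img[, , 3])
  v_out <- pmax(out[, , 1], out[, , 2], out[, , 3])
  expect_equal(mean(v_out) / mean(v_in), 1 + gain, tolerance = 0.01)
})

test_that("splits are stratified, disjoint and exhaustive", {
  df <- tibble::tibble(id = 1:100, class = rep(0L, 100))
  sp <- split_dataset(df, seed = 1)
  expect_equal(as.vector(table(sp$split)), c(80L, 15L, 5L))

  # per-fruit image counts of the study dataset
  df2 <- tibble::tibble(id = seq_len(1350 + 1959 + 948),
                        class = rep(0:2, c(1350, 1959, 948)))
  sp2 <- split_dataset(df2, seed = 2)
  expect_equal(nrow(sp2), nrow(df2))
  expect_false(any(is.na(sp2$split)))
  tab <- table(sp2$class, sp2$split)
  for (cl in 0:2) {
    n <- sum(df2$class == cl)
    expect_lte(max(abs(tab[as.character(cl), ] -
                         n * c(0.80, 0.15, 0.05))), 1)
  }
  expect_error(split_dataset(df, fractions = c(a = 0.5, b = 0.4)),
               "sum to 1")
})
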