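make_detections <- function(n, size = 100, classes = 0:1) {
  b <- random_boxes(n, size)
  b$class_id <- sample(classes, n, replace = TRUE)
  b$confidence <- runif(n)
  b
}

test_that("NMS keeps the highest-confidence of duplicate boxes", {
  d <- tibble::tibble(x1 = c(0, 0), y1 = c(0, 0), x2 = c(10, 10),
                      y2 = c(10, 10), class_id = c(0L, 0L),
                      confidence = c(0.9, 0.8))
  kept <- nms(d, 0.7)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 0.9)

  apart <- tibble::tibble(x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                          y2 = c(10, 30), class_id = c(0L, 0L),
                          confidence = c(0.9, 0.8))
  expect_equal(nrow(nms(apart, 0.7)), 2L)
})

test_that("NMS equals the exhaustive suppression oracle on random sets", {
  set.seed(41)
  for (rep in 1:25) {
    d <- make_detections(50)
    got <- nms(d, 0.5)
    want <- oracle_nms(d, 0.5)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("NMS output is a confidence-sorted subset with bounded overlap", {
  set.seed(42)
  d <- make_detections(80)
  kept <- nms(d, 0.45)
  expect_true(all(diff(kept$confidence) <= 0))
  expect_true(nrow(kept) <= nrow(d))
  if (nrow(kept) > 1) {
    for (i in seq_len(nrow(kept) - 1)) {
      same <- which(kept$class_id == kept$class_id[i] &
                      seq_len(nrow(kept)) > i)
      if (length(same)) {
        ious <- box_iou(
          matrix(unlist(kept[i, c("x1", "y1", "x2", "y2")]), length(same),
                 4, byrow = TRUE),
          as.matrix(kept[same, c("x1", "y1", "x2", "y2")]))
        expect_true(all(ious <= 0.45 + 1e-12))
      }
    }
  }
})

test_that("a short training run reduces the loss deterministically", {
  samples <- lapply(1:2, function(i) {
    generate_scene(scene_config(image_size = 64, n_targets = 2,
                                clutter_density = 2, seed = 40 + i))
  })
  cfg <- train_config(input_size = 32L, batch = 2L, epochs = 6L, seed = 9,
                      use_augment = FALSE, warmup_iters = 2L)
  fit <- train_detector(samples, num_classes = 3, config = cfg)
  log <- tidy(fit)
  expect_equal(nrow(log), 6L)
  expect_lt(log$total[6], log$total[1])
  fit2 <- train_detector(samples, num_classes = 3, config = cfg)
  expect_equal(tidy(fit2)$total, log$total, tolerance = 1e-10)
  expect_equal(glance(fit)$params, 1789657L)
})

test_that("the augmentation pipeline feeds training without error", {
  samples <- lapply(1:4, function(i) {
    generate_scene(scene_config(image_size = 64, n_targets = 2,
                                clutter_density = 2, seed = 50 + i))
  })
  cfg <- train_config(input_size = 32L, batch = 4L, epochs = 2L, seed = 10,
                      use_augment = TRUE,
                      augment = augment_config(size = 32L))
  fit <- train_detector(samples, num_classes = 3, config = cfg)
  expect_true(all(is.finite(tidy(fit)$total)))
})

test_that("prediction returns clipped boxes and an fps identity", {
  samples <- list(generate_scene(scene_config(image_size = 64, n_targets = 2,
                                              seed = 60)))
  cfg <- train_config(input_size = 32L, batch = 1L, epochs = 2L, seed = 11,
                      use_augment = FALSE)
  fit <- train_detector(samples, num_classes = 3, config = cfg)
  blank <- array(0.5, c(64, 64, 3))
  none <- predict_image(fit, blank, conf_threshold = 0.999)
  expect_equal(nrow(none), 0L)
  some <- predict_image(fit, samples[[1]]$image, conf_threshold = 0.01)
  if (nrow(some)) {
    expect_true(all(some$x1 >= 0 & some$y1 >= 0 &
                      some$x2 <= 64 & some$y2 <= 64))
  }
  sp <- attr(some, "speed")
  expect_equal(sp$fps, sp$frames / sp$elapsed_seconds)
  expect_equal(speed_report(10, 2)$fps, 5)
})

test_that("loss log export mirrors the per-epoch components", {
  samples <- list(generate_scene(scene_config(image_size = 64, n_targets = 1,
                                              seed = 61)))
  cfg <- train_config(input_size = 32L, batch = 1L, epochs = 3L, seed = 12,
                      use_augment = FALSE)
  fit <- train_detector(samples, num_classes = 3, config = cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_loss_log(fit, f)
  log <- utils::read.csv(f)
  expect_equal(names(log), c("epoch", "box", "cls", "dfl", "total"))
  expect_equal(nrow(log), 3L)
  # the weighted accounting identity holds row by row
  expect_equal(log$total, 7.5 * log$box + 0.5 * log$cls + 1.5 * log$dfl,
               tolerance = 1e-9)
})
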