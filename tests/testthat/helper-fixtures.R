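# Shared trained-model fixtures for the slow end-to-end checks. Training is
# lazy and memoised so repeated tests reuse one run.
.fixture_env <- new.env(parent = emptyenv())

overfit_scene_config <- function(seed) {
  scene_config(image_size = 160L, n_targets = 5L, occlusion_prob = 0.2,
               clutter_density = 4L, seed = seed)
}

# eight independent scenes memorized in 300 iterations
overfit_fixture <- function() {
  if (is.null(.fixture_env$fit)) {
    samples <- lapply(1:8, function(i) {
      generate_scene(overfit_scene_config(100L + i))
    })
    cfg <- train_config(input_size = 128L, batch = 8L, epochs = 300L,
                        seed = 1L, use_augment = FALSE)
    .fixture_env$samples <- samples
    .fixture_env$fit <- train_detector(samples, num_classes = 3L,
                                       config = cfg)
  }
  .fixture_env
}

# a 12-frame video of five moving targets, with a detector overfit to the
# video's own frames (the counting mechanics assume a detector that is
# reliable on the footage it counts)
video_fixture <- function() {
  if (is.null(.fixture_env$vid_fit)) {
    vid <- generate_video(overfit_scene_config(101L), n_frames = 12,
                          motion = c(3, 2))
    samples <- lapply(seq_along(vid$frames), function(f) {
      list(image = vid$frames[[f]], labels = vid$labels[[f]])
    })
    cfg <- train_config(input_size = 128L, batch = 9L, epochs = 200L,
                        seed = 1L, use_augment = FALSE)
    .fixture_env$video <- vid
    .fixture_env$vid_fit <- train_detector(samples, num_classes = 3L,
                                           config = cfg)
    .fixture_env$vid_samples <- samples
  }
  .fixture_env
}
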