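test_that("detect-scale shapes follow the stride-8/16/32 pyramid", {
  topo <- build_simplified(3, 640)
  st <- shape_trace(topo)
  det <- st[match(topo$detect_scales, st$index), ]
  expect_equal(det$height, c(80L, 40L, 20L))
  expect_equal(det$width, c(80L, 40L, 20L))

  st320 <- shape_trace(build_simplified(1, 320))
  det320 <- st320[match(c(25L, 28L, 31L), st320$index), ]
  expect_equal(det320$height, c(40L, 20L, 10L))

  for (sz in c(64L, 320L, 640L)) {
    sti <- shape_trace(build_simplified(2, sz))
    deti <- sti[match(c(25L, 28L, 31L), sti$index), ]
    expect_equal(deti$height, sz %/% c(8L, 16L, 32L))
  }
})

test_that("input sizes off the stride grid are rejected", {
  expect_error(build_simplified(3, 100), "multiple of 32")
  expect_error(build_simplified(3, 0), "multiple of 32")
  expect_error(shape_trace(build_simplified(3, 640), height = 100,
                           width = 100), "multiple of 32")
})

test_that("block kinds sit at the published indices", {
  b <- build_simplified(3, 640)$blocks
  kind_at <- function(k) b$index[b$kind == k]
  expect_equal(kind_at("maxpool"), c(4L, 10L, 16L))
  expect_equal(kind_at("concat"), c(8L, 14L, 21L, 24L, 27L, 30L))
  expect_equal(kind_at("sppf"), 19L)
  expect_equal(kind_at("upsample"), c(20L, 23L))
  conv32 <- b$index[b$kind == "conv" & b$kernel == 3L & b$stride == 2L]
  expect_equal(conv32, c(0L, 1L, 26L, 29L))
  conv11 <- b$index[b$kind == "conv" & b$kernel == 1L]
  expect_equal(conv11, c(2L, 5L, 7L, 9L, 11L, 13L, 15L, 17L, 22L, 25L,
                         28L, 31L))
  expect_equal(b$sources[[which(b$index == 8L)]], c(5L, 7L))
  expect_equal(b$sources[[which(b$index == 14L)]], c(11L, 13L))
})

test_that("parameter counting follows the i*k*k*o + o convention", {
  single <- function(i, k, o, bn = FALSE) {
    simplifruit:::new_fruit_topology(
      layer_spec(0, "conv", k, 1, in_channels = i, out_channels = o,
                 batch_norm = bn))
  }
  expect_identical(count_params(single(3, 3, 16)), 448L)
  expect_identical(count_params(single(64, 1, 32)), 2080L)
  # batch-normalized convs carry the scale/shift pair instead of a bias
  expect_identical(count_params(single(3, 3, 16, bn = TRUE)), 448L + 16L)
})

test_that("the assembled network has 1.8M parameters", {
  topo <- build_simplified(3, 640)
  expect_identical(count_params(topo), 1789657L)
  expect_equal(round(count_params(topo) / 1e6, 1), 1.8)
})

test_that("count_params equals brute-force enumeration of weight containers", {
  for (topo in list(build_simplified(3, 640), build_simplified(1, 320),
                    tiny_topology())) {
    plan <- simplifruit:::compile_plan(topo)
    params <- simplifruit:::init_params(plan, seed = 1)
    expect_identical(simplifruit:::enumerate_param_sizes(params),
                     count_params(topo))
  }
})

test_that("module census reports 104 under the YOLOv8n-calibrated convention", {
  expect_identical(reference_module_census(), 168L)
  expect_identical(module_census(build_simplified(3, 640)), 104L)
})

test_that("module census is invariant to the class count", {
  censuses <- vapply(c(1L, 3L, 10L),
                     function(nc) module_census(build_simplified(nc, 640)),
                     0L)
  expect_true(all(censuses == censuses[1]))
})

test_that("a one-block topology counts its primitive modules plus overhead", {
  topo <- simplifruit:::new_fruit_topology(
    layer_spec(0, "conv", 3, 1, in_channels = 3, out_channels = 8))
  # conv wrapper + conv primitive, plus model/sequential/shared-activation
  expect_identical(module_census(topo), 2L + 3L)
})

test_that("concat with mismatched spatial sources names the block", {
  blocks <- dplyr::bind_rows(
    layer_spec(0, "conv", 3, 2, in_channels = 3, out_channels = 4),
    layer_spec(1, "conv", 3, 1, in_channels = 4, out_channels = 4),
    layer_spec(2, "concat", sources = c(0, 1)))
  topo <- simplifruit:::new_fruit_topology(blocks)
  ok <- shape_trace(topo, 64, 64)  # conv s2 then s1: same sizes, fine
  expect_equal(nrow(ok), 3L)
  blocks_bad <- dplyr::bind_rows(
    layer_spec(0, "conv", 3, 1, in_channels = 3, out_channels = 4),
    layer_spec(1, "conv", 3, 2, in_channels = 4, out_channels = 4),
    layer_spec(2, "concat", sources = c(0, 1)))
  topo_bad <- simplifruit:::new_fruit_topology(blocks_bad)
  expect_error(shape_trace(topo_bad, 64, 64), "block 2")
})

test_that("concatenation sums channels and preserves space", {
  sh <- sppf_block(20, 20, 256, hidden_channels = 128)
  expect_equal(sh$channels[sh$stage == "concat"], 512L)
  expect_true(all(sh$height == 20L) && all(sh$width == 20L))
  expect_error(sppf_block(20, 20, 256, hidden_channels = 0), "positive")
})

test_that("chained stride-1 5x5 pools agree on constant input (RF 5/9/13)", {
  x <- matrix(3.7, 1, 12 * 12)
  p1 <- simplifruit:::maxpool_cpp(x, 12L, 12L, 5L, 1L, 2L)$y
  p2 <- simplifruit:::maxpool_cpp(p1, 12L, 12L, 5L, 1L, 2L)$y
  p3 <- simplifruit:::maxpool_cpp(p2, 12L, 12L, 5L, 1L, 2L)$y
  expect_equal(p1, p2)
  expect_equal(p2, p3)
  # receptive field: a single spike spreads to 5, 9, 13 columns wide
  d <- matrix(0, 1, 25 * 25); d[1, 12 * 25 + 13] <- 1
  width_of <- function(m) {
    cols <- which(m[1, ] > 0) %% 25
    diff(range(cols)) + 1
  }
  q1 <- simplifruit:::maxpool_cpp(d, 25L, 25L, 5L, 1L, 2L)$y
  q2 <- simplifruit:::maxpool_cpp(q1, 25L, 25L, 5L, 1L, 2L)$y
  q3 <- simplifruit:::maxpool_cpp(q2, 25L, 25L, 5L, 1L, 2L)$y
  expect_equal(vapply(list(q1, q2, q3), width_of, 0), c(5, 9, 13))
})

test_that("the shipped YAML config reproduces the canonical topology", {
  topo <- build_simplified(3, 640)
  from_yaml <- read_topology_config()
  expect_identical(count_params(from_yaml), count_params(topo))
  expect_identical(module_census(from_yaml), module_census(topo))
  expect_equal(from_yaml$blocks$kind, topo$blocks$kind)
  expect_equal(from_yaml$blocks$out_channels, topo$blocks$out_channels)
  expect_equal(graph_census(from_yaml), graph_census(topo))
})
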