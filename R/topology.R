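#' Declare one block of a detector topology
#'
#' A topology is an ordered list of indexed blocks. Each block is one of the
#' five primitive kinds used by the simplified detector: a convolution
#' (`conv`, batch-normalized and SiLU-activated unless flagged otherwise), a
#' downsampling max-pool (`maxpool`), a channel-wise feature concatenation
#' (`concat`), a serial spatial-pyramid-pooling block (`sppf`) or a 2x
#' nearest-neighbour upsample (`upsample`).
#'
#' @param index Integer block id (0-based).
#' @param kind One of `"conv"`, `"maxpool"`, `"concat"`, `"sppf"`,
#'   `"upsample"`.
#' @param kernel Kernel size in pixels (convs: 1 or 3; pools: 2 or 5).
#' @param stride Stride (1 or 2).
#' @param sources Integer vector of block indices feeding this block.
#'   Empty means "the previous block". Concatenations need at least two.
#' @param in_channels,out_channels Channel counts entering and leaving the
#'   block.
#' @param hidden_channels Hidden width of an `sppf` block (ignored
#'   otherwise).
#' @param batch_norm,activation Whether a conv carries batch normalization
#'   and a SiLU activation. Prediction convs in the head use neither.
#'
#' @return A one-row tibble describing the block.
#' @export
#' @examples
#' layer_spec(0, "conv", kernel = 3, stride = 2, in_channels = 3,
#'            out_channels = 16)
layer_spec <- function(index, kind, kernel = 0L, stride = 1L,
                       sources = integer(), in_channels = NA_integer_,
                       out_channels = NA_integer_,
                       hidden_channels = NA_integer_,
                       batch_norm = kind == "conv",
                       activation = kind %in% c("conv", "sppf")) {
  kind <- match.arg(kind, c("conv", "maxpool", "concat", "sppf", "upsample"))
  if (kind == "conv" && !kernel %in% c(1L, 3L)) {
    abort(sprintf("block %d: conv kernel must be 1 or 3, got %s", index, kernel))
  }
  if (!stride %in% c(1L, 2L)) {
    abort(sprintf("block %d: stride must be 1 or 2", index))
  }
  if (kind == "concat" && length(sources) < 2L) {
    abort(sprintf("block %d: concat needs at least two sources", index))
  }
  if (kind %in% c("conv", "sppf") &&
      (!is.na(in_channels) && in_channels <= 0 ||
       !is.na(out_channels) && out_channels <= 0)) {
    abort(sprintf("block %d: channel counts must be positive", index))
  }
  tibble::tibble(
    index = as.integer(index), kind = kind, kernel = as.integer(kernel),
    stride = as.integer(stride), sources = list(as.integer(sources)),
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels),
    hidden_channels = as.integer(hidden_channels),
    batch_norm = batch_norm, activation = activation
  )
}

new_fruit_topology <- function(blocks, detect_scales = integer(),
                               num_classes = 1L, input_size = NA_integer_,
                               reg_max = 16L, head_width = 64L,
                               width_multiple = 0.5, depth_multiple = 0.33) {
  structure(
    list(
      blocks = blocks,
      detect_scales = as.integer(detect_scales),
      num_classes = as.integer(num_classes),
      input_size = as.integer(input_size),
      reg_max = as.integer(reg_max),
      head_width = as.integer(head_width),
      width_multiple = width_multiple,
      depth_multiple = depth_multiple
    ),
    class = "fruit_topology"
  )
}

# Canonical channel schedule of the simplified detector. The published
# description pins the block kinds, kernels and strides per index plus the
# network totals (1.8M parameters, 104 layers, operator census); the free
# widths below were calibrated once so that those totals are reproduced, and
# are frozen here and in inst/extdata/simplified.yaml.
simplified_schedule <- function() {
  list(
    stem = c(16L, 32L),          # blocks 0, 1
    stage8_hidden = 64L,         # blocks 5-7
    stage8_out = 64L,            # block 9 (stride-8 skip to the neck)
    stage16_hidden = 96L,        # blocks 11-13
    stage16_out = 128L,          # block 15 (stride-16 skip)
    stage32 = c(128L, 256L),     # blocks 17, 18
    sppf_hidden = 128L,
    sppf_out = 256L,
    neck = c(p4_fuse = 128L, p3_out = 64L, p4_down = 64L, p4_out = 128L,
             p5_down = 128L, p5_out = 256L),
    head_width = 64L
  )
}

#' Assemble the simplified fruit-detection topology
#'
#' Builds the 32-block backbone/neck graph of the simplified anchor-free
#' detector: stride-2 convs at blocks 0, 1, 26 and 29; downsampling
#' max-pools at 4, 10 and 16; 1x1 convs at 2, 5, 7, 9, 11, 13, 15, 17, 22,
#' 25, 28 and 31; 3x3 stride-1 convs at 3, 6, 12 and 18; backbone
#' concatenations at 8 (joining 5 and 7) and 14 (joining 11 and 13); SPPF at
#' 19; upsamples at 20 and 23; and PAN/FPN neck concatenations at 21, 24, 27
#' and 30. Blocks 25, 28 and 31 feed the decoupled detect head at strides
#' 8, 16 and 32.
#'
#' @param num_classes Number of object classes (>= 1).
#' @param input_size Square input size in pixels; must be a positive
#'   multiple of 32 (the product of the network strides).
#'
#' @return A `fruit_topology` object: a tibble of [layer_spec()] blocks plus
#'   head metadata.
#' @export
#' @examples
#' topo <- build_simplified(num_classes = 3, input_size = 640)
#' shape_trace(topo)
build_simplified <- function(num_classes = 3L, input_size = 640L) {
  if (num_classes < 1L) abort("num_classes must be >= 1")
  if (input_size <= 0 || input_size %% 32L != 0L) {
    abort(sprintf(paste0(
      "input_size must be a positive multiple of 32 (the cumulative ",
      "stride of the stride-8/16/32 detection scales); got %s"), input_size))
  }
  s <- simplified_schedule()
  b <- dplyr::bind_rows(
    layer_spec(0, "conv", 3, 2, in_channels = 3, out_channels = s$stem[1]),
    layer_spec(1, "conv", 3, 2, in_channels = s$stem[1], out_channels = s$stem[2]),
    layer_spec(2, "conv", 1, 1, in_channels = s$stem[2], out_channels = s$stem[2]),
    layer_spec(3, "conv", 3, 1, in_channels = s$stem[2], out_channels = s$stem[2]),
    layer_spec(4, "maxpool", 2, 2),
    layer_spec(5, "conv", 1, 1, in_channels = s$stem[2], out_channels = s$stage8_hidden),
    layer_spec(6, "conv", 3, 1, in_channels = s$stage8_hidden, out_channels = s$stage8_hidden),
    layer_spec(7, "conv", 1, 1, in_channels = s$stage8_hidden, out_channels = s$stage8_hidden),
    layer_spec(8, "concat", sources = c(5, 7)),
    layer_spec(9, "conv", 1, 1, in_channels = 2L * s$stage8_hidden, out_channels = s$stage8_out),
    layer_spec(10, "maxpool", 2, 2),
    layer_spec(11, "conv", 1, 1, in_channels = s$stage8_out, out_channels = s$stage16_hidden),
    layer_spec(12, "conv", 3, 1, in_channels = s$stage16_hidden, out_channels = s$stage16_hidden),
    layer_spec(13, "conv", 1, 1, in_channels = s$stage16_hidden, out_channels = s$stage16_hidden),
    layer_spec(14, "concat", sources = c(11, 13)),
    layer_spec(15, "conv", 1, 1, in_channels = 2L * s$stage16_hidden, out_channels = s$stage16_out),
    layer_spec(16, "maxpool", 2, 2),
    layer_spec(17, "conv", 1, 1, in_channels = s$stage16_out, out_channels = s$stage32[1]),
    layer_spec(18, "conv", 3, 1, in_channels = s$stage32[1], out_channels = s$stage32[2]),
    layer_spec(19, "sppf", 5, 1, in_channels = s$stage32[2], out_channels = s$sppf_out,
               hidden_channels = s$sppf_hidden),
    layer_spec(20, "upsample"),
    layer_spec(21, "concat", sources = c(20, 15)),
    layer_spec(22, "conv", 1, 1, in_channels = s$sppf_out + s$stage16_out,
               out_channels = s$neck[["p4_fuse"]]),
    layer_spec(23, "upsample"),
    layer_spec(24, "concat", sources = c(23, 9)),
    layer_spec(25, "conv", 1, 1, in_channels = s$neck[["p4_fuse"]] + s$stage8_out,
               out_channels = s$neck[["p3_out"]]),
    layer_spec(26, "conv", 3, 2, in_channels = s$neck[["p3_out"]],
               out_channels = s$neck[["p4_down"]]),
    layer_spec(27, "concat", sources = c(26, 22)),
    layer_spec(28, "conv", 1, 1, in_channels = s$neck[["p4_down"]] + s$neck[["p4_fuse"]],
               out_channels = s$neck[["p4_out"]]),
    layer_spec(29, "conv", 3, 2, in_channels = s$neck[["p4_out"]],
               out_channels = s$neck[["p5_down"]]),
    layer_spec(30, "concat", sources = c(29, 19)),
    layer_spec(31, "conv", 1, 1, in_channels = s$neck[["p5_down"]] + s$sppf_out,
               out_channels = s$neck[["p5_out"]])
  )
  new_fruit_topology(b, detect_scales = c(25L, 28L, 31L),
                     num_classes = num_classes, input_size = input_size,
                     head_width = s$head_width)
}

#' @export
print.fruit_topology <- function(x, ...) {
  cat(sprintf("<fruit_topology> %d blocks, %d classes, input %dx%d\n",
              nrow(x$blocks), x$num_classes, x$input_size, x$input_size))
  if (length(x$detect_scales)) {
    cat(sprintf("detect head at blocks %s (reg_max = %d, branch width = %d)\n",
                paste(x$detect_scales, collapse = "/"), x$reg_max, x$head_width))
  }
  cat(sprintf("parameters: %s  |  module census: %d layers\n",
              format(count_params(x), big.mark = ","), module_census(x)))
  invisible(x)
}

# channels entering the head at each detect scale
head_in_channels <- function(topology) {
  idx <- match(topology$detect_scales, topology$blocks$index)
  topology$blocks$out_channels[idx]
}

#' Enumerate every weight container of a topology
#'
#' One row per convolution, covering the 32 backbone/neck blocks, the two
#' convs inside the SPPF block, and the six convs of each detect-head scale.
#' Parameter counts follow the i x k x k x o + o convention with the bias
#' slot taken by the batch-norm scale/shift pair (2o) on normalized convs
#' and by a plain bias (o) on the final prediction convs.
#'
#' @param topology A `fruit_topology`.
#' @return A tibble with columns `part`, `name`, `in_channels`, `kernel`,
#'   `out_channels`, `batch_norm` and `params`.
#' @export
param_table <- function(topology) {
  stopifnot(inherits(topology, "fruit_topology"))
  rows <- list()
  for (i in seq_len(nrow(topology$blocks))) {
    blk <- topology$blocks[i, ]
    if (blk$kind == "conv") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        part = "body", name = sprintf("block%d", blk$index),
        in_channels = blk$in_channels, kernel = blk$kernel,
        out_channels = blk$out_channels, batch_norm = blk$batch_norm)
    } else if (blk$kind == "sppf") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        part = "body",
        name = sprintf("block%d.cv%d", blk$index, 1:2),
        in_channels = c(blk$in_channels, 4L * blk$hidden_channels),
        kernel = 1L,
        out_channels = c(blk$hidden_channels, blk$out_channels),
        batch_norm = TRUE)
    }
  }
  if (length(topology$detect_scales)) {
    nc <- topology$num_classes
    w <- topology$head_width
    r4 <- 4L * topology$reg_max
    for (s in seq_along(topology$detect_scales)) {
      ci <- head_in_channels(topology)[s]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        part = "head",
        name = sprintf("detect%d.%s", s,
                       c("box1", "box2", "box3", "cls1", "cls2", "cls3")),
        in_channels = c(ci, w, w, ci, w, w),
        kernel = c(3L, 3L, 1L, 3L, 3L, 1L),
        out_channels = c(w, w, r4, w, w, nc),
        batch_norm = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$params <- out$in_channels * out$kernel^2 * out$out_channels +
    out$out_channels + ifelse(out$batch_norm, out$out_channels, 0L)
  out
}

#' Count trainable parameters of a topology
#'
#' Sums, over every convolution, i x k x k x o weights plus o bias-like
#' terms, with batch-normalized convs contributing the scale/shift pair
#' (2o, no conv bias) and bare convs a single bias. Pooling, upsampling and
#' concatenation contribute nothing.
#'
#' @param topology A `fruit_topology`.
#' @return Integer total parameter count.
#' @export
#' @examples
#' count_params(build_simplified(3, 640))  # 1789657, i.e. 1.8M
count_params <- function(topology) {
  as.integer(sum(param_table(topology)$params))
}

# modules contributed by one block under the fused module-enumeration
# convention (see module_census)
.module_counts <- c(conv = 2L, maxpool = 2L, upsample = 1L, concat = 1L,
                    sppf = 6L)

#' Count layers under the model-summary convention
#'
#' Reports the "layers" figure of a topology under the fused
#' module-enumeration convention of the reference training framework: every
#' named module in the model tree counts once, batch-norms are folded into
#' their convolutions, and the activation is a single shared module counted
#' once per model. Under this convention each conv block contributes 2
#' modules (block wrapper + conv primitive), each downsampling pool 2, each
#' upsample or concatenation 1, the SPPF block 6, and the decoupled head 41;
#' the model wrapper, its sequential container and the shared activation add
#' a constant 3. The same enumeration applied to the reference YOLOv8n
#' block table yields its published 168 layers ([reference_module_census()]),
#' which calibrates the convention.
#'
#' @param topology A `fruit_topology`.
#' @return Integer module count.
#' @export
#' @examples
#' module_census(build_simplified(3, 640))  # 104
module_census <- function(topology) {
  stopifnot(inherits(topology, "fruit_topology"))
  n <- sum(.module_counts[topology$blocks$kind])
  if (length(topology$detect_scales)) n <- n + .detect_module_count()
  n + 3L  # model wrapper + sequential container + shared activation
}

# decoupled head: per scale one sequential of Conv, Conv, prediction conv
# (1 + 2 + 2 + 1 = 6) per branch; each branch list adds 1; the
# distribution-focal decoder adds 2; the head wrapper 1.
.detect_module_count <- function() {
  per_scale <- 6L
  branch <- 1L + 3L * per_scale
  1L + 2L * branch + 2L
}

# fused module count of a C2f block with n inner bottlenecks: wrapper +
# two convs (2 each) + module list + n x (bottleneck wrapper + two convs)
.c2f_module_count <- function(n) 6L + 5L * n

#' Module census of the reference YOLOv8n architecture
#'
#' Assembles the published YOLOv8n block table (convolutions, C2f blocks
#' with their bottleneck repeats, SPPF, upsamples, concatenations and the
#' decoupled head) and applies the same fused module-enumeration convention
#' as [module_census()]. Used to calibrate the layer-count convention
#' against its published summary figure of 168 layers.
#'
#' @return Integer module count (168).
#' @export
reference_module_census <- function() {
  kinds <- c("conv", "conv", "c2f", "conv", "c2f", "conv", "c2f", "conv",
             "c2f", "sppf", "upsample", "concat", "c2f", "upsample",
             "concat", "c2f", "conv", "concat", "c2f", "conv", "concat",
             "c2f", "detect")
  c2f_reps <- c(1L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)  # in order of appearance
  n <- 0L
  j <- 0L
  for (k in kinds) {
    n <- n + switch(k,
      conv = .module_counts[["conv"]],
      sppf = .module_counts[["sppf"]],
      upsample = 1L,
      concat = 1L,
      c2f = { j <- j + 1L; .c2f_module_count(c2f_reps[j]) },
      detect = .detect_module_count())
  }
  n + 3L
}

#' Trace per-block feature-map shapes through a topology
#'
#' Propagates a `height x width x channels` input through every block:
#' stride-2 blocks halve the spatial size, SPPF and stride-1 convs preserve
#' it, upsamples double it, and concatenations sum their sources' channels
#' (which must agree spatially).
#'
#' @param topology A `fruit_topology`.
#' @param height,width Input spatial size in pixels (default: the
#'   topology's `input_size`); must be multiples of 32.
#' @param channels Input channel count.
#' @return A tibble with one row per block (`index`, `kind`, `height`,
#'   `width`, `channels`). The rows for the detect-scale blocks carry the
#'   stride-8/16/32 map sizes.
#' @export
#' @examples
#' topo <- build_simplified(3, 640)
#' subset(shape_trace(topo), index %in% topo$detect_scales)
shape_trace <- function(topology, height = topology$input_size,
                        width = topology$input_size, channels = 3L) {
  stopifnot(inherits(topology, "fruit_topology"))
  height <- as.integer(height); width <- as.integer(width)
  channels <- as.integer(channels)
  if (height %% 32L != 0L || width %% 32L != 0L) {
    abort("input spatial size must be a multiple of 32")
  }
  blocks <- topology$blocks
  shapes <- vector("list", nrow(blocks))
  get_src <- function(i, blk) {
    src <- blk$sources[[1]]
    if (length(src) == 0L) {
      if (i == 1L) list(list(h = height, w = width, c = channels))
      else shapes[i - 1L]
    } else {
      lapply(src, function(s) shapes[[match(s, blocks$index)]])
    }
  }
  for (i in seq_len(nrow(blocks))) {
    blk <- blocks[i, ]
    ins <- get_src(i, blk)
    s0 <- ins[[1]]
    shapes[[i]] <- switch(blk$kind,
      conv = {
        p <- blk$kernel %/% 2L
        list(h = (s0$h + 2L * p - blk$kernel) %/% blk$stride + 1L,
             w = (s0$w + 2L * p - blk$kernel) %/% blk$stride + 1L,
             c = blk$out_channels)
      },
      maxpool = list(h = s0$h %/% blk$stride, w = s0$w %/% blk$stride,
                     c = s0$c),
      upsample = list(h = 2L * s0$h, w = 2L * s0$w, c = s0$c),
      sppf = list(h = s0$h, w = s0$w, c = blk$out_channels),
      concat = {
        hs <- vapply(ins, `[[`, 0L, "h")
        ws <- vapply(ins, `[[`, 0L, "w")
        if (length(unique(hs)) > 1L || length(unique(ws)) > 1L) {
          abort(sprintf(
            "block %d: concat sources have mismatched spatial sizes (%s)",
            blk$index,
            paste(sprintf("%dx%d", hs, ws), collapse = " vs ")))
        }
        list(h = hs[1], w = ws[1], c = sum(vapply(ins, `[[`, 0L, "c")))
      })
  }
  tibble::tibble(
    index = blocks$index, kind = blocks$kind,
    height = vapply(shapes, `[[`, 0L, "h"),
    width = vapply(shapes, `[[`, 0L, "w"),
    channels = vapply(shapes, function(s) as.integer(s$c), 0L))
}

#' Shape arithmetic of the SPPF block
#'
#' The serial spatial-pyramid-pooling block applies one 1x1 conv down to
#' `hidden_channels`, three chained 5x5 stride-1 max-pools (receptive
#' fields 5, 9 and 13), concatenates the conv output with all three pool
#' outputs (4 x hidden channels) and fuses with a final 1x1 conv. Spatial
#' size is preserved throughout.
#'
#' @param height,width,channels Input feature-map shape.
#' @param hidden_channels Width of the internal 1x1 projection.
#' @param out_channels Width of the fused output (default `channels`).
#' @return A tibble of the internal stage shapes (`stage`, `height`,
#'   `width`, `channels`), ending with the block output.
#' @export
#' @examples
#' sppf_block(20, 20, 256, hidden_channels = 128)
sppf_block <- function(height, width, channels, hidden_channels,
                       out_channels = channels) {
  if (hidden_channels <= 0) abort("hidden_channels must be positive")
  tibble::tibble(
    stage = c("input", "cv1", "pool1", "pool2", "pool3", "concat", "cv2"),
    height = as.integer(height), width = as.integer(width),
    channels = as.integer(c(channels, hidden_channels, hidden_channels,
                            hidden_channels, hidden_channels,
                            4L * hidden_channels, out_channels)))
}
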