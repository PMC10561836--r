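#' @rdname export_graph
#' @export
graph_census <- function(topology) {
  nodes <- build_graph_nodes(topology)
  census_from_ops(vapply(nodes, `[[`, "", "op_type"))
}

.census_ops <- c("Conv", "Concat", "Maxpool", "Mul", "Sigmoid", "Resize",
                 "Reshape", "Transpose", "Add", "Slice")

census_from_ops <- function(ops) {
  ops[ops == "MaxPool"] <- "Maxpool"  # report under the census spelling
  n <- vapply(.census_ops, function(o) sum(ops == o), 0L)
  tibble::tibble(op = .census_ops, n = unname(n))
}

# One node per exported operator: each convolution is a single Conv node,
# each SiLU activation decomposes into one Sigmoid and one Mul, each
# upsample is a Resize, each pooling a MaxPool. The head contributes, per
# scale, six Conv nodes with four SiLUs, a box/class Concat and a Reshape;
# the three scales are then concatenated and transposed into the output
# layout.
build_graph_nodes <- function(topology) {
  stopifnot(inherits(topology, "fruit_topology"))
  nodes <- list()
  emit <- function(name, op, inputs, outputs) {
    nodes[[length(nodes) + 1L]] <<- list(name = name, op_type = op,
                                         inputs = inputs, outputs = outputs)
  }
  emit_conv_silu <- function(prefix, input, act, weight = paste0(prefix, ".w")) {
    emit(paste0(prefix, "/Conv"), "Conv", c(input, weight), paste0(prefix, ".conv"))
    if (!act) return(paste0(prefix, ".conv"))
    emit(paste0(prefix, "/Sigmoid"), "Sigmoid", paste0(prefix, ".conv"),
         paste0(prefix, ".sig"))
    emit(paste0(prefix, "/Mul"), "Mul",
         c(paste0(prefix, ".conv"), paste0(prefix, ".sig")),
         paste0(prefix, ".out"))
    paste0(prefix, ".out")
  }
  blocks <- topology$blocks
  out_of <- character(nrow(blocks))
  src_tensors <- function(i, blk) {
    src <- blk$sources[[1]]
    if (length(src) == 0L) {
      if (i == 1L) "images" else out_of[i - 1L]
    } else {
      out_of[match(src, blocks$index)]
    }
  }
  for (i in seq_len(nrow(blocks))) {
    blk <- blocks[i, ]
    ins <- src_tensors(i, blk)
    id <- sprintf("b%d", blk$index)
    out_of[i] <- switch(blk$kind,
      conv = emit_conv_silu(id, ins, blk$activation),
      maxpool = {
        emit(paste0(id, "/MaxPool"), "MaxPool", ins, paste0(id, ".out"))
        paste0(id, ".out")
      },
      upsample = {
        emit(paste0(id, "/Resize"), "Resize", ins, paste0(id, ".out"))
        paste0(id, ".out")
      },
      concat = {
        emit(paste0(id, "/Concat"), "Concat", ins, paste0(id, ".out"))
        paste0(id, ".out")
      },
      sppf = {
        t1 <- emit_conv_silu(paste0(id, ".cv1"), ins, TRUE)
        p <- t1
        pools <- character(3)
        for (k in 1:3) {
          emit(sprintf("%s/MaxPool_%d", id, k), "MaxPool", p,
               sprintf("%s.p%d", id, k))
          p <- sprintf("%s.p%d", id, k)
          pools[k] <- p
        }
        emit(paste0(id, "/Concat"), "Concat", c(t1, pools), paste0(id, ".cat"))
        emit_conv_silu(paste0(id, ".cv2"), paste0(id, ".cat"), TRUE)
      })
  }
  scale_outs <- character(length(topology$detect_scales))
  for (s in seq_along(topology$detect_scales)) {
    feat <- out_of[match(topology$detect_scales[s], blocks$index)]
    hid <- sprintf("head%d", s)
    box <- feat
    for (j in 1:3) {
      box <- emit_conv_silu(sprintf("%s.box%d", hid, j), box, act = j < 3)
    }
    cls <- feat
    for (j in 1:3) {
      cls <- emit_conv_silu(sprintf("%s.cls%d", hid, j), cls, act = j < 3)
    }
    emit(paste0(hid, "/Concat"), "Concat", c(box, cls), paste0(hid, ".cat"))
    emit(paste0(hid, "/Reshape"), "Reshape", paste0(hid, ".cat"),
         paste0(hid, ".flat"))
    scale_outs[s] <- paste0(hid, ".flat")
  }
  if (length(scale_outs)) {
    emit("head/Concat", "Concat", scale_outs, "head.cat")
    emit("head/Transpose", "Transpose", "head.cat", "output0")
  }
  nodes
}

#' Export a topology as an interchange operator graph
#'
#' Writes the full compute graph of the detector, decomposed into
#' interchange-format operators (ONNX vocabulary): one `Conv` node per
#' convolution, `Sigmoid` + `Mul` per SiLU activation, `MaxPool` per
#' pooling, `Resize` per upsample, `Concat` per concatenation, plus the
#' head's `Reshape`/`Transpose` output plumbing. The file is JSON with a
#' node list and weight-tensor dimensions, suitable for auditing which
#' operators a deployment runtime must support.
#'
#' `graph_census()` predicts the operator census from the topology without
#' writing a file; [read_graph_census()] recounts it from an exported file.
#'
#' @param topology A `fruit_topology`.
#' @param path File to write (JSON).
#' @return The operator census tibble (`op`, `n`), invisibly for
#'   `export_graph()`.
#' @export
#' @examples
#' topo <- build_simplified(3, 640)
#' graph_census(topo)
export_graph <- function(topology, path) {
  nodes <- build_graph_nodes(topology)
  pt <- param_table(topology)
  initializers <- purrr::pmap(
    list(pt$name, pt$in_channels, pt$kernel, pt$out_channels, pt$batch_norm),
    function(name, i, k, o, bn) {
      list(name = name,
           dims = c(o, i, k, k),
           aux = if (bn) c(scale = o, shift = o) else c(bias = o))
    })
  doc <- list(
    format = "simplifruit-operator-graph",
    operator_set = "onnx-compatible",
    input = list(name = "images",
                 dims = c(1L, 3L, topology$input_size, topology$input_size)),
    num_classes = topology$num_classes,
    reg_max = topology$reg_max,
    nodes = nodes,
    initializers = initializers
  )
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("cannot write graph: no directory %s", dir))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(census_from_ops(vapply(nodes, `[[`, "", "op_type")))
}

#' Recount operators from an exported graph file
#'
#' Independently walks the serialized node list of a graph written by
#' [export_graph()] and tallies operator types, so the census of the file
#' on disk can be compared with the census predicted from the topology.
#'
#' @param path Path to an exported graph JSON file.
#' @return A tibble (`op`, `n`) over the audited operator vocabulary.
#' @export
read_graph_census <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such graph file: %s", path))
  doc <- jsonlite::read_json(path)
  census_from_ops(vapply(doc$nodes, function(n) n$op_type, ""))
}
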