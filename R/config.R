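#' Read a topology from a YAML config
#'
#' Loads a declarative block list (the format of the canonical
#' `simplified.yaml` shipped in `inst/extdata`) into a `fruit_topology`.
#'
#' @param path YAML file; defaults to the canonical simplified topology.
#' @param num_classes,input_size Optional overrides of the config values.
#' @return A `fruit_topology`.
#' @export
#' @examples
#' topo <- read_topology_config()
#' count_params(topo)
read_topology_config <- function(path = simplified_config_path(),
                                 num_classes = NULL, input_size = NULL) {
  cfg <- yaml::read_yaml(path)
  blocks <- dplyr::bind_rows(lapply(cfg$blocks, function(b) {
    layer_spec(b$index, b$kind,
               kernel = b$kernel %||% 0L, stride = b$stride %||% 1L,
               sources = unlist(b$sources) %||% integer(),
               in_channels = b[["in"]] %||% NA_integer_,
               out_channels = b$out %||% NA_integer_,
               hidden_channels = b$hidden %||% NA_integer_)
  }))
  nc <- num_classes %||% cfg$num_classes
  isz <- input_size %||% cfg$input_size
  if (isz %% 32L != 0L) abort("input_size must be a multiple of 32")
  new_fruit_topology(blocks, detect_scales = unlist(cfg$detect_scales),
                     num_classes = nc, input_size = isz,
                     reg_max = cfg$reg_max %||% 16L,
                     head_width = cfg$head_width %||% 64L,
                     width_multiple = cfg$width_multiple %||% 0.5,
                     depth_multiple = cfg$depth_multiple %||% 0.33)
}

#' @rdname read_topology_config
#' @export
simplified_config_path <- function() {
  system.file("extdata", "simplified.yaml", package = "simplifruit",
              mustWork = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
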