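#' Network configuration
#'
#' Describes both the attention-enhanced backbone and the residual
#' baseline. The full-scale configuration is the default: 512 x 512 x 3
#' input lifted to 64 channels by the stem and carried unchanged through
#' 8 consecutive side-branch attention blocks before global average
#' pooling and a 2-class linear head. `stem_stride` (default 1, i.e. the
#' full-scale behaviour) lets desk-scale presets downsample once in the
#' stem to keep training cheap.
#'
#' @param input_size `c(H, W, channels)`.
#' @param stem_channels channels after the stem convolution.
#' @param n_blocks number of side-branch attention blocks.
#' @param branch_reduction branch channel-reduction ratio (at least 1).
#' @param branch_stride branch spatial stride (1 or even); the post-stem
#'   feature map must be divisible by it.
#' @param fusion_mode `"additive"` (element-wise addition of main path and
#'   upsampled branches) or `"gated"` (sigmoid of the branch sum gates the
#'   main path multiplicatively).
#' @param use_channel_attention insert a channel-attention gate after each
#'   block (off by default).
#' @param n_classes at least 2.
#' @param stem_stride stride of the stem convolution.
#' @param stem_pool add a 3x3 stride-2 max pool after the stem (desk-scale
#'   presets use it to enlarge the receptive field cheaply; the full-scale
#'   layout does not pool).
#' @param norm `"batch"` or `"none"` per-block normalization.
#' @param seed seed for weight initialization.
#' @return a `network_config` list.
#' @export
network_config <- function(input_size = c(512L, 512L, 3L),
                           stem_channels = 64L, n_blocks = 8L,
                           branch_reduction = 4L, branch_stride = 2L,
                           fusion_mode = c("additive", "gated"),
                           use_channel_attention = FALSE,
                           n_classes = 2L, stem_stride = 1L,
                           stem_pool = FALSE,
                           norm = c("batch", "none"), seed = 1L) {
  fusion_mode <- match.arg(fusion_mode)
  norm <- match.arg(norm)
  cfg <- list(input_size = as.integer(input_size),
              stem_channels = as.integer(stem_channels),
              n_blocks = as.integer(n_blocks),
              branch_reduction = as.integer(branch_reduction),
              branch_stride = as.integer(branch_stride),
              fusion_mode = fusion_mode,
              use_channel_attention = isTRUE(use_channel_attention),
              n_classes = as.integer(n_classes),
              stem_stride = as.integer(stem_stride),
              stem_pool = isTRUE(stem_pool),
              norm = norm, seed = as.integer(seed))
  bad <- character(0)
  if (length(cfg$input_size) != 3L || any(cfg$input_size < 1L))
    bad <- c(bad, "input_size must be c(H, W, channels), all positive")
  fh <- cfg$input_size[1L] / cfg$stem_stride
  fw <- cfg$input_size[2L] / cfg$stem_stride
  if (cfg$stem_pool) { fh <- ceiling(fh / 2); fw <- ceiling(fw / 2) }
  if (cfg$input_size[1L] %% cfg$stem_stride != 0 ||
      cfg$input_size[2L] %% cfg$stem_stride != 0)
    bad <- c(bad, "input size must be divisible by stem_stride")
  else if (fh %% cfg$branch_stride != 0 || fw %% cfg$branch_stride != 0)
    bad <- c(bad, "post-stem feature map must be divisible by branch_stride")
  if (cfg$stem_channels < 1L) bad <- c(bad, "stem_channels must be positive")
  if (cfg$n_blocks < 1L) bad <- c(bad, "n_blocks must be positive")
  if (cfg$branch_reduction < 1L) bad <- c(bad, "branch_reduction must be >= 1")
  if (cfg$n_classes < 2L) bad <- c(bad, "n_classes must be at least 2")
  if (length(bad))
    pn_stop(paste0("invalid network config: ", paste(bad, collapse = "; ")),
            "pneumonet_config_error")
  class(cfg) <- "network_config"
  cfg
}

#' Desk-scale network configuration
#'
#' A small preset for CPU training on 64 x 64 phantoms: 16 stem channels,
#' stem stride 2 plus a stem max pool (16 x 16 feature maps), and 4
#' side-branch blocks.
#'
#' @param input_size,stem_channels,n_blocks,... see [network_config()].
#' @return a `network_config`.
#' @export
desk_network_config <- function(input_size = c(64L, 64L, 1L),
                                stem_channels = 16L, n_blocks = 4L, ...) {
  network_config(input_size = input_size, stem_channels = stem_channels,
                 n_blocks = n_blocks, stem_stride = 2L, stem_pool = TRUE, ...)
}

#' Build the attention-enhanced network
#'
#' Assembles: stem convolution (3x3, `input channels -> stem_channels`)
#' with normalization and ReLU, `n_blocks` side-branch attention blocks
#' (each residual-skip wrapped; optionally each followed by a
#' channel-attention gate), global average pooling to a
#' `stem_channels`-vector, and a linear layer to `n_classes` logits.
#' Initialization is fully seeded: two builds from the same config are
#' parameter-identical.
#'
#' @param config a [network_config()].
#' @return a `pneumonet_model`.
#' @export
build_attention_net <- function(config) {
  if (!inherits(config, "network_config"))
    pn_stop("config must be a network_config", "pneumonet_config_error")
  with_seed(config$seed, {
    units <- list(unit_conv(3L, config$input_size[3L], config$stem_channels,
                            stride = config$stem_stride))
    if (config$norm == "batch") units <- c(units, list(unit_bn(config$stem_channels)))
    units <- c(units, list(unit_relu()))
    if (config$stem_pool) units <- c(units, list(unit_maxpool(3L, 2L, 1L)))
    for (i in seq_len(config$n_blocks)) {
      units <- c(units, list(unit_sideb(config$stem_channels,
                                        config$branch_reduction,
                                        config$branch_stride,
                                        fusion = config$fusion_mode,
                                        skip = TRUE, norm = config$norm)))
      if (config$use_channel_attention)
        units <- c(units, list(unit_chattn(config$stem_channels,
                                           config$branch_reduction)))
    }
    units <- c(units, list(unit_gap(),
                           unit_linear(config$stem_channels, config$n_classes)))
    structure(list(config = config, net = unit_seq(units),
                   arch = "attention"),
              class = "pneumonet_model")
  })
}

#' Build the residual baseline classifier
#'
#' A depth-reduced residual network honouring the canonical layout:
#' 7x7 stride-2 stem convolution, 3x3 stride-2 max pooling, four residual
#' stages (the first stride 1, the rest stride 2, channel count doubling
#' per stage), global average pooling and a linear classification head.
#' `stem_channels` sets the width (64 reproduces the full-scale channel
#' progression of the basic-block layout).
#'
#' @param config a [network_config()]; `n_blocks` is read as residual
#'   blocks per stage (at least 1).
#' @return a `pneumonet_model`.
#' @export
build_resnet_baseline <- function(config) {
  if (!inherits(config, "network_config"))
    pn_stop("config must be a network_config", "pneumonet_config_error")
  s <- config$input_size[1L]
  if (config$input_size[1L] != config$input_size[2L])
    pn_stop("residual baseline expects a square input", "pneumonet_config_error")
  if (s < 32L)
    pn_stop("input too small for 5 spatial downsamplings (need >= 32)",
            "pneumonet_config_error")
  per_stage <- max(1L, config$n_blocks %/% 4L)
  with_seed(config$seed, {
    w <- config$stem_channels
    units <- list(unit_conv(7L, config$input_size[3L], w, stride = 2L),
                  unit_bn(w), unit_relu(), unit_maxpool(3L, 2L, 1L))
    cin <- w
    for (stage in 1:4) {
      cout <- w * 2L^(stage - 1L)
      for (b in seq_len(per_stage)) {
        stride <- if (stage > 1L && b == 1L) 2L else 1L
        units <- c(units, list(unit_resblock(cin, cout, stride)))
        cin <- cout
      }
    }
    units <- c(units, list(unit_gap(), unit_linear(cin, config$n_classes)))
    structure(list(config = config, net = unit_seq(units), arch = "resnet"),
              class = "pneumonet_model")
  })
}

#' Stage-by-stage shape walk of the canonical 50-layer residual network
#'
#' Reports, for a square input, the output shape of every stage of the
#' standard bottleneck layout: 7x7/2 stem convolution with 64 filters,
#' 3x3/2 max pooling, conv2_x through conv5_x (output channels 256, 512,
#' 1024, 2048; spatial size halving from conv3_x on), then global average
#' pooling and the fully connected softmax head. For a 224 px input this
#' walks 112x112x64 -> 56x56x64 -> ... -> 7x7x2048.
#'
#' @param input_size square input side in pixels, at least 32.
#' @param n_classes classes reported for the head.
#' @return data frame with columns `stage`, `H`, `W`, `C`.
#' @export
resnet_shape_walk <- function(input_size = 224L, n_classes = 2L) {
  s <- as.integer(input_size)
  if (s < 32L)
    pn_stop("input too small for 5 spatial downsamplings (need >= 32)",
            "pneumonet_config_error")
  half <- function(n) as.integer(ceiling(n / 2))
  s1 <- half(s)        # conv1, stride 2
  s2 <- half(s1)       # max pool
  data.frame(
    stage = c("conv1", "maxpool", "conv2_x", "conv3_x", "conv4_x", "conv5_x",
              "avgpool", "fc"),
    H = c(s1, s2, s2, half(s2), half(half(s2)), half(half(half(s2))), 1L, 1L),
    W = c(s1, s2, s2, half(s2), half(half(s2)), half(half(half(s2))), 1L, 1L),
    C = c(64L, 64L, 256L, 512L, 1024L, 2048L, 2048L, as.integer(n_classes)),
    stringsAsFactors = FALSE)
}

#' Analytic shape walk of the attention-enhanced network
#'
#' @param config a [network_config()].
#' @return data frame with columns `stage`, `H`, `W`, `C`; blocks preserve
#'   the post-stem shape, pooling collapses it to a `stem_channels`-vector,
#'   and the head emits `n_classes` logits.
#' @export
attention_shape_walk <- function(config) {
  fh <- config$input_size[1L] %/% config$stem_stride
  fw <- config$input_size[2L] %/% config$stem_stride
  if (config$stem_pool) { fh <- as.integer(ceiling(fh / 2))
                          fw <- as.integer(ceiling(fw / 2)) }
  data.frame(
    stage = c("input", "stem",
              sprintf("block%d", seq_len(config$n_blocks)), "gap", "fc"),
    H = c(config$input_size[1L], fh, rep(fh, config$n_blocks), 1L, 1L),
    W = c(config$input_size[2L], fw, rep(fw, config$n_blocks), 1L, 1L),
    C = c(config$input_size[3L], rep(config$stem_channels, config$n_blocks + 1L),
          config$stem_channels, config$n_classes),
    stringsAsFactors = FALSE)
}

#' @export
print.pneumonet_model <- function(x, ...) {
  np <- sum(vapply(collect_param_vec(x$net), length, 0L))
  cat(sprintf("<pneumonet_model> arch=%s input=%s params=%d\n", x$arch,
              paste(x$config$input_size, collapse = "x"), np))
  invisible(x)
}

collect_param_vec <- function(u) {
  out <- u$params
  for (ch in u$children) out <- c(out, collect_param_vec(ch))
  out
}

forward_model <- function(model, x, training = FALSE) {
  r <- forward_unit(model$net, x, training)
  model$net <- r$unit
  list(logits = r$y, cache = r$cache, model = model)
}

#' Predict class logits
#'
#' @param object a `pneumonet_model`.
#' @param newdata an `xray_dataset`, a list of `xray_sample`s, or an
#'   `H x W x C x N` array.
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return `N x n_classes` logit matrix.
#' @export
predict.pneumonet_model <- function(object, newdata, batch_size = 64L, ...) {
  x <- if (is.array(newdata) && length(dim(newdata)) == 4L) newdata
       else as_batch_array(newdata)$x
  n <- dim(x)[4L]
  out <- matrix(0, n, object$config$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    xb <- x[, , , i:j, drop = FALSE]
    out[i:j, ] <- forward_unit(object$net, xb, training = FALSE)$y
    i <- j + 1L
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized file; a JSON sidecar
#' (`<path>.json`) records the network configuration and package version.
#'
#' @param model a `pneumonet_model`.
#' @param path checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(config = unclass(model$config), arch = model$arch,
               package_version = as.character(packageVersion("pneumonet")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pneumonet_model"))
    pn_stop("file does not contain a pneumonet model checkpoint",
            "pneumonet_io_error")
  m
}
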