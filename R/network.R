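#' Mixed-scale dense network configuration
#'
#' Configuration of the compact image-to-image denoiser: a width-1
#' mixed-scale dense (MS-D) network.  Hidden layer `i` consumes the input
#' channels plus *all* previous feature maps (dense connectivity), applies
#' one 3x3 convolution per incoming map with dilation
#' `((i - 1) mod dilation_cycle) + 1`, adds a bias and a ReLU, and emits a
#' single feature map; the output layer is a 1x1 linear map over every
#' feature map and input channel.  Dilations cycling through 1..10 give the
#' network a large receptive field at a very small parameter count
#' (54,662 trainable scalars at depth 100 with 11 input channels and one
#' output), which is what makes overfitting to noise unlikely and removes
#' the need for early stopping.
#'
#' @param depth number of hidden single-feature layers (>= 1).
#' @param in_channels,out_channels positive integers.
#' @param dilation_cycle dilations cycle through `1..dilation_cycle`
#'   (default 10).
#' @param weight_init_seed integer seed for the deterministic weight
#'   initialization.
#' @param pad_mode `"reflect"` (reflect-without-edge, default) or
#'   `"periodic"` (test hook for translation-equivariance checks).
#' @return Object of class `msd_config`.
#' @export
msd_config <- function(depth, in_channels = 1, out_channels = 1,
                       dilation_cycle = 10, weight_init_seed = 1,
                       pad_mode = c("reflect", "periodic")) {
  pad_mode <- match.arg(pad_mode)
  if (depth < 1) stop_invalid("depth must be >= 1")
  if (in_channels < 1 || out_channels < 1)
    stop_invalid("channel counts must be positive")
  if (dilation_cycle < 1) stop_invalid("dilation_cycle must be >= 1")
  structure(list(depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dilation_cycle = as.integer(dilation_cycle),
                 weight_init_seed = as.integer(weight_init_seed),
                 pad_mode = pad_mode),
            class = "msd_config")
}

msd_weight_length <- function(config) {
  as.integer(.msd_n_params_cpp(config$depth, config$in_channels,
                               config$out_channels))
}

#' Build an MS-D denoising model
#'
#' Instantiates the network of an [msd_config] with deterministic
#' He-style initial weights (convolution taps scaled by the fan-in of the
#' layer, final 1x1 layer near zero, biases zero).  The returned model holds
#' the weight vector, the configuration, and — once attached by training —
#' the affine normalization statistics mapping raw reconstructions to the
#' network's working range.
#'
#' @param config an [msd_config].
#' @return Object of class `denoising_model`.
#' @seealso [count_parameters()], [apply_model()], [noise2inverse()]
#' @export
build_msd <- function(config) {
  if (!inherits(config, "msd_config")) stop_invalid("config must be an msd_config")
  nw <- msd_weight_length(config)
  # per-position scale: He-style for conv taps, small for the 1x1 output
  # layer, zero for biases
  sds <- numeric(nw)
  pos <- 1L
  for (i in seq_len(config$depth)) {
    nin <- config$in_channels + i - 1L
    nconv <- 9L * nin
    sds[pos:(pos + nconv - 1L)] <- sqrt(2 / (9 * nin))
    pos <- pos + nconv + 1L  # skip bias (stays 0)
  }
  nmaps <- config$in_channels + config$depth
  for (o in seq_len(config$out_channels)) {
    sds[pos:(pos + nmaps - 1L)] <- sqrt(1 / nmaps) * 0.1
    pos <- pos + nmaps + 1L
  }
  w <- with_seed(config$weight_init_seed, function() rnorm(nw)) * sds
  structure(list(config = config, weights = w,
                 normalization = NULL, provenance = list()),
            class = "denoising_model")
}

#' @export
print.denoising_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("MS-D denoising model: depth %d, %d -> %d channels, dilations 1..%d, %d parameters%s\n",
              cfg$depth, cfg$in_channels, cfg$out_channels, cfg$dilation_cycle,
              count_parameters(x),
              if (is.null(x$normalization)) " (untrained)" else ""))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars:
#' `sum_{i=1}^{depth} (9 (in_channels + i - 1) + 1) +
#'  out_channels (in_channels + depth + 1)`.
#' Independent of image size (convolutional weight sharing).
#'
#' @param model a `denoising_model` or an [msd_config].
#' @return Integer parameter count.
#' @examples
#' count_parameters(msd_config(depth = 100, in_channels = 11))  # 54662
#' @export
count_parameters <- function(model) {
  config <- if (inherits(model, "denoising_model")) model$config else model
  if (!inherits(config, "msd_config")) stop_invalid("need a model or msd_config")
  msd_weight_length(config)
}

#' Assemble a 2.5D input stack
#'
#' Extracts slices `slice_index - context .. slice_index + context` from a
#' volume as the channel stack fed to a 2.5D network.  Out-of-range slice
#' indices are filled by mirror reflection about the boundary excluding the
#' edge slice itself (one below the first slice maps to the second slice),
#' avoiding duplicated edge statistics.
#'
#' @param volume numeric array `depth x N x N`.
#' @param slice_index 1-based index of the centre slice.
#' @param context non-negative integer; the stack has `2 * context + 1`
#'   slices.  `context = 0` is the plain 2D case.
#' @return Numeric array `N x N x (2 * context + 1)` (channels last, the
#'   layout [apply_model()] expects).
#' @export
assemble_25d_input <- function(volume, slice_index, context = 0) {
  d <- dim(volume)
  if (length(d) != 3) stop_invalid("volume must be a depth x N x N array")
  depth <- d[1]
  if (slice_index < 1 || slice_index > depth) stop_invalid("slice_index out of range")
  if (context < 0) stop_invalid("context must be non-negative")
  if (context >= depth)
    stop_invalid("context (", context, ") must be smaller than the volume depth (",
                 depth, ")")
  reflect <- function(s) {
    # mirror about the boundary excluding the edge: 0 -> 2, depth+1 -> depth-1
    while (s < 1 || s > depth) {
      if (s < 1) s <- 2 - s
      if (s > depth) s <- 2 * depth - s
    }
    s
  }
  idx <- vapply(slice_index + (-context):context, reflect, 1)
  out <- array(0, dim = c(d[2], d[3], length(idx)))
  for (k in seq_along(idx)) out[, , k] <- volume[idx[k], , ]
  out
}

#' Apply a denoising model to an image stack
#'
#' Normalizes the input with the model's stored statistics, runs the network
#' forward pass, and de-normalizes the output.  Single-threaded and
#' bitwise deterministic given the weights and input.
#'
#' @param model a trained `denoising_model` (normalization attached).
#' @param input numeric array `N x N x in_channels` (or an `N x N` matrix
#'   when the model has one input channel).
#' @param linear_act if `TRUE`, replace every ReLU by the identity so the
#'   network acts as a linear operator (diagnostic hook).
#' @return Numeric array `N x N x out_channels`.
#' @export
apply_model <- function(model, input, linear_act = FALSE) {
  if (!inherits(model, "denoising_model")) stop_invalid("model must be a denoising_model")
  cfg <- model$config
  if (is.matrix(input)) input <- array(input, dim = c(dim(input), 1L))
  d <- dim(input)
  if (length(d) != 3 || d[1] != d[2])
    stop_invalid("input must be an N x N x channels array")
  if (d[3] != cfg$in_channels)
    stop_invalid("input has ", d[3], " channels; model expects ", cfg$in_channels)
  ns <- model$normalization
  if (is.null(ns))
    ns <- list(input_offset = 0, input_scale = 1, output_offset = 0, output_scale = 1)
  xn <- (input - ns$input_offset) / ns$input_scale
  out <- .msd_forward_cpp(as.numeric(xn), model$weights, d[1], cfg$in_channels,
                          cfg$depth, cfg$out_channels, cfg$dilation_cycle,
                          if (cfg$pad_mode == "periodic") 1L else 0L,
                          isTRUE(linear_act))
  out * ns$output_scale + ns$output_offset
}

# normalization statistics: robust affine map sending the 1st/99th
# percentiles of the training data to [0, 1]
norm_stats <- function(inputs, targets) {
  qi <- quantile(unlist(lapply(inputs, as.vector)), c(0.01, 0.99), names = FALSE)
  qt <- quantile(unlist(lapply(targets, as.vector)), c(0.01, 0.99), names = FALSE)
  si <- qi[2] - qi[1]
  st <- qt[2] - qt[1]
  list(input_offset = qi[1], input_scale = if (si > 0) si else 1,
       output_offset = qt[1], output_scale = if (st > 0) st else 1)
}
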