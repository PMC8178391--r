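#' Training configuration
#'
#' Hyper-parameters of the self-supervised optimization loop.  Defaults are
#' an adaptive-moment stochastic gradient method (Adam) with learning rate
#' 1e-3 and batch size 4; there is no early stopping and no validation split
#' by default, because the network's small parameter count makes overfitting
#' to noise unlikely.  Every random stream (weight initialization, noise,
#' shuffling) has its own explicit seed.
#'
#' @param iterations positive integer number of optimization steps (one
#'   batch per step).
#' @param batch_size positive integer.
#' @param learning_rate positive real.
#' @param shuffle_seed integer seed for the per-epoch data order.
#' @param strategy one of `"static_25d"`, `"dynamic"`, `"multichannel"`.
#' @return Object of class `training_config`.
#' @export
training_config <- function(iterations, batch_size = 4, learning_rate = 1e-3,
                            shuffle_seed = 1,
                            strategy = c("static_25d", "dynamic", "multichannel")) {
  strategy <- match.arg(strategy)
  if (iterations < 1) stop_invalid("iterations must be >= 1")
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  if (learning_rate <= 0) stop_invalid("learning_rate must be positive")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 shuffle_seed = as.integer(shuffle_seed),
                 strategy = strategy),
            class = "training_config")
}

fbp_of_section <- function(sino, idx, filter_name = "ram-lak") {
  fbp_reconstruct(extract_section(sino, idx), filter_name)
}

#' Build self-supervised training pairs
#'
#' Constructs one training example per (section, slice/time) combination
#' from noisy measured data only — no ground truth is ever read, which is
#' the defining property of self-supervised training.  The split scheme must
#' pass [verify_conditions()]; otherwise pair construction is refused, since
#' overlapping sections would train the network to reproduce noise.
#'
#' Strategies:
#' \describe{
#'   \item{`static_25d`}{`noisy_data` is a list of per-slice [sinogram]s
#'     sharing one geometry; the scheme is an angular split.  The input of
#'     pair (j, s) is the 2.5D stack of input-section FBP reconstructions
#'     around slice `s`, the target the single-slice FBP of target section
#'     `j` at slice `s`.}
#'   \item{`dynamic`}{`noisy_data` is a list of per-time-step sinograms of
#'     one interlacing group; the scheme is [dynamic_split()].  The input of
#'     pair `j` is the FBP of time step `j` alone (sparse angles), the
#'     target the FBP of the combined sinogram of the other steps (denser
#'     angles), so the network also learns to remove streak artifacts.}
#'   \item{`multichannel`}{`noisy_data` is a list of per-channel sinograms;
#'     the scheme is a shared angular split.  Inputs and targets are both
#'     full C-channel reconstructions from complementary angular sections.}
#' }
#'
#' @param noisy_data list of [sinogram]s (see strategies above).
#' @param scheme a [split_scheme].
#' @param strategy `"static_25d"`, `"dynamic"` or `"multichannel"`.
#' @param context context slices for 2.5D assembly (static strategy).
#' @param filter_name FBP filter.
#' @return List of pairs; each pair is a list with `input`
#'   (`N x N x C` array), `target` (`N x N x C_out`), `j`, `provenance`.
#' @export
make_training_pairs <- function(noisy_data, scheme,
                                strategy = c("static_25d", "dynamic", "multichannel"),
                                context = 0, filter_name = "ram-lak") {
  strategy <- match.arg(strategy)
  rep_ok <- verify_conditions(scheme)
  if (!rep_ok$condition1_pass || !rep_ok$condition2_pass)
    stop("split scheme violates the self-supervision conditions: ",
         paste(rep_ok$violations, collapse = "; "))
  if (!is.list(noisy_data) || !all(vapply(noisy_data, inherits, TRUE, "sinogram")))
    stop_invalid("noisy_data must be a list of sinograms")
  J <- scheme$J

  if (strategy == "static_25d") {
    if (scheme$unit_kind != "angle") stop_invalid("static strategy needs an angular scheme")
    nsl <- length(noisy_data)
    N <- noisy_data[[1]]$geometry$image_size
    # per-section reconstruction volumes: [slice, x, y]
    in_vol <- lapply(seq_len(J), function(j) {
      v <- array(0, dim = c(nsl, N, N))
      for (s in seq_len(nsl))
        v[s, , ] <- fbp_of_section(noisy_data[[s]], scheme$input_sets[[j]], filter_name)
      v
    })
    tg_rec <- lapply(seq_len(J), function(j)
      lapply(seq_len(nsl), function(s)
        fbp_of_section(noisy_data[[s]], scheme$target_sets[[j]], filter_name)))
    pairs <- list()
    for (j in seq_len(J)) for (s in seq_len(nsl)) {
      pairs[[length(pairs) + 1L]] <- list(
        input = assemble_25d_input(in_vol[[j]], s, context),
        target = array(tg_rec[[j]][[s]], dim = c(N, N, 1L)),
        j = j, provenance = list(slice = s))
    }
    return(pairs)
  }

  if (strategy == "dynamic") {
    if (scheme$unit_kind != "time_step") stop_invalid("dynamic strategy needs a time-step scheme")
    if (length(noisy_data) != scheme$num_units)
      stop_invalid("need one sinogram per time step in the group")
    N <- noisy_data[[1]]$geometry$image_size
    pairs <- lapply(seq_len(J), function(j) {
      stopifnot(length(scheme$input_sets[[j]]) == 1L)
      input <- fbp_reconstruct(noisy_data[[scheme$input_sets[[j]][1]]], filter_name)
      comb <- combine_time_steps(noisy_data[scheme$target_sets[[j]]])
      target <- fbp_reconstruct(comb, filter_name)
      list(input = array(input, dim = c(N, N, 1L)),
           target = array(target, dim = c(N, N, 1L)),
           j = j, provenance = list(time_step = scheme$input_sets[[j]][1]))
    })
    return(pairs)
  }

  # multichannel
  if (scheme$unit_kind != "angle") stop_invalid("multichannel strategy needs an angular scheme")
  C <- length(noisy_data)
  N <- noisy_data[[1]]$geometry$image_size
  pairs <- lapply(seq_len(J), function(j) {
    input <- array(0, dim = c(N, N, C))
    target <- array(0, dim = c(N, N, C))
    for (c0 in seq_len(C)) {
      input[, , c0] <- fbp_of_section(noisy_data[[c0]], scheme$input_sets[[j]], filter_name)
      target[, , c0] <- fbp_of_section(noisy_data[[c0]], scheme$target_sets[[j]], filter_name)
    }
    list(input = input, target = target, j = j, provenance = list(section = j))
  })
  pairs
}

#' Train a denoising model on self-supervised pairs
#'
#' Minimizes the mean squared error between the network output on each input
#' reconstruction and the corresponding target reconstruction with Adam.
#' The data order is reshuffled every epoch from `shuffle_seed`; the loss
#' history records the mean per-sample loss of every epoch (normalized
#' units).  Fully reproducible from the seeds under the single-threaded
#' execution contract; training aborts with a diagnostic if the loss turns
#' non-finite.
#'
#' @param pairs output of [make_training_pairs()].
#' @param model a `denoising_model` from [build_msd()] (channel counts must
#'   match the pairs).
#' @param config a [training_config].
#' @return The trained `denoising_model`, with `loss_history` (per epoch)
#'   and provenance attached.
#' @export
train <- function(pairs, model, config) {
  if (!inherits(model, "denoising_model")) stop_invalid("model must be a denoising_model")
  if (!inherits(config, "training_config")) stop_invalid("config must be a training_config")
  if (length(pairs) == 0) stop_invalid("no training pairs")
  cfg <- model$config
  d_in <- dim(pairs[[1]]$input)
  d_tg <- dim(pairs[[1]]$target)
  if (d_in[3] != cfg$in_channels)
    stop_invalid("pairs have ", d_in[3], " input channels; model expects ", cfg$in_channels)
  if (d_tg[3] != cfg$out_channels)
    stop_invalid("pairs have ", d_tg[3], " target channels; model expects ", cfg$out_channels)
  N <- d_in[1]
  pad <- if (cfg$pad_mode == "periodic") 1L else 0L

  ns <- norm_stats(lapply(pairs, `[[`, "input"), lapply(pairs, `[[`, "target"))
  xin <- lapply(pairs, function(p) as.numeric((p$input - ns$input_offset) / ns$input_scale))
  tgt <- lapply(pairs, function(p) as.numeric((p$target - ns$output_offset) / ns$output_scale))

  w <- model$weights
  m <- numeric(length(w)); v <- numeric(length(w))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  npairs <- length(pairs)
  order_idx <- integer(0)
  epoch <- 0L
  epoch_losses <- numeric(0)
  history <- numeric(0)

  for (it in seq_len(config$iterations)) {
    batch <- integer(config$batch_size)
    for (b in seq_len(config$batch_size)) {
      if (length(order_idx) == 0) {
        if (epoch > 0L) {
          history <- c(history, mean(epoch_losses))
          epoch_losses <- numeric(0)
        }
        epoch <- epoch + 1L
        order_idx <- with_seed(config$shuffle_seed + epoch, function() sample.int(npairs))
      }
      batch[b] <- order_idx[1]
      order_idx <- order_idx[-1]
    }
    g <- numeric(length(w))
    loss <- 0
    for (b in batch) {
      lg <- .msd_loss_grad_cpp(xin[[b]], tgt[[b]], w, N, cfg$in_channels,
                               cfg$depth, cfg$out_channels, cfg$dilation_cycle,
                               pad, FALSE)
      g <- g + lg$grad
      loss <- loss + lg$loss
    }
    g <- g / config$batch_size
    loss <- loss / config$batch_size
    if (!is.finite(loss))
      stop("training diverged: non-finite loss at iteration ", it,
           " (learning rate too high or degenerate normalization)")
    epoch_losses <- c(epoch_losses, loss)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^it)
    vh <- v / (1 - b2^it)
    w <- w - lr * mh / (sqrt(vh) + eps)
  }
  if (length(epoch_losses)) history <- c(history, mean(epoch_losses))

  model$weights <- w
  model$normalization <- ns
  model$loss_history <- history
  model$provenance <- list(iterations = config$iterations,
                           batch_size = config$batch_size,
                           learning_rate = config$learning_rate,
                           shuffle_seed = config$shuffle_seed,
                           strategy = config$strategy,
                           epochs = length(history))
  model
}

#' Fit a self-supervised tomographic denoiser
#'
#' The main modelling entry point.  Given noisy measured sinograms and a
#' [split_scheme], it reconstructs complementary sections by filtered
#' backprojection, builds training pairs, and fits a mixed-scale dense
#' network by minimizing the self-supervised loss
#' `sum_j || CNN(x_{input(j)}) - x_{target(j)} ||^2`.  Because the noise in
#' the two reconstructions of a pair is independent and zero-mean, this loss
#' equals (in expectation) the supervised loss against the unavailable
#' noise-free reconstructions plus a constant noise-variance term, so
#' minimizing it trains a genuine denoiser without clean data.
#'
#' @param data list of [sinogram]s: per-slice sinograms for
#'   `strategy = "static_25d"`, per-time-step for `"dynamic"`, per-channel
#'   for `"multichannel"`.
#' @param scheme a [split_scheme]; defaults to [angular_split()] with
#'   `J = 2` (static/multichannel) or [dynamic_split()] over all steps.
#' @param strategy training strategy, see [make_training_pairs()].
#' @param context 2.5D context slices (static strategy only).
#' @param depth,dilation_cycle network shape passed to [msd_config()]
#'   (ignored when `model` is given).
#' @param model optionally a prebuilt `denoising_model`.
#' @param iterations,batch_size,learning_rate,shuffle_seed optimization
#'   settings, see [training_config()].
#' @param weight_init_seed seed for the initial weights.
#' @param filter_name FBP filter used for all reconstructions.
#' @return An object of class `noise2inverse` with components `model`
#'   (trained `denoising_model`), `scheme`, `strategy`, `context`,
#'   `loss_history`, `npairs` and `call`.  Use [predict.noise2inverse()] to
#'   denoise, `plot()` for the loss curve, `coef()` for the weight vector.
#' @examples
#' \donttest{
#' ph <- static_phantom(32, depth = 2, num_features = 3, seed = 7)
#' g <- make_geometry(64, pi, num_detector_pixels = 32, image_size = 32)
#' nc <- noise_config(2000, seed = 11)
#' sinos <- lapply(1:2, function(s)
#'   simulate_noisy_sinogram(forward_project(volume_slice(ph, s), g), nc, seed = s))
#' fit <- noise2inverse(sinos, angular_split(64, 2), strategy = "static_25d",
#'                      depth = 5, iterations = 50, shuffle_seed = 3)
#' den <- predict(fit, sinos)
#' }
#' @export
noise2inverse <- function(data, scheme = NULL,
                          strategy = c("static_25d", "dynamic", "multichannel"),
                          context = 0, depth = 25, dilation_cycle = 10,
                          model = NULL, iterations = 1000, batch_size = 4,
                          learning_rate = 1e-3, shuffle_seed = 1,
                          weight_init_seed = 1, filter_name = "ram-lak") {
  strategy <- match.arg(strategy)
  if (is.null(scheme)) {
    scheme <- if (strategy == "dynamic") dynamic_split(length(data))
              else angular_split(length(data[[1]]$geometry$angles), 2)
  }
  pairs <- make_training_pairs(data, scheme, strategy, context, filter_name)
  if (is.null(model)) {
    in_ch <- dim(pairs[[1]]$input)[3]
    out_ch <- dim(pairs[[1]]$target)[3]
    model <- build_msd(msd_config(depth, in_ch, out_ch, dilation_cycle,
                                  weight_init_seed))
  }
  tc <- training_config(iterations, batch_size, learning_rate, shuffle_seed,
                        strategy)
  model <- train(pairs, model, tc)
  structure(list(model = model, scheme = scheme, strategy = strategy,
                 context = context, filter_name = filter_name,
                 loss_history = model$loss_history, npairs = length(pairs),
                 call = match.call()),
            class = "noise2inverse")
}

#' @export
print.noise2inverse <- function(x, ...) {
  cat("Self-supervised tomographic denoiser (Noise2Inverse)\n")
  cat(sprintf("  strategy: %s, %d training pairs, J = %d sections\n",
              x$strategy, x$npairs, x$scheme$J))
  print(x$model)
  if (length(x$loss_history))
    cat(sprintf("  final epoch loss: %.4g (%d epochs)\n",
                tail(x$loss_history, 1), length(x$loss_history)))
  invisible(x)
}

#' @export
summary.noise2inverse <- function(object, ...) {
  cat("Self-supervised tomographic denoiser (Noise2Inverse)\n\n")
  cat("Call: "); print(object$call)
  cat(sprintf("\nStrategy %s with %d sections over %d %ss; context %d; %d pairs/epoch\n",
              object$strategy, object$scheme$J, object$scheme$num_units,
              object$scheme$unit_kind, object$context, object$npairs))
  pr <- object$model$provenance
  cat(sprintf("Optimizer: Adam, lr %.3g, batch %d, %d iterations (%d epochs)\n",
              pr$learning_rate, pr$batch_size, pr$iterations, pr$epochs))
  cat(sprintf("Network: depth %d, %d -> %d channels, %d parameters\n",
              object$model$config$depth, object$model$config$in_channels,
              object$model$config$out_channels, count_parameters(object$model)))
  if (length(object$loss_history)) {
    cat("Per-epoch self-supervised loss (normalized units):\n")
    print(summary(object$loss_history))
  }
  invisible(object)
}

#' @export
coef.noise2inverse <- function(object, ...) object$model$weights

#' @export
plot.noise2inverse <- function(x, ...) {
  if (!length(x$loss_history)) stop("no loss history recorded")
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "b",
                 xlab = "epoch", ylab = "mean self-supervised MSE (normalized)",
                 main = "Noise2Inverse training loss", log = "y", ...)
  invisible(x)
}

#' Denoise reconstructions with a fitted model
#'
#' Two inference modes exist.  `"full"` (default) applies the network to the
#' FBP reconstruction of *all* measurements — the recommended mode, which
#' empirically outperforms the original alternative.  `"split_average"`
#' applies the network to each input-section reconstruction separately and
#' averages the outputs over the sections of the training scheme.
#'
#' @param object a fitted [noise2inverse] model.
#' @param newdata list of [sinogram]s in the layout of the training strategy
#'   (per slice, per time step, or per channel).
#' @param mode `"full"` or `"split_average"`.
#' @param ... unused.
#' @return For `static_25d`: a `depth x N x N` array. For `multichannel`: an
#'   `N x N x C` array.  For `dynamic`: a list of `N x N` matrices, one per
#'   time step (each step reconstructed alone, then denoised).
#' @export
predict.noise2inverse <- function(object, newdata, mode = c("full", "split_average"),
                                  ...) {
  mode <- match.arg(mode)
  denoise_full(object, newdata, mode)
}

#' Apply a trained model to full or per-section reconstructions
#'
#' Worker behind [predict.noise2inverse()]; callable directly with a fitted
#' model.  See there for the inference modes.
#'
#' @param fit a `noise2inverse` object.
#' @param data list of [sinogram]s in the training layout.
#' @param mode `"full"` or `"split_average"`.
#' @return See [predict.noise2inverse()].
#' @export
denoise_full <- function(fit, data, mode = c("full", "split_average")) {
  mode <- match.arg(mode)
  if (!inherits(fit, "noise2inverse")) stop_invalid("fit must be a noise2inverse object")
  scheme <- fit$scheme
  model <- fit$model
  strategy <- fit$strategy
  fl <- fit$filter_name

  if (strategy == "dynamic") {
    if (mode == "split_average")
      stop_invalid("split_average is not defined for the dynamic strategy; each step is denoised alone")
    return(dynamic_inference(fit, data))
  }

  if (strategy == "static_25d") {
    nsl <- length(data)
    N <- data[[1]]$geometry$image_size
    recon_vol <- function(idx) {
      v <- array(0, dim = c(nsl, N, N))
      for (s in seq_len(nsl))
        v[s, , ] <- if (is.null(idx)) fbp_reconstruct(data[[s]], fl)
                    else fbp_of_section(data[[s]], idx, fl)
      v
    }
    apply_vol <- function(v) {
      out <- array(0, dim = c(nsl, N, N))
      for (s in seq_len(nsl))
        out[s, , ] <- apply_model(model, assemble_25d_input(v, s, fit$context))[, , 1]
      out
    }
    if (mode == "full") return(apply_vol(recon_vol(NULL)))
    acc <- 0
    for (j in seq_len(scheme$J))
      acc <- acc + apply_vol(recon_vol(scheme$input_sets[[j]]))
    return(acc / scheme$J)
  }

  # multichannel
  C <- length(data)
  N <- data[[1]]$geometry$image_size
  recon_ch <- function(idx) {
    arr <- array(0, dim = c(N, N, C))
    for (c0 in seq_len(C))
      arr[, , c0] <- if (is.null(idx)) fbp_reconstruct(data[[c0]], fl)
                     else fbp_of_section(data[[c0]], idx, fl)
    arr
  }
  if (mode == "full") return(apply_model(model, recon_ch(NULL)))
  acc <- 0
  for (j in seq_len(scheme$J))
    acc <- acc + apply_model(model, recon_ch(scheme$input_sets[[j]]))
  acc / scheme$J
}

#' Per-time-step inference for dynamic acquisitions
#'
#' Reconstructs every time step alone from its (sparsely sampled) sinogram
#' and passes it through the trained network, yielding a sequence of
#' denoised reconstructions — including time steps after the training
#' window, where the dynamic process is underway.
#'
#' @param fit a `noise2inverse` object trained with the dynamic strategy.
#' @param per_time_step_sinograms list of [sinogram]s, one per time step.
#' @return List of denoised `N x N` matrices, one per time step.
#' @export
dynamic_inference <- function(fit, per_time_step_sinograms) {
  if (!inherits(fit, "noise2inverse")) stop_invalid("fit must be a noise2inverse object")
  model <- fit$model
  lapply(per_time_step_sinograms, function(s) {
    rec <- fbp_reconstruct(s, fit$filter_name)
    apply_model(model, rec)[, , 1]
  })
}
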