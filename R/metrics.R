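#' Image quality metrics
#'
#' Mean squared error, peak signal-to-noise ratio relative to the reference
#' dynamic range, and mean structural similarity (SSIM, Gaussian 11x11
#' window with sigma 1.5 and the standard constants K1 = 0.01, K2 = 0.03).
#' For volumes, SSIM is averaged over 2D slices (first axis of a 3D array
#' when it is a slice stack).  Identical inputs give `mse = 0`, `ssim = 1`
#' and `psnr = Inf`.
#'
#' @param candidate,reference numeric arrays of identical shape.
#' @return List with elements `mse`, `psnr`, `ssim`.
#' @export
image_metrics <- function(candidate, reference) {
  if (!identical(dim2(candidate), dim2(reference)))
    stop_invalid("candidate and reference must have identical shapes")
  err <- candidate - reference
  mse <- mean(err^2)
  rng <- max(reference) - min(reference)
  psnr <- if (mse == 0) Inf else 10 * log10(rng^2 / mse)
  d <- dim(reference)
  ssim <- if (is.null(d) || length(d) == 2) {
    ssim_2d(as.matrix(candidate), as.matrix(reference), rng)
  } else {
    mean(vapply(seq_len(d[1]), function(s)
      ssim_2d(matrix(candidate[s, , ], d[2]), matrix(reference[s, , ], d[2]), rng),
      1))
  }
  list(mse = mse, psnr = psnr, ssim = ssim)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# separable Gaussian filter with symmetric (reflected) boundary
gauss_blur <- function(x, sd = 1.5, half = 5) {
  k <- exp(-(((-half):half)^2) / (2 * sd^2))
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  ref <- function(i, n) {  # symmetric padding indices
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  out <- matrix(0, n, m)
  for (t in (-half):half)
    out <- out + k[t + half + 1] * x[ref(seq_len(n) + t, n), , drop = FALSE]
  out2 <- matrix(0, n, m)
  for (t in (-half):half)
    out2 <- out2 + k[t + half + 1] * out[, ref(seq_len(m) + t, m), drop = FALSE]
  out2
}

ssim_2d <- function(x, y, rng) {
  if (rng == 0) rng <- 1
  c1 <- (0.01 * rng)^2
  c2 <- (0.03 * rng)^2
  mx <- gauss_blur(x); my <- gauss_blur(y)
  sxx <- gauss_blur(x * x) - mx^2
  syy <- gauss_blur(y * y) - my^2
  sxy <- gauss_blur(x * y) - mx * my
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
       ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(s)
}

#' Monte-Carlo check of the self-supervised loss decomposition
#'
#' For a *fixed* (measurement-independent) linear denoiser `f`, the
#' self-supervised training loss decomposes, in expectation over the noise,
#' into the supervised loss against the noise-free reconstructions plus the
#' variance of the noise:
#' `sum_j ||f(x_noisy_input(j)) - x_noisy_target(j)||^2  =E=
#'  sum_j ||f(x_noisy_input(j)) - x_clean_target(j)||^2 +
#'  sum_j ||x_clean_target(j) - x_noisy_target(j)||^2`.
#' The cross term vanishes because the noise in complementary angular
#' sections is independent and zero-mean in the reconstruction.  This
#' routine estimates all three terms over repeated noise realizations and
#' reports the Monte-Carlo mean discrepancy and its standard error; the
#' identity holds when the discrepancy is within a few standard errors of
#' zero, and the discrepancy shrinks as `1/sqrt(realizations)`.
#'
#' A denoiser that peeks at the target would break the premise; this cannot
#' be detected here, so the caller must supply a measurement-independent
#' operator (e.g. the identity or a fixed blur).
#'
#' @param phantom ground-truth image (`N x N` matrix).
#' @param geometry a [projection_geometry].
#' @param noise noise configuration ([noise_config]), or `NULL` to disable
#'   noise (then the variance term is exactly zero and the self-supervised
#'   loss equals the supervised loss).
#' @param J number of angular sections.
#' @param fixed_denoiser function mapping an `N x N` matrix to an `N x N`
#'   matrix; must not depend on the realizations.
#' @param realizations number of Monte-Carlo noise draws (>= 2; >= 50 for a
#'   meaningful standard error).
#' @param seed integer; realization `r` uses seed `seed + r`.
#' @param filter_name FBP filter.
#' @return Object of class `loss_decomposition`: list with `n2i_loss`,
#'   `supervised_loss`, `noise_variance` (Monte-Carlo means of the three
#'   terms, summed over sections), `discrepancy`, `mc_standard_error`, and
#'   `realizations`.
#' @export
verify_loss_decomposition <- function(phantom, geometry, noise, J,
                                      fixed_denoiser = identity,
                                      realizations = 100, seed = 1,
                                      filter_name = "ram-lak") {
  if (realizations < 2) stop_invalid("need at least 2 realizations")
  scheme <- angular_split(length(geometry$angles), J)
  clean <- forward_project(phantom, geometry)
  clean_tgt <- lapply(seq_len(J), function(j)
    fbp_of_section(clean, scheme$target_sets[[j]], filter_name))

  terms <- matrix(0, realizations, 3)
  for (r in seq_len(realizations)) {
    noisy <- if (is.null(noise)) clean
             else simulate_noisy_sinogram(clean, noise, seed = seed + r)
    t_n2i <- t_sup <- t_var <- 0
    for (j in seq_len(J)) {
      xin <- fbp_of_section(noisy, scheme$input_sets[[j]], filter_name)
      xtg <- fbp_of_section(noisy, scheme$target_sets[[j]], filter_name)
      fx <- fixed_denoiser(xin)
      t_n2i <- t_n2i + sum((fx - xtg)^2)
      t_sup <- t_sup + sum((fx - clean_tgt[[j]])^2)
      t_var <- t_var + sum((clean_tgt[[j]] - xtg)^2)
    }
    terms[r, ] <- c(t_n2i, t_sup, t_var)
  }
  delta <- terms[, 1] - terms[, 2] - terms[, 3]
  structure(list(n2i_loss = mean(terms[, 1]),
                 supervised_loss = mean(terms[, 2]),
                 noise_variance = mean(terms[, 3]),
                 discrepancy = mean(delta),
                 mc_standard_error = sd(delta) / sqrt(realizations),
                 realizations = realizations),
            class = "loss_decomposition")
}

#' @export
print.loss_decomposition <- function(x, ...) {
  cat(sprintf("Loss decomposition over %d realizations:\n", x$realizations))
  cat(sprintf("  self-supervised loss  %.6g\n", x$n2i_loss))
  cat(sprintf("  supervised loss       %.6g\n", x$supervised_loss))
  cat(sprintf("  noise variance        %.6g\n", x$noise_variance))
  cat(sprintf("  discrepancy %.3g (MC standard error %.3g)\n",
              x$discrepancy, x$mc_standard_error))
  invisible(x)
}

#' Fixed uniform blur operator
#'
#' A `k x k` box blur with symmetric boundary, usable as a fixed linear
#' denoiser in [verify_loss_decomposition()].
#'
#' @param k odd window size (default 5).
#' @return A function mapping a matrix to a matrix.
#' @export
uniform_blur <- function(k = 5) {
  if (k %% 2 != 1) stop_invalid("k must be odd")
  half <- (k - 1) / 2
  function(x) {
    n <- nrow(x); m <- ncol(x)
    ref <- function(i, n) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
      i
    }
    out <- matrix(0, n, m)
    for (t in (-half):half) out <- out + x[ref(seq_len(n) + t, n), , drop = FALSE]
    out2 <- matrix(0, n, m)
    for (t in (-half):half) out2 <- out2 + out[, ref(seq_len(m) + t, m), drop = FALSE]
    out2 / k^2
  }
}
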