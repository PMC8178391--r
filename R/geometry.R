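#' Parallel-beam projection geometry
#'
#' A `projection_geometry` records everything that defines the linear forward
#' operator of 2D parallel-beam tomography: the rotation angles, the number
#' and size of detector pixels, the reconstruction grid size, and the
#' rotation centre on the detector axis.
#'
#' Conventions: the object rotates counterclockwise; angle 0 sends rays along
#' the image +x axis, so the detector axis at angle `theta` is
#' `(-sin theta, cos theta)`.  Pixel `(i, j)` of an `N x N` image is centred
#' at `(i - (N-1)/2, j - (N-1)/2)` in units of one image pixel.  Sinograms
#' from external tools can be matched by comparing against these conventions.
#'
#' @param angles numeric vector of distinct, finite angles in radians; stored
#'   reduced modulo `2*pi`.
#' @param num_detector_pixels positive integer, detector bins per projection.
#' @param image_size positive integer `N`; reconstructed images are `N x N`.
#' @param detector_pixel_size positive real, detector bin width in image-pixel
#'   units (default 1).
#' @param rotation_center real detector coordinate of the rotation axis;
#'   defaults to the detector midpoint `(num_detector_pixels - 1) / 2`.
#' @return An object of class `projection_geometry`.
#' @seealso [make_geometry()] for equally spaced angle grids,
#'   [forward_project()], [fbp_reconstruct()].
#' @export
projection_geometry <- function(angles, num_detector_pixels, image_size,
                                detector_pixel_size = 1,
                                rotation_center = (num_detector_pixels - 1) / 2) {
  angles <- as.numeric(angles)
  if (length(angles) < 1L || any(!is.finite(angles)))
    stop_invalid("angles must be a nonempty vector of finite reals")
  angles <- angles %% (2 * pi)
  if (anyDuplicated(angles))
    stop_invalid("angles must be pairwise distinct (after reduction mod 2*pi)")
  if (!is.numeric(num_detector_pixels) || num_detector_pixels < 1)
    stop_invalid("num_detector_pixels must be a positive integer")
  if (!is.numeric(image_size) || image_size < 1)
    stop_invalid("image_size must be a positive integer")
  if (detector_pixel_size <= 0)
    stop_invalid("detector_pixel_size must be positive")
  structure(list(
    angles = angles,
    num_detector_pixels = as.integer(num_detector_pixels),
    image_size = as.integer(image_size),
    detector_pixel_size = as.numeric(detector_pixel_size),
    rotation_center = as.numeric(rotation_center)
  ), class = "projection_geometry")
}

#' Equally spaced projection geometry
#'
#' Builds a [projection_geometry] with `num_angles` equally spaced angles,
#' `angles[k] = offset + (k-1) * angular_range / num_angles`, reduced modulo
#' `2*pi`.  Both half-turn (`pi`) and full-turn (`2*pi`) ranges are used in
#' practice; full-turn acquisitions arise from interlaced dynamic scans.
#'
#' @param num_angles positive integer.
#' @param angular_range angular span in radians, typically `pi` or `2*pi`.
#' @param offset first angle in radians (default 0).
#' @param num_detector_pixels,image_size,detector_pixel_size,rotation_center
#'   passed to [projection_geometry()].
#' @return A `projection_geometry`.
#' @examples
#' g <- make_geometry(4, pi, num_detector_pixels = 64, image_size = 64)
#' g$angles  # 0, pi/4, pi/2, 3*pi/4
#' @export
make_geometry <- function(num_angles, angular_range = pi, offset = 0,
                          num_detector_pixels, image_size,
                          detector_pixel_size = 1,
                          rotation_center = (num_detector_pixels - 1) / 2) {
  if (!is.numeric(num_angles) || num_angles < 1)
    stop_invalid("num_angles must be >= 1")
  k <- seq_len(num_angles) - 1
  projection_geometry(offset + k * angular_range / num_angles,
                      num_detector_pixels, image_size,
                      detector_pixel_size, rotation_center)
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("Parallel-beam geometry: %d angles in [%.4f, %.4f], %d detector px, %dx%d image\n",
              length(x$angles), min(x$angles), max(x$angles),
              x$num_detector_pixels, x$image_size, x$image_size))
  invisible(x)
}

#' Sinogram container
#'
#' A sinogram stores measured or simulated line integrals as a
#' `num_angles x num_detector_pixels` matrix together with its
#' [projection_geometry].  Optional indices record where the sinogram sits in
#' a larger acquisition (slice within a stack, time step, channel), and
#' `provenance` tracks the source time step of each row after
#' [combine_time_steps()].
#'
#' @param values numeric matrix, rows indexed by angle.
#' @param geometry a `projection_geometry` with matching angle count.
#' @param slice_index,time_index,channel_index optional integer annotations.
#' @param provenance optional integer vector, one entry per row.
#' @return Object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, slice_index = NULL, time_index = NULL,
                     channel_index = NULL, provenance = NULL) {
  values <- as.matrix(values)
  if (!inherits(geometry, "projection_geometry"))
    stop_invalid("geometry must be a projection_geometry")
  if (nrow(values) != length(geometry$angles))
    stop_invalid("sinogram rows (", nrow(values), ") must match angle count (",
                 length(geometry$angles), ")")
  if (ncol(values) != geometry$num_detector_pixels)
    stop_invalid("sinogram columns must match num_detector_pixels")
  if (any(!is.finite(values)))
    stop_invalid("sinogram values must all be finite")
  if (!is.null(provenance) && length(provenance) != nrow(values))
    stop_invalid("provenance must have one entry per sinogram row")
  structure(list(values = values, geometry = geometry,
                 slice_index = slice_index, time_index = time_index,
                 channel_index = channel_index, provenance = provenance),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram: %d angles x %d detector px (range %.3g .. %.3g)\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

check_image <- function(image, geometry) {
  image <- as.matrix(image)
  if (nrow(image) != ncol(image))
    stop_invalid("image must be square")
  if (nrow(image) != geometry$image_size)
    stop_invalid("image size ", nrow(image), " does not match geometry image_size ",
                 geometry$image_size)
  if (any(!is.finite(image)))
    stop_invalid("image values must all be finite")
  image
}

#' Forward projection (discrete Radon transform)
#'
#' Computes line integrals of an image along the rays of `geometry` using a
#' ray-driven scheme: each ray is sampled at unit (1 pixel) steps and the
#' image is interpolated bilinearly at every sample, so the operator is
#' linear in the image.  Samples outside the image contribute zero; if the
#' detector is narrower than the image diagonal the outer parts of the
#' object are silently truncated.
#'
#' @param image square numeric matrix of side `geometry$image_size`.
#' @param geometry a [projection_geometry].
#' @return A [sinogram].
#' @seealso [backproject()] for the exact transpose, [fbp_reconstruct()].
#' @export
forward_project <- function(image, geometry) {
  image <- check_image(image, geometry)
  vals <- .fp_cpp(image, geometry$angles, geometry$num_detector_pixels,
                  geometry$rotation_center, geometry$detector_pixel_size)
  sinogram(vals, geometry)
}

#' Unfiltered backprojection (transpose of the forward projector)
#'
#' Applies the exact matrix transpose of [forward_project()], accumulating
#' each sinogram entry back along its ray with the same bilinear weights.
#' Consequently the adjoint identity `<Ax, y> == <x, A^T y>` holds to
#' rounding error.  Note this is the plain transpose: it carries an overall
#' scale proportional to the number of angles and is not normalized as an
#' angular average.
#'
#' @param sino a [sinogram], or a matrix together with `geometry`.
#' @param geometry required when `sino` is a bare matrix.
#' @return Square numeric matrix of side `geometry$image_size`.
#' @export
backproject <- function(sino, geometry = NULL) {
  if (inherits(sino, "sinogram")) {
    geometry <- sino$geometry
    vals <- sino$values
  } else {
    if (is.null(geometry)) stop_invalid("geometry required for a bare matrix")
    vals <- as.matrix(sino)
    if (nrow(vals) != length(geometry$angles) ||
        ncol(vals) != geometry$num_detector_pixels)
      stop_invalid("sinogram shape does not match geometry")
  }
  if (any(!is.finite(vals))) stop_invalid("sinogram values must all be finite")
  .bp_cpp(vals, geometry$angles, geometry$image_size,
          geometry$rotation_center, geometry$detector_pixel_size)
}

ramp_filter <- function(npad, filter_name, pixel_size = 1) {
  # frequency response of the band-limited ramp: FFT of the real-space
  # impulse response h[0] = 1/4, h[odd n] = -1/(pi^2 n^2), h[even] = 0.
  # Unlike the naive |f| sampling this keeps the correct (nonzero) DC term,
  # avoiding a several-percent negative bias of reconstructed gray values.
  n <- c(0:(npad / 2), -(npad / 2 - 1):-1)
  h <- numeric(npad)
  h[n == 0] <- 0.25
  odd <- (n %% 2) != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2)
  base <- Re(fft(h))
  f <- n / npad  # cycles per sample
  m <- switch(filter_name,
    "ram-lak" = rep(1, npad),
    "shepp-logan" = ifelse(f == 0, 1, sin(pi * f) / (pi * f)),
    "cosine" = cos(pi * f),
    stop_invalid("unknown filter name: ", filter_name,
                 " (use ram-lak, shepp-logan or cosine)"))
  base * m / pixel_size
}

#' Filtered backprojection reconstruction
#'
#' Classic FBP for parallel-beam data: each projection is zero-padded to the
#' next power of two at least twice the detector width (suppressing circular
#' convolution wrap), ramp-filtered in the frequency domain, backprojected,
#' and scaled by `pi / num_angles`.  With a full-turn angle grid the same
#' scale applies because opposing rays are averaged implicitly (each point is
#' covered twice).  The whole map is linear in the sinogram, and densely
#' sampled noise-free projections of a phantom reconstruct its gray values.
#'
#' @param sino a [sinogram].
#' @param filter_name one of `"ram-lak"`, `"shepp-logan"`, `"cosine"`.
#' @return Square numeric matrix (the reconstructed slice).
#' @examples
#' g <- make_geometry(64, pi, num_detector_pixels = 32, image_size = 32)
#' img <- disk_image(32, radius = 10)
#' rec <- fbp_reconstruct(forward_project(img, g))
#' mean(rec[img > 0])  # close to 1
#' @export
fbp_reconstruct <- function(sino, filter_name = "ram-lak") {
  if (!inherits(sino, "sinogram")) stop_invalid("sino must be a sinogram")
  vals <- sino$values
  if (any(!is.finite(vals))) stop_invalid("sinogram values must all be finite")
  g <- sino$geometry
  ndet <- ncol(vals)
  npad <- 2^ceiling(log2(max(2 * ndet, 8)))
  filt <- ramp_filter(npad, filter_name, g$detector_pixel_size)
  # columns of `pr` are projections
  pr <- matrix(0, npad, nrow(vals))
  pr[seq_len(ndet), ] <- t(vals)
  fq <- mvfft(pr) * filt
  q <- Re(mvfft(fq, inverse = TRUE)) / npad
  filtered <- t(q[seq_len(ndet), , drop = FALSE])
  bp <- .bp_cpp(filtered, g$angles, g$image_size, g$rotation_center,
                g$detector_pixel_size)
  bp * (pi / length(g$angles)) * g$detector_pixel_size
}

#' Operator norm of the projection operator by power iteration
#'
#' Estimates the largest singular value of the forward projector `A` (or of
#' the stacked operator `[A; grad]` with the isotropic forward-difference
#' gradient, as needed for Chambolle-Pock step sizes) by power iteration on
#' `A^T A` from a seeded random start.  Deterministic given the seed, and
#' nondecreasing in the iteration count for a fixed seed.
#'
#' @param geometry a [projection_geometry].
#' @param iterations positive integer number of power iterations (default 20).
#' @param seed integer seed for the random start vector.
#' @param include_gradient if `TRUE`, estimate the norm of the stacked
#'   projection + gradient operator used by [tvmin_reconstruct()].
#' @return Positive scalar estimate of the spectral norm.
#' @export
operator_norm <- function(geometry, iterations = 20, seed = 1,
                          include_gradient = FALSE) {
  if (!inherits(geometry, "projection_geometry"))
    stop_invalid("geometry must be a projection_geometry")
  if (iterations < 1) stop_invalid("iterations must be >= 1")
  N <- geometry$image_size
  x <- with_seed(seed, function() matrix(rnorm(N * N), N, N))
  x <- x / sqrt(sum(x^2))
  est <- 0
  for (it in seq_len(iterations)) {
    y <- .fp_cpp(x, geometry$angles, geometry$num_detector_pixels,
                 geometry$rotation_center, geometry$detector_pixel_size)
    z <- .bp_cpp(y, geometry$angles, N, geometry$rotation_center,
                 geometry$detector_pixel_size)
    if (include_gradient) {
      gx <- image_gradient(x)
      z <- z + gradient_transpose(gx)
    }
    nrm <- sqrt(sum(z^2))
    if (nrm == 0) return(0)
    est <- sqrt(nrm)  # ||A^T A x|| -> lambda_max, so sqrt gives sigma_max
    x <- z / nrm
  }
  est
}

#' Uniform disk test image
#'
#' A centred disk of constant `value`, the standard analytic test object:
#' every ray through the centre has line integral `2 * radius * value`.
#'
#' @param N image side length.
#' @param radius disk radius in pixels.
#' @param value gray value inside the disk.
#' @return `N x N` numeric matrix.
#' @export
disk_image <- function(N, radius = N / 3, value = 1) {
  c0 <- (N - 1) / 2
  xx <- matrix(rep(0:(N - 1), N), N) - c0
  yy <- t(xx)
  out <- matrix(0, N, N)
  out[xx^2 + yy^2 <= radius^2] <- value
  out
}
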