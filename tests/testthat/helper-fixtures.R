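# Shared fixtures, all generated in code.

tiny_geometry <- function(num_angles = 24, N = 32, range = pi)
  make_geometry(num_angles, range, num_detector_pixels = N, image_size = N)

# Independent line-integral oracle: dense sampling (1000 sub-samples per
# ray) of the bilinearly interpolated image.  Deliberately written without
# any of the projector's internals.
oracle_ray_integral <- function(image, theta, t, nsub = 1000) {
  N <- nrow(image)
  c0 <- (N - 1) / 2
  smax <- 0.75 * N
  s <- seq(-smax, smax, length.out = nsub)
  ds <- s[2] - s[1]
  gx <- t * (-sin(theta)) + s * cos(theta) + c0
  gy <- t * cos(theta) + s * sin(theta) + c0
  val <- numeric(nsub)
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  at <- function(i, j) {
    ok <- i >= 0 & i <= N - 1 & j >= 0 & j <= N - 1
    out <- numeric(length(i))
    out[ok] <- image[cbind(i[ok] + 1, j[ok] + 1)]
    out
  }
  v <- (1 - fx) * (1 - fy) * at(i0, j0) + fx * (1 - fy) * at(i0 + 1, j0) +
       (1 - fx) * fy * at(i0, j0 + 1) + fx * fy * at(i0 + 1, j0 + 1)
  sum(v) * ds
}

# smooth test phantom for reconstruct-project identity checks
smooth_phantom <- function(N) {
  c0 <- (N - 1) / 2
  x <- (matrix(rep(0:(N - 1), N), N) - c0) / (N / 2)
  y <- t(x)
  r2 <- x^2 + y^2
  ifelse(r2 < 0.8^2, (1 + cos(pi * sqrt(r2) / 0.8))^2 / 4, 0)
}
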