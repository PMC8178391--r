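test_that("make_geometry produces equally spaced angle grids", {
  g <- make_geometry(4, pi, num_detector_pixels = 64, image_size = 64)
  expect_equal(g$angles, c(0, pi / 4, pi / 2, 3 * pi / 4))
  g1 <- make_geometry(1, 2 * pi, offset = 0.1, num_detector_pixels = 32,
                      image_size = 32)
  expect_equal(g1$angles, 0.1)
  g300 <- make_geometry(300, 2 * pi, num_detector_pixels = 128, image_size = 128)
  expect_length(g300$angles, 300)
  expect_equal(diff(g300$angles), rep(2 * pi / 300, 299))
  expect_error(make_geometry(0, pi, num_detector_pixels = 8, image_size = 8),
               "num_angles")
  expect_error(projection_geometry(c(0, 0.1), -4, 8), "detector")
  expect_error(projection_geometry(c(0.2, 0.2), 8, 8), "distinct")
})

test_that("forward projection matches a dense ray-sampling oracle", {
  N <- 33
  g <- make_geometry(8, pi, num_detector_pixels = N, image_size = N)
  # single unit pixel at the exact centre: central bin stays near 1
  img <- matrix(0, N, N)
  img[17, 17] <- 1
  s <- forward_project(img, g)$values
  for (a in seq_along(g$angles)) {
    orc <- oracle_ray_integral(img, g$angles[a], 0)
    expect_lt(abs(s[a, 17] - orc), 0.25)
    expect_lt(abs(s[a, 17] - 1), 0.2)
  }
  # random smooth image, random rays
  ph <- smooth_phantom(N)
  sp <- forward_project(ph, g)$values
  for (a in c(1, 3, 6)) for (p in c(5, 17, 25)) {
    orc <- oracle_ray_integral(ph, g$angles[a], p - 17)
    expect_lt(abs(sp[a, p] - orc), 0.02 * max(sp))
  }
})

test_that("a centred disk projects to its chord length at every angle", {
  N <- 128
  g <- make_geometry(12, pi, num_detector_pixels = N, image_size = N)
  s <- forward_project(disk_image(N, radius = 20), g)$values
  # unit-step ray sampling of the discretized edge: worst case ~1.6%
  expect_true(all(abs(s[, 64] - 40) / 40 < 0.02))
  # zero image -> zero sinogram (linearity)
  z <- forward_project(matrix(0, N, N), g)$values
  expect_true(all(z == 0))
  expect_error(forward_project(matrix(0, 16, 16), g), "size")
})

test_that("backprojection is the exact adjoint of forward projection", {
  set.seed(42)
  for (rep in 1:5) {
    g <- make_geometry(sample(8:48, 1), sample(c(pi, 2 * pi), 1),
                       num_detector_pixels = 40, image_size = 32)
    x <- matrix(rnorm(32 * 32), 32)
    y <- matrix(rnorm(length(g$angles) * 40), length(g$angles))
    lhs <- sum(forward_project(x, g)$values * y)
    rhs <- sum(x * backproject(y, g))
    expect_lt(abs(lhs - rhs) / (abs(lhs) + abs(rhs)), 1e-12)
  }
  g <- tiny_geometry()
  expect_true(all(backproject(matrix(0, 24, 32), g) == 0))
  expect_error(backproject(matrix(0, 5, 5), g), "shape")
})

test_that("one-angle backprojection is constant along the ray direction", {
  N <- 32
  g <- make_geometry(1, pi, offset = 0, num_detector_pixels = N, image_size = N)
  s <- matrix(0, 1, N)
  s[1, 16] <- 1
  b <- backproject(s, g)
  # angle 0: rays run along +x (the first image axis); interior rows constant
  interior <- b[5:28, 16]
  expect_true(max(abs(interior - interior[1])) < 1e-12)
})

test_that("FBP is linear and reconstructs a disk's gray values", {
  N <- 128
  g <- make_geometry(256, pi, num_detector_pixels = N, image_size = N)
  sino <- forward_project(disk_image(N, radius = 40), g)
  rec <- fbp_reconstruct(sino)
  inner <- disk_image(N, radius = 37) > 0
  expect_lt(abs(mean(rec[inner]) - 1), 0.05)
  # linearity to machine precision
  rec2 <- fbp_reconstruct(sinogram(2 * sino$values, g))
  expect_lt(max(abs(rec2 - 2 * rec)), 1e-12)
  set.seed(7)
  y1 <- matrix(rnorm(256 * N), 256); y2 <- matrix(rnorm(256 * N), 256)
  a <- 0.7; b <- -1.3
  lin <- fbp_reconstruct(sinogram(a * y1 + b * y2, g))
  sep <- a * fbp_reconstruct(sinogram(y1, g)) + b * fbp_reconstruct(sinogram(y2, g))
  expect_lt(max(abs(lin - sep)), 1e-8 * max(abs(sep)))
  # zero in, zero out
  expect_true(all(fbp_reconstruct(sinogram(matrix(0, 256, N), g)) == 0))
  expect_error(fbp_reconstruct(sino, filter_name = "hann"), "filter")
})

test_that("all three FBP filters reconstruct a smooth phantom", {
  N <- 64
  g <- make_geometry(2 * N, pi, num_detector_pixels = N, image_size = N)
  ph <- smooth_phantom(N)
  sino <- forward_project(ph, g)
  for (f in c("ram-lak", "shepp-logan", "cosine")) {
    rec <- fbp_reconstruct(sino, f)
    rel <- sqrt(mean((rec - ph)^2)) / sqrt(mean(ph^2))
    expect_lt(rel, 0.1)
  }
})

test_that("operator norm matches a dense SVD and is monotone and reproducible", {
  g <- make_geometry(12, pi, num_detector_pixels = 16, image_size = 16)
  A <- matrix(0, 12 * 16, 256)
  for (k in 1:256) {
    e <- matrix(0, 16, 16); e[k] <- 1
    A[, k] <- as.vector(forward_project(e, g)$values)
  }
  sv <- svd(A)$d[1]
  est <- operator_norm(g, iterations = 60, seed = 3)
  expect_lt(abs(est - sv) / sv, 0.01)
  ests <- vapply(c(1, 3, 10, 30), function(it)
    operator_norm(g, iterations = it, seed = 5), 1)
  expect_true(all(diff(ests) >= -1e-12))
  expect_identical(operator_norm(g, iterations = 15, seed = 9),
                   operator_norm(g, iterations = 15, seed = 9))
})

test_that("project-then-reconstruct approximates the identity on smooth images", {
  N <- 48
  g <- make_geometry(2 * N, pi, num_detector_pixels = N, image_size = N)
  ph <- smooth_phantom(N)
  rec <- fbp_reconstruct(forward_project(ph, g))
  expect_lt(sqrt(mean((rec - ph)^2)) / sqrt(mean(ph^2)), 0.1)
})
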