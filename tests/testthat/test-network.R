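test_that("parameter accounting matches the closed form", {
  expect_equal(count_parameters(msd_config(1, 1, 1)), 13L)
  expect_equal(count_parameters(msd_config(100, 11, 1)), 54662L)
  # closed form for arbitrary configs
  closed <- function(depth, cin, cout)
    sum(9 * (cin + seq_len(depth) - 1) + 1) + cout * (cin + depth + 1)
  for (d in c(1, 3, 25)) for (cin in c(1, 5)) for (cout in c(1, 4)) {
    expect_equal(count_parameters(msd_config(d, cin, cout)),
                 closed(d, cin, cout))
  }
  # each extra output channel costs in + depth + 1 parameters
  d5a <- count_parameters(msd_config(5, 3, 1))
  d5b <- count_parameters(msd_config(5, 3, 2))
  expect_equal(d5b - d5a, 3 + 5 + 1)
  # independent of image size: the count never references N anywhere
  m <- build_msd(msd_config(4, 2, 1, weight_init_seed = 3))
  expect_length(m$weights, count_parameters(m))
})

test_that("weight initialization is deterministic", {
  m1 <- build_msd(msd_config(6, 2, 1, weight_init_seed = 11))
  m2 <- build_msd(msd_config(6, 2, 1, weight_init_seed = 11))
  expect_identical(m1$weights, m2$weights)
  m3 <- build_msd(msd_config(6, 2, 1, weight_init_seed = 12))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("2.5D assembly mirrors out-of-range slices without the edge", {
  vol <- array(0, dim = c(5, 8, 8))
  for (s in 1:5) vol[s, , ] <- s
  expect_equal(assemble_25d_input(vol, 3, 0)[1, 1, 1], 3)
  # centre slice 1 with context 2: order 3, 2, 1, 2, 3
  st <- assemble_25d_input(vol, 1, 2)
  expect_equal(st[1, 1, ], c(3, 2, 1, 2, 3))
  # centre slice 5: order 3, 4, 5, 4, 3
  expect_equal(assemble_25d_input(vol, 5, 2)[1, 1, ], c(3, 4, 5, 4, 3))
  # depth-11 volume, slice 6, context 5 covers the whole stack
  v11 <- array(rep(1:11, each = 1), dim = c(11, 4, 4))
  for (s in 1:11) v11[s, , ] <- s
  expect_equal(assemble_25d_input(v11, 6, 5)[1, 1, ], as.numeric(1:11))
  expect_error(assemble_25d_input(vol, 6, 0), "range")
  expect_error(assemble_25d_input(vol, 3, 5), "smaller than")
})

test_that("a zero-weight network outputs its de-normalized bias", {
  cfg <- msd_config(3, 1, 1, weight_init_seed = 1)
  m <- build_msd(cfg)
  m$weights[] <- 0
  nb <- length(m$weights)
  m$weights[nb] <- 0.5  # output bias
  m$normalization <- list(input_offset = 0, input_scale = 1,
                          output_offset = 2, output_scale = 4)
  out <- apply_model(m, matrix(rnorm(16 * 16), 16))
  expect_true(all(out == 0.5 * 4 + 2))
})

test_that("the forward pass is deterministic and respects channel contracts", {
  m <- build_msd(msd_config(5, 3, 2, weight_init_seed = 2))
  x <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  expect_identical(apply_model(m, x), apply_model(m, x))
  expect_equal(dim(apply_model(m, x)), c(12, 12, 2))
  expect_error(apply_model(m, array(0, c(12, 12, 2))), "channels")
})

test_that("periodic-padding networks are translation equivariant", {
  m <- build_msd(msd_config(6, 1, 1, dilation_cycle = 3, weight_init_seed = 4,
                            pad_mode = "periodic"))
  x <- matrix(rnorm(40 * 40), 40)
  shift <- function(mat, k) mat[c((k + 1):40, 1:k), ]
  o1 <- apply_model(m, x)[, , 1]
  o2 <- apply_model(m, shift(x, 4))[, , 1]
  expect_lt(max(abs(shift(o1, 4) - o2)), 1e-12)
})

test_that("the loss gradient matches finite differences", {
  cfg <- msd_config(3, 2, 2, dilation_cycle = 2, weight_init_seed = 5)
  m <- build_msd(cfg)
  N <- 10
  set.seed(3)
  x <- as.numeric(array(rnorm(N * N * 2), c(N, N, 2)))
  tg <- as.numeric(array(rnorm(N * N * 2), c(N, N, 2)))
  lg <- noise2inverse:::.msd_loss_grad_cpp(x, tg, m$weights, N, 2L, 3L, 2L, 2L,
                                           0L, FALSE)
  idx <- round(seq(1, length(m$weights), length.out = 15))
  eps <- 1e-6
  for (k in idx) {
    wp <- m$weights; wp[k] <- wp[k] + eps
    wm <- m$weights; wm[k] <- wm[k] - eps
    lp <- noise2inverse:::.msd_loss_grad_cpp(x, tg, wp, N, 2L, 3L, 2L, 2L, 0L, FALSE)$loss
    lm <- noise2inverse:::.msd_loss_grad_cpp(x, tg, wm, N, 2L, 3L, 2L, 2L, 0L, FALSE)$loss
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - lg$grad[k]), 1e-5 * (abs(num) + 1e-3))
  }
})

test_that("the receptive field spans far pixels for deep dilated networks", {
  cfg <- msd_config(30, 1, 1, dilation_cycle = 10, weight_init_seed = 6)
  m <- build_msd(cfg)
  N <- 72
  x <- matrix(0, N, N)
  base <- apply_model(m, x)[36, 36, 1]
  x2 <- x
  x2[36 + 30, 36] <- 1
  pert <- apply_model(m, x2)[36, 36, 1]
  expect_gt(abs(pert - base), 0)
})

test_that("the linear-activation hook makes the network a linear operator", {
  m <- build_msd(msd_config(4, 1, 1, weight_init_seed = 7))
  m$normalization <- list(input_offset = 0, input_scale = 1,
                          output_offset = 0, output_scale = 1)
  x1 <- matrix(rnorm(16 * 16), 16)
  x2 <- matrix(rnorm(16 * 16), 16)
  f <- function(z) apply_model(m, z, linear_act = TRUE)[, , 1]
  lhs <- f(0.3 * x1 - 1.7 * x2)
  rhs0 <- f(matrix(0, 16, 16))  # affine offset from biases
  rhs <- 0.3 * (f(x1) - rhs0) - 1.7 * (f(x2) - rhs0) + rhs0
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})
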