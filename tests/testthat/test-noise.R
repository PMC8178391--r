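test_that("expected counts follow the transmission model exactly", {
  nc <- noise_config(1000, seed = 1)
  expect_equal(to_expected_counts(matrix(0, 2, 2), nc), matrix(1000, 2, 2))
  expect_equal(to_expected_counts(matrix(1, 1, 1), nc)[1],
               1000 * exp(-1), tolerance = 1e-12)
  # p -> infinity approaches the dark level
  ncd <- noise_config(1000, dark_level = 7, seed = 1)
  expect_equal(to_expected_counts(matrix(50, 1, 1), ncd)[1], 7,
               tolerance = 1e-12)
  expect_error(to_expected_counts(matrix(-1, 1, 1), nc), "non-negative")
  # config invariants
  expect_error(noise_config(0.5, virtual_time_fraction = 1), "at least one")
  expect_error(noise_config(100, virtual_time_fraction = 0), "0, 1")
  expect_error(noise_config(100, dark_level = -1), "dark")
})

test_that("Poisson draws are reproducible and match their expectation", {
  expect_true(all(apply_poisson(matrix(0, 3, 3), seed = 1) == 0))
  a <- apply_poisson(matrix(1:9, 3), seed = 5)
  b <- apply_poisson(matrix(1:9, 3), seed = 5)
  expect_identical(a, b)
  draws <- apply_poisson(rep(100, 1e5), seed = 7)
  expect_lt(abs(mean(draws) - 100), 3 * 10 / sqrt(1e5))
  expect_error(apply_poisson(matrix(-1, 1, 1), 1), "non-negative")
})

test_that("log correction inverts the noiseless forward model and clamps starvation", {
  p <- matrix(runif(20, 0, 2), 4)
  counts <- 1000 * exp(-p)
  expect_equal(log_correct(counts, flat = 1000, dark = 0), p, tolerance = 1e-12)
  # photon starvation: counts below the floor stay finite
  out <- log_correct(matrix(0, 2, 2), flat = 100, dark = 0)
  expect_true(all(is.finite(out)))
  expect_equal(out, matrix(-log(1 / 100), 2, 2))
  expect_error(log_correct(matrix(5, 1, 1), flat = 1, dark = 2), "flat")
})

test_that("corrected-noise variance matches the delta-method prediction", {
  # Var(-log(X / I0)) ~ exp(p) / I0 for X ~ Poisson(I0 exp(-p))
  I0 <- 1000; p <- 1
  vals <- vapply(1:4000, function(k) {
    x <- apply_poisson(matrix(I0 * exp(-p), 1, 1), seed = 10000 + k)
    log_correct(x, flat = I0, dark = 0)[1]
  }, 1)
  v <- var(vals)
  pred <- exp(p) / I0
  # chi-square spread of a variance estimate: sd ~ pred * sqrt(2/n)
  expect_lt(abs(v - pred), 4 * pred * sqrt(2 / 4000))
})

test_that("simulated sinogram noise is reproducible, vanishing and 1/t-scaled", {
  g <- tiny_geometry(8, 16)
  clean <- sinogram(matrix(runif(8 * 16, 0, 1.5), 8), g)
  nc <- noise_config(1e12, seed = 3)
  out <- simulate_noisy_sinogram(clean, nc)
  expect_lt(sqrt(mean((out$values - clean$values)^2)), 1e-4)
  nc2 <- noise_config(500, seed = 4)
  expect_identical(simulate_noisy_sinogram(clean, nc2)$values,
                   simulate_noisy_sinogram(clean, nc2)$values)
  # variance ratio ~ 5 between t = 1 and t = 0.2
  nm <- experiment_noise_model(seed = 11, realizations = 120)
  expect_lt(abs(nm$variance_ratio - 5) / 5, 0.1)
  expect_error(simulate_noisy_sinogram(sinogram(matrix(-1, 8, 16), g), nc2),
               "non-negative")
})

test_that("corrected noise is zero-mean at adequate counts and bias stays under 1%", {
  nm <- experiment_noise_model(seed = 5, realizations = 150)
  expect_lt(abs(nm$mean_bias_se), 3)
  expect_lt(nm$bias_at_20_rel, 0.01)
})

test_that("noise is independent across angles and detector pixels", {
  g <- tiny_geometry(8, 40)
  clean <- sinogram(matrix(1, 8, 40), g)
  nc <- noise_config(500, seed = 1)
  R <- 300
  draws <- vapply(seq_len(R), function(k)
    simulate_noisy_sinogram(clean, nc, seed = 5000 + k)$values - 1,
    matrix(0, 8, 40))
  # correlations of neighbouring entries across realizations stay near zero
  cors <- c(
    vapply(1:20, function(j) cor(draws[1, j, ], draws[1, j + 1, ]), 1),
    vapply(1:7, function(i) cor(draws[i, 5, ], draws[i + 1, 5, ]), 1))
  expect_lt(max(abs(cors)), 4 / sqrt(R))
})

test_that("the Gaussian noise mode adds seeded zero-mean noise", {
  g <- tiny_geometry(8, 16)
  clean <- sinogram(matrix(1, 8, 16), g)
  nc <- noise_config(100, seed = 6, type = "gaussian", sigma = 0.05)
  out <- simulate_noisy_sinogram(clean, nc)
  expect_identical(out$values, simulate_noisy_sinogram(clean, nc)$values)
  resid <- out$values - clean$values
  expect_lt(abs(mean(resid)), 3 * 0.05 / sqrt(length(resid)))
  expect_lt(abs(sd(resid) - 0.05) / 0.05, 0.2)
})
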