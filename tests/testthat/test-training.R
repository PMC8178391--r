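make_static_fixture <- function(N = 32, nsl = 3, num_angles = 48, I0 = 2000,
                                seed = 1) {
  ph <- static_phantom(N, depth = nsl, num_features = 3, seed = seed)
  g <- make_geometry(num_angles, pi, num_detector_pixels = N, image_size = N)
  nc <- noise_config(I0, seed = seed + 1)
  sinos <- lapply(seq_len(nsl), function(s)
    simulate_noisy_sinogram(forward_project(volume_slice(ph, s), g), nc,
                            seed = 100 * seed + s))
  list(phantom = ph, geometry = g, sinos = sinos)
}

test_that("training pairs follow the round-robin layout per strategy", {
  fx <- make_static_fixture(N = 32, nsl = 8)
  sch <- angular_split(48, 2)
  pairs <- make_training_pairs(fx$sinos, sch, "static_25d", context = 1)
  expect_length(pairs, 16)  # 2 sections x 8 slices
  expect_equal(dim(pairs[[1]]$input), c(32, 32, 3))
  expect_equal(dim(pairs[[1]]$target), c(32, 32, 1))
  combos <- vapply(pairs, function(p) paste(p$j, p$provenance$slice), "")
  expect_equal(anyDuplicated(combos), 0)

  # dynamic: K = 3, one group -> 3 pairs, target reconstructed from 2 steps
  N <- 32
  sched <- interlaced_schedule(3, 20)
  dsin <- lapply(1:3, function(t) {
    g <- projection_geometry(sched[[t]], N, N)
    sinogram(matrix(abs(rnorm(20 * N)), 20), g)
  })
  dp <- make_training_pairs(dsin, dynamic_split(3), "dynamic")
  expect_length(dp, 3)
  expect_equal(dim(dp[[1]]$input), c(N, N, 1))
  expect_equal(vapply(dp, function(p) p$provenance$time_step, 1L), 1:3)

  # multichannel: inputs and targets carry all channels
  g <- make_geometry(24, pi, num_detector_pixels = N, image_size = N)
  chans <- lapply(1:4, function(c0) sinogram(matrix(abs(rnorm(24 * N)), 24), g))
  mp <- make_training_pairs(chans, multichannel_split(chans, 3), "multichannel")
  expect_length(mp, 3)
  expect_equal(dim(mp[[1]]$input), c(N, N, 4))
  expect_equal(dim(mp[[1]]$target), c(N, N, 4))
})

test_that("condition-violating schemes are refused", {
  fx <- make_static_fixture()
  bad <- split_scheme(list(c(1, 2), c(3, 4)), list(2:48, c(1, 2, 5)),
                      "angle", 48)
  expect_error(make_training_pairs(fx$sinos, bad, "static_25d"), "conditions")
})

test_that("training reduces the loss on an identity-learnable fixture and is reproducible", {
  # noise-free pairs with input == target: the model can learn the identity
  N <- 32
  ph <- 0.02 * smooth_phantom(N)
  img <- array(ph, c(N, N, 1))
  pairs <- lapply(1:4, function(k)
    list(input = img + 0.001 * k, target = img + 0.001 * k, j = 1,
         provenance = list(slice = k)))
  cfg <- training_config(iterations = 120, batch_size = 2, shuffle_seed = 5)
  m <- build_msd(msd_config(4, 1, 1, weight_init_seed = 2))
  fit1 <- train(pairs, m, cfg)
  expect_lt(tail(fit1$loss_history, 1), 0.1 * fit1$loss_history[1])
  fit2 <- train(pairs, build_msd(msd_config(4, 1, 1, weight_init_seed = 2)), cfg)
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_identical(fit1$weights, fit2$weights)
})

test_that("the fitted model object exposes the standard S3 surface", {
  fx <- make_static_fixture(N = 32, nsl = 2)
  fit <- noise2inverse(fx$sinos, angular_split(48, 2), strategy = "static_25d",
                       depth = 3, iterations = 30, batch_size = 2,
                       shuffle_seed = 2, weight_init_seed = 3)
  expect_s3_class(fit, "noise2inverse")
  expect_output(print(fit), "Noise2Inverse")
  expect_output(summary(fit), "Optimizer")
  expect_length(coef(fit), count_parameters(fit$model))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  den <- predict(fit, fx$sinos)
  expect_equal(dim(den), c(2, 32, 32))
})

test_that("split-average inference equals the mean of per-section outputs", {
  fx <- make_static_fixture(N = 32, nsl = 2)
  sch <- angular_split(48, 2)
  fit <- noise2inverse(fx$sinos, sch, strategy = "static_25d", depth = 3,
                       iterations = 20, batch_size = 2, shuffle_seed = 1,
                       weight_init_seed = 1)
  avg <- predict(fit, fx$sinos, mode = "split_average")
  manual <- 0
  for (j in 1:2) {
    vol <- array(0, dim = c(2, 32, 32))
    for (s in 1:2)
      vol[s, , ] <- fbp_reconstruct(extract_section(fx$sinos[[s]],
                                                    sch$input_sets[[j]]))
    out <- array(0, dim = c(2, 32, 32))
    for (s in 1:2)
      out[s, , ] <- apply_model(fit$model, assemble_25d_input(vol, s, 0))[, , 1]
    manual <- manual + out
  }
  expect_identical(avg, manual / 2)
})

test_that("dynamic inference denoises each step alone with stable statics", {
  res <- experiment_dynamic(seed = 2, N = 48, angles_per_step = 40,
                            I0 = 500, depth = 10, iterations = 600)
  # shapes: one output per evaluated step
  expect_length(res$eval_steps, 3)
  expect_lt(res$mse_denoised, res$mse_single)
  expect_lt(res$mse_combined, res$mse_single)
})

test_that("self-supervised training lowers the supervised loss it never sees", {
  # the supervised loss (against noise-free reconstructions, known only to
  # the simulation) should drop over training in (nearly) every seeded run
  N <- 32
  ph <- static_phantom(N, depth = 2, num_features = 3, seed = 21)
  g <- make_geometry(48, pi, num_detector_pixels = N, image_size = N)
  clean_recs <- lapply(1:2, function(s)
    fbp_reconstruct(forward_project(volume_slice(ph, s), g)))
  wins <- 0
  for (seed in 1:5) {
    nc <- noise_config(300, seed = 30 + seed)
    sinos <- lapply(1:2, function(s)
      simulate_noisy_sinogram(forward_project(volume_slice(ph, s), g), nc,
                              seed = 100 * seed + s))
    sup_loss <- function(fit) {
      den <- predict(fit, sinos)
      mean(vapply(1:2, function(s) mean((den[s, , ] - clean_recs[[s]])^2), 1))
    }
    fit0 <- noise2inverse(sinos, angular_split(48, 2), strategy = "static_25d",
                          depth = 6, iterations = 1, batch_size = 2,
                          shuffle_seed = seed, weight_init_seed = seed)
    fit1 <- noise2inverse(sinos, angular_split(48, 2), strategy = "static_25d",
                          depth = 6, iterations = 250, batch_size = 2,
                          shuffle_seed = seed, weight_init_seed = seed)
    if (sup_loss(fit1) < sup_loss(fit0)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("training refuses mismatched channel counts", {
  fx <- make_static_fixture(N = 32, nsl = 2)
  pairs <- make_training_pairs(fx$sinos, angular_split(48, 2), "static_25d",
                               context = 1)
  m <- build_msd(msd_config(3, 1, 1))
  expect_error(train(pairs, m, training_config(10)), "channels")
})
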