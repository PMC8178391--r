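test_that("static phantoms are deterministic and confined to the inscribed circle", {
  a <- static_phantom(48, depth = 4, num_features = 5, seed = 9)
  b <- static_phantom(48, depth = 4, num_features = 5, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$attenuation, b$attenuation)
  c0 <- (48 - 1) / 2
  xx <- matrix(rep(0:47, 48), 48) - c0
  outside <- xx^2 + t(xx)^2 > (48 / 2 - 2)^2
  for (s in 1:4) {
    sl <- matrix(a$labels[s, , ], 48)
    expect_true(all(sl[outside] == 0L))
  }
  # features exist and use the declared material classes
  expect_true(any(a$labels >= 2))
  expect_true(all(unique(as.vector(a$labels)) %in% c(0L, 1L, 2L, 3L, 4L)))
  # no features -> a uniform background disk
  u <- static_phantom(32, depth = 2, num_features = 0, seed = 1)
  expect_equal(sort(unique(as.vector(u$labels))), c(0L, 1L))
  expect_error(static_phantom(8, 1, 0, 1), "16")
})

test_that("dynamic phantoms stay static before the start step and grow monotonically", {
  dyn <- dynamic_phantom(48, depth = 2, T_steps = 8, start_step = 4,
                         growth_rate = 1, seed = 3, num_features = 3)
  for (t in 1:3)
    expect_identical(dyn$volumes[[t]]$labels, dyn$volumes[[1]]$labels)
  vol_incl <- vapply(1:8, function(t) sum(dyn$volumes[[t]]$labels == 9L), 1L)
  expect_true(all(vol_incl[1:3] == 0))
  expect_gt(vol_incl[4], 0)
  expect_true(all(diff(vol_incl) >= 0))
  # radius formula: a lone inclusion's area tracks pi r(t)^2
  d1 <- dynamic_phantom(64, depth = 1, T_steps = 6, start_step = 2,
                        growth_rate = 2, seed = 5, num_inclusions = 1,
                        num_features = 0, r0 = 2)
  areas <- vapply(2:6, function(t) sum(d1$volumes[[t]]$labels == 9L), 1L)
  radii <- 2 + 2 * (0:4)
  expect_lt(max(abs(areas / (pi * radii^2) - 1)), 0.2)
  expect_error(dynamic_phantom(48, 1, 5, 7, 1, 1), "start_step")
})

test_that("spectral phantoms satisfy the diffractogram correspondence invariant", {
  sp <- spectral_phantom(64, num_materials = 4, C = 11, seed = 2)
  expect_equal(dim(sp$channels), c(64, 64, 11))
  for (m in sort(unique(as.vector(sp$labels)))) {
    mask <- sp$labels == m
    for (c0 in seq_len(11)) {
      vals <- unique(sp$channels[, , c0][mask])
      expect_length(vals, 1)          # identical label, identical signature
      expect_equal(vals, sp$signature_table[m + 1, c0])
    }
  }
  expect_true(all(sp$signature_table >= 0))
  # every channel carries some signal (materials have a broadband baseline)
  expect_true(all(apply(sp$channels, 3, max) > 0))
  # C = 1 degenerates to a scalar-valued phantom
  s1 <- spectral_phantom(32, num_materials = 2, C = 1, seed = 4)
  expect_equal(dim(s1$channels)[3], 1)
  expect_identical(spectral_phantom(64, 4, 11, seed = 2)$channels, sp$channels)
})

test_that("interlaced schedules tile the full turn evenly", {
  # single step: plain uniform schedule over 2*pi
  s1 <- interlaced_schedule(1, 12)
  expect_equal(s1[[1]], (0:11) * 2 * pi / 12)
  # 6 x 300: union has 1800 distinct angles with equal consecutive gaps
  s6 <- interlaced_schedule(6, 300)
  all_angles <- sort(unlist(s6))
  expect_length(unique(all_angles), 1800)
  expect_equal(diff(all_angles), rep(2 * pi / 1800, 1799), tolerance = 1e-10)
  # jitter-free schedules never duplicate angles across steps
  expect_equal(anyDuplicated(unlist(s6)), 0)
  # jitter displaces each step rigidly
  sj <- interlaced_schedule(3, 10, jitter_sd = 0.001, seed = 8)
  s0 <- interlaced_schedule(3, 10)
  for (t in 1:3) {
    offs <- (sj[[t]] - s0[[t]] + pi) %% (2 * pi) - pi
    expect_lt(diff(range(offs)), 1e-12)
  }
})

test_that("volume slices expose the derived attenuation", {
  ph <- static_phantom(32, depth = 3, num_features = 2, seed = 6)
  sl <- volume_slice(ph, 2)
  expect_equal(dim(sl), c(32, 32))
  expect_equal(sl, matrix(ph$attenuation[2, , ], 32))
  expect_error(volume_slice(ph, 4), "range")
})
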