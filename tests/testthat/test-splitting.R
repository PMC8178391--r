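test_that("angular split is strided with complementary inputs", {
  sch <- angular_split(6, 3)
  expect_equal(sch$target_sets, list(c(1L, 4L), c(2L, 5L), c(3L, 6L)))
  expect_equal(vapply(sch$input_sets, length, 1L), rep(4L, 3))
  expect_equal(sch$input_sets[[1]], c(2L, 3L, 5L, 6L))
  # J = n: singleton targets
  schn <- angular_split(5, 5)
  expect_equal(vapply(schn$target_sets, length, 1L), rep(1L, 5))
  expect_equal(vapply(schn$input_sets, length, 1L), rep(4L, 5))
  # J = 3 over 360: inputs cover exactly 2/3
  s360 <- angular_split(360, 3)
  expect_equal(vapply(s360$input_sets, length, 1L) / 360, rep(2 / 3, 3))
  expect_error(angular_split(10, 1), "J")
  expect_error(angular_split(10, 11), "J")
})

test_that("non-divisible angle counts give near-equal sections covering all units", {
  for (n in c(7, 11, 100)) for (J in c(2, 3, 4)) {
    sch <- angular_split(n, J)
    sizes <- vapply(sch$target_sets, length, 1L)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_equal(sum(sizes), n)
    all_t <- unlist(sch$target_sets)
    expect_equal(sort(all_t), 1:n)        # exact cover, pairwise disjoint
    rep <- verify_conditions(sch)
    expect_true(rep$condition1_pass && rep$condition2_pass)
    # remainder goes to the lowest-index sections
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("extract_section subsets rows and derives the right geometry", {
  g <- tiny_geometry(6, 16)
  s <- sinogram(matrix(rnorm(6 * 16), 6), g)
  sub <- extract_section(s, c(1, 4))
  expect_equal(sub$values, s$values[c(1, 4), ])
  expect_equal(sub$geometry$angles, g$angles[c(1, 4)])
  ident <- extract_section(s, 1:6)
  expect_equal(ident$values, s$values)
  expect_error(extract_section(s, integer(0)), "nonempty")
  expect_error(extract_section(s, 7), "range")
})

test_that("dynamic split pairs one step against the rest", {
  sch <- dynamic_split(3)
  expect_equal(sch$input_sets, list(1L, 2L, 3L))
  expect_equal(sch$target_sets[[1]], c(2L, 3L))
  expect_equal(sch$unit_kind, "time_step")
  rep <- verify_conditions(sch)
  expect_true(rep$condition1_pass && rep$condition2_pass)
  # K = 6: input:target size ratio 1:5
  s6 <- dynamic_split(6)
  expect_equal(vapply(s6$input_sets, length, 1L), rep(1L, 6))
  expect_equal(vapply(s6$target_sets, length, 1L), rep(5L, 6))
  # K = 2: symmetric 1:1
  s2 <- dynamic_split(2)
  expect_equal(vapply(s2$target_sets, length, 1L), rep(1L, 2))
  expect_error(dynamic_split(1), "2")
})

test_that("combining interlaced time steps merges and sorts disjoint angle lists", {
  N <- 16
  sched <- interlaced_schedule(2, 4)
  sinos <- lapply(1:2, function(t) {
    g <- projection_geometry(sched[[t]], N, N)
    sinogram(matrix(t, 4, N), g)
  })
  comb <- combine_time_steps(sinos)
  expect_equal(nrow(comb$values), 8)
  expect_true(all(diff(comb$geometry$angles) > 0))
  expect_equal(sort(unique(comb$provenance)), 1:2)
  # identity on a single sinogram
  expect_identical(combine_time_steps(sinos[1]), sinos[[1]])
  # duplicate angles are rejected
  expect_error(combine_time_steps(list(sinos[[1]], sinos[[1]])), "duplicate")
})

test_that("combining interlaced steps of a static object lowers FBP error", {
  N <- 64
  ph <- 0.03 * smooth_phantom(N)  # attenuation scaled to photon-friendly paths
  sched <- interlaced_schedule(6, 50)
  nc <- noise_config(5000, seed = 2)
  sinos <- lapply(1:6, function(t) {
    g <- projection_geometry(sched[[t]], N, N)
    simulate_noisy_sinogram(forward_project(ph, g), nc, seed = 100 + t)
  })
  mse_single <- mean((fbp_reconstruct(sinos[[1]]) - ph)^2)
  mse_comb <- mean((fbp_reconstruct(combine_time_steps(sinos)) - ph)^2)
  expect_lt(mse_comb, mse_single)
})

test_that("multichannel split shares one scheme across identical geometries", {
  g <- tiny_geometry(12, 16)
  chans <- lapply(1:4, function(c0) sinogram(matrix(rnorm(12 * 16), 12), g))
  sch <- multichannel_split(chans, 3)
  expect_equal(sch$J, 3)
  expect_equal(sch$num_units, 12L)
  # single channel reduces to the plain angular split
  expect_equal(multichannel_split(chans[1], 3), angular_split(12, 3))
  # mismatched angle counts rejected
  g2 <- tiny_geometry(10, 16)
  bad <- sinogram(matrix(0, 10, 16), g2)
  expect_error(multichannel_split(list(chans[[1]], bad), 2), "identical")
})

test_that("condition verification flags overlaps and unequal target coverage", {
  good <- angular_split(360, 4)
  rep <- verify_conditions(good)
  expect_true(rep$condition1_pass)
  expect_true(rep$condition2_pass)
  expect_length(rep$violations, 0)

  overlap <- split_scheme(list(c(1, 2), c(3, 4)), list(c(2, 3, 4), c(1, 2)),
                          "angle", 4)
  r1 <- verify_conditions(overlap)
  expect_false(r1$condition1_pass)
  expect_match(paste(r1$violations, collapse = " "), "overlap")

  gap <- split_scheme(list(c(1, 2), c(3, 4)), list(c(3, 4, 5, 6), c(1, 2, 5, 6)),
                      "angle", 6)
  r2 <- verify_conditions(gap, num_units = 6)
  expect_false(r2$condition2_pass)
  expect_match(paste(r2$violations, collapse = " "), "no target set")
})

test_that("split schemes round-trip through JSON", {
  sch <- angular_split(17, 4)
  txt <- scheme_to_json(sch)
  back <- scheme_from_json(txt)
  expect_equal(back, sch)
  f <- tempfile(fileext = ".json")
  scheme_to_json(dynamic_split(5), f)
  expect_equal(scheme_from_json(f), dynamic_split(5))
})

test_that("noise in complementary section reconstructions is uncorrelated", {
  # Monte-Carlo: per-pixel covariance between input- and target-section
  # reconstruction noise averages to zero within 3 standard errors.
  N <- 32
  g <- make_geometry(48, pi, num_detector_pixels = N, image_size = N)
  ph <- disk_image(N, 10, 0.02)
  clean <- forward_project(ph, g)
  sch <- angular_split(48, 2)
  nc <- noise_config(1000, seed = 1)
  R <- 60
  rin <- array(0, dim = c(R, N, N))
  rtg <- array(0, dim = c(R, N, N))
  in_clean <- fbp_reconstruct(extract_section(clean, sch$input_sets[[1]]))
  tg_clean <- fbp_reconstruct(extract_section(clean, sch$target_sets[[1]]))
  for (r in 1:R) {
    noisy <- simulate_noisy_sinogram(clean, nc, seed = 400 + r)
    rin[r, , ] <- fbp_reconstruct(extract_section(noisy, sch$input_sets[[1]])) - in_clean
    rtg[r, , ] <- fbp_reconstruct(extract_section(noisy, sch$target_sets[[1]])) - tg_clean
  }
  covs <- vapply(seq_len(N * N), function(k) {
    i <- (k - 1) %% N + 1; j <- (k - 1) %/% N + 1
    cov(rin[, i, j], rtg[, i, j])
  }, 1)
  z <- mean(covs) / (sd(covs) / sqrt(length(covs)))
  expect_lt(abs(z), 3)
})
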