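test_that("circular convolution matches the brute-force oracle and commutes", {
  set.seed(4)
  n <- 8
  x <- matrix(runif(n * n), n, n)
  k <- matrix(runif(n * n), n, n)
  expect_equal(circ_conv2(x, k), brute_cconv2(x, k), tolerance = 1e-10)
  ab <- circ_conv2(x, k)
  ba <- circ_conv2(k, x)
  expect_lt(max(abs(ab - ba)) / max(abs(ab)), 1e-10)

  # centered delta kernel is the identity; padded (linear) mode agrees with
  # the cyclic one when the kernel is compactly supported near the center
  expect_equal(circ_conv2(x, delta_kernel(n)), x, tolerance = 1e-12)
  expect_equal(circ_conv2(x, delta_kernel(n), pad = TRUE), x, tolerance = 1e-10)
})

test_that("incoherent frames follow I_m = P_m (*) O with energy conservation", {
  obj <- make_test_target(16, "ring") + 0.2
  M <- 6
  fr_delta <- synthesize_frames(obj, delta_psf_stack(16, M))
  for (m in seq_len(M)) expect_equal(fr_delta[, , m], obj, tolerance = 1e-12)

  sim <- simulate_incoherent_stack(obj, M = 8,
                                   screen_params = list(corr_len_px = 2, rms_rad = 2 * pi),
                                   seed = 5)
  expect_s3_class(sim$stack, "frame_stack")
  expect_true(all(sim$stack$frames >= 0))
  # unit-sum PSFs conserve every frame's total under circular convolution
  per_frame <- apply(sim$stack$frames, 3, sum)
  expect_equal(per_frame, rep(sum(obj), 8), tolerance = 1e-9)
  psum <- apply(sim$psfs, 3, sum)
  expect_equal(psum, rep(1, 8), tolerance = 1e-12)

  sim2 <- simulate_incoherent_stack(obj, M = 8,
                                    screen_params = list(corr_len_px = 2, rms_rad = 2 * pi),
                                    seed = 5)
  expect_identical(sim$stack$frames, sim2$stack$frames)

  expect_error(simulate_incoherent_stack(obj, M = 1), "M")
  expect_error(simulate_incoherent_stack(matrix(1i, 4, 4), M = 4), "real")
})

test_that("distinct-frame centered PSFs are uncorrelated for strong screens", {
  # the sampling bound is set by the effective number of speckle modes (the
  # variance participation ratio), not the raw pixel count: the PSF
  # envelope concentrates the variance on a subset of the grid
  n <- 64
  M <- 60
  sim <- simulate_incoherent_stack(matrix(1.5, n, n) + 0.001, M = M,
                                   screen_params = list(corr_len_px = 1.5, rms_rad = 2 * pi),
                                   seed = 9)
  v <- apply(sim$psfs, c(1, 2), var)
  n_eff <- sum(v)^2 / sum(v^2)
  ctr <- sweep(sim$psfs, c(1, 2), apply(sim$psfs, c(1, 2), mean), "-")
  set.seed(1)
  pairs <- cbind(sample(M), sample(M))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE][1:30, ]
  cors <- apply(pairs, 1, function(p) {
    cor(as.vector(ctr[, , p[1]]), as.vector(ctr[, , p[2]]))
  })
  expect_lt(median(abs(cors)), 3 / sqrt(n_eff))
})

test_that("coherent frames follow E_m = P_m (*) (O E_ill) with Parseval", {
  n <- 16
  refl <- matrix(0i, n, n); refl[5:12, 5:12] <- 1
  illum <- matrix(exp(1i * 0.3), n, n)
  sim <- simulate_coherent_stack(refl, illum, M = 6,
                                 screen_params = list(corr_len_px = 2, rms_rad = 2 * pi),
                                 seed = 2)
  expect_true(is.complex(sim$stack$frames))
  # unit-energy APSFs under cyclic convolution preserve field energy only on
  # average, but the spectral product form gives exact per-frame energy
  # sum |E_m|^2 = sum_k |P~|^2 |O~|^2 / N^2; for phase-only full-aperture
  # screens |P~| is flat so energy equals that of O_eff exactly
  e_o <- sum(Mod(sim$o_eff)^2)
  per <- apply(sim$stack$frames, 3, function(f) sum(Mod(f)^2))
  expect_equal(per, rep(e_o, 6), tolerance = 1e-9)

  # delta APSF reduces to the effective object
  fr <- synthesize_frames(sim$o_eff, array(rep(delta_kernel(n) + 0i, 2), c(n, n, 2)))
  expect_equal(fr[, , 1], sim$o_eff, tolerance = 1e-12)

  expect_error(simulate_coherent_stack(refl, matrix(1i, 4, 4), M = 4), "grid")
  expect_error(simulate_coherent_stack(refl, matrix(0i, n, n), M = 4), "energy")
})

test_that("strong-screen speckle fields are zero-mean across realizations", {
  n <- 32
  refl <- bandlimited_field(n, 0.4, seed = 8)
  sim <- simulate_coherent_stack(refl, M = 50,
                                 screen_params = list(corr_len_px = 2, rms_rad = 2 * pi),
                                 seed = 13)
  emean <- apply(sim$stack$frames, c(1, 2), mean)
  ratio <- mean(Mod(emean)) / mean(Mod(sim$stack$frames))
  expect_lt(ratio, 0.2)
})

test_that("off-axis holograms are non-negative with a pure-reference limit", {
  n <- 32
  h0 <- simulate_offaxis_hologram(matrix(0i, n, n), c(8, 8), ref_amplitude = 1.5)
  expect_equal(h0, matrix(1.5^2, n, n), tolerance = 1e-12)
  fld <- bandlimited_field(n, 0.2, seed = 3)
  h <- simulate_offaxis_hologram(fld, c(9, 9))
  expect_true(min(h) >= 0)
  expect_error(simulate_offaxis_hologram(fld, c(16, 0)), "Nyquist")
})

test_that("frame correlation produces temporally correlated screens", {
  n <- 32
  s_un <- simulate_incoherent_stack(matrix(1, n, n) + delta_kernel(n), M = 20,
                                    screen_params = list(corr_len_px = 3, rms_rad = 2 * pi),
                                    frame_correlation = 0, seed = 21)
  # the phasor decorrelates much faster than the underlying Gaussian, so a
  # mixing weight very close to 1 is needed for visibly correlated PSFs
  s_co <- simulate_incoherent_stack(matrix(1, n, n) + delta_kernel(n), M = 20,
                                    screen_params = list(corr_len_px = 3, rms_rad = 2 * pi),
                                    frame_correlation = 0.995, seed = 21)
  adj <- function(sim) {
    mean(vapply(1:19, function(m) {
      cor(as.vector(sim$psfs[, , m]), as.vector(sim$psfs[, , m + 1]))
    }, numeric(1)))
  }
  expect_gt(adj(s_co), adj(s_un) + 0.3)
})
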