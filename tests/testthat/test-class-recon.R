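test_that("exact-model covariances yield machine-level phase recovery", {
  set.seed(14)
  n <- 8
  Otil <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  # PSF pixel covariance concentrated at the origin (rank-1 covariance) and
  # at an off-origin pixel (pure-ramp Toeplitz kernel): both cases recover
  # arg(Otil) up to constant + integer linear ramp
  for (r0 in list(c(0, 0), c(2, 1))) {
    C <- model_covariance(Otil, r0)
    pr <- class_phase_retrieval_cov(C, c(n, n), n_iter = 200, tol = 1e-12)
    res <- remove_phase_ramp(pr$psi - Arg(Otil))$psi
    expect_lt(max(abs(res)), 1e-6)
  }
})

test_that("a real positive spectrum is a fixed point of the update", {
  n <- 8
  amp <- matrix(runif(n * n, 0.5, 2), n, n)
  C <- model_covariance(amp + 0i, c(0, 0))
  pr <- class_phase_retrieval_cov(C, c(n, n), n_iter = 5, tol = 0)
  expect_lt(max(abs(pr$psi)), 1e-10)
})

test_that("frame-domain and dense-covariance updates agree", {
  obj <- make_test_target(8, "ring") + 0.1
  sim <- simulate_incoherent_stack(obj, M = 10,
                                   screen_params = list(corr_len_px = 2, rms_rad = 2 * pi),
                                   seed = 3)
  A <- frames_to_spectral_matrix(sim$stack)
  p1 <- class_phase_retrieval(A, n_iter = 15, tol = 0)
  p2 <- class_phase_retrieval_cov(covariance(A), A$dim, n_iter = 15, tol = 0)
  expect_lt(max(abs(wrap_phase(p1$psi - p2$psi))), 1e-8)
  expect_lt(max(Mod(p1$kernel - p2$kernel)) / max(Mod(p1$kernel)), 1e-8)
  expect_equal(p1$trace, p2$trace, tolerance = 1e-8)

  expect_error(class_phase_retrieval(
    frames_to_spectral_matrix(frame_stack(array(0, c(4, 4, 3)), "incoherent"))),
    "zero")
})

test_that("phase trace decreases monotonically after burn-in on noiseless input", {
  set.seed(15)
  n <- 8
  Otil <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  pr <- class_phase_retrieval_cov(model_covariance(Otil), c(n, n),
                                  n_iter = 60, tol = 0)
  tr <- pr$trace[-(1:5)]
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("delta-PSF stacks reconstruct the object exactly", {
  obj <- make_test_target(16, "bars")
  fr <- synthesize_frames(obj, delta_psf_stack(16, 5))
  # tiny per-frame perturbation so the centered stack is not identically zero
  for (m in 1:5) fr[, , m] <- fr[, , m] * (1 + 0.01 * m)
  rec <- iclass_reconstruct(frame_stack(fr, "incoherent"), n_iter = 200)
  expect_gt(registered_correlation(rec$object_image, obj)$r, 1 - 1e-6)
})

test_that("reconstruction is equivariant under common cyclic shifts", {
  obj <- make_test_target(16, "ring") + 0.05
  sim <- simulate_incoherent_stack(obj, M = 40,
                                   screen_params = list(corr_len_px = 2, rms_rad = 2 * pi),
                                   seed = 16)
  rec0 <- iclass_reconstruct(sim$stack, n_iter = 150)
  sh <- c(3, 5)
  fr_sh <- array(0, dim(sim$stack$frames))
  for (m in seq_len(dim(fr_sh)[3])) fr_sh[, , m] <- circ_shift(sim$stack$frames[, , m], sh)
  rec1 <- iclass_reconstruct(frame_stack(fr_sh, "incoherent"), n_iter = 150)
  r0 <- registered_correlation(rec0$object_image, obj)$r
  r1 <- registered_correlation(rec1$object_image, obj)$r
  expect_lt(abs(r0 - r1), 1e-6)
})

test_that("registered correlation is invariant to shift and reflection", {
  set.seed(17)
  img <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(registered_correlation(img, img)$r, 1, tolerance = 1e-12)
  expect_equal(registered_correlation(img, circ_shift(img, c(5, 9)))$r, 1,
               tolerance = 1e-12)
  refl <- img[c(1, 32:2), c(1, 32:2)]
  reg <- registered_correlation(img, refl)
  expect_equal(reg$r, 1, tolerance = 1e-12)
  expect_true(reg$reflected)

  rs <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    registered_correlation(img, matrix(rnorm(32 * 32), 32, 32))$r
  }, numeric(1))
  # registration maximizes over 2*32^2 shifts, inflating the null; still
  # far below any genuine-structure correlation
  expect_lt(max(abs(rs)), 0.25)
  expect_lt(median(abs(rs)), 0.15)

  expect_error(registered_correlation(matrix(1, 4, 4), img[1:4, 1:4]), "constant")
})

test_that("Wiener deconvolution recovers the per-frame PSFs", {
  # a random scatterer field has a flat spectrum, so every frequency the
  # white speckle PSFs occupy is recoverable; objects with deep spectral
  # zeros lose the corresponding PSF content irrespective of reg_eps
  set.seed(18)
  obj <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64) * 1
  sim <- simulate_incoherent_stack(obj, M = 6,
                                   screen_params = list(corr_len_px = 3, rms_rad = 2 * pi),
                                   seed = 18)
  ph <- estimate_frame_psfs(sim$stack, obj, reg_eps = 1e-6)
  for (m in 1:6) {
    expect_gt(registered_correlation(ph[, , m], sim$psfs[, , m])$r, 0.99)
    expect_equal(sum(ph[, , m]), 1, tolerance = 1e-12)
    expect_true(all(ph[, , m] >= 0))
  }

  # delta object: the PSF estimate is the renormalized frame itself
  dl <- delta_kernel(64)
  fr <- synthesize_frames(dl, sim$psfs)
  pd <- estimate_frame_psfs(frame_stack(fr, "incoherent"), dl, reg_eps = 1e-10)
  expect_equal(pd[, , 3], sim$psfs[, , 3], tolerance = 1e-6)

  expect_error(estimate_frame_psfs(sim$stack, matrix(0, 64, 64)), "zero")
  expect_error(estimate_frame_psfs(sim$stack, obj, reg_eps = 0), "reg_eps")
})

test_that("APSF estimates recover the scatterer realizations", {
  n <- 32
  # diffusely reflecting mask: the weak random phase spreads its spectrum
  # across the pupil so the ratio carries the scatterer phase everywhere
  mask <- matrix(0, n, n); mask[9:24, 9:24] <- 1
  refl <- mask * exp(1i * generate_phase_screen(n, 2, 1, seed = 77)$phase)
  sim <- simulate_coherent_stack(refl, M = 6,
                                 screen_params = list(corr_len_px = 3, rms_rad = 2 * pi,
                                                      pupil_frac = 0.5),
                                 seed = 19)
  est <- estimate_apsfs(sim$stack, sim$o_eff, support_thresh = 0.02)
  for (m in 1:6) {
    expect_equal(sum(Mod(est[, , m])^2), 1, tolerance = 1e-12)
    expect_gt(registered_correlation(Mod(est[, , m]), Mod(sim$apsfs[, , m]))$r, 0.9)
  }

  # identical field and reference give a diffraction-limited (delta) APSF;
  # use a flat-spectrum object so the support covers the whole grid
  set.seed(20)
  flat <- ifft2(matrix(exp(2i * pi * runif(n * n)), n, n))
  st1 <- frame_stack(array(rep(flat, 2), c(n, n, 2)), "coherent")
  e1 <- estimate_apsfs(st1, flat, support_thresh = 0.02)
  expect_gt(max(Mod(e1[, , 1])^2), 0.99)   # energy concentrated in one sample

  expect_error(estimate_apsfs(sim$stack, sim$o_eff, support_thresh = 2), "support")
})
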