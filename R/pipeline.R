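# End-to-end experiment runner: simulate -> (modulate) -> reconstruct ->
# evaluate, with a reproducible manifest.

#' Built-in binary test targets
#'
#' Resolution-chart-like binary objects used by the examples, tests and the
#' experiment runner: three-bar groups plus squares (`"bars"`), a ring of
#' disks emulating a bead sample (`"beads"`), or a centered annulus
#' (`"ring"`).
#'
#' @param n Grid size.
#' @param kind `"bars"`, `"beads"` or `"ring"`.
#' @return An `n x n` binary matrix.
#' @export
make_test_target <- function(n, kind = c("bars", "beads", "ring")) {
  kind <- match.arg(kind)
  x <- matrix(0, n, n)
  if (kind == "bars") {
    bw <- max(1L, round(n / 16))     # bar width
    len <- max(4L, round(n / 4))
    top <- round(n / 5)
    left <- round(n / 6)
    for (k in 0:2) {                 # vertical three-bar group
      x[top + seq_len(len), left + k * 2L * bw + seq_len(bw)] <- 1
    }
    top2 <- round(3 * n / 5)
    for (k in 0:2) {                 # horizontal group
      x[top2 + k * 2L * bw + seq_len(bw), left + seq_len(len)] <- 1
    }
    sq <- max(3L, round(n / 10))
    x[top + seq_len(sq), round(2 * n / 3) + seq_len(sq)] <- 1
    x[round(2 * n / 3) + seq_len(sq), round(2 * n / 3) + seq_len(sq)] <- 1
  } else if (kind == "beads") {
    cx <- n / 2; rad <- n / 4; brad <- max(1.5, n / 24)
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    ii <- matrix(seq_len(n), n, n)
    jj <- t(ii)
    for (a in ang) {
      x[(ii - cx - rad * cos(a))^2 + (jj - cx - rad * sin(a))^2 <= brad^2] <- 1
    }
    x[(ii - cx)^2 + (jj - cx)^2 <= brad^2] <- 1
  } else {
    ii <- matrix(seq_len(n), n, n)
    jj <- t(ii)
    r2 <- (ii - n / 2)^2 + (jj - n / 2)^2
    x[r2 <= (n / 3)^2 & r2 >= (n / 5)^2] <- 1
  }
  x
}

#' Background-haze metric of a reconstruction
#'
#' Registers the ground-truth object to the reconstruction (cyclic shift
#' and twin reflection), normalizes the reconstruction to `[0, 1]`, and
#' returns the median intensity over the pixels outside the registered
#' object support.  Lower is better; a haze-free reconstruction of a binary
#' object scores near 0.
#'
#' @param recon Reconstructed image (matrix or `recon_result`).
#' @param truth Ground-truth object matrix.
#' @param support_thresh Support threshold on the normalized truth.
#' @return List with `haze` (median outside intensity) and `r` (the
#'   registered correlation used for alignment).
#' @export
haze_metric <- function(recon, truth, support_thresh = 0.5) {
  img <- if (inherits(recon, "recon_result")) recon$object_image else recon
  if (is.complex(img)) img <- Mod(img)
  reg <- registered_correlation(img, truth)
  tb <- truth
  if (reg$reflected) {
    tb <- tb[c(1, rev(seq_len(nrow(tb))[-1])), c(1, rev(seq_len(ncol(tb))[-1]))]
  }
  tb <- circ_shift(tb, reg$shift)
  rng <- range(img)
  imgn <- (img - rng[1]) / (rng[2] - rng[1])
  outside <- tb <= support_thresh * max(tb)
  list(haze = stats::median(imgn[outside]), r = reg$r)
}

#' Default experiment configuration
#'
#' @param mode `"incoherent"` or `"coherent"`.
#' @return A config list accepted by [run_experiment()], reflecting the
#'   reference study conditions: 64 x 64 grid, M = 150 uncorrelated
#'   phase-only screens (rms 3 pi, correlation length 4 px) with the 1 to 2
#'   intensity-modulation protocol in incoherent mode; M = 180 realizations
#'   with focused (constant) illumination, off-axis holographic recording
#'   and Fresnel back-propagation in coherent mode; 1000 iterations.
#' @export
default_config <- function(mode = c("incoherent", "coherent")) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    n = if (mode == "incoherent") 64L else 128L,
    M = if (mode == "incoherent") 150L else 180L,
    object = "bars",
    # incoherent: Nyquist-sampled diffraction-limited system (pupil at half
    # the sampling Nyquist); coherent: quarter-Nyquist pupil so the off-axis
    # hologram sidebands separate.  Phase-only screens conserve energy in
    # both cases.
    screen_params = list(corr_len_px = 4, rms_rad = 3 * pi,
                         pupil_frac = if (mode == "incoherent") 0.5 else 0.25),
    frame_correlation = 0,
    noise_params = NULL,
    modulation = if (mode == "incoherent") c(1, 2) else NULL,
    n_iter = 1000L,
    tol = 1e-6,
    seed = 1L
  )
  if (mode == "coherent") {
    # dz chosen well inside the transfer-function sampling limit
    # lambda |dz| / (N pitch^2) < 1 for the 128 x 128, 5.5 um default grid
    cfg$propagation <- list(wavelength_um = 0.6328, pitch_um = 5.5,
                            dz_um = 4000)
    cfg$carrier_cycles <- c(38, 38)
    cfg$crop_radius_frac <- 0.25
    # support threshold for APSF estimation; noiseless synthetic fields
    # tolerate a low threshold, raise it for noisy data
    cfg$apsf_support_thresh <- 0.01
    # diffuse-backing phase of the reflective mask (spreads its spectrum
    # across the pupil, as a diffusive slide behind the target would)
    cfg$object_phase_rms <- 1
    cfg$object_phase_corr_px <- 2
  }
  cfg
}

# Central spatial window of a PSF stack: the pixelwise-covariance
# diagnostic is quadratic in the pixel count, so it is evaluated on a crop.
central_crop <- function(stack, w) {
  d <- dim(stack)
  if (d[1] <= w) return(stack)
  ii <- floor(d[1] / 2) + 1 - floor(w / 2) - 1 + seq_len(w)
  jj <- floor(d[2] / 2) + 1 - floor(w / 2) - 1 + seq_len(w)
  stack[ii, jj, , drop = FALSE]
}

# Merge user settings over the defaults; validate the few invariants the
# stages do not already check.
resolve_config <- function(config = list()) {
  mode <- if (is.null(config$mode)) "incoherent" else config$mode
  cfg <- utils::modifyList(default_config(mode), config)
  if (cfg$n < 8) stop("grid size must be >= 8", call. = FALSE)
  if (cfg$M < 2) stop("M must be >= 2", call. = FALSE)
  if (cfg$n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  cfg
}

#' Run a full simulated imaging experiment
#'
#' Simulates a frame stack through a dynamic scatterer under the given
#' configuration, reconstructs the hidden object, and evaluates the result
#' against the ground truth.  In coherent mode the pipeline additionally
#' records and demodulates off-axis holograms and Fresnel-propagates
#' between the object and scattering-layer planes.  Fully deterministic per
#' seed.
#'
#' @param config A config list (see [default_config()]), or a path to a
#'   YAML file with the same fields.
#' @param out_dir Optional output directory; when given, the object, the
#'   reconstruction, the frame stack, the resolved config and a JSON
#'   manifest are written there.
#' @return The manifest: a list with `config`, `metrics` (registered
#'   correlations `r_recon` and `r_mean_frame`, `psf_recovery` mean
#'   correlation, `diagonality`, `haze`), `trace` (convergence), and
#'   `results` (object, reconstruction, stack) unless `out_dir` captured
#'   them.
#' @export
run_experiment <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- resolve_config(config)
  truth <- if (is.matrix(cfg$object)) cfg$object else make_test_target(cfg$n, cfg$object)

  if (cfg$mode == "incoherent") {
    sim <- simulate_incoherent_stack(truth, M = cfg$M,
                                     screen_params = cfg$screen_params,
                                     frame_correlation = cfg$frame_correlation,
                                     noise_params = cfg$noise_params,
                                     seed = cfg$seed)
    rec <- iclass_reconstruct(sim$stack, n_iter = cfg$n_iter, tol = cfg$tol,
                              modulation = cfg$modulation)
    recon_img <- rec$object_image
    mean_frame <- rec$mean_frame
    psfs_hat <- estimate_frame_psfs(sim$stack, rec)
    sub <- seq_len(min(20L, cfg$M))
    psf_r <- vapply(sub, function(m) {
      registered_correlation(psfs_hat[, , m], sim$psfs[, , m])$r
    }, numeric(1))
    diagonality <- tryCatch(
      psf_diagonality(central_crop(sim$psfs, 32L)[, , seq_len(min(cfg$M, 50L))]),
      error = function(e) NA_real_)  # e.g. static (rms = 0) control screens
  } else {
    pc_back <- propagation_config(cfg$propagation$wavelength_um,
                                  cfg$propagation$pitch_um,
                                  -cfg$propagation$dz_um, cfg$n)
    pc_fwd <- propagation_config(cfg$propagation$wavelength_um,
                                 cfg$propagation$pitch_um,
                                 cfg$propagation$dz_um, cfg$n)
    # the object is a diffusely reflecting mask (a weak random phase stands
    # in for a diffusive backing), so its spectrum fills the system pupil;
    # it sits dz behind the scattering layer: propagate its field to the
    # layer plane, scatter there, then image the layer plane
    dphase <- generate_phase_screen(cfg$n, cfg$object_phase_corr_px,
                                    cfg$object_phase_rms,
                                    seed = derive_seed(cfg$seed, 424243L))$phase
    o_field <- fresnel_propagate(truth * exp(1i * dphase), pc_back)$field
    sim <- simulate_coherent_stack(o_field, M = cfg$M,
                                   screen_params = cfg$screen_params,
                                   seed = cfg$seed)
    holos <- array(0, dim(sim$stack$frames))
    fields <- array(0i, dim(sim$stack$frames))
    for (m in seq_len(cfg$M)) {
      h <- simulate_offaxis_hologram(sim$stack$frames[, , m],
                                     cfg$carrier_cycles)
      holos[, , m] <- h
      fields[, , m] <- demodulate_offaxis(h, cfg$carrier_cycles,
                                          cfg$crop_radius_frac)$field
    }
    dstack <- frame_stack(fields, "coherent", seed = cfg$seed)
    rec <- iclass_reconstruct(dstack, n_iter = cfg$n_iter, tol = cfg$tol)
    recon_obj <- fresnel_propagate(rec$object_image, pc_fwd)$field
    recon_img <- Mod(recon_obj)
    mean_frame <- Mod(fresnel_propagate(apply(fields, c(1, 2), mean), pc_fwd)$field)
    apsfs_hat <- estimate_apsfs(dstack, sim$o_eff,
                                support_thresh = cfg$apsf_support_thresh)
    sub <- seq_len(min(20L, cfg$M))
    psf_r <- vapply(sub, function(m) {
      registered_correlation(Mod(apsfs_hat[, , m]), Mod(sim$apsfs[, , m]))$r
    }, numeric(1))
    diagonality <- psf_diagonality(
      Mod(central_crop(sim$apsfs, 32L)[, , seq_len(min(cfg$M, 50L))])^2)
    sim$stack$frames <- holos
  }

  r_recon <- registered_correlation(recon_img, truth)$r
  r_mean <- registered_correlation(mean_frame, truth)$r
  hz <- haze_metric(recon_img, truth)$haze
  manifest <- list(
    config = cfg,
    metrics = list(r_recon = r_recon, r_mean_frame = r_mean,
                   psf_recovery = mean(psf_r), diagonality = diagonality,
                   haze = hz, n_iter = rec$n_iter,
                   converged = rec$converged),
    trace = rec$phase_trace
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_image_tiff(truth, file.path(out_dir, "object.tif"))
    write_image_tiff(recon_img, file.path(out_dir, "reconstruction.tif"))
    write_frame_stack(sim$stack, file.path(out_dir, "stack.tif"))
    cfg_out <- cfg
    if (is.matrix(cfg_out$object)) cfg_out$object <- "custom"
    yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(manifest[c("metrics", "trace")],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$files <- list.files(out_dir)
  } else {
    manifest$results <- list(object = truth, reconstruction = recon_img,
                             recon = rec, sim = sim)
  }
  manifest
}
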