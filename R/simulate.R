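# Forward simulators: short-exposure frame stacks through a dynamic
# scatterer under the isoplanatic convolution model.
#
# Incoherent: I_m = P_m (*) O, with P_m the m-th intensity PSF.
# Coherent:   E_m = Pcoh_m (*) [O . E_ill], with Pcoh_m the m-th APSF and a
#             fixed illumination field (the focused-spot condition).
# (*) denotes CIRCULAR convolution computed via products of 2-D DFTs, so the
# forward model matches the reconstruction's Fourier factorization exactly.

#' Static object on a pixel grid
#'
#' @param values Real non-negative matrix (incoherent intensity) or complex
#'   matrix (coherent reflectivity).
#' @param pitch_um Pixel pitch in micrometers.
#' @param mode `"incoherent"` or `"coherent"`; inferred from `values` when
#'   missing.
#' @return An `object_image` list with `values`, `pitch_um`, `mode`.
#' @export
object_image <- function(values, pitch_um = 1,
                         mode = if (is.complex(values)) "coherent" else "incoherent") {
  mode <- match.arg(mode, c("incoherent", "coherent"))
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (mode == "incoherent") {
    if (is.complex(values)) stop("incoherent object must be real", call. = FALSE)
    if (min(values) < 0) stop("incoherent object must be non-negative", call. = FALSE)
  }
  if (all(values == 0)) stop("object must have a nonzero pixel", call. = FALSE)
  structure(list(values = values, pitch_um = pitch_um, mode = mode),
            class = "object_image")
}

#' Frame stack container
#'
#' @param frames `H x W x M` array, real intensities or complex fields.
#' @param mode `"incoherent"` or `"coherent"`.
#' @param seed Seed used to generate the stack, if any.
#' @param meta Optional list of extra metadata (exposure, modulation, ...).
#' @return A `frame_stack` list.
#' @export
frame_stack <- function(frames, mode = c("incoherent", "coherent"),
                        seed = NULL, meta = list()) {
  mode <- match.arg(mode)
  if (length(dim(frames)) != 3L || dim(frames)[3] < 2L) {
    stop("`frames` must be an H x W x M array with M >= 2", call. = FALSE)
  }
  structure(list(frames = frames, mode = mode, seed = seed, meta = meta),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %s, %d frames of %d x %d\n",
              x$mode, d[3], d[1], d[2]))
  invisible(x)
}

#' Render frames from an object and an explicit PSF stack
#'
#' Low-level forward model: frame m is the circular convolution of the
#' object with the m-th kernel (intensity PSF or complex APSF, origin at the
#' center sample).  Exposed so tests and oracles can drive the model with
#' arbitrary kernels (white, delta-correlated, ...).
#'
#' @param object An [object_image()] (or plain matrix).
#' @param psfs `H x W x M` array of kernels on the object grid.
#' @return `H x W x M` array of frames; real when both inputs are real.
#' @export
synthesize_frames <- function(object, psfs) {
  ov <- if (inherits(object, "object_image")) object$values else object
  d <- dim(psfs)
  if (length(d) != 3L || !all(d[1:2] == dim(ov))) {
    stop("`psfs` must be H x W x M on the object grid", call. = FALSE)
  }
  Of <- fft2(ov)
  # shift kernel origins from grid center to [1,1], transform all at once
  shifted <- array(apply(psfs, 3, ifftshift2), d)
  Pf <- fft2_stack(shifted)
  out <- fft2_stack(Pf * as.vector(Of), inverse = TRUE)
  if (!is.complex(ov) && !is.complex(psfs)) Re(out) else out
}

#' Simulate an incoherent frame stack through a dynamic scatterer
#'
#' Draws `M` mutually (or partially) correlated random phase screens, turns
#' each into an intensity PSF, and renders frame `m` as the circular
#' convolution of the object intensity with the m-th PSF, optionally
#' followed by Poisson shot noise and Gaussian read noise.
#'
#' @param object A real non-negative [object_image()] or matrix.
#' @param M Number of frames (>= 2).
#' @param screen_params List with `corr_len_px` (default 4), `rms_rad`
#'   (default `3*pi`) and `pupil_frac` (default `Inf`, an energy-conserving
#'   phase-only screen).
#' @param frame_correlation In `[0, 1)`; `0` gives fully uncorrelated
#'   screens frame to frame.
#' @param noise_params `NULL` (noiseless, the default) or a list with
#'   `photons_per_frame` (Poisson scale) and/or `read_sd` (additive Gaussian
#'   sd, in the same photon units).
#' @param seed Integer seed; the stack is deterministic given the seed.
#' @return A list with `stack` (a [frame_stack()]), `psfs` (the ground-truth
#'   `H x W x M` intensity PSFs) and `screens`.
#' @export
simulate_incoherent_stack <- function(object, M = 150,
                                      screen_params = list(),
                                      frame_correlation = 0,
                                      noise_params = NULL, seed = 1) {
  obj <- if (inherits(object, "object_image")) object else object_image(object)
  if (obj$mode != "incoherent") {
    stop("incoherent simulation requires a real non-negative object",
         call. = FALSE)
  }
  if (M < 2) stop("M must be >= 2", call. = FALSE)
  if (frame_correlation < 0 || frame_correlation >= 1) {
    stop("`frame_correlation` must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(obj$values)
  ps <- make_psf_stack(n, M, screen_params, frame_correlation, seed,
                       kind = "intensity")
  frames <- synthesize_frames(obj, ps$psfs)
  frames[frames < 0 & frames > -1e-12] <- 0  # fft round-off
  if (!is.null(noise_params)) {
    set.seed(derive_seed(seed, 999983))
    if (!is.null(noise_params$photons_per_frame)) {
      scale <- noise_params$photons_per_frame
      per <- apply(frames, 3, sum)
      for (m in seq_len(dim(frames)[3])) {
        lam <- frames[, , m] / per[m] * scale
        frames[, , m] <- stats::rpois(length(lam), pmax(lam, 0)) / scale * per[m]
      }
    }
    if (!is.null(noise_params$read_sd) && noise_params$read_sd > 0) {
      frames <- frames + stats::rnorm(length(frames), sd = noise_params$read_sd)
    }
  }
  list(stack = frame_stack(frames, "incoherent", seed = seed,
                           meta = list(screen_params = screen_params,
                                       frame_correlation = frame_correlation,
                                       noise_params = noise_params)),
       psfs = ps$psfs, screens = ps$screens)
}

#' Simulate a coherent frame stack through a dynamic scatterer
#'
#' Under the focused-illumination condition the object-plane illumination is
#' the same for every realization, so the effective static object is
#' `O_eff = O * E_ill` and frame `m` is the complex circular convolution of
#' `O_eff` with the m-th APSF.
#'
#' @param reflectivity Complex (or real) object reflectivity matrix or
#'   [object_image()].
#' @param illumination Complex illumination field at the object plane on the
#'   same grid; `NULL` for uniform unit illumination.
#' @param M Number of field realizations (>= 2).
#' @param screen_params As in [simulate_incoherent_stack()]; default
#'   `pupil_frac` is `Inf`.
#' @param seed Integer seed.
#' @return A list with `stack` (complex [frame_stack()]), `apsfs` (the
#'   ground-truth `H x W x M` complex APSFs), `screens`, and `o_eff`.
#' @export
simulate_coherent_stack <- function(reflectivity, illumination = NULL,
                                    M = 180, screen_params = list(),
                                    seed = 1) {
  ov <- if (inherits(reflectivity, "object_image")) reflectivity$values else reflectivity
  ov <- ov + 0i
  if (M < 2) stop("M must be >= 2", call. = FALSE)
  n <- nrow(ov)
  if (is.null(illumination)) illumination <- matrix(1 + 0i, n, n)
  if (!all(dim(illumination) == dim(ov))) {
    stop("illumination grid must match the object grid", call. = FALSE)
  }
  if (sum(Mod(illumination)^2) == 0) {
    stop("illumination must carry energy", call. = FALSE)
  }
  o_eff <- ov * illumination
  ps <- make_psf_stack(n, M, screen_params, 0, seed, kind = "amplitude")
  frames <- synthesize_frames(o_eff, ps$psfs)
  list(stack = frame_stack(frames, "coherent", seed = seed,
                           meta = list(screen_params = screen_params)),
       apsfs = ps$psfs, screens = ps$screens, o_eff = o_eff)
}

#' Record an off-axis hologram of a complex field
#'
#' Interferes the field with a tilted plane-wave reference and records the
#' intensity, `|E + A_ref exp(i 2 pi (c_x x + c_y y) / N)|^2`, as a camera
#' would.  The carrier must sit below Nyquist and above the field bandwidth
#' so the two sidebands and the autocorrelation term separate in the Fourier
#' plane.
#'
#' @param field Complex matrix.
#' @param carrier_cycles Length-2 numeric: carrier frequency in cycles per
#'   field along each axis; each must satisfy `|c| < N/2`.
#' @param ref_amplitude Reference-beam amplitude (default: the field's rms
#'   amplitude times 2).
#' @return Real non-negative matrix (the hologram).
#' @export
simulate_offaxis_hologram <- function(field, carrier_cycles,
                                      ref_amplitude = NULL) {
  d <- dim(field)
  carrier_cycles <- rep(carrier_cycles, length.out = 2)
  if (any(abs(carrier_cycles) >= d / 2)) {
    stop("carrier at or above Nyquist", call. = FALSE)
  }
  if (is.null(ref_amplitude)) {
    ref_amplitude <- 2 * sqrt(mean(Mod(field)^2))
  }
  x <- (seq_len(d[1]) - 1)
  y <- (seq_len(d[2]) - 1)
  ramp <- outer(x * carrier_cycles[1] / d[1], y * carrier_cycles[2] / d[2], "+")
  ref <- ref_amplitude * exp(2i * pi * ramp)
  Mod(field + ref)^2
}
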