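# Random phase screens and the speckle PSFs they generate.
#
# A thin dynamic diffuser is modeled as a random phase screen in the pupil
# (Fourier) plane of the imaging system.  Each screen realization yields a
# complex amplitude point spread function (APSF) by Fourier transforming the
# pupil-masked phasor, and an intensity PSF as its squared modulus.

#' Generate a Gaussian random phase screen
#'
#' Draws a stationary Gaussian random field with Gaussian spatial
#' autocorrelation and rescales it to the requested root-mean-square phase.
#' The field is synthesized as white Gaussian noise filtered by a Gaussian
#' kernel in the Fourier domain.  `corr_len_px` parameterizes the
#' correlation length of the complex phasor `exp(i*phase)` — the quantity
#' diffuser data sheets quote and the one that sets the speckle-PSF
#' envelope (a Gaussian phase field of correlation length `l` and RMS
#' `sigma` has phasor correlation `~ l / sigma`, so the underlying phase
#' correlation is scaled by `max(1, rms_rad)` internally).  Speckle
#' statistics are fully developed when `corr_len_px * rms_rad` is small
#' compared with the grid, i.e. when many independent phase cells fit in
#' the aperture.
#'
#' @param shape Integer vector of length 1 or 2; the (square) grid size.
#' @param corr_len_px Correlation length of the screen phasor, in pixels
#'   (>= 1).
#' @param rms_rad Root-mean-square phase in radians (>= 0); `0` gives a flat
#'   screen.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   screen bit for bit.
#' @param prev For internal use by the simulators: a previous screen's raw
#'   Gaussian field, mixed in with weight `mix` to produce temporally
#'   correlated screens.
#' @param mix Mixing weight in `[0, 1)`: the new raw field is
#'   `mix * prev + sqrt(1 - mix^2) * fresh`, then rescaled to `rms_rad`.
#' @return An object of class `phase_screen`: a list with `phase` (matrix of
#'   radians), `raw` (the underlying unit-variance Gaussian field),
#'   `corr_len_px`, `rms_rad`, `seed`.
#' @export
generate_phase_screen <- function(shape, corr_len_px, rms_rad, seed = NULL,
                                  prev = NULL, mix = 0) {
  shape <- as.integer(rep(shape, length.out = 2))
  if (any(shape <= 0)) stop("`shape` must be positive", call. = FALSE)
  if (shape[1] != shape[2]) stop("`shape` must be square", call. = FALSE)
  if (corr_len_px < 1) stop("`corr_len_px` must be >= 1", call. = FALSE)
  if (rms_rad < 0) stop("`rms_rad` must be >= 0", call. = FALSE)
  if (mix < 0 || mix >= 1) stop("`mix` must be in [0, 1)", call. = FALSE)
  n <- shape[1]
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- matrix(stats::rnorm(n * n), n, n)
  # Gaussian low-pass so the phase autocorrelation is ~ exp(-r^2 / l^2)
  # with l chosen so that exp(i*phase) decorrelates over ~corr_len_px
  l_phase <- corr_len_px * max(1, rms_rad)
  f2 <- outer(freq_axis(n)^2, freq_axis(n)^2, "+")
  filt <- ifftshift2(exp(-(pi^2 * l_phase^2 / 2) * f2))
  smooth <- function(g) Re(ifft2(fft2(g) * filt))
  raw <- smooth(w)
  raw <- raw - mean(raw)
  s <- stats::sd(as.vector(raw))
  raw <- if (s > 0) raw / s else raw
  if (!is.null(prev)) {
    raw <- mix * prev + sqrt(1 - mix^2) * raw
    raw <- raw - mean(raw)
    s <- stats::sd(as.vector(raw))
    raw <- if (s > 0) raw / s else raw
  }
  phase <- raw * rms_rad
  structure(list(phase = phase, raw = raw,
                 corr_len_px = corr_len_px, rms_rad = rms_rad, seed = seed),
            class = "phase_screen")
}

#' Circular pupil mask
#'
#' Binary circular aperture, centered on the zero-frequency sample, with
#' radius expressed as a fraction of the Nyquist frequency.  It sets the
#' diffraction limit of the simulated imaging system.
#'
#' @param shape Grid size (length 1 or 2, square).
#' @param radius_frac Radius as a fraction of Nyquist in `(0, 1]`, or `Inf`
#'   for an all-pass (energy-conserving phase-only) pupil.
#' @return An object of class `pupil`: list with `mask` (0/1 matrix,
#'   centered) and `radius_frac`.
#' @export
pupil_mask <- function(shape, radius_frac = 1) {
  shape <- as.integer(rep(shape, length.out = 2))
  if (any(shape <= 0)) stop("`shape` must be positive", call. = FALSE)
  if (!is.infinite(radius_frac) && (radius_frac <= 0 || radius_frac > 1)) {
    stop("`radius_frac` must be in (0, 1] or Inf", call. = FALSE)
  }
  if (is.infinite(radius_frac)) {
    mask <- matrix(1, shape[1], shape[2])
  } else {
    f2 <- outer(freq_axis(shape[1])^2, freq_axis(shape[2])^2, "+")
    mask <- (f2 <= (0.5 * radius_frac)^2) * 1
  }
  structure(list(mask = mask, radius_frac = radius_frac), class = "pupil")
}

#' Amplitude PSF from a phase screen
#'
#' The APSF is the centered 2-D discrete Fourier transform of the
#' pupil-masked screen phasor, normalized to unit total energy.
#'
#' @param screen A [generate_phase_screen()] object (or a plain phase
#'   matrix in radians).
#' @param pupil A [pupil_mask()] object, a plain 0/1 matrix on the same
#'   grid, or `NULL` for an all-pass pupil.
#' @return An object of class `apsf`: list with `field` (complex matrix,
#'   spatial origin at the center sample) and the source parameters.
#' @export
screen_to_apsf <- function(screen, pupil = NULL) {
  phase <- if (inherits(screen, "phase_screen")) screen$phase else screen
  if (!all(is.finite(phase))) stop("screen phase must be finite", call. = FALSE)
  mask <- if (is.null(pupil)) {
    matrix(1, nrow(phase), ncol(phase))
  } else if (inherits(pupil, "pupil")) pupil$mask else pupil
  if (!all(dim(mask) == dim(phase))) {
    stop("screen and pupil must share a grid", call. = FALSE)
  }
  g <- mask * exp(1i * phase)
  field <- fftshift2(fft2(ifftshift2(g)))
  en <- sum(Mod(field)^2)
  if (en == 0) stop("pupil passes no energy", call. = FALSE)
  structure(list(field = field / sqrt(en)), class = "apsf")
}

#' Intensity PSF from an amplitude PSF
#'
#' The incoherent point spread function is the squared modulus of the APSF,
#' renormalized to unit sum so circular convolution conserves frame energy.
#'
#' @param apsf An [screen_to_apsf()] object or a complex matrix.
#' @return An object of class `intensity_psf`: list with `psf`, a real
#'   non-negative unit-sum matrix (origin at the center sample).
#' @export
apsf_to_ipsf <- function(apsf) {
  field <- if (inherits(apsf, "apsf")) apsf$field else apsf
  p <- Mod(field)^2
  s <- sum(p)
  if (s == 0) stop("degenerate all-zero APSF", call. = FALSE)
  structure(list(psf = p / s), class = "intensity_psf")
}

# One PSF (or APSF) stack from screen parameters; shared by both simulators.
# Returns list(psfs = H x W x M array, screens = list).  `kind` chooses the
# intensity PSF (|APSF|^2, unit sum) or the complex APSF (unit energy).
make_psf_stack <- function(n, M, screen_params, frame_correlation = 0,
                           seed = 1, kind = c("intensity", "amplitude")) {
  kind <- match.arg(kind)
  sp <- screen_params
  corr <- if (!is.null(sp$corr_len_px)) sp$corr_len_px else 4
  rms <- if (!is.null(sp$rms_rad)) sp$rms_rad else 3 * pi
  pfrac <- if (!is.null(sp$pupil_frac)) sp$pupil_frac else Inf
  pup <- pupil_mask(n, pfrac)
  psfs <- array(0, c(n, n, M))
  if (kind == "amplitude") psfs <- array(0i, c(n, n, M))
  screens <- vector("list", M)
  prev <- NULL
  for (m in seq_len(M)) {
    scr <- generate_phase_screen(n, corr, rms, seed = derive_seed(seed, m),
                                 prev = prev, mix = frame_correlation)
    prev <- scr$raw
    a <- screen_to_apsf(scr, pup)
    psfs[, , m] <- if (kind == "amplitude") a$field else apsf_to_ipsf(a)$psf
    screens[[m]] <- scr
  }
  list(psfs = psfs, screens = screens, pupil = pup)
}
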