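# Fresnel transfer-function propagation and off-axis hologram demodulation.
#
# Paraxial free-space propagation over dz between the scattering-layer and
# object planes, implemented purely in the spatial-frequency domain:
#   E(z + dz) = IFT{ FT{E(z)} . H(fx, fy; dz) },
#   H = exp(i 2 pi dz / lambda) . exp(-i pi lambda dz (fx^2 + fy^2)),
# with fx, fy in cycles per micrometer on centered grids.  |H| = 1, so
# propagation is unitary and inverted by flipping the sign of dz.

#' Propagation configuration
#'
#' @param wavelength_um Wavelength in micrometers (> 0).
#' @param pitch_um Sample spacing in micrometers (> 0).
#' @param dz_um Propagation distance `z_obj - z_scatt` in micrometers
#'   (either sign).
#' @param shape Grid size, length 1 or 2.
#' @return A `propagation_config` with the centered frequency axes `fx`,
#'   `fy` (cycles/um).
#' @export
propagation_config <- function(wavelength_um, pitch_um, dz_um, shape) {
  if (wavelength_um <= 0 || pitch_um <= 0) {
    stop("wavelength and pitch must be positive", call. = FALSE)
  }
  shape <- as.integer(rep(shape, length.out = 2))
  if (any(shape <= 0)) stop("`shape` must be positive", call. = FALSE)
  structure(list(wavelength_um = wavelength_um, pitch_um = pitch_um,
                 dz_um = dz_um, shape = shape,
                 fx = freq_axis(shape[1], pitch_um),
                 fy = freq_axis(shape[2], pitch_um)),
            class = "propagation_config")
}

#' Fresnel transfer function
#'
#' @param config A [propagation_config()].
#' @return Centered complex matrix `H(fx, fy)` with `|H| = 1` everywhere;
#'   identically 1 at `dz = 0`.
#' @export
fresnel_transfer <- function(config) {
  stopifnot(inherits(config, "propagation_config"))
  f2 <- outer(config$fx^2, config$fy^2, "+")
  exp(1i * 2 * pi * config$dz_um / config$wavelength_um) *
    exp(-1i * pi * config$wavelength_um * config$dz_um * f2)
}

#' Complex field container
#'
#' @param field Complex matrix.
#' @param pitch_um Sample spacing in micrometers.
#' @param plane Label: `"scatt"`, `"obj"` or `"camera"`.
#' @return A `complex_field` list.
#' @export
complex_field <- function(field, pitch_um = 1,
                          plane = c("scatt", "obj", "camera")) {
  plane <- match.arg(plane)
  structure(list(field = field + 0i, pitch_um = pitch_um, plane = plane),
            class = "complex_field")
}

#' Fresnel propagation between planes
#'
#' Forward or backward paraxial propagation by `config$dz_um`; the sign of
#' `dz` selects the direction.  Warns (does not error) when the quadratic
#' phase is badly sampled, `lambda |dz| / (N pitch^2) > aliasing_limit`.
#'
#' @param field A [complex_field()] or complex matrix.
#' @param config A [propagation_config()]; its pitch must match the field's.
#' @param aliasing_limit Sampling guard threshold (default 1).
#' @return A [complex_field()] at the shifted plane (the plane label flips
#'   between `"scatt"` and `"obj"` according to the sign of `dz`).
#' @export
fresnel_propagate <- function(field, config, aliasing_limit = 1) {
  stopifnot(inherits(config, "propagation_config"))
  cf <- if (inherits(field, "complex_field")) field else complex_field(field, config$pitch_um)
  if (abs(cf$pitch_um - config$pitch_um) > 1e-12) {
    stop("field pitch does not match the propagation config", call. = FALSE)
  }
  if (!all(dim(cf$field) == config$shape)) {
    stop("field grid does not match the propagation config", call. = FALSE)
  }
  n <- max(config$shape)
  fresno <- config$wavelength_um * abs(config$dz_um) / (n * config$pitch_um^2)
  if (fresno > aliasing_limit) {
    warning(sprintf(
      "propagation poorly sampled (lambda |dz| / (N pitch^2) = %.2f > %.2f); expect wrap-around artifacts",
      fresno, aliasing_limit), call. = FALSE)
  }
  H <- ifftshift2(fresnel_transfer(config))
  out <- ifft2(fft2(cf$field) * H)
  plane <- if (config$dz_um >= 0) "obj" else "scatt"
  complex_field(out, cf$pitch_um, plane)
}

#' Demodulate an off-axis hologram
#'
#' Extracts the complex field from a single off-axis hologram: transform to
#' the Fourier plane, crop a disk around the `+carrier` sideband, recenter
#' it on the zero frequency, and inverse transform.  The result equals the
#' original field up to a constant complex factor provided the sidebands
#' are separated.
#'
#' @param hologram Real matrix from [simulate_offaxis_hologram()] (or a
#'   camera).
#' @param carrier_cycles Length-2 carrier frequency in cycles per field.
#' @param crop_radius_frac Radius of the sideband crop as a fraction of
#'   Nyquist (default 0.25).
#' @return A [complex_field()] labeled `"camera"`.  Warns when the carrier
#'   is closer than three crop radii to the zero frequency — taking the
#'   crop radius as the field bandwidth, that is when the sideband would
#'   penetrate the hologram's autocorrelation (DC) term.
#' @export
demodulate_offaxis <- function(hologram, carrier_cycles,
                               crop_radius_frac = 0.25) {
  d <- dim(hologram)
  carrier_cycles <- rep(carrier_cycles, length.out = 2)
  if (any(abs(carrier_cycles) >= d / 2)) {
    stop("carrier at or above Nyquist", call. = FALSE)
  }
  crop_px <- crop_radius_frac * min(d) / 2
  if (sqrt(sum(carrier_cycles^2)) < 3 * crop_px) {
    warning("sideband and DC terms overlap; increase the carrier or reduce the crop radius",
            call. = FALSE)
  }
  spec <- fftshift2(fft2(hologram))
  c0 <- floor(d / 2) + 1
  # +carrier sideband center: note the simulator multiplies the *reference*
  # by exp(+i 2 pi c r / N), so the field term E conj(ref) sits at -c and
  # E* ref at +c; crop the latter's conjugate partner carrying E itself.
  ctr <- c0 - round(carrier_cycles)  # integer carriers: exact recentering
  i <- matrix(seq_len(d[1]), d[1], d[2])
  j <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  r2 <- ((i - ctr[1]) / (d[1] / 2))^2 + ((j - ctr[2]) / (d[2] / 2))^2
  inside <- r2 <= crop_radius_frac^2
  cropped <- matrix(0i, d[1], d[2])
  sel <- which(inside, arr.ind = TRUE)
  dest <- cbind(((sel[, 1] - ctr[1] + c0[1] - 1) %% d[1]) + 1,
                ((sel[, 2] - ctr[2] + c0[2] - 1) %% d[2]) + 1)
  cropped[dest] <- spec[sel]
  out <- ifft2(ifftshift2(cropped))
  complex_field(out, plane = "camera")
}
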