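# Centered-FFT helpers shared by all modules.
#
# Convention: "centered" grids place the zero frequency (or the spatial
# origin) at the sample with 0-based index floor(N/2), i.e. R index
# floor(N/2) + 1.  Internally most algorithms work in the natural (unshifted)
# DFT ordering, where cyclic index arithmetic is direct, and shift only at
# the interface.

#' Cyclic shift of a matrix
#'
#' Shifts a matrix cyclically by an integer offset along each dimension,
#' as used for registering images defined on a torus.
#'
#' @param x A matrix.
#' @param shift Integer vector of length 2: row and column offset.
#' @return The shifted matrix.
#' @export
circ_shift <- function(x, shift) {
  d <- dim(x)
  i <- ((seq_len(d[1]) - 1 - shift[1]) %% d[1]) + 1
  j <- ((seq_len(d[2]) - 1 - shift[2]) %% d[2]) + 1
  x[i, j, drop = FALSE]
}

#' Move the zero-frequency sample to the grid center
#'
#' @param x A matrix in natural DFT ordering.
#' @return The matrix with the origin at R index `floor(N/2) + 1`.
#' @export
fftshift2 <- function(x) {
  d <- dim(x)
  circ_shift(x, c(floor(d[1] / 2), floor(d[2] / 2)))
}

#' Move the grid-center sample back to the first index
#'
#' Inverse of [fftshift2()] for any (even or odd) grid size.
#'
#' @param x A matrix in centered ordering.
#' @return The matrix in natural DFT ordering.
#' @export
ifftshift2 <- function(x) {
  d <- dim(x)
  circ_shift(x, c(-floor(d[1] / 2), -floor(d[2] / 2)))
}

#' 2-D discrete Fourier transform
#'
#' Thin wrappers over [stats::fft()] with the inverse normalized by the
#' number of samples, so `ifft2(fft2(x))` is the identity.
#'
#' @param x A matrix (real or complex).
#' @return A complex matrix of the same shape.
#' @export
fft2 <- function(x) stats::fft(x)

#' @rdname fft2
#' @export
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Batched 2-D FFT of an (H, W, M) array, slice by slice along the third
# dimension, using mvfft at C level twice.  Much faster than apply().
fft2_stack <- function(x, inverse = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  y <- stats::mvfft(matrix(x, nrow = d[1]), inverse = inverse)
  y <- array(y, d)
  y <- aperm(y, c(2, 1, 3))
  y <- stats::mvfft(matrix(y, nrow = d[2]), inverse = inverse)
  y <- aperm(array(y, d[c(2, 1, 3)]), c(2, 1, 3))
  if (inverse) y / (d[1] * d[2]) else y
}

#' Circular 2-D convolution via the DFT
#'
#' Computes the cyclic convolution of an image with a kernel whose origin is
#' at the grid center (so a centered delta kernel is the identity).  This is
#' the exact forward model used throughout: products of 2-D DFTs, no padding.
#'
#' @param x Image matrix (real or complex).
#' @param kernel Kernel matrix on the same grid, origin at the center sample.
#' @param kernel_centered If `FALSE` the kernel origin is taken at index
#'   `[1, 1]` (natural ordering) instead.
#' @param pad If `TRUE`, zero-pad both inputs to double size for a linear
#'   (aperiodic) convolution, then crop back; used for realism checks only.
#' @return Matrix of the same shape; real if both inputs are real.
#' @export
circ_conv2 <- function(x, kernel, kernel_centered = TRUE, pad = FALSE) {
  if (!all(dim(x) == dim(kernel))) {
    stop("`x` and `kernel` must share a grid", call. = FALSE)
  }
  if (pad) {
    d <- dim(x)
    ck <- if (kernel_centered) kernel else fftshift2(kernel)
    xp <- matrix(0, 2 * d[1], 2 * d[2])
    kp <- xp
    xp[seq_len(d[1]), seq_len(d[2])] <- x
    kp[seq_len(d[1]), seq_len(d[2])] <- ck
    # the kernel patch has its origin at 0-based index floor(d/2); the linear
    # convolution result is therefore read off at that offset
    full <- ifft2(fft2(xp) * fft2(kp))
    out <- full[floor(d[1] / 2) + seq_len(d[1]),
                floor(d[2] / 2) + seq_len(d[2])]
  } else {
    k <- if (kernel_centered) ifftshift2(kernel) else kernel
    out <- ifft2(fft2(x) * fft2(k))
  }
  if (is.double(x) && is.double(kernel)) Re(out) else out
}

# Centered frequency axis in cycles per sample (or per unit if pitch given):
# values k/N for k = -floor(N/2) ... ceil(N/2)-1.
freq_axis <- function(n, pitch = 1) {
  (seq_len(n) - 1 - floor(n / 2)) / (n * pitch)
}

# Deterministic stream-splitting of a user seed into per-frame seeds,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(k)) %% 2147483647)
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
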