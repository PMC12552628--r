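# Measurement matrix A and its covariance.
#
# Column m of A is the vectorized, centered 2-D Fourier transform of frame m
# (mean-subtracted per mode).  Under the isoplanatic model the covariance
# factorizes as Cov(A) = diag(O~) T diag(O~)* with T a Toeplitz kernel in
# the frequency difference q = k1 - k2 (the Fourier transform of the
# diagonal PSF-ensemble covariance), which is what the CLASS iteration
# exploits.

#' Apply linear intensity modulation across frames
#'
#' Multiplies frame `m` by `s_min + (s_max - s_min) * (m - 1) / (M - 1)`.
#' Used to break the exact energy-conservation constraint of phase-only
#' scattering (unit-sum PSFs make every frame total identical), whose
#' residual spatial correlations otherwise leak background haze into the
#' reconstruction.
#'
#' @param stack A [frame_stack()].
#' @param s_min,s_max Positive scalars, `s_max >= s_min`; the canonical
#'   protocol is 1 to 2.
#' @return The modulated [frame_stack()]; the per-frame factors are recorded
#'   in `meta$modulation`.
#' @export
apply_intensity_modulation <- function(stack, s_min = 1, s_max = 2) {
  if (!inherits(stack, "frame_stack")) stop("need a frame_stack", call. = FALSE)
  if (s_min <= 0 || s_max < s_min) {
    stop("need s_max >= s_min > 0", call. = FALSE)
  }
  M <- dim(stack$frames)[3]
  s <- s_min + (s_max - s_min) * (seq_len(M) - 1) / (M - 1)
  stack$frames <- sweep(stack$frames, 3, s, "*")
  stack$meta$modulation <- list(s_min = s_min, s_max = s_max, factors = s)
  stack
}

#' Arrange frames as columns of the spectral measurement matrix
#'
#' In incoherent mode the temporal mean frame is subtracted first (it
#' carries the dominant DC/haze term); coherent speckle fields are zero-mean
#' and are transformed as-is.  An optional low-pass crop keeps the centered
#' `lowpass_frac` portion of the spectrum, which is equivalent to Fourier
#' downsampling of the frames.
#'
#' @param stack A [frame_stack()].
#' @param subtract_mean Default: `TRUE` in incoherent mode, `FALSE` in
#'   coherent mode.
#' @param lowpass_frac Fraction of the grid to keep per axis, in `(0, 1]`.
#' @return A `measurement_matrix`: list with `columns` (`N_k x M` complex),
#'   `dim` (cropped grid size), `k_index` (per-row centered frequency
#'   indices), `mode`, `mean_frame`, `subtract_mean`, `lowpass_frac`.
#' @export
frames_to_spectral_matrix <- function(stack, subtract_mean = NULL,
                                      lowpass_frac = 1) {
  if (!inherits(stack, "frame_stack")) stop("need a frame_stack", call. = FALSE)
  if (lowpass_frac <= 0 || lowpass_frac > 1) {
    stop("`lowpass_frac` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(subtract_mean)) subtract_mean <- stack$mode == "incoherent"
  fr <- stack$frames
  d <- dim(fr)
  mean_frame <- apply(fr, c(1, 2), mean)
  if (subtract_mean) fr <- sweep(fr, c(1, 2), mean_frame, "-")
  spec <- fft2_stack(fr)                       # natural DFT order
  spec <- array(apply(spec, 3, fftshift2), d)  # centered
  h <- d[1]; w <- d[2]
  if (lowpass_frac < 1) {
    hc <- max(2L, 2L * floor(lowpass_frac * h / 2))
    wc <- max(2L, 2L * floor(lowpass_frac * w / 2))
    ri <- floor(h / 2) + 1 + seq(-floor(hc / 2), by = 1, length.out = hc)
    ci <- floor(w / 2) + 1 + seq(-floor(wc / 2), by = 1, length.out = wc)
    spec <- spec[ri, ci, , drop = FALSE]
    h <- hc; w <- wc
  }
  kx <- rep(seq_len(h) - 1 - floor(h / 2), times = w)
  ky <- rep(seq_len(w) - 1 - floor(w / 2), each = h)
  structure(list(columns = matrix(spec, nrow = h * w),
                 dim = c(h, w),
                 k_index = cbind(kx = kx, ky = ky),
                 mode = stack$mode,
                 mean_frame = mean_frame,
                 subtract_mean = subtract_mean,
                 lowpass_frac = lowpass_frac,
                 modulation = stack$meta$modulation),
            class = "measurement_matrix")
}

#' @export
print.measurement_matrix <- function(x, ...) {
  cat(sprintf("<measurement_matrix> %s, %d frequencies x %d frames (%d x %d grid)\n",
              x$mode, nrow(x$columns), ncol(x$columns), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Covariance of the measurement matrix
#'
#' `C = A A^H / (M - 1)`, Hermitian positive semidefinite by construction.
#' The dense matrix is only materialized for `N_k <= max_dense` rows; above
#' that an operator backed by `A` is returned whose matrix-vector products
#' are identical to the dense form.
#'
#' @param A A [frames_to_spectral_matrix()] result (or plain `N_k x M`
#'   complex matrix).
#' @param max_dense Largest row count for which the dense matrix is formed.
#' @return A `cov_matrix`: list with either `C` (dense complex Hermitian) or
#'   `A`, plus `n_rows`, `M`, `form`, and a `matvec` function.
#' @export
covariance <- function(A, max_dense = 4096) {
  cols <- if (inherits(A, "measurement_matrix")) A$columns else A
  M <- ncol(cols)
  if (is.null(M) || M < 2) stop("need at least M = 2 frames", call. = FALSE)
  n_rows <- nrow(cols)
  if (n_rows <= max_dense) {
    C <- tcrossprod(cols, Conj(cols)) / (M - 1)
    out <- list(C = C, n_rows = n_rows, M = M, form = "dense",
                matvec = function(v) C %*% v)
  } else {
    out <- list(A = cols, n_rows = n_rows, M = M, form = "operator",
                matvec = function(v) cols %*% (Conj(t(cols)) %*% v) / (M - 1))
  }
  structure(out, class = "cov_matrix")
}

#' Diagonality score of a PSF-ensemble covariance
#'
#' The uncorrelated-PSF condition requires the pixelwise covariance of the
#' centered PSF stack to be (close to) diagonal.  This returns
#' `sum_i |Cov(i,i)| / sum_ij |Cov(i,j)|`, which is 1 for a perfectly
#' diagonal covariance.
#'
#' @param psf_stack `H x W x M` array of PSF realizations (`M >= 2`).
#' @return A scalar in `[0, 1]`.
#' @export
psf_diagonality <- function(psf_stack) {
  d <- dim(psf_stack)
  if (length(d) != 3L || d[3] < 2L) stop("need an H x W x M stack", call. = FALSE)
  X <- matrix(psf_stack, nrow = d[1] * d[2])     # pixels x frames
  X <- X - rowMeans(X)
  if (all(X == 0)) {
    stop("constant PSF stack: covariance is identically zero", call. = FALSE)
  }
  C <- tcrossprod(X, Conj(X)) / (d[3] - 1)
  sum(Mod(diag(C))) / sum(Mod(C))
}

# Reconstruct the frame stack that produced a measurement matrix (inverse of
# frames_to_spectral_matrix without low-pass crop); used by invariance tests.
spectral_matrix_to_frames <- function(A) {
  stopifnot(inherits(A, "measurement_matrix"), A$lowpass_frac == 1)
  d <- c(A$dim, ncol(A$columns))
  spec <- array(A$columns, d)
  spec <- array(apply(spec, 3, ifftshift2), d)
  fr <- fft2_stack(spec, inverse = TRUE)
  if (A$subtract_mean) fr <- sweep(fr, c(1, 2), A$mean_frame, "+")
  if (A$mode == "incoherent") Re(fr) else fr
}
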