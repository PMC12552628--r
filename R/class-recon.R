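# CLASS-type reconstruction from the covariance of the measured frames.
#
# Model: column m of A is a_m(k) = O~(k) p_m(k), so
# Cov(A)(k1,k2) = O~(k1) T(k1-k2) O~*(k2) for uncorrelated PSF realizations.
# The iteration alternates
#   (a) kernel   t(q)  = sum_k C(k+q, k) e^{-i psi(k+q)} e^{+i psi(k)}
#   (b) phase    psi(k1) = arg( sum_k2 C(k1,k2) e^{+i psi(k2)} t*(k1-k2) )
# and is implemented in the frame domain (never forming the dense C):
# with b_m = a_m e^{-i psi},
#   t(q)  = sum_m (b_m star b_m)(q) / (M-1)          (autocorrelation)
#   S(k1) = sum_m a_m(k1) conj((t (*) b_m)(k1)) / (M-1),  psi = arg S,
# each term two FFTs per frame.  The dense form is retained as the oracle.

#' Iterative Fourier-phase retrieval on the measurement matrix
#'
#' Alternates kernel and phase updates until the mean absolute phase update
#' falls below `tol` or `n_iter` iterations are reached.  Fully
#' deterministic given `A` (phase initialized at zero).  After convergence
#' the gauge is fixed by removing the best-fit integer linear ramp (an
#' unobservable cyclic shift) and zeroing the phase at the zero frequency.
#'
#' @param A A [frames_to_spectral_matrix()] result.
#' @param n_iter Iteration budget (default 1000, the standard protocol).
#' @param tol Convergence tolerance on the mean absolute phase update, in
#'   radians.
#' @param hermitian If `TRUE`, project the phase onto Hermitian antisymmetry
#'   (`psi(-k) = -psi(k)`) after each update — the constraint satisfied by
#'   the spectrum of any real object, appropriate for incoherent
#'   intensities.
#' @return List with `psi` (centered phase map of the object spectrum),
#'   `kernel` (centered Toeplitz kernel estimate `t(q)`), `trace`
#'   (per-iteration mean absolute update), `n_iter`, `converged`.
#' @export
class_phase_retrieval <- function(A, n_iter = 1000, tol = 1e-6,
                                  hermitian = FALSE) {
  stopifnot(inherits(A, "measurement_matrix"))
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  d <- A$dim
  M <- ncol(A$columns)
  if (all(Mod(A$columns) == 0)) {
    stop("degenerate all-zero measurement matrix", call. = FALSE)
  }
  # natural-order spectral grids, one slice per frame
  Ag <- array(apply(array(A$columns, c(d, M)), 3, ifftshift2), c(d, M))
  psi <- matrix(0, d[1], d[2])
  trace <- numeric(0)
  converged <- FALSE
  tmat <- NULL
  for (it in seq_len(n_iter)) {
    u <- exp(-1i * psi)
    B <- Ag * as.vector(u)
    FB <- fft2_stack(B)
    # (a) kernel: sum over frames of the cyclic autocorrelation of b_m
    ptot <- rowSums(Mod(FB)^2, dims = 2)
    tmat <- ifft2(ptot) / (M - 1)
    # (b) phase: S(k1) = sum_m a_m(k1) conj( (t (*) b_m)(k1) )
    Th <- fft2(tmat)
    G <- fft2_stack(FB * as.vector(Th), inverse = TRUE)
    S <- rowSums(Ag * Conj(G), dims = 2) / (M - 1)
    psi_new <- Arg(S)
    psi_new[Mod(S) == 0] <- 0
    if (hermitian) psi_new <- hermitian_project(psi_new)
    delta <- mean(abs(wrap_phase(psi_new - psi)))
    trace <- c(trace, delta)
    psi <- psi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  g <- remove_phase_ramp(fftshift2(psi))
  list(psi = g$psi, kernel = fftshift2(tmat), trace = trace,
       n_iter = length(trace), converged = converged, shift = g$shift)
}

#' Dense-covariance phase retrieval (test oracle)
#'
#' The same alternating updates as [class_phase_retrieval()], evaluated
#' literally on a dense covariance matrix.  Quadratic in the pixel count;
#' intended for small grids and as the independent check of the
#' frame-domain implementation, and for covariances synthesized directly
#' from the model factorization.
#'
#' @param C Dense `N_k x N_k` complex covariance (a [covariance()] object
#'   or plain matrix) over a consistent cyclic vectorization of the grid.
#' @param dims The 2-D grid size, `c(h, w)` with `h * w == nrow(C)`.
#' @inheritParams class_phase_retrieval
#' @return As [class_phase_retrieval()]; `psi` and `kernel` are on the same
#'   (centered, if `C` came from a measurement matrix) grid as the rows of
#'   `C`, gauge-fixed identically.
#' @export
class_phase_retrieval_cov <- function(C, dims, n_iter = 1000, tol = 1e-6) {
  Cm <- if (inherits(C, "cov_matrix")) {
    if (C$form != "dense") stop("dense covariance required", call. = FALSE)
    C$C
  } else C
  dims <- as.integer(dims)
  nk <- nrow(Cm)
  stopifnot(prod(dims) == nk)
  if (all(Mod(Cm) == 0)) stop("degenerate all-zero covariance", call. = FALSE)
  h <- dims[1]; w <- dims[2]
  i <- (seq_len(nk) - 1) %% h
  j <- (seq_len(nk) - 1) %/% h
  qidx <- (outer(i, i, "-") %% h) + (outer(j, j, "-") %% w) * h + 1
  psi <- numeric(nk)
  trace <- numeric(0)
  converged <- FALSE
  tv <- NULL
  for (it in seq_len(n_iter)) {
    u <- exp(-1i * psi)
    D <- Cm * (u %o% Conj(u))
    acc <- rowsum(cbind(Re(as.vector(D)), Im(as.vector(D))),
                  group = as.vector(qidx))
    # rowsum returns groups in sorted order, i.e. q = 1..nk
    tv <- complex(real = acc[, 1], imaginary = acc[, 2])
    E <- Cm * matrix(Conj(u), nk, nk, byrow = TRUE) * Conj(matrix(tv[qidx], nk, nk))
    S <- rowSums(E)
    psi_new <- Arg(S)
    psi_new[Mod(S) == 0] <- 0
    delta <- mean(abs(wrap_phase(psi_new - psi)))
    trace <- c(trace, delta)
    psi <- psi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  g <- remove_phase_ramp(matrix(psi, h, w))
  # q accumulates in natural cyclic order regardless of the row ordering of
  # C; recenter so q = 0 sits at the grid center, as in the frame path
  list(psi = g$psi, kernel = fftshift2(matrix(tv, h, w)), trace = trace,
       n_iter = length(trace), converged = converged, shift = g$shift)
}

# Average the phasor with the conjugate of its point reflection (natural
# DFT ordering), projecting psi onto psi(-k) = -psi(k).
hermitian_project <- function(psi) {
  d <- dim(psi)
  ri <- c(1, rev(seq_len(d[1])[-1]))
  ci <- c(1, rev(seq_len(d[2])[-1]))
  v <- exp(1i * psi) + exp(-1i * psi[ri, ci])
  out <- Arg(v)
  out[Mod(v) == 0] <- 0
  out
}

#' Remove the linear-ramp and constant gauge from a phase map
#'
#' Fourier-phase reconstructions are defined only up to a constant and a
#' linear ramp (an integer cyclic shift of the image).  The ramp slope is
#' estimated from cyclic neighbor phase differences, rounded to an integer
#' number of cycles, and subtracted; the remaining constant is fixed by
#' zeroing the phase at the map center.
#'
#' @param psi A phase matrix (radians), origin at the center sample.
#' @return List with `psi` (gauge-fixed, wrapped to `(-pi, pi]`) and
#'   `shift` (the removed integer cyclic shift along each axis).
#' @export
remove_phase_ramp <- function(psi) {
  d <- dim(psi)
  dx <- wrap_phase(psi[c(2:d[1], 1), ] - psi)
  dy <- wrap_phase(psi[, c(2:d[2], 1)] - psi)
  sx <- round(Arg(mean(exp(1i * dx))) * d[1] / (2 * pi))
  sy <- round(Arg(mean(exp(1i * dy))) * d[2] / (2 * pi))
  i <- seq_len(d[1]) - 1 - floor(d[1] / 2)
  j <- seq_len(d[2]) - 1 - floor(d[2] / 2)
  ramp <- outer(2 * pi * sx * i / d[1], 2 * pi * sy * j / d[2], "+")
  out <- wrap_phase(psi - ramp)
  out <- wrap_phase(out - out[floor(d[1] / 2) + 1, floor(d[2] / 2) + 1])
  list(psi = out, shift = c(sx, sy))
}

#' Reconstruct the hidden object from a frame stack
#'
#' The full pipeline: optional intensity modulation, spectral measurement
#' matrix, iterative Fourier-phase retrieval, and amplitude estimation from
#' the covariance diagonal, `|O~(k)| = sqrt(max(C(k,k), 0))` (the moment
#' estimator under the factorized model; the unknown kernel constant
#' `T(0)` is absorbed into the global scale).  In incoherent mode the
#' mean-subtracted pipeline loses the zero-frequency term: the image offset
#' is fixed by non-negativity (minimum pixel at zero) and the global scale
#' by matching the image total to the temporal-mean frame total, which for
#' unit-sum PSFs equals the object total.
#'
#' @param stack A [frame_stack()] (or a list with a `$stack` element as the
#'   simulators return).
#' @param n_iter,tol Passed to [class_phase_retrieval()].
#' @param modulation `NULL` (off, the default) or `c(s_min, s_max)` applied
#'   before the transform.
#' @param lowpass_frac,subtract_mean Passed to
#'   [frames_to_spectral_matrix()].
#' @return A `recon_result`: list with `object_spectrum` (centered complex),
#'   `object_image` (real non-negative in incoherent mode; the complex
#'   field at the scattering-layer plane in coherent mode), `psi`,
#'   `kernel`, `phase_trace`, `n_iter`, `converged`, `mode`, `mean_frame`,
#'   `neg_fraction` (fraction of pixels below zero before the offset fix).
#' @export
iclass_reconstruct <- function(stack, n_iter = 1000, tol = 1e-6,
                               modulation = NULL, lowpass_frac = 1,
                               subtract_mean = NULL) {
  if (!inherits(stack, "frame_stack") && !is.null(stack$stack)) {
    stack <- stack$stack
  }
  stopifnot(inherits(stack, "frame_stack"))
  if (!is.null(modulation)) {
    stack <- apply_intensity_modulation(stack, modulation[1], modulation[2])
  }
  A <- frames_to_spectral_matrix(stack, subtract_mean = subtract_mean,
                                 lowpass_frac = lowpass_frac)
  pr <- class_phase_retrieval(A, n_iter = n_iter, tol = tol,
                              hermitian = stack$mode == "incoherent")
  M <- ncol(A$columns)
  diagC <- rowSums(Mod(A$columns)^2) / (M - 1)
  amp <- matrix(sqrt(pmax(diagC, 0)), A$dim[1], A$dim[2])
  spectrum <- amp * exp(1i * pr$psi)
  if (lowpass_frac < 1) {
    # re-embed the cropped band on the acquisition grid so the (band-limited)
    # reconstruction has the same size as the input frames
    d0 <- dim(stack$frames)[1:2]
    big <- matrix(0i, d0[1], d0[2])
    ri <- floor(d0[1] / 2) + 1 - floor(A$dim[1] / 2) - 1 + seq_len(A$dim[1])
    ci <- floor(d0[2] / 2) + 1 - floor(A$dim[2] / 2) - 1 + seq_len(A$dim[2])
    big[ri, ci] <- spectrum
    spectrum <- big
  }
  img <- ifft2(ifftshift2(spectrum))
  neg_fraction <- NA_real_
  if (stack$mode == "incoherent") {
    img <- Re(img)
    neg_fraction <- mean(img < 0)
    img <- img - min(img)
    total <- sum(A$mean_frame)
    if (sum(img) > 0 && total > 0) img <- img * total / sum(img)
  }
  structure(list(object_spectrum = spectrum, object_image = img,
                 psi = pr$psi, kernel = pr$kernel, phase_trace = pr$trace,
                 n_iter = pr$n_iter, converged = pr$converged,
                 mode = stack$mode, mean_frame = A$mean_frame,
                 neg_fraction = neg_fraction),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s, %d x %d, %d iterations (%s)\n",
              x$mode, nrow(x$object_image), ncol(x$object_image), x$n_iter,
              if (x$converged) "converged" else "budget reached"))
  invisible(x)
}

#' Per-frame PSF estimation by Wiener deconvolution
#'
#' Deconvolves each raw frame with the reconstructed (or true) object:
#' `P_m = IFT[ I~_m(k) O~*(k) / (|O~(k)|^2 + eps * max|O~|^2) ]`, with the
#' kernel origin returned at the grid center.  In incoherent mode the
#' estimates are clipped to be non-negative and renormalized to unit sum.
#'
#' @param stack A [frame_stack()] (raw, unmodulated frames).
#' @param object_estimate A matrix, [object_image()], or `recon_result`.
#' @param reg_eps Wiener regularization, relative to the peak spectral
#'   power (> 0).
#' @return `H x W x M` array of PSF estimates (real in incoherent mode).
#' @export
estimate_frame_psfs <- function(stack, object_estimate, reg_eps = 1e-6) {
  if (!inherits(stack, "frame_stack") && !is.null(stack$stack)) stack <- stack$stack
  stopifnot(inherits(stack, "frame_stack"))
  if (reg_eps <= 0) stop("`reg_eps` must be > 0", call. = FALSE)
  ov <- object_estimate
  if (inherits(ov, "recon_result")) ov <- ov$object_image
  if (inherits(ov, "object_image")) ov <- ov$values
  if (all(ov == 0)) stop("degenerate all-zero object", call. = FALSE)
  d <- dim(stack$frames)
  Of <- fft2(ov)
  den <- Mod(Of)^2 + reg_eps * max(Mod(Of)^2)
  wiener <- Conj(Of) / den
  Pf <- fft2_stack(stack$frames) * as.vector(wiener)
  P <- fft2_stack(Pf, inverse = TRUE)
  P <- array(apply(P, 3, fftshift2), d)
  if (stack$mode == "incoherent") {
    P <- Re(P)
    P[P < 0] <- 0
    sums <- apply(P, 3, sum)
    if (any(sums == 0)) stop("deconvolution produced an empty PSF", call. = FALSE)
    P <- sweep(P, 3, sums, "/")
  }
  P
}

#' Per-frame APSF estimation from a coherent stack
#'
#' Estimates the scatterer phase of each realization from the ratio of the
#' measured field to the reconstructed object field in the conjugate
#' (diffuser/pupil) plane, where the scatterer acts multiplicatively:
#' `phi_m = arg(E~_m(k) / E~_CLASS(k))` on the support where the object
#' spectrum carries energy, and the APSF is the centered Fourier transform
#' of `exp(i phi_m)` restricted to that support, energy-normalized.
#'
#' @param field_stack A coherent [frame_stack()] (or simulator output list).
#' @param E_class Reconstructed object field (matrix, or `recon_result`).
#' @param support_thresh Support threshold as a fraction of the peak object
#'   spectral magnitude.
#' @param min_support Minimum admissible support pixel count.
#' @return `H x W x M` complex array of unit-energy APSF estimates.
#' @export
estimate_apsfs <- function(field_stack, E_class, support_thresh = 0.05,
                           min_support = 16) {
  if (!inherits(field_stack, "frame_stack") && !is.null(field_stack$stack)) {
    field_stack <- field_stack$stack
  }
  stopifnot(inherits(field_stack, "frame_stack"))
  if (field_stack$mode != "coherent") {
    stop("APSF estimation requires a coherent stack", call. = FALSE)
  }
  if (inherits(E_class, "recon_result")) E_class <- E_class$object_image
  Ospec <- fftshift2(fft2(E_class))
  supp <- Mod(Ospec) > support_thresh * max(Mod(Ospec))
  if (sum(supp) < min_support) {
    stop("object spectral support below the minimum pixel count", call. = FALSE)
  }
  d <- dim(field_stack$frames)
  out <- array(0i, d)
  for (m in seq_len(d[3])) {
    Fm <- fftshift2(fft2(field_stack$frames[, , m]))
    # outside the system pupil the measured spectrum is (numerically) zero
    # and the ratio carries no phase: restrict the support to frequencies
    # the frame actually recorded
    sm <- supp & (Mod(Fm) > 1e-9 * max(Mod(Fm)))
    phi <- matrix(0, d[1], d[2])
    phi[sm] <- Arg(Fm[sm] / Ospec[sm])
    g <- sm * exp(1i * phi)
    field <- fftshift2(fft2(ifftshift2(g)))
    out[, , m] <- field / sqrt(sum(Mod(field)^2))
  }
  out
}

#' Registration-invariant Pearson correlation
#'
#' Reconstructions from Fourier phase are defined only up to an integer
#' cyclic shift and a point-reflected (twin) copy.  This maximizes the
#' Pearson correlation of two images over all cyclic shifts (via FFT
#' cross-correlation) and over reflection of the second image.
#'
#' @param image_a,image_b Matrices of the same shape (complex inputs are
#'   reduced to their modulus); both must be nonconstant.
#' @return List with `r` (the maximized correlation), `shift`, `reflected`.
#' @export
registered_correlation <- function(image_a, image_b) {
  a <- if (is.complex(image_a)) Mod(image_a) else image_a
  b <- if (is.complex(image_b)) Mod(image_b) else image_b
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  a0 <- a - mean(a); b0 <- b - mean(b)
  sa <- sqrt(sum(a0^2)); sb <- sqrt(sum(b0^2))
  if (sa == 0 || sb == 0) stop("constant image", call. = FALSE)
  best <- list(r = -Inf, shift = c(0, 0), reflected = FALSE)
  Fa <- fft2(a0)
  for (refl in c(FALSE, TRUE)) {
    bb <- if (refl) b0[c(1, rev(seq_len(nrow(b0))[-1])),
                       c(1, rev(seq_len(ncol(b0))[-1]))] else b0
    # cc(s) = sum_r a0(r) bb(r - s) / (sa sb); the 1/N^2 of ifft2 cancels
    # the N^2 delta of the correlation theorem
    cc <- Re(ifft2(Fa * Conj(fft2(bb)))) / (sa * sb)
    idx <- which.max(cc)
    if (cc[idx] > best$r) {
      s <- c((idx - 1) %% nrow(cc), (idx - 1) %/% nrow(cc))
      best <- list(r = cc[idx], shift = s, reflected = refl)
    }
  }
  best
}
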