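# Shared fixtures and independent oracles, all built in code.

# Brute-force centered 2-D DFT, O(N^4): the oracle for every FFT-based path.
brute_dft2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  kx <- seq_len(h) - 1 - floor(h / 2)
  ky <- seq_len(w) - 1 - floor(w / 2)
  out <- matrix(0i, h, w)
  for (a in seq_len(h)) {
    for (b in seq_len(w)) {
      ph <- outer((seq_len(h) - 1) * kx[a] / h, (seq_len(w) - 1) * ky[b] / w, "+")
      out[a, b] <- sum(x * exp(-2i * pi * ph))
    }
  }
  out
}

# Brute-force cyclic convolution with a centered kernel, O(N^4).
brute_cconv2 <- function(x, k_centered) {
  h <- nrow(x); w <- ncol(x)
  kn <- dynscatter::ifftshift2(k_centered)  # origin at [1,1]
  out <- matrix(0, h, w)
  for (a in seq_len(h)) {
    for (b in seq_len(w)) {
      s <- 0
      for (p in seq_len(h)) {
        for (q in seq_len(w)) {
          s <- s + x[p, q] * kn[((a - p) %% h) + 1, ((b - q) %% w) + 1]
        }
      }
      out[a, b] <- s
    }
  }
  out
}

# A delta kernel with its peak on the center sample.
delta_kernel <- function(n) {
  k <- matrix(0, n, n)
  k[floor(n / 2) + 1, floor(n / 2) + 1] <- 1
  k
}

# Stack of M copies of one centered-delta PSF.
delta_psf_stack <- function(n, M) {
  array(rep(delta_kernel(n), M), c(n, n, M))
}

# A band-limited random complex field (spectrum confined to a centered disk
# of the given fractional radius), unit peak.
bandlimited_field <- function(n, radius_frac, seed = 1) {
  set.seed(seed)
  f2 <- outer(dynscatter:::freq_axis(n)^2, dynscatter:::freq_axis(n)^2, "+")
  disk <- f2 <= (0.5 * radius_frac)^2
  spec <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n) * disk
  fld <- ifft2(ifftshift2(spec))
  fld / max(Mod(fld))
}

# Magnitude of the normalized complex inner product: 1 iff the fields agree
# up to one constant complex factor.
complex_corr <- function(a, b) {
  Mod(sum(a * Conj(b))) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
}

# Model covariance diag(Otil) T diag(Otil)* for a PSF pixel covariance
# concentrated at a single 0-based pixel offset r0 (natural ordering):
# T(k1, k2) = exp(-2 pi i ((k1 - k2) . r0) / n).
model_covariance <- function(Otil, r0 = c(0, 0)) {
  n <- nrow(Otil)
  a <- as.vector(Otil)
  idx <- seq_along(a) - 1
  i <- idx %% n
  j <- idx %/% n
  Tq <- exp(-2i * pi * ((outer(i, i, "-") * r0[1] + outer(j, j, "-") * r0[2]) / n))
  (a %*% Conj(t(a))) * Tq
}
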