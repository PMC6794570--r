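# Independent oracles used against the FFT-based implementation paths.

# Direct quadratic-time 2-D DFT: X[u, v] = sum_x x[r, c] e^{-2pi i (ur + vc)/n}
# with u, v running over 0..n-1 (unshifted). Deliberately written as plain
# summation, independent of stats::fft.
dft2_direct <- function(x, inverse = FALSE) {
  n <- nrow(x); m <- ncol(x)
  s <- if (inverse) 1 else -1
  out <- matrix(0 + 0i, n, m)
  wr <- exp(s * 2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  wc <- exp(s * 2i * pi * outer(0:(m - 1), 0:(m - 1)) / m)
  for (u in seq_len(n)) for (v in seq_len(m))
    out[u, v] <- sum(wr[u, ] * x * rep(wc[v, ], each = n))
  out
}

# Band-limited projection oracle: truncate the DC-centered spectrum of `hr`
# to an N x N block (unpaired Nyquist row/col zeroed for even N) and return
# both the native N-grid image and the restored n-grid image, all via the
# direct DFT above.
oracle_truncate <- function(hr, N) {
  n <- nrow(hr)
  F <- dft2_direct(hr)
  # reorder to DC-centered indexing
  sh <- function(k, n) ((k + floor(n / 2)) %% n) + 1L   # shifted -> unshifted
  ctr <- floor(n / 2) + 1L
  lo <- floor(n / 2) - floor(N / 2) + 1L
  keep <- lo:(lo + N - 1L)
  Fc <- matrix(0 + 0i, N, N)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    u <- keep[a] - ctr; v <- keep[b] - ctr       # signed frequency
    Fc[a, b] <- F[((u %% n) + 1L), ((v %% n) + 1L)]
  }
  if (N %% 2 == 0 && N < n) { Fc[1, ] <- 0; Fc[, 1] <- 0 }
  # native: inverse N-point DFT of Fc (DC-centered -> unshifted N indexing)
  Fn <- matrix(0 + 0i, N, N)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    u <- keep[a] - ctr; v <- keep[b] - ctr
    Fn[((u %% N) + 1L), ((v %% N) + 1L)] <- Fc[a, b]
  }
  native <- Re(dft2_direct(Fn, inverse = TRUE)) / n^2
  # restored: embed in the n-grid and invert
  Fb <- matrix(0 + 0i, n, n)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    u <- keep[a] - ctr; v <- keep[b] - ctr
    Fb[((u %% n) + 1L), ((v %% n) + 1L)] <- Fc[a, b]
  }
  restored <- Re(dft2_direct(Fb, inverse = TRUE)) / n^2
  list(native = native, restored = restored)
}

# Brute-force percentile (sort-based), independent of stats::quantile's
# interpolation machinery only insofar as it re-derives the type-7 rule.
percentile_oracle <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

# FWHM of a peak in a sampled magnitude spectrum, by linear interpolation
# of the half-maximum crossings.
measure_fwhm <- function(spec, freq) {
  i0 <- which.max(spec)
  half <- spec[i0] / 2
  li <- max(which(spec[1:i0] <= half))
  ri <- i0 + min(which(spec[i0:length(spec)] <= half)) - 1
  fl <- stats::approx(spec[c(li, li + 1)], freq[c(li, li + 1)], xout = half)$y
  fr <- stats::approx(spec[c(ri - 1, ri)], freq[c(ri - 1, ri)], xout = half)$y
  fr - fl
}

# Small reusable fixture: one fully generated synthetic case.
tiny_case <- function(seed = 42L, size = 32L, lr = 8L,
                      noise = c(0.02, 0.05)) {
  sisr:::generate_case(as.integer(seed), as.integer(size), as.integer(lr),
                       noise)
}
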