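# Metabolite-map synthesis and the k-space truncation channel that turns a
# high-resolution map into its matched low-resolution acquisition.

# DC-centered index block: for an n-point axis the shifted DC bin sits at
# n/2 + 1 (even n); the retained central block of length N spans
# [n/2 - N/2 + 1, n/2 + N/2] so DC is always included.
center_block <- function(n, N) {
  lo <- floor(n / 2) - floor(N / 2) + 1L
  seq.int(lo, lo + N - 1L)
}

fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((floor(n / 2) + 1L):n, 1:floor(n / 2)),
    c((floor(m / 2) + 1L):m, 1:floor(m / 2))]
}

# For even N < n the retained block's lowest-frequency row/col (-N/2) has
# no +N/2 partner inside the block; zeroing it keeps the pass-band
# conjugate-symmetric, so the truncated spectrum of a real image inverts
# to an exactly real image and truncate -> zero-fill is an exact
# orthogonal projection.
symmetrize_block <- function(Fc, truncated) {
  N <- nrow(Fc)
  if (truncated && N %% 2 == 0) {
    Fc[1, ] <- 0
    Fc[, 1] <- 0
  }
  Fc
}

ifftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((n - floor(n / 2) + 1L):n, 1:(n - floor(n / 2))),
    c((m - floor(m / 2) + 1L):m, 1:(m - floor(m / 2)))]
}

#' Sample metabolite-map parameters
#'
#' Draws the random mixing and corruption parameters for one synthetic
#' metabolite map: WM/GM mixing ratio `r2 ~ U(0, 1)`, lesion metabolite
#' weight `r3 ~ U(-1, 1)`, a random linear signal-bias field (magnitude
#' bounded by `bias_max` over the grid), and a noise fraction drawn
#' uniformly from `noise_range`.
#'
#' @param seed integer seed.
#' @param noise_range length-2 numeric, noise std as a fraction of the
#'   maximum map intensity (default the low band, 2-5%).
#' @param bias_max bound on the bias-field magnitude (default 0.15).
#' @return list of class `map_params` with `r2`, `r3`, `bias`
#'   (`grad_row`, `grad_col`, `offset`) and `noise_frac`.
#' @export
sample_map_params <- function(seed, noise_range = c(0.02, 0.05),
                              bias_max = 0.15) {
  with_seed(seed, {
    r2 <- runif(1)
    r3 <- runif(1, -1, 1)
    gr <- runif(1, -1, 1); gc <- runif(1, -1, 1); off <- runif(1, -1, 1)
    amp <- sum(abs(c(gr, gc, off)))
    sc <- if (amp > 0) bias_max * runif(1) / amp else 0
    structure(list(
      r2 = r2, r3 = r3,
      bias = list(grad_row = gr * sc, grad_col = gc * sc, offset = off * sc),
      noise_frac = runif(1, noise_range[1], noise_range[2]),
      seed = as.integer(seed)
    ), class = "map_params")
  })
}

# Evaluate the linear bias field on an n x m grid; coordinates scaled to
# [-1, 1] so the gradient terms read as anterior/posterior, left/right tilt.
bias_field <- function(bias, n, m) {
  r <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  c_ <- (seq_len(m) - (m + 1) / 2) / (m / 2)
  outer(r, c_, function(rr, cc)
    bias$grad_row * rr + bias$grad_col * cc + bias$offset)
}

#' Synthesize a high-resolution metabolite map
#'
#' Mixes the tissue fraction maps with a random ratio,
#' `hr = r2 * WM + (1 - r2) * GM + B + r3 * L`, where `B` is a smooth linear
#' signal-bias field and `L` the lesion field; the result is clipped at zero
#' (metabolite signal is nonnegative) and masked to the brain.
#'
#' @param tissues a `tissue_pair`.
#' @param lesion_field lesion matrix (same shape), or NULL for none.
#' @param params a `map_params` set.
#' @return list of class `metabolite_map` with matrix `hr` and `params`.
#' @export
make_hrsi <- function(tissues, lesion_field = NULL, params) {
  n <- nrow(tissues$wm); m <- ncol(tissues$wm)
  B <- bias_field(params$bias, n, m)
  L <- if (is.null(lesion_field)) 0 else lesion_field
  hr <- params$r2 * tissues$wm + (1 - params$r2) * tissues$gm + B + params$r3 * L
  hr <- pmax(hr, 0) * tissues$mask
  structure(list(hr = hr, params = params), class = "metabolite_map")
}

#' Downsample a map by k-space truncation, with optional noise
#'
#' Takes the DC-centered 2-D DFT of `hr`, keeps the central
#' `lr_size x lr_size` block, adds i.i.d. circular complex Gaussian noise to
#' the retained coefficients, inverse-transforms, and takes the magnitude.
#' The transform pair is scaled so a constant image maps to the same
#' constant at every `lr_size`; under that convention the per-coefficient
#' k-space noise std `noise_frac * max(hr) * n^2 / lr_size` yields an
#' image-domain (per real component) noise std of `noise_frac * max(hr)`.
#' The native low-resolution grid is then nearest-neighbor upscaled back to
#' `n x n`, mirroring how a coarse acquisition is displayed on the anatomy
#' grid.
#'
#' @param hr `n x n` matrix (a high-resolution map).
#' @param lr_size retained block side (<= n); acquisitions of 16, 24 or 32
#'   points are the standard cases.
#' @param noise_frac noise std as a fraction of `max(hr)`; 0 disables noise.
#' @param seed integer seed for the noise draw.
#' @return list of class `lowres_map`: `native` (`lr_size x lr_size`),
#'   `upscaled` (`n x n`), `lr_size`, `noise_frac`.
#' @export
downsample_kspace <- function(hr, lr_size, noise_frac = 0, seed = 0L) {
  n <- nrow(hr)
  stop_if(lr_size > n, "`lr_size` must not exceed the grid size")
  F <- fftshift2(fft(hr))
  blk <- center_block(n, lr_size)
  Fc <- symmetrize_block(F[blk, blk], lr_size < n)
  if (noise_frac > 0) {
    sigma_k <- noise_frac * max(hr) * n^2 / lr_size
    noise <- with_seed(seed, complex(
      real = rnorm(lr_size^2, sd = sigma_k),
      imaginary = rnorm(lr_size^2, sd = sigma_k)))
    Fc <- Fc + matrix(noise, lr_size, lr_size)
    # magnitude reconstruction of the noisy complex acquisition
    native <- Mod(fft(ifftshift2(Fc), inverse = TRUE)) / n^2
  } else {
    # noise-free spectrum is Hermitian: the inverse is real, and keeping
    # the real part (ringing lobes included) makes truncation followed by
    # zero-filling the exact band-limited projection
    native <- Re(fft(ifftshift2(Fc), inverse = TRUE)) / n^2
  }
  up <- nn_upscale(native, n)
  structure(list(native = native, upscaled = up,
                 lr_size = as.integer(lr_size), noise_frac = noise_frac),
            class = "lowres_map")
}

#' Nearest-neighbor upscale
#'
#' Pixel-center aligned replication: target pixel `(i, j)` (1-based) reads
#' source pixel `floor((i - 0.5) * N / n) + 1`. Handles non-integer scale
#' factors (e.g. 24 -> 128) without ties.
#'
#' @param native `N x N` matrix.
#' @param target output side length (>= N).
#' @return `target x target` matrix whose distinct values are a subset of
#'   the source's.
#' @export
nn_upscale <- function(native, target) {
  N <- nrow(native)
  idx <- pmin(floor((seq_len(target) - 0.5) * N / target) + 1L, N)
  native[idx, idx, drop = FALSE]
}

#' Generate a stream of matched training triples
#'
#' Draws `n_cases` independent synthetic cases. Each case gets a fresh
#' phantom, fresh augmentation parameters and fresh map parameters (all
#' derived deterministically from `seed` and the case index, so a dataset
#' is reproducible from one integer and no triple repeats within or across
#' epoch-indexed streams).
#'
#' @param n_cases number of triples (>= 1).
#' @param hr_size working grid side (network input size).
#' @param lr_size native low-resolution side.
#' @param noise_range length-2 noise-fraction band for the LRSI.
#' @param seed integer stream seed.
#' @param n_gyri phantom folding parameter.
#' @param collect if TRUE (default) return a list of cases; if a function,
#'   it is called with (case, index) per case and nothing is stored.
#' @return list of cases, each a list with `at1w`, `lrsi` (upscaled),
#'   `lrsi_native`, `hrsi`, `tissues`, `case_seed`; or invisible NULL when
#'   `collect` is a function.
#' @export
generate_dataset <- function(n_cases, hr_size = 128L, lr_size = 32L,
                             noise_range = c(0.02, 0.05), seed = 1L,
                             n_gyri = 10L, collect = TRUE) {
  stop_if(n_cases < 1, "`n_cases` must be at least 1")
  sink_fun <- if (is.function(collect)) collect else NULL
  out <- if (is.null(sink_fun)) vector("list", n_cases) else NULL
  for (i in seq_len(n_cases)) {
    case <- generate_case(derive_seed(seed, 101L, i), hr_size, lr_size,
                          noise_range, n_gyri)
    if (is.null(sink_fun)) out[[i]] <- case else sink_fun(case, i)
  }
  if (is.null(sink_fun)) out else invisible(NULL)
}

# One matched (aT1w, LRSI, HRSI) case from a case seed.
generate_case <- function(case_seed, hr_size, lr_size, noise_range, n_gyri = 10L) {
  sc <- generate_phantom(derive_seed(case_seed, 1L), size = hr_size,
                         n_gyri = n_gyri)
  th <- estimate_thresholds(sc$t1w, sc$mask)
  tp <- segment_tissues(sc$t1w, sc$mask, th$wm_max, th$gm_min)
  ap <- sample_augment_params(derive_seed(case_seed, 2L), sc$mask)
  ac <- augment_case(sc, tp, ap)
  mp <- sample_map_params(derive_seed(case_seed, 3L), noise_range)
  mm <- make_hrsi(ac$tissues, ac$lesion_field, mp)
  lr <- downsample_kspace(mm$hr, lr_size, mp$noise_frac,
                          seed = derive_seed(case_seed, 4L))
  list(at1w = ac$at1w, lrsi = lr$upscaled, lrsi_native = lr$native,
       hrsi = mm$hr, tissues = ac$tissues, map_params = mp,
       case_seed = as.integer(case_seed))
}
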