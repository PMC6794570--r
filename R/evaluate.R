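# Reconstruction baselines and the evaluation battery: interpolation
# methods, noise-band sweeps, spectral-voxel errors, ratio-vs-T1w curves,
# and mixing-ratio recovery.

#' Zero-filling (k-space) interpolation
#'
#' Embeds the DC-centered DFT of the native low-resolution grid at the
#' center of a `target x target` zero array (the same shift convention as
#' [downsample_kspace()]), inverse-transforms and takes the magnitude,
#' scaled so constant images are preserved. Composing truncation with
#' zero-filling yields the ideal band-limited projection of the original.
#'
#' @param native `N x N` matrix.
#' @param target output side (>= N).
#' @return `target x target` matrix.
#' @export
zero_fill_upsample <- function(native, target) {
  N <- nrow(native)
  stop_if(N > target, "`target` must be at least the native size")
  if (N == target) {
    # full-band round trip, no resampling
    return(Re(fft(fft(native), inverse = TRUE)) / N^2)
  }
  F <- fftshift2(fft(native))
  big <- matrix(0 + 0i, target, target)
  blk <- center_block(target, N)
  big[blk, blk] <- symmetrize_block(F, TRUE)
  # real input has a Hermitian spectrum, so the inverse is real; 1/N^2
  # keeps constants fixed and makes truncate->zero-fill the exact
  # band-limited projection under the downsample_kspace scaling
  Re(fft(ifftshift2(big), inverse = TRUE)) / N^2
}

# Catmull-Rom cubic kernel (Keys, a = -1/2)
cubic_kernel <- function(t) {
  at <- abs(t)
  ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

#' Bicubic interpolation
#'
#' Separable Catmull-Rom bicubic resampling with pixel-center alignment and
#' replicated edges. Reproduces constants exactly and degree-1 ramps away
#' from the borders; negative undershoot is clipped at zero (metabolite
#' maps are nonnegative).
#'
#' @param native `N x N` matrix.
#' @param target output side (>= N).
#' @return `target x target` matrix.
#' @export
bicubic_upsample <- function(native, target) {
  N <- nrow(native)
  stop_if(N > target, "`target` must be at least the native size")
  if (N == target) return(native)
  # interpolation matrix: rows = target positions, cols = source pixels
  x <- (seq_len(target) - 0.5) * N / target + 0.5   # continuous source coord
  W <- matrix(0, target, N)
  base <- floor(x)
  for (k in -1:2) {
    src <- base + k
    w <- cubic_kernel(x - src)
    src_cl <- pmin(pmax(src, 1L), N)               # replicate edges
    for (i in seq_len(target)) W[i, src_cl[i]] <- W[i, src_cl[i]] + w[i]
  }
  pmax(W %*% native %*% t(W), 0)
}

#' Mean squared image error
#'
#' The training/evaluation error for an `m x m` reconstruction:
#' `sum((O - truth)^2) / m^2` — the summed squared difference over both
#' spatial dimensions divided by the squared output dimension, yielding one
#' scalar per image.
#'
#' @param output,target `m x m` matrices.
#' @return nonnegative scalar.
#' @export
mse_loss <- function(output, target) {
  stop_if(!all(dim(output) == dim(target)), "shape mismatch")
  sum((output - target)^2) / length(output)
}

# Normalization convention for cross-method comparison: both reconstruction
# and truth are divided by the truth's max before the MSE.
normalized_mse <- function(recon, truth) {
  mx <- max(truth)
  if (mx <= 0) return(mse_loss(recon, truth))
  mse_loss(recon / mx, truth / mx)
}

#' Noise-robustness sweep over reconstruction methods
#'
#' For each synthetic case and each noise band, one low-resolution
#' acquisition is simulated (a single noise draw shared by all methods, the
#' fair comparison) and every method reconstructs the high-resolution map;
#' mean normalized MSE is tabulated per method and band.
#'
#' @param methods named list of functions `(case, lowres) -> target x target
#'   matrix`, where `lowres` is the `lowres_map` for the draw.
#' @param n_cases number of synthetic cases.
#' @param lr_size native acquisition side.
#' @param hr_size working grid side.
#' @param noise_bands named list of length-2 noise-fraction ranges; defaults
#'   to the low (2-5%), medium (15-20%) and high (30-40%) bands.
#' @param seed integer seed.
#' @return object of class `eval_report`: matrix `mse` (methods x bands),
#'   plus `n_cases`, `lr_size`, `seed`.
#' @export
noise_sweep <- function(methods, n_cases = 50, lr_size = 32L, hr_size = 128L,
                        noise_bands = list(low = c(0.02, 0.05),
                                           medium = c(0.15, 0.20),
                                           high = c(0.30, 0.40)),
                        seed = 1L) {
  mse <- matrix(0, length(methods), length(noise_bands),
                dimnames = list(names(methods), names(noise_bands)))
  for (i in seq_len(n_cases)) {
    case_seed <- derive_seed(seed, 301L, i)
    case <- generate_case(case_seed, hr_size, lr_size, c(0, 0))
    for (b in seq_along(noise_bands)) {
      band <- noise_bands[[b]]
      nf <- with_seed(derive_seed(case_seed, 5L + b), runif(1, band[1], band[2]))
      lr <- downsample_kspace(case$hrsi, lr_size, nf,
                              seed = derive_seed(case_seed, 50L + b))
      for (m in seq_along(methods)) {
        recon <- methods[[m]](case, lr)
        mse[m, b] <- mse[m, b] + normalized_mse(recon, case$hrsi)
      }
    }
  }
  structure(list(mse = mse / n_cases, n_cases = n_cases,
                 lr_size = as.integer(lr_size), seed = as.integer(seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d cases, native %dx%d, seed %d\n",
              x$n_cases, x$lr_size, x$lr_size, x$seed))
  cat("mean normalized MSE (rows = methods, cols = noise bands):\n")
  print(round(x$mse, 4))
  invisible(x)
}

#' Spectral MSE at one voxel
#'
#' Mean over spectral bins of the squared magnitude difference between a
#' reconstructed and a ground-truth spectrum at voxel `(row, col)`.
#'
#' @param recon,truth `si_volume` objects of matching shape.
#' @param voxel integer (row, col).
#' @return nonnegative scalar.
#' @export
spectral_voxel_mse <- function(recon, truth, voxel) {
  stop_if(!all(dim(recon$data) == dim(truth$data)), "shape mismatch")
  d <- dim(recon$data)
  stop_if(voxel[1] < 1 || voxel[1] > d[1] || voxel[2] < 1 || voxel[2] > d[2],
          "voxel out of range")
  mean((recon$data[voxel[1], voxel[2], ] - truth$data[voxel[1], voxel[2], ])^2)
}

#' Metabolite ratio as a function of T1w intensity
#'
#' Bins in-mask voxels by T1w intensity (equal-width bins over the in-mask
#' range) and returns the per-bin mean of `numerator / denominator`, with
#' the denominator floored at `eps_frac * max(denominator)` to keep
#' near-zero voxels from dominating. Since T1w intensity tracks the WM/GM
#' mix, these curves expose how a ratio varies with tissue composition.
#'
#' @param numerator,denominator metabolite map matrices.
#' @param t1w T1w intensity matrix.
#' @param mask binary matrix.
#' @param n_bins number of intensity bins (default 20).
#' @param eps_frac denominator floor as a fraction of its max.
#' @return object of class `ratio_curve`: `centers`, `mean_ratio` (NA for
#'   bins with < 5 voxels), `counts`.
#' @export
ratio_vs_t1w <- function(numerator, denominator, t1w, mask, n_bins = 20,
                         eps_frac = 1e-3) {
  idx <- mask > 0
  stop_if(!any(idx), "mask is empty")
  ti <- t1w[idx]
  den <- pmax(denominator[idx], eps_frac * max(denominator))
  ratio <- numerator[idx] / den
  br <- range(ti)
  stop_if(diff(br) <= 0, "degenerate T1w range inside mask")
  edges <- seq(br[1], br[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(ti, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  means <- rep(NA_real_, n_bins)
  ok <- counts >= 5
  if (!any(ok)) stop("all ratio bins are empty", call. = FALSE)
  sums <- vapply(seq_len(n_bins), function(b) sum(ratio[bin == b]), 0)
  means[ok] <- sums[ok] / counts[ok]
  structure(list(centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 mean_ratio = means, counts = counts),
            class = "ratio_curve")
}

#' Correlation between two ratio curves
#'
#' Pearson correlation between the per-bin means of two [ratio_vs_t1w()]
#' curves over bins populated in both.
#'
#' @param a,b `ratio_curve` objects with identical binning.
#' @return correlation coefficient in \[-1, 1\].
#' @export
ratio_curve_cor <- function(a, b) {
  ok <- !is.na(a$mean_ratio) & !is.na(b$mean_ratio)
  stop_if(sum(ok) < 3, "too few shared populated bins")
  x <- a$mean_ratio[ok]; y <- b$mean_ratio[ok]
  # flat curves have no Pearson correlation; coinciding ones count as 1
  if (sd(x) == 0 || sd(y) == 0)
    return(if (max(abs(x - y)) < 1e-12) 1 else NA_real_)
  stats::cor(x, y)
}

#' Recover the WM/GM mixing ratio from a metabolite map
#'
#' Least-squares estimate of `r2` in `map = r2 * WM + (1 - r2) * GM` by
#' regressing `map - GM` on `WM - GM` over in-mask pixels. When `map` is a
#' low-resolution acquisition, pass WM and GM through the identical
#' noise-free k-space truncation first (`lr_size`), so the regression
#' compares like with like.
#'
#' @param map observed map (high-resolution matrix, or the upscaled
#'   low-resolution map when `lr_size` is given).
#' @param tissues `tissue_pair` of ground-truth fraction maps.
#' @param lr_size if non-NULL, the native acquisition side used to produce
#'   `map`; WM/GM are truncated to match.
#' @return estimated `r2`.
#' @export
recover_r2 <- function(map, tissues, lr_size = NULL) {
  wm <- tissues$wm; gm <- tissues$gm
  if (!is.null(lr_size)) {
    wm <- downsample_kspace(wm, lr_size, 0)$upscaled
    gm <- downsample_kspace(gm, lr_size, 0)$upscaled
  }
  idx <- tissues$mask > 0
  x <- (wm - gm)[idx]
  y <- (map - gm)[idx]
  sum(x * y) / sum(x * x)
}
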