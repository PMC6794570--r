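#' Generate a synthetic T1w-like brain slice with known tissue composition
#'
#' Builds a 2-D digital phantom: an elliptical brain mask containing a
#' central white-matter (WM) region whose boundary is sinusoidally perturbed
#' (a gyri/sulci-like folding pattern) surrounded by a gray-matter (GM) rim.
#' The per-pixel WM and GM fractions are continuous in \[0, 1\] and sum to the
#' brain mask exactly, so partial-volume mixing at tissue boundaries is part
#' of the ground truth. The rendered T1w image gives WM a brighter plateau
#' than GM (conventional T1 contrast), modulated by a smooth multiplicative
#' shading field plus fine Gaussian texture.
#'
#' @param seed integer; the scene is bit-reproducible from this seed.
#' @param size side length in pixels (>= 16); all grids are `size x size`.
#' @param n_gyri number of sinusoidal lobes on the WM boundary.
#' @param gm_level,wm_level rendered plateau intensities before shading.
#' @return an object of class `phantom_scene`: a list with matrices `t1w`
#'   (intensities in \[0,1\], zero outside the mask), `mask` (binary),
#'   `wm_true`, `gm_true` (tissue fractions, `wm_true + gm_true == mask`),
#'   and the `seed`/`size` used.
#' @examples
#' sc <- generate_phantom(seed = 7, size = 64, n_gyri = 8)
#' range(sc$wm_true + sc$gm_true - sc$mask)
#' @export
generate_phantom <- function(seed, size = 128L, n_gyri = 12L,
                             gm_level = 0.45, wm_level = 0.85) {
  stop_if(size < 16, "`size` must be at least 16")
  stop_if(n_gyri < 1, "`n_gyri` must be positive")
  size <- as.integer(size)
  with_seed(seed, {
    ctr <- (size + 1) / 2
    # mildly randomized ellipse axes (fractions of the half-width)
    a <- size / 2 * runif(1, 0.78, 0.88)
    b <- size / 2 * runif(1, 0.62, 0.74)
    rot <- runif(1, -0.3, 0.3)
    g <- expand.grid(r = seq_len(size), c = seq_len(size))
    dr <- g$r - ctr; dc <- g$c - ctr
    x <- cos(rot) * dc + sin(rot) * dr
    y <- -sin(rot) * dc + cos(rot) * dr
    rho <- sqrt((x / a)^2 + (y / b)^2)   # 1 on the brain boundary
    mask_v <- as.numeric(rho <= 1)

    # WM boundary: base radius with an n_gyri-lobed sinusoidal perturbation
    theta <- atan2(y / b, x / a)
    phase <- runif(1, 0, 2 * pi)
    amp   <- runif(1, 0.08, 0.14)
    amp2  <- runif(1, 0.02, 0.05)
    rho_wm <- 0.55 + amp * sin(n_gyri * theta + phase) +
      amp2 * sin(2 * theta + runif(1, 0, 2 * pi))
    # soft edge (2-pixel-scale) gives fractional partial-volume boundary
    edge <- 2 / (size / 2)
    wm_v <- clip01((rho_wm - rho) / edge + 0.5) * mask_v
    gm_v <- mask_v - wm_v

    shading <- 1 + 0.1 * cos(2 * pi * g$r / size + runif(1, 0, 2 * pi)) *
      cos(2 * pi * g$c / size + runif(1, 0, 2 * pi))
    tex <- rnorm(size * size, sd = 0.02)
    t1w_v <- clip01((gm_level * gm_v + wm_level * wm_v) * shading + tex * mask_v) * mask_v

    structure(list(
      t1w = matrix(t1w_v, size, size),
      mask = matrix(mask_v, size, size),
      wm_true = matrix(wm_v, size, size),
      gm_true = matrix(gm_v, size, size),
      seed = as.integer(seed), size = size
    ), class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom_scene: %dx%d grid, seed %d\n", x$size, x$size, x$seed))
  cat(sprintf("  brain area fraction: %.3f; WM fraction of brain: %.3f\n",
              mean(x$mask), sum(x$wm_true) / sum(x$mask)))
  invisible(x)
}

#' Write a phantom scene to disk
#'
#' Either one NIfTI file per grid (`t1w`, `mask`, `wm`, `gm` suffixes) or a
#' single serialized archive keyed the same way.
#'
#' @param scene a `phantom_scene`.
#' @param path output path; for `format = "nifti"` a path prefix, for
#'   `format = "archive"` a single file path.
#' @param format `"archive"` (serialized list) or `"nifti"`.
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(scene, path, format = c("archive", "nifti")) {
  format <- match.arg(format)
  keys <- c(t1w = "t1w", mask = "mask", wm = "wm_true", gm = "gm_true")
  if (format == "archive") {
    obj <- list(t1w = scene$t1w, mask = scene$mask,
                wm = scene$wm_true, gm = scene$gm_true, seed = scene$seed)
    saveRDS(obj, path, compress = "gzip")
    return(invisible(path))
  }
  paths <- character(0)
  for (k in names(keys)) {
    p <- paste0(path, "_", k, ".nii.gz")
    RNifti::writeNifti(scene[[keys[[k]]]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
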