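# Intensity-based WM/GM segmentation and the T1w augmentation chain:
# contrast exponent, rotation + field-of-view truncation, random lesions.

#' Estimate segmentation thresholds from a T1w image
#'
#' The segmentation needs the maximum WM intensity and minimum GM intensity
#' of the image. These are estimated robustly from the in-mask intensity
#' distribution: `gm_min` is the `p_lo` percentile and `wm_max` is the
#' `p_hi` percentile minus `gm_min`, so outlier pixels (noise spikes, bright
#' vessels) do not set the scale.
#'
#' @param t1w nonnegative intensity matrix.
#' @param mask binary matrix of the same shape (brain region).
#' @param p_lo,p_hi percentiles in \[0, 1\] (defaults 0.05 and 0.98).
#' @return list with `gm_min` and `wm_max` (`wm_max > 0` guaranteed).
#' @export
estimate_thresholds <- function(t1w, mask, p_lo = 0.05, p_hi = 0.98) {
  v <- t1w[mask > 0]
  stop_if(length(v) == 0, "mask is empty: no in-brain pixels")
  gm_min <- unname(quantile(v, p_lo))
  wm_max <- unname(quantile(v, p_hi)) - gm_min
  stop_if(wm_max <= 0,
          "degenerate image: in-mask intensity spread is zero")
  list(gm_min = gm_min, wm_max = wm_max)
}

#' Segment a T1w image into WM and GM fraction maps
#'
#' Linear intensity model: the WM fraction at a pixel is
#' `(S - gm_min) / wm_max`, clipped to \[0, 1\] and masked; the GM fraction
#' is its complement inside the mask, so `wm + gm == mask` by construction
#' and both maps read as per-voxel tissue percentages.
#'
#' @param t1w nonnegative intensity matrix.
#' @param mask binary matrix.
#' @param wm_max,gm_min intensity thresholds (see [estimate_thresholds()]).
#' @return list of class `tissue_pair` with matrices `wm`, `gm`, `mask`.
#' @export
segment_tissues <- function(t1w, mask, wm_max, gm_min) {
  stop_if(wm_max <= 0, "`wm_max` must be positive")
  stop_if(any(t1w < 0), "`t1w` must be nonnegative")
  wm <- clip01((t1w - gm_min) / wm_max) * mask
  gm <- (1 - wm) * mask
  structure(list(wm = wm, gm = gm, mask = mask), class = "tissue_pair")
}

#' Render a lesion field
#'
#' Each lesion is an isotropic Gaussian bump
#' `amplitude * exp(-d^2 / (2 sigma^2))` with `sigma = radius / 2`;
#' amplitudes may be negative (hypo-intense). At most 6 lesions; the summed
#' field is zeroed outside the brain mask.
#'
#' @param specs list of lesion specs, each a list with `center` (row, col),
#'   `radius` (pixels, > 0) and `amplitude`.
#' @param shape integer vector (nrow, ncol).
#' @param mask binary matrix of that shape.
#' @return matrix of the summed lesion field.
#' @export
render_lesions <- function(specs, shape, mask) {
  stop_if(length(specs) > 6, "at most 6 lesions are supported")
  field <- matrix(0, shape[1], shape[2])
  if (length(specs) == 0) return(field)
  g <- expand.grid(r = seq_len(shape[1]), c = seq_len(shape[2]))
  for (sp in specs) {
    stop_if(sp$radius <= 0, "lesion radius must be positive")
    stop_if(sp$radius > min(shape) / 4, "lesion radius exceeds grid/4")
    s2 <- (sp$radius / 2)^2
    d2 <- (g$r - sp$center[1])^2 + (g$c - sp$center[2])^2
    field <- field + matrix(sp$amplitude * exp(-d2 / (2 * s2)),
                            shape[1], shape[2])
  }
  field * (mask > 0)
}

#' Sample a random augmentation parameter set
#'
#' Draws one parameter set for the T1w augmentation: contrast exponent
#' `r1 ~ U(0.5, 2.5)`, rotation angle `U(-15, 15)` degrees, per-edge
#' field-of-view truncation `U{0..40}` pixels (scaled down proportionally
#' for grids smaller than 128), and 0-6 random Gaussian lesions with
#' amplitude drawn from `U(-0.6, 0.6)` excluding `(-0.05, 0.05)`.
#'
#' @param seed integer seed.
#' @param mask binary matrix; lesion centers are drawn inside it.
#' @param max_crop maximum per-edge truncation in pixels on a 128 grid.
#' @return list of class `augment_params`.
#' @export
sample_augment_params <- function(seed, mask, max_crop = 40L) {
  n <- nrow(mask)
  # scale the 0-40-pixel truncation range proportionally for smaller grids,
  # and never crop so far that fewer than 9 pixels remain per axis
  crop_cap <- max(0L, min(as.integer(max_crop),
                          as.integer(round(max_crop * n / 128)),
                          as.integer((n - 9) %/% 2)))
  with_seed(seed, {
    r1 <- runif(1, 0.5, 2.5)
    angle <- runif(1, -15, 15)
    crop <- sample.int(crop_cap + 1L, 4, replace = TRUE) - 1L
    n_les <- sample.int(7L, 1) - 1L
    idx <- which(mask > 0)
    lesions <- list()
    if (n_les > 0 && length(idx) > 0) {
      centers <- sample(idx, n_les, replace = TRUE)
      for (k in seq_len(n_les)) {
        amp <- runif(1, 0.05, 0.6) * sample(c(-1, 1), 1)
        lesions[[k]] <- list(
          center = c((centers[k] - 1L) %% n + 1L, (centers[k] - 1L) %/% n + 1L),
          radius = runif(1, 2, n / 8), amplitude = amp)
      }
    }
    structure(list(r1 = r1, angle_deg = angle, crop = crop,
                   lesions = lesions, seed = as.integer(seed)),
              class = "augment_params")
  })
}

# The geometric transform R(): rotate (bilinear, zero fill), truncate the
# field of view per edge, then resample back onto the working n x n grid.
# crop = (top, bottom, left, right) in pixels. Identity parameters are an
# exact passthrough.
apply_fov_transform <- function(img, angle_deg, crop) {
  n <- nrow(img); m <- ncol(img)
  if (angle_deg == 0 && all(crop == 0)) return(img)
  out <- rotate_bilinear(img, angle_deg)
  if (any(crop > 0)) {
    r1 <- 1 + crop[1]; r2 <- n - crop[2]
    c1 <- 1 + crop[3]; c2 <- m - crop[4]
    stop_if(r2 - r1 < 8 || c2 - c1 < 8, "truncation leaves too little image")
    out <- resize_window_bilinear(out, r1, r2, c1, c2, n, m)
  }
  out
}

#' Augment a phantom scene into one training anatomy
#'
#' Applies the augmentation model: the max-normalized T1w signal is raised
#' to the contrast exponent `r1`, the lesion field is added, and the
#' rotation/FOV-truncation transform is applied. The identical geometric
#' transform is applied to the WM/GM fraction maps and the mask (the mask is
#' re-binarized at 0.5, ties mapping to 1, and the tissue fractions are
#' renormalized so `wm + gm == mask` holds exactly after interpolation).
#' The augmented T1w image is renormalized to maximum 1.
#'
#' @param scene a `phantom_scene` (or any list with `t1w` and `mask`).
#' @param tissues a `tissue_pair` for the same grid.
#' @param params an `augment_params` set.
#' @return list of class `augmented_case`: `at1w`, `tissues` (transformed
#'   `tissue_pair`), `lesion_field` (transformed), `params`.
#' @export
augment_case <- function(scene, tissues, params) {
  s <- scene$t1w
  mx <- max(s)
  sn <- if (mx > 0) s / mx else s
  lesions <- render_lesions(params$lesions, dim(sn), scene$mask)
  core <- sn^params$r1 + lesions

  tf <- function(img) apply_fov_transform(img, params$angle_deg, params$crop)
  at1w <- tf(core)
  mask_t <- tf(scene$mask)
  mask_b <- (mask_t >= 0.5) * 1
  wm_t <- clip01(tf(tissues$wm))
  gm_t <- clip01(tf(tissues$gm))
  tot <- wm_t + gm_t
  safe <- pmax(tot, 1e-9)
  wm_n <- (wm_t / safe) * mask_b
  gm_n <- mask_b - wm_n
  les_t <- tf(lesions)

  at1w <- pmax(at1w, 0) * mask_b
  amax <- max(at1w)
  if (amax > 0) at1w <- at1w / amax

  structure(list(
    at1w = at1w,
    tissues = structure(list(wm = wm_n, gm = gm_n, mask = mask_b),
                        class = "tissue_pair"),
    lesion_field = les_t,
    params = params
  ), class = "augmented_case")
}
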