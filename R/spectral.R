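# Parametric spectral layer: Lorentzian metabolite basis spectra, spatial
# distribution of spectra by metabolite maps, and point-by-point spectral
# super-resolution.

GYROMAGNETIC_MHZ_PER_T <- 42.577

#' Define a spectral axis
#'
#' @param bandwidth_hz spectral bandwidth in Hz (default 2000).
#' @param n_points number of spectral points (default 512).
#' @param b0_tesla static field strength in T (default 3).
#' @param reference_ppm carrier position in ppm (water, default 4.7).
#' @return object of class `spectral_axis` with the frequency axis
#'   `freq_hz` (ascending, DC-centered) and matching `ppm` axis.
#' @export
spectral_axis <- function(bandwidth_hz = 2000, n_points = 512L,
                          b0_tesla = 3, reference_ppm = 4.7) {
  stop_if(n_points < 2, "`n_points` must be at least 2")
  stop_if(bandwidth_hz <= 0, "`bandwidth_hz` must be positive")
  n <- as.integer(n_points)
  f0 <- GYROMAGNETIC_MHZ_PER_T * b0_tesla           # MHz
  freq <- (seq_len(n) - 1 - floor(n / 2)) * bandwidth_hz / n
  structure(list(bandwidth_hz = bandwidth_hz, n_points = n,
                 b0_tesla = b0_tesla, reference_ppm = reference_ppm,
                 freq_hz = freq, ppm = reference_ppm + freq / f0),
            class = "spectral_axis")
}

#' Built-in metabolite basis set
#'
#' Multi-Lorentzian templates at literature chemical shifts for the major
#' proton-visible brain metabolites (singlet approximations; J-coupled
#' multiplet structure is not modeled). Relative amplitudes are plausible
#' for healthy brain and fully configurable.
#'
#' @param names which metabolites to return (default all six).
#' @param fwhm_hz Lorentzian linewidth (default 8 Hz).
#' @return named list of `metabolite_basis` objects.
#' @export
default_metabolite_bases <- function(names = c("NAA", "Cr", "Ch", "Glu",
                                               "Gln", "mI"), fwhm_hz = 8) {
  all <- list(
    NAA = list(c(2.01, 1.0)),
    Cr  = list(c(3.03, 0.65), c(3.93, 0.45)),
    Ch  = list(c(3.19, 0.55)),
    Glu = list(c(2.35, 0.45), c(3.75, 0.25)),
    Gln = list(c(2.45, 0.20), c(3.77, 0.12)),
    mI  = list(c(3.56, 0.50))
  )
  stats::setNames(lapply(names, function(nm) {
    pk <- all[[nm]]
    stop_if(is.null(pk), paste("unknown metabolite:", nm))
    metabolite_basis(nm, do.call(rbind, pk), fwhm_hz)
  }), names)
}

#' Construct a metabolite basis
#'
#' @param name metabolite label.
#' @param peaks two-column matrix: ppm position, relative amplitude (>= 0).
#' @param fwhm_hz Lorentzian full width at half maximum in Hz.
#' @return object of class `metabolite_basis`.
#' @export
metabolite_basis <- function(name, peaks, fwhm_hz = 8) {
  peaks <- matrix(peaks, ncol = 2)
  stop_if(nrow(peaks) < 1, "at least one peak is required")
  stop_if(any(peaks[, 2] < 0), "relative amplitudes must be nonnegative")
  structure(list(name = name, peaks = peaks, fwhm_hz = fwhm_hz),
            class = "metabolite_basis")
}

#' Simulate a basis spectrum
#'
#' Synthesizes the time-domain signal as a sum of complex exponentials (one
#' per peak, at the peak's offset from the carrier, ppm converted to Hz via
#' the field strength) under an exponential decay chosen so each line's
#' Lorentzian FWHM equals `fwhm_hz`, then discrete-Fourier-transforms to
#' the spectral axis.
#'
#' @param basis a `metabolite_basis`.
#' @param axis a `spectral_axis`.
#' @param magnitude if TRUE (default) return the magnitude spectrum,
#'   otherwise the complex spectrum (DC-centered, matching `axis$freq_hz`).
#' @return numeric (or complex) vector of length `axis$n_points`.
#' @export
simulate_basis <- function(basis, axis, magnitude = TRUE) {
  f0 <- GYROMAGNETIC_MHZ_PER_T * axis$b0_tesla
  offs <- (basis$peaks[, 1] - axis$reference_ppm) * f0   # Hz
  stop_if(any(abs(offs) > axis$bandwidth_hz / 2),
          "peak falls outside the representable band")
  n <- axis$n_points
  t <- (seq_len(n) - 1) / axis$bandwidth_hz
  # the pipeline works in magnitude spectra, whose Lorentzian half-width is
  # sqrt(3) times the absorption-mode width for the same decay; fwhm_hz
  # specifies the magnitude-spectrum FWHM, hence the sqrt(3) in the rate
  decay <- exp(-pi * basis$fwhm_hz * t / sqrt(3))
  fid <- decay * colSums(basis$peaks[, 2] * exp(2i * pi * outer(offs, t)))
  spec <- fftshift_vec(fft(fid)) / n
  if (magnitude) Mod(spec) else spec
}

fftshift_vec <- function(x) {
  n <- length(x)
  x[c((floor(n / 2) + 1L):n, 1:floor(n / 2))]
}

#' Distribute basis spectra over metabolite maps
#'
#' Builds a spatial-spectral volume: each voxel's spectrum is the magnitude
#' of the map-weighted complex sum of the metabolite basis spectra (all
#' bases are zero-phase, so for nonnegative maps this coincides with the
#' weighted sum of magnitude spectra).
#'
#' @param maps named list of metabolite map matrices (shared shape).
#' @param bases named list of `metabolite_basis` matching `names(maps)`.
#' @param axis a `spectral_axis`.
#' @return object of class `si_volume`: 3-D array `data`
#'   (row, col, spectral index) of magnitudes, plus `axis`.
#' @export
build_si_volume <- function(maps, bases, axis) {
  stop_if(!setequal(names(maps), names(bases)), "map/basis names mismatch")
  dims <- dim(maps[[1]])
  stop_if(!all(vapply(maps, function(m) all(dim(m) == dims), TRUE)),
          "all maps must share one shape")
  n <- axis$n_points
  # complex accumulation as an (n_voxel x n_bins) outer-product sum
  acc <- matrix(0 + 0i, prod(dims), n)
  for (nm in names(maps)) {
    spec <- simulate_basis(bases[[nm]], axis, magnitude = FALSE)
    acc <- acc + as.vector(maps[[nm]]) %o% spec
  }
  structure(list(data = array(Mod(acc), c(dims, n)), axis = axis),
            class = "si_volume")
}

#' Downsample every spectral slice of a volume
#'
#' Applies [downsample_kspace()] to each spectral bin's spatial map
#' independently, producing the matched low-resolution volume (upscaled
#' back to the anatomy grid).
#'
#' @param volume an `si_volume`.
#' @param lr_size native acquisition side.
#' @param noise_frac noise fraction (applied per slice, relative to that
#'   slice's max).
#' @param seed integer seed.
#' @return an `si_volume` on the same spatial grid.
#' @export
downsample_si_volume <- function(volume, lr_size, noise_frac = 0, seed = 0L) {
  d <- dim(volume$data)
  out <- array(0, d)
  for (s in seq_len(d[3])) {
    sl <- volume$data[, , s]
    if (max(sl) == 0 && noise_frac > 0) { next }
    out[, , s] <- downsample_kspace(sl, lr_size, noise_frac,
                                    seed = derive_seed(seed, 7L, s))$upscaled
  }
  structure(list(data = out, axis = volume$axis), class = "si_volume")
}

#' Point-by-point spectral super-resolution
#'
#' Reconstructs a high-spatial-resolution volume by applying a trained
#' reconstructor to each spectral bin independently: the bin's spatial map
#' is max-normalized, reconstructed together with the T1w image, and
#' un-normalized with the carried scale. Spectral length and order are
#' preserved exactly.
#'
#' @param lr_volume an `si_volume` whose spatial grid is already upscaled
#'   to the anatomy grid.
#' @param at1w T1w matrix on the same grid.
#' @param model a trained [dunet] or any function
#'   `(at1w, lrsi) -> matrix` (e.g. an interpolation baseline or a stub).
#' @return an `si_volume` of reconstructed magnitudes (clipped at 0).
#' @export
pointwise_superres <- function(lr_volume, at1w, model) {
  d <- dim(lr_volume$data)
  recon_fun <- if (inherits(model, "dunet")) {
    function(a, l) predict(model, a, l)
  } else model
  out <- array(0, d)
  for (s in seq_len(d[3])) {
    sl <- lr_volume$data[, , s]
    mx <- max(sl)
    if (mx == 0) next
    r <- recon_fun(at1w, sl / mx)
    stop_if(!all(dim(r) == d[1:2]),
            "reconstructor changed the spatial shape")
    out[, , s] <- pmax(r, 0) * mx
  }
  structure(list(data = out, axis = lr_volume$axis), class = "si_volume")
}
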