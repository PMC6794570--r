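# Shared numeric helpers: seeded RNG scoping, sub-seed derivation,
# bilinear resampling used by the rotation/FOV transform.

clip01 <- function(x) pmin(pmax(x, 0), 1)

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls never perturb a caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation (splitmix-style integer hash), kept in
# [0, 2^31 - 2] so the result is always a valid R seed.
derive_seed <- function(seed, stream, index = 0L) {
  x <- (as.double(seed) * 2654435761 + as.double(stream) * 40503 +
        as.double(index) * 2246822519) %% 2147483647
  as.integer(x)
}

# Bilinear sample of matrix `img` at fractional (row, col) positions.
# Coordinates are 1-based pixel centers; points outside [1, n] read zero.
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0;   fc <- cols - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- numeric(length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  (1 - fr) * (1 - fc) * val(r0,     c0) +
  (1 - fr) * fc       * val(r0,     c0 + 1) +
  fr       * (1 - fc) * val(r0 + 1, c0) +
  fr       * fc       * val(r0 + 1, c0 + 1)
}

# Rotate a matrix by `angle_deg` (counter-clockwise, about the image center)
# with bilinear interpolation and zero fill.
rotate_bilinear <- function(img, angle_deg) {
  if (angle_deg == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  cr <- (n + 1) / 2; cc <- (m + 1) / 2
  th <- angle_deg * pi / 180
  g <- expand.grid(r = seq_len(n), c = seq_len(m))
  dr <- g$r - cr; dc <- g$c - cc
  src_r <- cr + cos(th) * dr - sin(th) * dc
  src_c <- cc + sin(th) * dr + cos(th) * dc
  matrix(bilinear_sample(img, src_r, src_c), n, m)
}

# Resample the sub-window rows [r1, r2], cols [c1, c2] of `img` onto an
# `out_n` x `out_m` grid (pixel-center aligned, bilinear).
resize_window_bilinear <- function(img, r1, r2, c1, c2, out_n, out_m) {
  sr <- (r2 - r1 + 1) / out_n
  sc <- (c2 - c1 + 1) / out_m
  rows <- r1 - 0.5 + (seq_len(out_n) - 0.5) * sr
  cols <- c1 - 0.5 + (seq_len(out_m) - 0.5) * sc
  g <- expand.grid(r = rows, c = cols)
  matrix(bilinear_sample(img, g$r, g$c), out_n, out_m)
}
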