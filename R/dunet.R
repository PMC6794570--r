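# The densely connected U-Net: an encoder-decoder in which every
# convolution's output is concatenated onto its input (dense connectivity
# within each resolution level), encoder features skip to the matching
# decoder level, and — because each level's concatenation carries its whole
# input forward — the last convolution at full resolution sees every
# full-resolution feature map produced anywhere in the network. Max-pooled
# (lower-resolution) features are not re-upsampled for that final
# collection; a higher-resolution version of them already exists.

#' Declare a densely connected U-Net architecture
#'
#' @param input_size spatial side of the (square) inputs; must be divisible
#'   by `2^n_pool`. Default 128.
#' @param growth_maps feature maps produced by every convolution
#'   (default 32).
#' @param n_pool number of max-pooling levels (default 3; the bottleneck
#'   then sits at `input_size / 2^n_pool`).
#' @param kernel convolution kernel side (default 3, same-padded).
#' @param dropout_rate dropout applied to convolution outputs during
#'   training (default 0.1).
#' @return object of class `dunet_spec`.
#' @export
dunet_spec <- function(input_size = 128L, growth_maps = 32L, n_pool = 3L,
                       kernel = 3L, dropout_rate = 0.1) {
  stop_if(input_size %% 2^n_pool != 0,
          "`input_size` must be divisible by 2^n_pool")
  stop_if(growth_maps < 1, "`growth_maps` must be at least 1")
  structure(list(input_size = as.integer(input_size), in_channels = 2L,
                 growth_maps = as.integer(growth_maps),
                 n_pool = as.integer(n_pool), kernel = as.integer(kernel),
                 dropout_rate = dropout_rate), class = "dunet_spec")
}

# Channel bookkeeping shared by the builder and the forward/backward pass.
# Dense level: input c -> conv(g), cat -> conv(g), cat => c + 2g channels.
dunet_channels <- function(spec) {
  g <- spec$growth_maps
  enc_in <- integer(spec$n_pool)
  c_ <- spec$in_channels
  for (i in seq_len(spec$n_pool)) {
    enc_in[i] <- c_
    c_ <- c_ + 2L * g          # level output after two dense convs
  }
  enc_out <- enc_in + 2L * g
  bot_in <- c_                 # pooled deepest encoder output
  bot_out <- bot_in + 2L * g
  dec_in <- integer(spec$n_pool)   # channels entering each decoder tconv
  cur <- bot_out
  for (i in rev(seq_len(spec$n_pool))) {
    dec_in[i] <- cur
    cur <- (g + enc_out[i]) + 2L * g   # cat(tconv, skip) + two dense convs
  }
  list(enc_in = enc_in, enc_out = enc_out, bot_in = bot_in,
       bot_out = bot_out, dec_in = dec_in, final_in = cur)
}

#' Build a densely connected U-Net
#'
#' Instantiates the architecture with reproducible He-initialized weights.
#' The model maps a 2-channel `input_size x input_size` input (T1w image
#' and nearest-neighbor-upscaled low-resolution map, each max-normalized)
#' to a 1-channel map of the same size. All convolutions use ReLU; the
#' decoder upsamples with stride-2 transposed convolutions.
#'
#' @param spec a [dunet_spec()].
#' @param seed integer; weights are bit-reproducible from it.
#' @return object of class `dunet`: the spec, a named list of parameter
#'   arrays, and the `parameter_count`.
#' @export
dunet <- function(spec = dunet_spec(), seed = 1L) {
  ch <- dunet_channels(spec)
  k <- spec$kernel; g <- spec$growth_maps
  pars <- list()
  with_seed(seed, {
    he_conv <- function(cin, cout)
      matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             k * k * cin, cout)
    he_tconv <- function(cin, cout)
      matrix(rnorm(4 * cout * cin, sd = sqrt(2 / cin)), 4 * cout, cin)
    add_conv <- function(nm, cin, cout, bias = 0) {
      pars[[paste0(nm, ".W")]] <<- he_conv(cin, cout)
      pars[[paste0(nm, ".b")]] <<- rep(bias, cout)
    }
    for (i in seq_len(spec$n_pool)) {
      add_conv(sprintf("enc%da", i), ch$enc_in[i], g)
      add_conv(sprintf("enc%db", i), ch$enc_in[i] + g, g)
    }
    add_conv("bota", ch$bot_in, g)
    add_conv("botb", ch$bot_in + g, g)
    for (i in rev(seq_len(spec$n_pool))) {
      pars[[sprintf("dec%dt.W", i)]] <- he_tconv(ch$dec_in[i], g)
      pars[[sprintf("dec%dt.b", i)]] <- rep(0, g)
      zin <- g + ch$enc_out[i]
      add_conv(sprintf("dec%da", i), zin, g)
      add_conv(sprintf("dec%db", i), zin + g, g)
    }
    add_conv("final", ch$final_in, 1L, bias = 0.01)
  })
  structure(list(spec = spec, pars = pars, seed = as.integer(seed),
                 parameter_count = sum(vapply(pars, length, 0L)),
                 trained = FALSE, history = NULL),
            class = "dunet")
}

cat_cube <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# Forward pass. Returns list(y = H x W matrix, cache) — cache only when
# requested (training). Dropout (inverted) is applied to convolution
# outputs only when `training`.
dunet_forward <- function(model, x, training = FALSE, keep_cache = training) {
  spec <- model$spec; p <- model$pars; k <- spec$kernel
  drop <- if (training) spec$dropout_rate else 0
  cache <- if (keep_cache) list(enc = vector("list", spec$n_pool),
                                dec = vector("list", spec$n_pool)) else NULL

  conv <- function(nm, input, relu = TRUE) {
    y <- .conv2d_forward(input, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]],
                         k, relu)
    mask <- NULL
    if (drop > 0 && nm != "final") {
      mask <- array(runif(length(y)) >= drop, dim(y)) / (1 - drop)
      y_d <- y * mask
    } else y_d <- y
    list(y = y_d, pre = y, mask = mask)
  }

  d <- x
  skips <- vector("list", spec$n_pool)
  for (i in seq_len(spec$n_pool)) {
    a <- conv(sprintf("enc%da", i), d)
    d1 <- cat_cube(d, a$y)
    b <- conv(sprintf("enc%db", i), d1)
    d2 <- cat_cube(d1, b$y)
    mp <- .maxpool_forward(d2)
    skips[[i]] <- d2
    if (keep_cache) cache$enc[[i]] <- list(d = d, a = a, d1 = d1, b = b,
                                           arg = mp$arg, hw = dim(d2)[1:2])
    d <- mp$y
  }
  a <- conv("bota", d)
  d1 <- cat_cube(d, a$y)
  b <- conv("botb", d1)
  cur <- cat_cube(d1, b$y)
  if (keep_cache) cache$bot <- list(d = d, a = a, d1 = d1, b = b)

  for (i in rev(seq_len(spec$n_pool))) {
    u_pre <- .tconv2_forward(cur, p[[sprintf("dec%dt.W", i)]],
                             p[[sprintf("dec%dt.b", i)]], TRUE)
    z <- cat_cube(u_pre, skips[[i]])
    a <- conv(sprintf("dec%da", i), z)
    z1 <- cat_cube(z, a$y)
    b <- conv(sprintf("dec%db", i), z1)
    z2 <- cat_cube(z1, b$y)
    if (keep_cache) cache$dec[[i]] <- list(x_in = cur, u = u_pre, z = z,
                                           a = a, z1 = z1, b = b)
    cur <- z2
  }
  fin <- conv("final", cur, relu = TRUE)
  if (keep_cache) cache$fin <- list(input = cur, out = fin)
  list(y = fin$y[, , 1], cache = cache)
}

# Backward pass: gradient of a scalar loss wrt every parameter, given
# d(loss)/d(output) as a matrix. Returns a named list matching pars.
dunet_backward <- function(model, cache, dy_out) {
  spec <- model$spec; p <- model$pars; k <- spec$kernel
  grads <- lapply(model$pars, function(w) array(0, dim(w) %||% length(w)))

  conv_bw <- function(nm, cc, input, dy) {
    if (!is.null(cc$mask)) dy <- dy * cc$mask
    res <- .conv2d_backward(input, p[[paste0(nm, ".W")]], cc$pre, dy, k, TRUE)
    grads[[paste0(nm, ".W")]] <<- grads[[paste0(nm, ".W")]] + res$dW
    grads[[paste0(nm, ".b")]] <<- grads[[paste0(nm, ".b")]] + as.vector(res$db)
    res$dx
  }
  split_cube <- function(dc, n_first) {
    list(head = dc[, , seq_len(n_first), drop = FALSE],
         tail = dc[, , -seq_len(n_first), drop = FALSE])
  }

  dyc <- array(dy_out, c(dim(dy_out), 1L))
  d_cur <- conv_bw("final", cache$fin$out, cache$fin$input, dyc)

  g <- spec$growth_maps
  d_skip <- vector("list", spec$n_pool)
  for (i in seq_len(spec$n_pool)) {          # decoder in reverse exec order
    dc <- cache$dec[[i]]
    s <- split_cube(d_cur, dim(dc$z1)[3])    # z2 = cat(z1, b)
    dz1 <- s$head + conv_bw(sprintf("dec%db", i), dc$b, dc$z1, s$tail)
    s <- split_cube(dz1, dim(dc$z)[3])       # z1 = cat(z, a)
    dz <- s$head + conv_bw(sprintf("dec%da", i), dc$a, dc$z, s$tail)
    s <- split_cube(dz, g)                   # z = cat(u, skip)
    d_skip[[i]] <- s$tail
    tb <- .tconv2_backward(dc$x_in, p[[sprintf("dec%dt.W", i)]], dc$u,
                           s$head, TRUE)
    grads[[sprintf("dec%dt.W", i)]] <- grads[[sprintf("dec%dt.W", i)]] + tb$dW
    grads[[sprintf("dec%dt.b", i)]] <- grads[[sprintf("dec%dt.b", i)]] + as.vector(tb$db)
    d_cur <- tb$dx
  }

  bc <- cache$bot                            # d_cur is grad at bottleneck out
  s <- split_cube(d_cur, dim(bc$d1)[3])
  dd1 <- s$head + conv_bw("botb", bc$b, bc$d1, s$tail)
  s <- split_cube(dd1, dim(bc$d)[3])
  d_pooled <- s$head + conv_bw("bota", bc$a, bc$d, s$tail)

  for (i in rev(seq_len(spec$n_pool))) {
    ec <- cache$enc[[i]]
    dd2 <- d_skip[[i]] +
      .maxpool_backward(ec$arg, d_pooled, ec$hw[1], ec$hw[2])
    s <- split_cube(dd2, dim(ec$d1)[3])
    dd1 <- s$head + conv_bw(sprintf("enc%db", i), ec$b, ec$d1, s$tail)
    s <- split_cube(dd1, dim(ec$d)[3])
    d_pooled <- s$head + conv_bw(sprintf("enc%da", i), ec$a, ec$d, s$tail)
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct a high-resolution map
#'
#' Runs the network on one case. Both inputs must be `input_size` square
#' and are expected max-normalized to \[0, 1\]; the output is on the same
#' normalized scale. Dropout is disabled; inference is deterministic.
#'
#' @param object a [dunet] model.
#' @param at1w T1w matrix.
#' @param lrsi_upscaled nearest-neighbor-upscaled low-resolution map.
#' @param ... unused.
#' @return `input_size x input_size` matrix.
#' @export
predict.dunet <- function(object, at1w, lrsi_upscaled, ...) {
  n <- object$spec$input_size
  stop_if(!all(dim(at1w) == c(n, n)) || !all(dim(lrsi_upscaled) == c(n, n)),
          sprintf("inputs must be %d x %d", n, n))
  x <- array(0, c(n, n, 2))
  x[, , 1] <- at1w; x[, , 2] <- lrsi_upscaled
  dunet_forward(object, x, training = FALSE)$y
}

#' @export
print.dunet <- function(x, ...) {
  s <- x$spec
  cat(sprintf("dunet: %dx%d input, %d growth maps, %d pooling levels\n",
              s$input_size, s$input_size, s$growth_maps, s$n_pool))
  cat(sprintf("  parameters: %s; %s\n",
              format(x$parameter_count, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
summary.dunet <- function(object, ...) {
  ch <- dunet_channels(object$spec)
  nm <- names(object$pars)
  wnames <- nm[endsWith(nm, ".W")]
  tab <- data.frame(
    layer = sub("\\.W$", "", wnames),
    weights = vapply(wnames, function(n) length(object$pars[[n]]), 0L),
    row.names = NULL)
  cat(sprintf("Densely connected U-Net (%s parameters)\n",
              format(object$parameter_count, big.mark = ",")))
  cat(sprintf("  bottleneck %dx%d, final layer sees %d full-resolution maps\n",
              object$spec$input_size / 2^object$spec$n_pool,
              object$spec$input_size / 2^object$spec$n_pool, ch$final_in))
  print(tab)
  invisible(tab)
}
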