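# Training protocol: streamed fresh-data epochs, summed-squared-error /
# m^2 loss, Adam, and the small-then-large batch-size schedule.

#' Training configuration
#'
#' Defaults follow the reference protocol: learning rate 1e-3, 102 epochs
#' of 1000 freshly generated cases each, batch size 1 for the first two
#' epochs and 10 thereafter (the early small batches help the optimizer
#' escape poor basins before the larger batches stabilize the descent).
#'
#' @param learning_rate Adam step size.
#' @param n_epochs number of epochs.
#' @param samples_per_epoch fresh cases generated per epoch.
#' @param batch_schedule list of `list(epochs = c(from, to), size = k)`
#'   entries covering every epoch exactly once.
#' @param lr_size native low-resolution side (16, 24 or 32 on a 128 grid;
#'   scaled equivalents on smaller grids).
#' @param noise_range noise-fraction band for training acquisitions
#'   (default the low band, 2-5%).
#' @param seed integer master seed for data and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, n_epochs = 102L,
                         samples_per_epoch = 1000L,
                         batch_schedule = list(list(epochs = c(1, 2), size = 1L),
                                               list(epochs = c(3, n_epochs), size = 10L)),
                         lr_size = 32L, noise_range = c(0.02, 0.05),
                         seed = 1L) {
  covered <- integer(0)
  for (entry in batch_schedule)
    covered <- c(covered, seq.int(entry$epochs[1], entry$epochs[2]))
  stop_if(!identical(sort(covered), seq_len(n_epochs)),
          "batch schedule must cover every epoch exactly once")
  structure(list(learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
                 samples_per_epoch = as.integer(samples_per_epoch),
                 batch_schedule = batch_schedule, lr_size = as.integer(lr_size),
                 noise_range = noise_range, seed = as.integer(seed)),
            class = "train_config")
}

batch_size_for_epoch <- function(config, epoch) {
  for (entry in config$batch_schedule)
    if (epoch >= entry$epochs[1] && epoch <= entry$epochs[2])
      return(entry$size)
  stop("epoch not covered by batch schedule", call. = FALSE)
}

# One Adam update in place; m, v are same-shaped moment lists.
adam_step <- function(pars, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(pars)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    pars[[nm]] <- pars[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(pars = pars, state = state)
}

# Normalize one generated case into a training pair: inputs and target are
# each divided by their own max (the carried scale is max(lrsi)).
case_to_pair <- function(case, n) {
  x <- array(0, c(n, n, 2))
  x[, , 1] <- case$at1w                     # already max 1
  mx_l <- max(case$lrsi)
  x[, , 2] <- if (mx_l > 0) case$lrsi / mx_l else case$lrsi
  mx_h <- max(case$hrsi)
  y <- if (mx_h > 0) case$hrsi / mx_h else case$hrsi
  list(x = x, y = y)
}

#' Train a densely connected U-Net on streamed synthetic cases
#'
#' Each epoch draws `samples_per_epoch` fresh matched triples from the
#' generator (epoch-indexed sub-seeds, so no case is ever presented twice),
#' optimizes the summed-squared-error / m^2 loss with Adam under the batch
#' schedule, and records the epoch-mean training loss. Fully reproducible
#' from the config seed on a single thread.
#'
#' @param model an untrained (or partially trained) [dunet].
#' @param config a [train_config()]; `lr_size` applies on the model's grid.
#' @param progress if TRUE, print one line per epoch.
#' @return the trained model (class `dunet`), with `history` (data frame of
#'   epoch, mean_loss, seconds) attached.
#' @export
train_dunet <- function(model, config, progress = FALSE) {
  n <- model$spec$input_size
  pars <- model$pars
  state <- list(t = 0,
                m = lapply(pars, function(w) array(0, dim(w) %||% length(w))),
                v = lapply(pars, function(w) array(0, dim(w) %||% length(w))))
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                        seconds = numeric(0))
  work <- model
  for (epoch in seq_len(config$n_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    bs <- batch_size_for_epoch(config, epoch)
    epoch_seed <- derive_seed(config$seed, 900L, epoch)
    losses <- numeric(config$samples_per_epoch)
    i <- 0L
    with_seed(derive_seed(config$seed, 901L, epoch), {   # dropout stream
      while (i < config$samples_per_epoch) {
        nb <- min(bs, config$samples_per_epoch - i)
        acc <- NULL
        for (j in seq_len(nb)) {
          case <- generate_case(derive_seed(epoch_seed, 101L, i + j),
                                n, config$lr_size, config$noise_range)
          pair <- case_to_pair(case, n)
          work$pars <- pars
          fw <- dunet_forward(work, pair$x, training = TRUE)
          resid <- fw$y - pair$y
          loss <- sum(resid^2) / length(resid)
          if (!is.finite(loss))
            stop(sprintf("non-finite loss at epoch %d, sample %d",
                         epoch, i + j), call. = FALSE)
          losses[i + j] <- loss
          dy <- 2 * resid / (length(resid) * nb)
          g <- dunet_backward(work, fw$cache, dy)
          acc <- if (is.null(acc)) g else Map(`+`, acc, g)
        }
        st <- adam_step(pars, acc, state, config$learning_rate)
        pars <- st$pars; state <- st$state
        i <- i + nb
      }
    })
    secs <- proc.time()[["elapsed"]] - t0
    history <- rbind(history, data.frame(epoch = epoch,
                                         mean_loss = mean(losses),
                                         seconds = secs))
    if (progress)
      message(sprintf("epoch %3d  batch %2d  mean loss %.5f  (%.1fs)",
                      epoch, bs, mean(losses), secs))
  }
  model$pars <- pars
  model$trained <- TRUE
  model$history <- history
  model$train_config <- config
  model
}

#' Overfit a single training pair
#'
#' Optimizes the model on one fixed (input, target) pair for `n_steps` Adam
#' steps with dropout disabled — the standard expressiveness sanity check:
#' a sufficiently flexible network must be able to memorize one example.
#'
#' @param model a [dunet].
#' @param x `input_size x input_size x 2` input array.
#' @param y target matrix.
#' @param n_steps Adam steps (default 500).
#' @param learning_rate Adam step size.
#' @return list with the updated `model` and the `loss` trace.
#' @export
overfit_pair <- function(model, x, y, n_steps = 500L, learning_rate = 1e-3) {
  pars <- model$pars
  state <- list(t = 0,
                m = lapply(pars, function(w) array(0, dim(w) %||% length(w))),
                v = lapply(pars, function(w) array(0, dim(w) %||% length(w))))
  trace <- numeric(n_steps)
  work <- model
  for (s in seq_len(n_steps)) {
    work$pars <- pars
    fw <- dunet_forward(work, x, training = FALSE, keep_cache = TRUE)
    resid <- fw$y - y
    trace[s] <- sum(resid^2) / length(resid)
    g <- dunet_backward(work, fw$cache, 2 * resid / length(resid))
    st <- adam_step(pars, g, state, learning_rate)
    pars <- st$pars; state <- st$state
  }
  model$pars <- pars
  list(model = model, loss = trace)
}
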