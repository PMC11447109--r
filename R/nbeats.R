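#' N-BEATS model configuration
#'
#' Describes one N-BEATS forecaster: `stacks` stacks of `blocks` blocks each.
#' Every block is a fully-connected trunk (`depth` layers of `width` rectified
#' linear units) followed by two linear heads: a *backcast* head that
#' reconstructs the block's input, and a *forecast* head that emits the
#' block's contribution to the horizon (generic/identity basis). Blocks chain
#' through residuals: each block receives the previous block's input minus its
#' backcast. Block forecasts sum within a stack to a stack signal; stack
#' signals sum to the model forecast.
#'
#' Covariates enter by concatenating their lookback windows to the target's,
#' so the input length is `lookback * (1 + covariate_count)`; only the target
#' channel is forecast.
#'
#' @param stacks number of stacks (S >= 1).
#' @param blocks blocks per stack (B >= 1).
#' @param lookback input window length L in hours (default 120).
#' @param horizon forecast length H in hours (default 24).
#' @param covariate_count number of covariate channels (0-11).
#' @param width hidden units per trunk layer (default 256; tests use 32-64).
#' @param depth fully-connected trunk layers per block (default 4).
#' @param seed integer seed governing parameter initialization and batch
#'   shuffling for this member.
#' @param epochs,batch_size,lr,patience training-loop controls: maximum
#'   epochs, mini-batch size, Adam learning rate, and early-stopping patience
#'   (epochs without validation-RRMSE improvement).
#' @return An object of class `nbeats_spec`.
#' @export
nbeats_spec <- function(stacks, blocks, lookback = 120L, horizon = 24L,
                        covariate_count = 0L, width = 256L, depth = 4L,
                        seed = 1L, epochs = 100L, batch_size = 64L,
                        lr = 1e-3, patience = 10L) {
  counts <- c(stacks, blocks, lookback, horizon, width, depth, epochs,
              batch_size, patience)
  if (any(counts < 1) || covariate_count < 0 || lr <= 0) {
    stop_domain("all nbeats_spec counts must be positive")
  }
  structure(
    list(stacks = as.integer(stacks), blocks = as.integer(blocks),
         lookback = as.integer(lookback), horizon = as.integer(horizon),
         covariate_count = as.integer(covariate_count),
         width = as.integer(width), depth = as.integer(depth),
         seed = as.integer(seed), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), lr = lr,
         patience = as.integer(patience)),
    class = "nbeats_spec"
  )
}

input_size <- function(spec) spec$lookback * (1L + spec$covariate_count)

#' Initialize an (untrained) N-BEATS member
#'
#' Parameters are drawn pseudo-randomly from `spec$seed` (Glorot-uniform
#' weights, zero biases), so two members built from the same spec are
#' identical, bit for bit.
#'
#' @param spec an [nbeats_spec()].
#' @return An object of class `nbeats_member` with untrained parameters.
#' @export
init_member <- function(spec) {
  stopifnot(inherits(spec, "nbeats_spec"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(spec$seed)
  LC <- input_size(spec)
  n_blocks <- spec$stacks * spec$blocks
  params <- vector("list", n_blocks)
  for (k in seq_len(n_blocks)) {
    blk <- list()
    d_in <- LC
    for (l in seq_len(spec$depth)) {
      blk[[paste0("W", l)]] <- glorot(d_in, spec$width)
      blk[[paste0("b", l)]] <- numeric(spec$width)
      d_in <- spec$width
    }
    blk$Wb <- glorot(spec$width, LC)
    blk$bb <- numeric(LC)
    blk$Wf <- glorot(spec$width, spec$horizon)
    blk$bf <- numeric(spec$horizon)
    params[[k]] <- blk
  }
  structure(
    list(spec = spec, params = params, trained = FALSE, scaler = NULL,
         val_rrmse = NA_real_, training_log = NULL),
    class = "nbeats_member"
  )
}

glorot <- function(d_in, d_out) {
  s <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -s, s), d_in, d_out)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

addb <- function(M, b) M + rep(b, each = nrow(M)) # add bias row-wise

#' Forward pass through one block
#'
#' @param block named list of block parameters (trunk weights `W1..Wd`,
#'   biases `b1..bd`, backcast head `Wb`,`bb`, forecast head `Wf`,`bf`).
#' @param X input matrix (rows are flattened lookback windows) or a single
#'   vector.
#' @param cache keep trunk activations for backpropagation?
#' @return list with `backcast` (n x L*C), `forecast` (n x H) and, when
#'   requested, `cache`.
#' @export
block_forward <- function(block, X, cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(block$W1)) {
    stop_contract(sprintf("input length %d != expected %d", ncol(X), nrow(block$W1)))
  }
  depth <- sum(grepl("^W[0-9]+$", names(block)))
  acts <- vector("list", depth + 1L)
  acts[[1L]] <- X
  h <- X
  for (l in seq_len(depth)) {
    h <- addb(h %*% block[[paste0("W", l)]], block[[paste0("b", l)]])
    h[h < 0] <- 0
    acts[[l + 1L]] <- h
  }
  out <- list(backcast = addb(h %*% block$Wb, block$bb),
              forecast = addb(h %*% block$Wf, block$bf))
  if (cache) out$cache <- acts
  out
}

#' Forward pass through a full N-BEATS member
#'
#' Implements double residual stacking: the first block sees the input; each
#' subsequent block sees the running residual (previous input minus previous
#' backcast). Block forecasts are summed within each stack into a stack
#' signal, and stack signals are summed into the model forecast.
#'
#' @param member an [init_member()] result (trained or not).
#' @param X input matrix (n x L*C) or single flattened window vector.
#' @param cache keep per-block activations (internal, for training)?
#' @return list with `forecast` (n x H), `stack_forecasts` (list of S n x H
#'   matrices), `residual` (input minus the sum of all backcasts), and
#'   optionally `caches`.
#' @export
model_forward <- function(member, X, cache = FALSE) {
  stopifnot(inherits(member, "nbeats_member"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  spec <- member$spec
  n_blocks <- spec$stacks * spec$blocks
  r <- X
  forecast <- matrix(0, nrow(X), spec$horizon)
  stack_forecasts <- rep(list(matrix(0, nrow(X), spec$horizon)), spec$stacks)
  caches <- if (cache) vector("list", n_blocks) else NULL
  for (k in seq_len(n_blocks)) {
    s_i <- ((k - 1L) %/% spec$blocks) + 1L
    bf <- block_forward(member$params[[k]], r, cache = cache)
    if (cache) caches[[k]] <- bf$cache
    stack_forecasts[[s_i]] <- stack_forecasts[[s_i]] + bf$forecast
    forecast <- forecast + bf$forecast
    r <- r - bf$backcast
  }
  out <- list(forecast = forecast, stack_forecasts = stack_forecasts, residual = r)
  if (cache) out$caches <- caches
  out
}

# Loss and analytic gradient of mean((forecast - Y)^2) over all horizon
# cells, backpropagated through the full residual chain: each block's input
# gradient carries both the pass-through residual term and the trunk term
# from its two heads (backcast head weighted by minus the downstream residual
# gradient).
nbeats_loss_grad <- function(member, X, Y) {
  spec <- member$spec
  n_blocks <- spec$stacks * spec$blocks
  fwd <- model_forward(member, X, cache = TRUE)
  err <- fwd$forecast - Y
  loss <- mean(err^2)
  dF <- (2 / length(err)) * err
  Gr <- matrix(0, nrow(X), ncol(X)) # gradient wrt residual after last block
  grads <- vector("list", n_blocks)
  for (k in rev(seq_len(n_blocks))) {
    blk <- member$params[[k]]
    acts <- fwd$caches[[k]]
    depth <- length(acts) - 1L
    h <- acts[[depth + 1L]]
    g <- list()
    g$Wf <- crossprod(h, dF); g$bf <- colSums(dF)
    Gb <- -Gr
    g$Wb <- crossprod(h, Gb); g$bb <- colSums(Gb)
    Gh <- dF %*% t(blk$Wf) + Gb %*% t(blk$Wb)
    for (l in rev(seq_len(depth))) {
      Gh <- Gh * (acts[[l + 1L]] > 0)
      g[[paste0("W", l)]] <- crossprod(acts[[l]], Gh)
      g[[paste0("b", l)]] <- colSums(Gh)
      Gh <- Gh %*% t(blk[[paste0("W", l)]])
    }
    Gr <- Gr + Gh # d input_k = d residual_k (pass-through) + trunk term
    grads[[k]] <- g
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(blk) lapply(blk, function(p) p * 0))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    for (nm in names(params[[k]])) {
      g <- grads[[k]][[nm]]
      state$m[[k]][[nm]] <- beta1 * state$m[[k]][[nm]] + (1 - beta1) * g
      state$v[[k]][[nm]] <- beta2 * state$v[[k]][[nm]] + (1 - beta2) * g^2
      params[[k]][[nm]] <- params[[k]][[nm]] -
        lr * (state$m[[k]][[nm]] / bc1) / (sqrt(state$v[[k]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train an N-BEATS member
#'
#' Minimizes the mean squared error of the horizon forecast (in scaled space)
#' by mini-batch Adam, with early stopping on validation RRMSE computed in
#' original concentration units; the best-validation parameters are restored.
#' Deterministic given the member's seed (single-threaded math).
#'
#' @param member an [init_member()] result.
#' @param train,val `window_batch`es in *scaled* space (see [scale_batch()]
#'   via the pipeline, or scale manually); both non-empty.
#' @param scaler the [fit_scaler()] used to scale the batches; its first
#'   channel must be the target. Used to report validation RRMSE in original
#'   units, and kept on the member for [predict.nbeats_member()].
#' @param verbose print per-epoch progress?
#' @return The trained member, with `val_rrmse` and a per-epoch
#'   `training_log` (`epoch`, `train_mse`, `val_rrmse`).
#' @export
train_member <- function(member, train, val, scaler, verbose = FALSE) {
  stopifnot(inherits(member, "nbeats_member"))
  if (n_windows(train) == 0 || n_windows(val) == 0) {
    stop_insufficient("training and validation batches must be non-empty")
  }
  spec <- member$spec
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(spec$seed + 1L)

  target <- names(scaler$center)[1]
  val_actual_raw <- val$targets * scaler$scale[target] + scaler$center[target]

  params <- member$params
  state <- adam_init(params)
  n <- n_windows(train)
  best <- list(rrmse = Inf, params = params, epoch = 0L)
  log_rows <- vector("list", spec$epochs)
  wait <- 0L
  tmp_member <- member
  for (epoch in seq_len(spec$epochs)) {
    idx <- sample.int(n)
    epoch_loss <- 0
    n_batches <- 0L
    for (b0 in seq(1L, n, by = spec$batch_size)) {
      bi <- idx[b0:min(b0 + spec$batch_size - 1L, n)]
      tmp_member$params <- params
      lg <- nbeats_loss_grad(tmp_member,
                             train$inputs[bi, , drop = FALSE],
                             train$targets[bi, , drop = FALSE])
      if (!is.finite(lg$loss)) {
        stop_numeric(sprintf(
          "non-finite training loss at epoch %d (batch starting %d); try a lower learning rate",
          epoch, b0))
      }
      upd <- adam_step(params, lg$grads, state, spec$lr)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + lg$loss
      n_batches <- n_batches + 1L
    }
    tmp_member$params <- params
    val_fc_scaled <- model_forward(tmp_member, val$inputs)$forecast
    val_fc_raw <- val_fc_scaled * scaler$scale[target] + scaler$center[target]
    v_rrmse <- rrmse(as.vector(val_actual_raw), as.vector(val_fc_raw))
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    train_mse = epoch_loss / n_batches,
                                    val_rrmse = v_rrmse)
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.5f  val RRMSE %.4f",
                      epoch, epoch_loss / n_batches, v_rrmse))
    }
    if (v_rrmse < best$rrmse) {
      best <- list(rrmse = v_rrmse, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  member$params <- best$params
  member$val_rrmse <- best$rrmse
  member$training_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
  member$trained <- TRUE
  member$scaler <- scaler
  member
}

#' Forecast from a trained member, in original units
#'
#' Scales the raw input window with the member's stored scaler, runs the
#' forward pass, and inverse-scales the target channel.
#'
#' @param object a trained `nbeats_member`.
#' @param newdata raw (unscaled) input matrix `n x L*(1+C)` laid out as
#'   target lookback then each covariate lookback, or a single such vector.
#' @param ... unused.
#' @return Forecast matrix `n x H` in original concentration units (a vector
#'   for a single window).
#' @export
predict.nbeats_member <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) stop_state("member is untrained; call train_member() first")
  scaler <- object$scaler
  vec <- is.null(dim(newdata))
  X <- if (vec) matrix(newdata, nrow = 1) else as.matrix(newdata)
  channels <- names(scaler$center)
  L <- object$spec$lookback
  for (c_i in seq_along(channels)) {
    cols <- ((c_i - 1L) * L + 1L):(c_i * L)
    X[, cols] <- (X[, cols] - scaler$center[c_i]) / scaler$scale[c_i]
  }
  fc <- model_forward(object, X)$forecast
  fc <- fc * scaler$scale[1] + scaler$center[1]
  if (vec) drop(fc) else fc
}

#' @export
print.nbeats_member <- function(x, ...) {
  cat(sprintf("<nbeats_member> %dx%d (stacks x blocks), width %d, depth %d, %s\n",
              x$spec$stacks, x$spec$blocks, x$spec$width, x$spec$depth,
              if (x$trained) sprintf("trained (val RRMSE %.4f)", x$val_rrmse)
              else "untrained"))
  invisible(x)
}
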