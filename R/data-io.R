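#' Fill missing cells by Akima interpolation
#'
#' Interior gaps in each channel are filled with Akima piecewise-cubic
#' interpolation on the hourly index (locally determined slopes, resistant to
#' the overshoot that global cubic splines show near sharp sensor
#' transitions). Leading and trailing gaps, where the spline is undefined, are
#' filled with the nearest observed value. Channels with fewer than five
#' observed points fall back to linear interpolation, since Akima's
#' ghost-point construction needs at least that much support. Imputed values
#' on pollutant channels (NO, NO2, NOx, O3, PM2.5) are clamped at zero:
#' concentrations are non-negative.
#'
#' Filling is idempotent: a table without missing cells is returned unchanged.
#'
#' @param tab a [ts_table()], possibly containing `NA` cells.
#' @return A [ts_table()] with no missing values; `gap_mask` still records
#'   which cells were imputed.
#' @export
fill_gaps_akima <- function(tab) {
  stopifnot(inherits(tab, "ts_table"))
  vals <- tab$values
  n <- nrow(vals)
  for (ch in colnames(vals)) {
    y <- vals[, ch]
    obs <- which(!is.na(y))
    if (length(obs) == n) next
    if (length(obs) == 0) {
      stop_insufficient(paste0("channel `", ch, "` is entirely missing"))
    }
    if (length(obs) < 2) {
      stop_insufficient(paste0("channel `", ch, "` has fewer than 2 observed values"))
    }
    miss <- which(is.na(y))
    interior <- miss[miss > obs[1] & miss < obs[length(obs)]]
    if (length(interior)) {
      y[interior] <- if (length(obs) >= 5) {
        pracma::akimaInterp(as.numeric(obs), y[obs], as.numeric(interior))
      } else {
        stats::approx(obs, y[obs], xout = interior)$y
      }
    }
    # Extrapolation beyond the observed hull: nearest observed value.
    y[miss[miss < obs[1]]] <- y[obs[1]]
    y[miss[miss > obs[length(obs)]]] <- y[obs[length(obs)]]
    if (ch %in% pollutant_channels()) y[miss] <- pmax(y[miss], 0)
    vals[, ch] <- y
  }
  ts_table(tab$timestamps, vals, tab$target, tab$covariates, gap_mask = tab$gap_mask)
}

#' Chronological train/validation/test split
#'
#' Splits `n` consecutive indices into contiguous, ordered train, validation
#' and test intervals with no shuffling: train gets `floor(f1 * n)` rows,
#' validation `floor(f2 * n)`, and the test set the remainder.
#'
#' @param n number of rows to split.
#' @param fractions three positive proportions summing to 1; default
#'   `c(0.76, 0.19, 0.05)`.
#' @return An object of class `split_indices`: a list with integer vectors
#'   `train`, `val`, `test` (1-based, contiguous, covering `1:n`).
#' @examples
#' lengths(chronological_split(1000)) # 760, 190, 50
#' @export
chronological_split <- function(n, fractions = c(0.76, 0.19, 0.05)) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != floor(n)) {
    stop_domain("`n` must be a positive integer")
  }
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_domain("`fractions` must be three positive values summing to 1")
  }
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  n_test <- n - n_train - n_val
  structure(
    list(
      train = seq_len(n_train),
      val = seq_len(n_val) + n_train,
      test = seq_len(n_test) + n_train + n_val
    ),
    class = "split_indices"
  )
}

#' Build supervised sliding windows
#'
#' Enumerates lookback/horizon windows left to right over a contiguous
#' segment. Each input row is the target channel's last `L` values followed by
#' each covariate's last `L` values (layout `L * (1 + n_covariates)`); each
#' target row is the target's next `H` values.
#'
#' @param tab a gap-free [ts_table()] (or a numeric matrix whose first column
#'   is the target and remaining columns are covariates).
#' @param segment integer vector of contiguous row indices into `tab`.
#' @param L lookback length in hours (default 120).
#' @param H forecast horizon in hours (default 24).
#' @param stride window step; 1 for training, 24 for non-overlapping daily
#'   evaluation windows.
#' @return A `window_batch`: list with `inputs` (n_windows x L*C matrix),
#'   `targets` (n_windows x H matrix) and `starts` (segment-relative start
#'   indices). A segment shorter than `L + H` signals a
#'   `synbeats_empty_batch` warning and returns a zero-row batch.
#' @export
make_windows <- function(tab, segment, L = 120L, H = 24L, stride = 1L) {
  if (L < 1 || H < 1 || stride < 1) stop_domain("L, H and stride must be >= 1")
  if (inherits(tab, "ts_table")) {
    if (anyNA(tab$values[, model_channels(tab)])) {
      stop_data("table has missing cells; run fill_gaps_akima() first")
    }
    mat <- tab$values[, model_channels(tab), drop = FALSE]
  } else {
    mat <- as.matrix(tab)
  }
  segment <- as.integer(segment)
  if (length(segment) && any(diff(segment) != 1L)) {
    stop_contract("`segment` must be contiguous indices")
  }
  n <- length(segment)
  C <- ncol(mat)
  if (n < L + H) {
    signal_empty_batch(sprintf("segment length %d < L + H = %d: no windows", n, L + H))
    return(window_batch(matrix(0, 0, L * C), matrix(0, 0, H), integer(0), L = L, H = H))
  }
  starts <- seq.int(1L, n - L - H + 1L, by = stride)
  seg_mat <- mat[segment, , drop = FALSE]
  inputs <- matrix(0, length(starts), L * C)
  targets <- matrix(0, length(starts), H)
  off <- outer(starts - 1L, seq_len(L), `+`) # length(starts) x L index matrix
  for (c_i in seq_len(C)) {
    col <- seg_mat[, c_i]
    inputs[, ((c_i - 1L) * L + 1L):(c_i * L)] <- matrix(col[off], length(starts), L)
  }
  toff <- outer(starts - 1L + L, seq_len(H), `+`)
  targets[, ] <- matrix(seg_mat[, 1L][toff], length(starts), H)
  window_batch(inputs, targets, starts, L = L, H = H)
}

window_batch <- function(inputs, targets, starts, L, H) {
  structure(
    list(inputs = inputs, targets = targets, starts = as.integer(starts),
         L = as.integer(L), H = as.integer(H)),
    class = "window_batch"
  )
}

#' @export
print.window_batch <- function(x, ...) {
  cat(sprintf("<window_batch> %d windows, input length %d, horizon %d\n",
              nrow(x$inputs), ncol(x$inputs), x$H))
  invisible(x)
}

#' Number of windows in a batch
#' @param batch a `window_batch`.
#' @return Integer count.
#' @export
n_windows <- function(batch) nrow(batch$inputs)

#' Fit a per-channel standardizing scaler on the training rows
#'
#' Centers by the training-segment mean and scales by the training-segment
#' population standard deviation, per channel. A degenerate (constant)
#' channel gets scale 1 so that scaling stays invertible. Only `train_range`
#' rows enter the statistics: validation and test rows never leak into the
#' scaler.
#'
#' @param tab a gap-free [ts_table()].
#' @param train_range integer vector of training row indices.
#' @return An object of class `channel_scaler` with `center` and `scale`
#'   named vectors.
#' @export
fit_scaler <- function(tab, train_range) {
  stopifnot(inherits(tab, "ts_table"))
  mat <- tab$values[train_range, model_channels(tab), drop = FALSE]
  if (anyNA(mat)) stop_data("training rows contain missing cells")
  center <- colMeans(mat)
  n <- nrow(mat)
  scale <- sqrt(colMeans(sweep(mat, 2, center)^2)) # population SD
  scale[!is.finite(scale) | scale <= 0] <- 1
  structure(list(center = center, scale = scale), class = "channel_scaler")
}

#' Apply / invert a channel scaler
#'
#' @param scaler a [fit_scaler()] result.
#' @param mat numeric matrix with columns named after (a subset of) the
#'   scaler's channels, or an unnamed matrix/vector taken to be the target
#'   channel.
#' @return The transformed matrix.
#' @export
apply_scaler <- function(scaler, mat) {
  scale_transform(scaler, mat, invert = FALSE)
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, mat) {
  scale_transform(scaler, mat, invert = TRUE)
}

scale_transform <- function(scaler, mat, invert) {
  vec <- is.null(dim(mat))
  m <- if (vec) matrix(mat, ncol = 1) else as.matrix(mat)
  chans <- colnames(m)
  if (is.null(chans)) chans <- rep(names(scaler$center)[1], ncol(m))
  unknown <- setdiff(chans, names(scaler$center))
  if (length(unknown)) stop_contract(paste0("unknown channel(s): ", paste(unknown, collapse = ", ")))
  ctr <- scaler$center[chans]
  scl <- scaler$scale[chans]
  out <- if (invert) {
    sweep(sweep(m, 2, scl, `*`), 2, ctr, `+`)
  } else {
    sweep(sweep(m, 2, ctr, `-`), 2, scl, `/`)
  }
  if (vec) drop(out) else out
}

# Scale a full ts_table (model channels only), returning a plain matrix in
# model-channel order; used by the training pipeline.
scale_table <- function(tab, scaler) {
  apply_scaler(scaler, tab$values[, model_channels(tab), drop = FALSE])
}

# Scale/invert a window_batch's inputs (layout: L per channel) and targets
# (target channel). Needs the channel order used when the batch was built.
scale_batch <- function(batch, scaler, channels) {
  L <- batch$L
  inputs <- batch$inputs
  for (c_i in seq_along(channels)) {
    cols <- ((c_i - 1L) * L + 1L):(c_i * L)
    inputs[, cols] <- (inputs[, cols] - scaler$center[channels[c_i]]) /
      scaler$scale[channels[c_i]]
  }
  targets <- (batch$targets - scaler$center[channels[1]]) / scaler$scale[channels[1]]
  window_batch(inputs, targets, batch$starts, batch$L, batch$H)
}
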