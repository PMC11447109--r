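#' Enumerate ensemble member configurations for a block budget
#'
#' One configuration per divisor `d` of the budget, ascending: `d` stacks of
#' `budget / d` blocks each, so every member spends exactly the same total
#' number of blocks. Many-stacks/few-blocks members act as weak learners
#' (broad patterns, overfit-resistant); few-stacks/many-blocks members act as
#' strong learners (fine detail). Budget 30 yields the eight configurations
#' (1,30), (2,15), (3,10), (5,6), (6,5), (10,3), (15,2), (30,1).
#'
#' @param block_budget total blocks per member (default 30).
#' @return List of `c(stacks, blocks)` integer pairs, ascending by stacks.
#' @export
enumerate_configs <- function(block_budget = 30L) {
  if (length(block_budget) != 1 || !is.finite(block_budget) ||
      block_budget < 1 || block_budget != floor(block_budget)) {
    stop_domain("`block_budget` must be a positive integer")
  }
  b <- as.integer(block_budget)
  divs <- which(b %% seq_len(b) == 0L)
  lapply(divs, function(d) c(stacks = d, blocks = b %/% d))
}

#' Predefined ensemble weights from inner-validation RRMSE
#'
#' Each weight is the normalized reciprocal of the member's squared
#' validation RRMSE: accurate members dominate, and the weights sum to one.
#' A single member with RRMSE exactly 0 (perfect on validation) gets weight
#' one; several zeros leave the weights undefined and raise an error.
#'
#' @param val_rrmses vector of per-member validation RRMSEs (finite, >= 0).
#' @return Weight vector summing to 1, same order as `val_rrmses`.
#' @examples
#' predefined_weights(c(0.1, 0.2)) # 0.8, 0.2
#' @export
predefined_weights <- function(val_rrmses) {
  if (!length(val_rrmses) || !all(is.finite(val_rrmses)) || any(val_rrmses < 0)) {
    stop_domain("`val_rrmses` must be finite and >= 0")
  }
  zero <- val_rrmses == 0
  if (any(zero)) {
    if (sum(zero) > 1L) {
      stop_domain("multiple members have zero validation RRMSE; weights undefined")
    }
    w <- as.numeric(zero) # one-hot on the perfect member
    return(w)
  }
  inv <- 1 / val_rrmses^2
  inv / sum(inv)
}

#' Linearly combine member forecasts
#'
#' The ensemble forecast at each horizon step is the weighted sum of the
#' member forecasts at that step.
#'
#' @param member_forecasts list of N forecast matrices (or vectors) of
#'   identical shape.
#' @param weights length-N finite weight vector.
#' @return Combined forecast with the members' shape.
#' @export
combine_forecasts <- function(member_forecasts, weights) {
  if (length(member_forecasts) != length(weights)) {
    stop_contract("need one weight per member forecast")
  }
  if (!all(is.finite(weights))) stop_contract("weights must be finite")
  shp <- dim(member_forecasts[[1]])
  len <- length(member_forecasts[[1]])
  out <- 0
  for (j in seq_along(weights)) {
    fj <- member_forecasts[[j]]
    if (length(fj) != len || !identical(dim(fj), shp)) {
      stop_contract("member forecasts must share one shape")
    }
    out <- out + weights[j] * fj
  }
  out
}

#' Train one member with an inner validation split
#'
#' The member's training segment is divided chronologically 80/20 into inner
#' train and inner validation; training windows stride by 1, validation
#' windows by 24 (non-overlapping daily forecasts). The returned member's
#' `val_rrmse` (original units) is the quantity the predefined ensemble
#' weights are built from.
#'
#' @param spec an [nbeats_spec()].
#' @param scaled_mat scaled model-channel matrix (target first) for the outer
#'   training segment.
#' @param scaler the scaler used, for original-unit RRMSE.
#' @param inner_fraction fraction of the segment used for inner training
#'   (default 0.8).
#' @param verbose print training progress?
#' @return A trained `nbeats_member`.
#' @export
fit_inner_validation <- function(spec, scaled_mat, scaler,
                                 inner_fraction = 0.8, verbose = FALSE) {
  n <- nrow(scaled_mat)
  L <- spec$lookback; H <- spec$horizon
  n_inner <- floor(inner_fraction * n)
  if (n_inner < L + H || (n - n_inner) < H) {
    stop_insufficient(sprintf(
      "training segment too short for an inner %.0f/%.0f split with >= 1 window each",
      100 * inner_fraction, 100 * (1 - inner_fraction)))
  }
  train_b <- make_windows(scaled_mat, seq_len(n_inner), L = L, H = H, stride = 1L)
  val_b <- eval_windows(scaled_mat, (n_inner + 1L):n, L = L, H = H, stride = 24L)
  member <- init_member(spec)
  train_member(member, train_b, val_b, scaler, verbose = verbose)
}

#' Build a syN-BEATS ensemble
#'
#' Trains one N-BEATS member per divisor configuration of the block budget on
#' the chronological training segment (76% by default), using an inner 80/20
#' split of that segment for each member's validation RRMSE, then attaches
#' predefined inverse-squared-RRMSE weights. Member `j`'s seed is
#' `seed + j`, so the whole build is reproducible from one integer.
#'
#' @param tab a gap-free [ts_table()].
#' @param block_budget total blocks per member (default 30).
#' @param seed ensemble seed.
#' @param fractions outer train/val/test fractions (default 0.76/0.19/0.05).
#' @param width,depth,epochs,batch_size,lr,patience member architecture and
#'   training controls, shared across configurations (see [nbeats_spec()]).
#' @param lookback,horizon window geometry (default 120 h -> 24 h).
#' @param verbose print per-member progress?
#' @return An object of class `synbeats_ensemble`: members (ascending stack
#'   count), predefined `weights`, `weight_mode`, the scaler, the outer
#'   `split`, and bookkeeping.
#' @export
build_ensemble <- function(tab, block_budget = 30L, seed = 1L,
                           fractions = c(0.76, 0.19, 0.05),
                           width = 256L, depth = 4L, epochs = 100L,
                           batch_size = 64L, lr = 1e-3, patience = 10L,
                           lookback = 120L, horizon = 24L, verbose = FALSE) {
  stopifnot(inherits(tab, "ts_table"))
  if (anyNA(tab$values[, model_channels(tab)])) {
    stop_data("table has missing cells; run fill_gaps_akima() first")
  }
  n <- nrow(tab$values)
  split <- chronological_split(n, fractions)
  scaler <- fit_scaler(tab, split$train)
  scaled <- scale_table(tab, scaler)
  configs <- enumerate_configs(block_budget)
  members <- vector("list", length(configs))
  for (j in seq_along(configs)) {
    cfg <- configs[[j]]
    spec <- nbeats_spec(
      stacks = cfg["stacks"], blocks = cfg["blocks"],
      lookback = lookback, horizon = horizon,
      covariate_count = length(tab$covariates),
      width = width, depth = depth, seed = seed + j,
      epochs = epochs, batch_size = batch_size, lr = lr, patience = patience
    )
    if (verbose) {
      message(sprintf("training member %d/%d: %d stacks x %d blocks",
                      j, length(configs), cfg["stacks"], cfg["blocks"]))
    }
    members[[j]] <- fit_inner_validation(
      spec, scaled[split$train, , drop = FALSE], scaler, verbose = verbose)
  }
  val_rrmses <- vapply(members, function(m) m$val_rrmse, numeric(1))
  structure(
    list(members = members, weights = predefined_weights(val_rrmses),
         block_budget = as.integer(block_budget), weight_mode = "predefined",
         inner_val_rrmses = val_rrmses, scaler = scaler, split = split,
         seed = as.integer(seed), schema_version = 1L),
    class = "synbeats_ensemble"
  )
}

#' Ensemble forecast in original units
#'
#' @param object a `synbeats_ensemble`.
#' @param newdata raw input window matrix (or vector), same layout as
#'   [predict.nbeats_member()].
#' @param weights optional override of the stored weight vector.
#' @param ... unused.
#' @return Combined forecast matrix/vector in original units.
#' @export
predict.synbeats_ensemble <- function(object, newdata, weights = NULL, ...) {
  w <- if (is.null(weights)) object$weights else weights
  fcs <- lapply(object$members, predict, newdata = newdata)
  combine_forecasts(fcs, w)
}

#' @export
print.synbeats_ensemble <- function(x, ...) {
  cfg <- vapply(x$members, function(m) sprintf("%dx%d", m$spec$stacks, m$spec$blocks), "")
  cat(sprintf("<synbeats_ensemble> budget %d, %d members (%s)\n  weight mode: %s\n  weights: %s\n",
              x$block_budget, length(x$members), paste(cfg, collapse = ", "),
              x$weight_mode, paste(sprintf("%.3f", x$weights), collapse = " ")))
  invisible(x)
}

#' Save / load an ensemble checkpoint
#'
#' The checkpoint is a directory with one RDS file per member plus a YAML
#' manifest (schema version, budget, configurations, weights, weight mode,
#' seeds, inner-validation RRMSEs, scaler).
#'
#' @param ensemble a `synbeats_ensemble`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (save) or the restored ensemble (load).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    schema_version = ensemble$schema_version,
    block_budget = ensemble$block_budget,
    weight_mode = ensemble$weight_mode,
    weights = as.numeric(ensemble$weights),
    inner_val_rrmses = as.numeric(ensemble$inner_val_rrmses),
    seed = ensemble$seed,
    configs = lapply(ensemble$members, function(m) {
      list(stacks = m$spec$stacks, blocks = m$spec$blocks, seed = m$spec$seed)
    }),
    scaler = list(center = as.list(ensemble$scaler$center),
                  scale = as.list(ensemble$scaler$scale)),
    split_sizes = as.integer(lengths(ensemble$split))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (j in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[j]], file.path(dir, sprintf("member_%02d.rds", j)))
  }
  saveRDS(ensemble, file.path(dir, "ensemble.rds"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  path <- file.path(dir, "ensemble.rds")
  if (!file.exists(path)) stop_data(paste0("no ensemble checkpoint in ", dir))
  ens <- readRDS(path)
  if (!inherits(ens, "synbeats_ensemble")) stop_data("corrupt checkpoint")
  ens
}
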