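#' Bayesian-optimization configuration for ensemble weights
#'
#' @param iterations surrogate-guided evaluations after the initial design
#'   (default 60).
#' @param candidate_pool random candidates scored by expected improvement per
#'   iteration (default 2048).
#' @param jitter diagonal jitter for the Gaussian-process Cholesky (default
#'   1e-6; escalated x100 up to twice on failure).
#' @param lengthscale_bounds bounds for the Matern-5/2 length-scale.
#' @param seed integer seed for the design and candidate draws.
#' @return An object of class `bo_config`.
#' @export
bo_config <- function(iterations = 60L, candidate_pool = 2048L, jitter = 1e-6,
                      lengthscale_bounds = c(1e-3, 1e3), seed = 1L) {
  if (iterations < 1 || candidate_pool < 16 || jitter <= 0) {
    stop_domain("need iterations >= 1, candidate_pool >= 16, jitter > 0")
  }
  structure(
    list(iterations = as.integer(iterations),
         candidate_pool = as.integer(candidate_pool),
         jitter = jitter, lengthscale_bounds = lengthscale_bounds,
         seed = as.integer(seed)),
    class = "bo_config"
  )
}

#' Validation mean-squared-error objective for a weight vector
#'
#' Weights are normalized to sum one, the members' validation-window
#' forecasts are combined linearly, and the mean squared error over all
#' pooled horizon points is returned, in squared concentration units. A
#' weight vector with (numerically) zero sum cannot be normalized and is
#' rejected with a `+Inf` sentinel.
#'
#' @param member_forecasts list of N forecast matrices (windows x horizon) in
#'   original units.
#' @param weights length-N vector in `[0, 1]`.
#' @param actual matching matrix of observed values.
#' @return Scalar validation MSE, or `Inf` for a rejected candidate.
#' @export
objective_val_mse <- function(member_forecasts, weights, actual) {
  s <- sum(weights)
  if (s <= 1e-8) return(Inf)
  fc <- combine_forecasts(member_forecasts, weights / s)
  mean((as.matrix(actual) - fc)^2)
}

#' Initial design for the weight search
#'
#' The N one-hot vectors (so no ensemble can start worse than its best single
#' member), the uniform vector, and `max(5, N)` Latin-hypercube points in
#' `[0,1]^N`, deduplicated.
#'
#' @param n_members number of ensemble members N.
#' @param seed integer seed.
#' @return Matrix of design points, one per row.
#' @export
initial_design <- function(n_members, seed = 1L) {
  if (n_members < 1) stop_domain("`n_members` must be >= 1")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  pts <- rbind(
    diag(n_members),
    matrix(1 / n_members, 1, n_members),
    lhs::randomLHS(max(5L, n_members), n_members)
  )
  pts[!duplicated(round(pts, 12)), , drop = FALSE]
}

#' Optimize ensemble weights by Bayesian optimization
#'
#' Evaluates the initial design, then iteratively fits a Gaussian-process
#' surrogate (Matern-5/2) to all observed (weights, validation-MSE) pairs,
#' scores a fresh uniform candidate pool by expected improvement, and
#' evaluates the best candidate. The returned weights are the normalized
#' incumbent — the lowest objective ever evaluated — so the optimized
#' ensemble's validation MSE can never exceed the best single member's
#' (one-hot vectors are in the design). With one member the answer is
#' trivially `1`.
#'
#' @param member_forecasts list of N validation-forecast matrices in original
#'   units (see [member_val_forecasts()]).
#' @param actual matching matrix of observed validation values.
#' @param config a [bo_config()].
#' @return List with `weights` (normalized, length N) and `trace` (data frame
#'   `iteration`, `w_1..w_N`, `objective`, `incumbent_flag`; iteration 0 rows
#'   are the initial design).
#' @export
optimize_weights <- function(member_forecasts, actual, config = bo_config()) {
  stopifnot(inherits(config, "bo_config"))
  N <- length(member_forecasts)
  if (N < 1) stop_domain("need at least one member")
  if (N == 1) {
    obj <- objective_val_mse(member_forecasts, 1, actual)
    trace <- data.frame(iteration = 0L, w_1 = 1, objective = obj,
                        incumbent_flag = TRUE)
    return(list(weights = 1, trace = trace))
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(config$seed)

  design <- rbind(diag(N), matrix(1 / N, 1, N),
                  lhs::randomLHS(max(5L, N), N))
  design <- design[!duplicated(round(design, 12)), , drop = FALSE]
  X <- design
  y <- apply(design, 1, function(w) objective_val_mse(member_forecasts, w, actual))
  iter_id <- rep(0L, nrow(design))

  for (it in seq_len(config$iterations)) {
    ok <- is.finite(y)
    gp <- gp_fit(X[ok, , drop = FALSE], y[ok], jitter = config$jitter,
                 lengthscale_bounds = config$lengthscale_bounds)
    cand <- matrix(stats::runif(config$candidate_pool * N),
                   config$candidate_pool, N)
    post <- gp_predict(gp, cand)
    ei <- expected_improvement(post$mean, post$sd, min(y[ok]))
    w_next <- cand[which.max(ei), ]
    y <- c(y, objective_val_mse(member_forecasts, w_next, actual))
    X <- rbind(X, w_next)
    iter_id <- c(iter_id, it)
  }
  best_i <- which.min(y)
  w_best <- X[best_i, ] / sum(X[best_i, ])
  run_min <- cummin(ifelse(is.finite(y), y, Inf))
  prev_min <- c(Inf, run_min[-length(run_min)])
  trace <- data.frame(iteration = iter_id, X, objective = y,
                      incumbent_flag = y < prev_min)
  names(trace)[2:(N + 1)] <- paste0("w_", seq_len(N))
  rownames(trace) <- NULL
  list(weights = w_best, trace = trace)
}

#' Member forecasts over an evaluation segment
#'
#' Builds stride-24 (by default) evaluation windows whose horizons tile the
#' segment (inputs may draw lookback context from earlier rows, see
#' [eval_windows()]) and returns each member's forecasts in original units
#' plus the matching actuals — the inputs [optimize_weights()] and
#' [evaluate_forecasts()] need.
#'
#' @param ensemble a `synbeats_ensemble`.
#' @param tab the gap-free [ts_table()] the ensemble was built on.
#' @param segment row indices (e.g. `ensemble$split$val`).
#' @param stride window stride; defaults to the horizon (non-overlapping
#'   forecasts, daily for the default 24 h horizon).
#' @return List with `forecasts` (list of N windows x horizon matrices) and
#'   `actual` (windows x horizon matrix).
#' @export
member_val_forecasts <- function(ensemble, tab, segment, stride = NULL) {
  L <- ensemble$members[[1]]$spec$lookback
  H <- ensemble$members[[1]]$spec$horizon
  if (is.null(stride)) stride <- H
  batch <- eval_windows(tab, segment, L = L, H = H, stride = stride)
  if (n_windows(batch) == 0) stop_insufficient("segment yields no evaluation windows")
  list(
    forecasts = lapply(ensemble$members, predict, newdata = batch$inputs),
    actual = batch$targets
  )
}

#' Attach Bayesian-optimized weights to an ensemble
#'
#' Runs [optimize_weights()] against the ensemble's outer validation segment
#' and returns the ensemble with `weights` replaced and
#' `weight_mode = "optimized"`; the trace is attached as `bo_trace`.
#'
#' @param ensemble a `synbeats_ensemble`.
#' @param tab the table it was built on.
#' @param config a [bo_config()].
#' @return The updated ensemble.
#' @export
optimize_ensemble_weights <- function(ensemble, tab, config = bo_config()) {
  mv <- member_val_forecasts(ensemble, tab, ensemble$split$val)
  opt <- optimize_weights(mv$forecasts, mv$actual, config)
  ensemble$weights <- opt$weights
  ensemble$weight_mode <- "optimized"
  ensemble$bo_trace <- opt$trace
  ensemble
}

#' Write a Bayesian-optimization trace to CSV
#'
#' @param trace the `trace` element of an [optimize_weights()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bo_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
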