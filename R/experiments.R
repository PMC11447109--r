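#' Evaluation windows over a segment, with lookback context
#'
#' Builds stride-`stride` forecast windows whose horizons tile a segment from
#' its first row, letting inputs draw their lookback from up to `L` rows
#' *before* the segment (earlier data only, so chronology is preserved and
#' nothing future leaks into an input). Without this, short evaluation
#' segments would waste their first `L` rows on context.
#'
#' @param tab a gap-free [ts_table()] or model-channel matrix (target first).
#' @param segment contiguous row indices to evaluate on.
#' @param L,H,stride lookback, horizon, and window step.
#' @return A `window_batch`; targets lie entirely within `segment`.
#' @export
eval_windows <- function(tab, segment, L = 120L, H = 24L, stride = 24L) {
  mat <- if (inherits(tab, "ts_table")) {
    if (anyNA(tab$values[, model_channels(tab)])) {
      stop_data("table has missing cells; run fill_gaps_akima() first")
    }
    tab$values[, model_channels(tab), drop = FALSE]
  } else {
    as.matrix(tab)
  }
  segment <- as.integer(segment)
  ctx_start <- max(1L, segment[1] - L)
  ext <- ctx_start:segment[length(segment)]
  ctx_len <- segment[1] - ctx_start
  n_ext <- length(ext)
  first <- ctx_len + 1L - L # first window whose horizon starts in the segment
  starts <- seq.int(max(1L, first), by = stride,
                    length.out = max(0L, (n_ext - L - H - max(1L, first) + 1L) %/% stride + 1L))
  if (!length(starts)) {
    signal_empty_batch("segment too short for any evaluation window")
    return(window_batch(matrix(0, 0, L * ncol(mat)), matrix(0, 0, H), integer(0), L, H))
  }
  seg_mat <- mat[ext, , drop = FALSE]
  C <- ncol(mat)
  inputs <- matrix(0, length(starts), L * C)
  off <- outer(starts - 1L, seq_len(L), `+`)
  for (c_i in seq_len(C)) {
    inputs[, ((c_i - 1L) * L + 1L):(c_i * L)] <-
      matrix(seg_mat[, c_i][off], length(starts), L)
  }
  toff <- outer(starts - 1L + L, seq_len(H), `+`)
  targets <- matrix(seg_mat[, 1L][toff], length(starts), H)
  window_batch(inputs, targets, starts, L, H)
}

#' Run the full forecasting comparison on one table
#'
#' Trains a syN-BEATS ensemble, then evaluates three models on the held-out
#' test segment: the single-model baseline (the `budget` stacks x 1 block
#' member), the ensemble with predefined inverse-squared-RRMSE weights, and
#' the ensemble with Bayesian-optimized weights. Reports RMSE, RRMSE and the
#' relative error reduction of each ensemble against the baseline.
#'
#' @param tab a gap-free [ts_table()] with the desired target channel.
#' @param block_budget blocks per member (default 30).
#' @param seed integer seed driving member initialization and the weight
#'   search.
#' @param width,depth,epochs,batch_size,lr,patience member controls, see
#'   [nbeats_spec()].
#' @param lookback,horizon window geometry.
#' @param bo a [bo_config()]; its seed is re-derived from `seed`.
#' @param out_dir optional directory for artifacts (report, trace,
#'   checkpoint, manifest).
#' @param verbose print progress?
#' @return List with `report` (one row per model: rmse, rrmse,
#'   relative_reduction), `ensemble` (optimized weights attached),
#'   `val_mse` (named: per-member one-hot and optimized validation MSEs) and
#'   `predefined_weights`.
#' @export
run_experiments <- function(tab, block_budget = 30L, seed = 1L,
                            width = 256L, depth = 4L, epochs = 100L,
                            batch_size = 64L, lr = 1e-3, patience = 10L,
                            lookback = 120L, horizon = 24L,
                            bo = NULL, out_dir = NULL, verbose = FALSE) {
  if (is.null(bo)) bo <- bo_config(seed = seed + 500L)
  ens <- build_ensemble(tab, block_budget = block_budget, seed = seed,
                        width = width, depth = depth, epochs = epochs,
                        batch_size = batch_size, lr = lr, patience = patience,
                        lookback = lookback, horizon = horizon,
                        verbose = verbose)
  predefined_w <- ens$weights

  val_mv <- member_val_forecasts(ens, tab, ens$split$val)
  onehot_mse <- vapply(seq_along(ens$members), function(j) {
    w <- replace(numeric(length(ens$members)), j, 1)
    objective_val_mse(val_mv$forecasts, w, val_mv$actual)
  }, numeric(1))
  ens <- optimize_ensemble_weights(ens, tab, bo)
  optimized_mse <- objective_val_mse(val_mv$forecasts, ens$weights, val_mv$actual)

  test_mv <- member_val_forecasts(ens, tab, ens$split$test)
  stacks <- vapply(ens$members, function(m) m$spec$stacks, integer(1))
  i_base <- which(stacks == block_budget) # budget stacks of one block each
  fc_base <- test_mv$forecasts[[i_base]]
  fc_pre <- combine_forecasts(test_mv$forecasts, predefined_w)
  fc_opt <- combine_forecasts(test_mv$forecasts, ens$weights)

  rep_base <- evaluate_forecasts(test_mv$actual, fc_base)
  rep_pre <- evaluate_forecasts(test_mv$actual, fc_pre)
  rep_opt <- evaluate_forecasts(test_mv$actual, fc_opt)
  report <- data.frame(
    target = tab$target,
    model = c("baseline_nbeats", "synbeats_predefined", "synbeats_optimized"),
    rmse = c(rep_base$rmse, rep_pre$rmse, rep_opt$rmse),
    rrmse = c(rep_base$rrmse, rep_pre$rrmse, rep_opt$rrmse),
    relative_reduction = c(
      0L,
      relative_reduction(rep_base$rrmse, rep_pre$rrmse),
      relative_reduction(rep_base$rrmse, rep_opt$rrmse)
    )
  )
  out <- list(report = report, ensemble = ens,
              val_mse = c(stats::setNames(onehot_mse,
                                          sprintf("member_%dx%d", stacks, block_budget %/% stacks)),
                          optimized = optimized_mse),
              predefined_weights = predefined_w)
  if (!is.null(out_dir)) write_run_artifacts(out, tab, seed, out_dir)
  out
}

write_run_artifacts <- function(run, tab, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$report, file.path(out_dir, "report.csv"), row.names = FALSE)
  yaml::write_yaml(
    lapply(split(run$report, run$report$model), function(r) as.list(r[1, ])),
    file.path(out_dir, "report.yaml")
  )
  if (!is.null(run$ensemble$bo_trace)) {
    write_bo_trace(run$ensemble$bo_trace, file.path(out_dir, "bo_trace.csv"))
  }
  save_ensemble(run$ensemble, file.path(out_dir, "checkpoint"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("synbeats")),
    r_version = R.version.string,
    seed = seed,
    target = tab$target,
    covariates = tab$covariates,
    n_rows = nrow(tab$values),
    weights_predefined = as.numeric(run$predefined_weights),
    weights_optimized = as.numeric(run$ensemble$weights)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Multi-seed scaled-down skill study
#'
#' Repeats [run_experiments()] on freshly generated synthetic data across
#' several seeds and summarizes how often each ensemble variant beats the
#' single-model baseline on test RRMSE. This is the package's end-to-end
#' check that the ensemble's advantage holds on learnable diurnal data.
#'
#' @param seeds integer vector of study seeds.
#' @param n_hours hours of synthetic data per seed (default 2000).
#' @param regime generator regime (default `"mediterranean"`).
#' @param target target pollutant channel (default `"PM2.5"`).
#' @param covariates covariate channels to feed the models (default
#'   `temp_avg`, `wind_speed`, `rel_humidity`).
#' @param width,epochs,patience,block_budget member controls, scaled down by
#'   default (width 32, 12 epochs).
#' @param bo_iterations Bayesian-optimization iterations (default 40).
#' @param verbose print progress?
#' @return List with `runs` (per-seed reports), `summary` (mean RRMSE per
#'   model plus mean reductions) and `wins` (seeds where each ensemble's test
#'   RRMSE is <= the baseline's).
#' @export
run_skill_study <- function(seeds = 1:5, n_hours = 2000L,
                            regime = "mediterranean", target = "PM2.5",
                            covariates = c("temp_avg", "wind_speed", "rel_humidity"),
                            width = 32L, epochs = 12L, patience = 4L,
                            block_budget = 30L, bo_iterations = 40L,
                            verbose = FALSE) {
  runs <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    s <- as.integer(seeds[i])
    params <- region_params(regime, n_hours = n_hours, seed = s)
    tab <- generate_pollutants(generate_meteorology(params), params)
    tab <- set_target(tab, target, covariates)
    if (verbose) message(sprintf("seed %d: training ensemble...", s))
    runs[[i]] <- run_experiments(
      tab, block_budget = block_budget, seed = s, width = width,
      epochs = epochs, patience = patience,
      bo = bo_config(iterations = bo_iterations, seed = s + 500L),
      verbose = FALSE
    )
  }
  reports <- do.call(rbind, Map(function(r, s) cbind(seed = s, r$report),
                                runs, seeds))
  base <- reports[reports$model == "baseline_nbeats", ]
  pre <- reports[reports$model == "synbeats_predefined", ]
  opt <- reports[reports$model == "synbeats_optimized", ]
  summary <- data.frame(
    model = c("baseline_nbeats", "synbeats_predefined", "synbeats_optimized"),
    mean_rrmse = c(mean(base$rrmse), mean(pre$rrmse), mean(opt$rrmse)),
    mean_rmse = c(mean(base$rmse), mean(pre$rmse), mean(opt$rmse)),
    mean_relative_reduction = c(0, mean(pre$relative_reduction),
                                mean(opt$relative_reduction))
  )
  list(
    runs = runs, reports = reports, summary = summary,
    wins = list(
      predefined = seeds[pre$rrmse <= base$rrmse],
      optimized = seeds[opt$rrmse <= base$rrmse]
    )
  )
}

#' Persistence baseline forecast
#'
#' Repeats each window's last observed target value across the horizon — the
#' naive skill floor any trained forecaster must beat.
#'
#' @param batch a `window_batch` (raw or scaled; the forecast is in the
#'   batch's own units).
#' @return Matrix `n_windows x H`.
#' @export
persistence_forecast <- function(batch) {
  last <- batch$inputs[, batch$L]
  matrix(last, nrow = length(last), ncol = batch$H)
}
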