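small_spec <- function(stacks = 2, blocks = 2, ...) {
  nbeats_spec(stacks, blocks, lookback = 24, horizon = 6,
              covariate_count = 1, width = 16, depth = 3, seed = 11, ...)
}

test_that("initialization is deterministic given spec and seed", {
  spec <- small_spec()
  m1 <- init_member(spec)
  m2 <- init_member(spec)
  expect_identical(m1$params, m2$params)
  x <- sin(seq_len(48) / 5)
  expect_identical(model_forward(m1, x)$forecast, model_forward(m2, x)$forecast)
  # a different seed changes the draw
  m3 <- init_member(nbeats_spec(2, 2, lookback = 24, horizon = 6,
                                covariate_count = 1, width = 16, depth = 3,
                                seed = 12))
  expect_false(identical(m1$params, m3$params))
})

test_that("block and model outputs have the contracted shapes", {
  m <- init_member(small_spec(1, 1))
  x <- rnorm(48)
  bf <- block_forward(m$params[[1]], x)
  expect_equal(dim(bf$backcast), c(1, 48))
  expect_equal(dim(bf$forecast), c(1, 6))
  fw <- model_forward(m, x)
  expect_length(drop(fw$forecast), 6)
  expect_error(block_forward(m$params[[1]], rnorm(47)),
               class = "synbeats_contract_error")

  m30 <- init_member(nbeats_spec(30, 1, lookback = 12, horizon = 4,
                                 width = 8, depth = 2, seed = 3))
  fw30 <- model_forward(m30, rnorm(12))
  expect_length(fw30$stack_forecasts, 30)
})

test_that("zeroed heads produce zero backcast and forecast", {
  m <- init_member(small_spec(1, 1))
  m$params[[1]]$Wb[] <- 0; m$params[[1]]$bb[] <- 0
  m$params[[1]]$Wf[] <- 0; m$params[[1]]$bf[] <- 0
  bf <- block_forward(m$params[[1]], rnorm(48))
  expect_true(all(bf$backcast == 0) && all(bf$forecast == 0))
  fw <- model_forward(m, rnorm(48))
  expect_true(all(fw$forecast == 0))
  expect_equal(fw$residual, model_forward(m, fw$residual + 0 * fw$residual)$residual)
})

test_that("tiny block forward matches hand-computed matrix algebra", {
  # L=2, H=1, width=2, depth=1, no covariates: all arithmetic by hand
  blk <- list(
    W1 = matrix(c(1, 0, -1, 2), 2, 2), b1 = c(0.5, -0.5),
    Wb = matrix(c(1, 1, 0, 2), 2, 2), bb = c(0, 1),
    Wf = matrix(c(3, -1), 2, 1), bf = 2
  )
  x <- c(1, 2) # trunk pre-activation: (1*1+2*0+0.5, 1*-1+2*2+(-0.5)) = (1.5, 2.5)
  h <- c(1.5, 2.5)
  out <- block_forward(blk, x)
  expect_equal(drop(out$backcast), c(h[1] * 1 + h[2] * 1 + 0, h[1] * 0 + h[2] * 2 + 1))
  expect_equal(drop(out$forecast), h[1] * 3 + h[2] * -1 + 2)
  # negative pre-activation is rectified to zero
  out2 <- block_forward(blk, c(-2, 0)) # pre = (-1.5, 1.5) -> h = (0, 1.5)
  expect_equal(drop(out2$forecast), 1.5 * -1 + 2)
})

test_that("forecast equals the sum of stack signals and residuals telescope", {
  set.seed(7)
  for (trial in 1:200) {
    S <- sample(1:4, 1); B <- sample(1:3, 1)
    spec <- nbeats_spec(S, B, lookback = sample(4:10, 1), horizon = sample(2:5, 1),
                        covariate_count = sample(0:2, 1), width = sample(3:8, 1),
                        depth = sample(1:3, 1), seed = trial)
    m <- jitter_member(init_member(spec), seed = trial, sd = 0.3)
    d_in <- spec$lookback * (1 + spec$covariate_count)
    X <- matrix(rnorm(2 * d_in), 2, d_in)
    fw <- model_forward(m, X)
    expect_equal(fw$forecast, Reduce(`+`, fw$stack_forecasts), tolerance = 1e-12)
    # telescoping: final residual = input - sum of backcasts (manual chain)
    r <- X; bsum <- 0
    for (k in seq_len(S * B)) {
      bf <- block_forward(m$params[[k]], r)
      bsum <- bsum + bf$backcast
      r <- r - bf$backcast
    }
    expect_equal(fw$residual, X - bsum, tolerance = 1e-12)
    expect_equal(fw$residual, r, tolerance = 1e-12)
  }
})

test_that("two-block model composes exactly as two manual block calls", {
  m <- jitter_member(init_member(small_spec(2, 1)), seed = 3, sd = 0.2)
  x <- matrix(rnorm(48), 1)
  b1 <- block_forward(m$params[[1]], x)
  b2 <- block_forward(m$params[[2]], x - b1$backcast) # second sees the residual
  fw <- model_forward(m, x)
  expect_equal(fw$forecast, b1$forecast + b2$forecast, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  # single tiny block, width 3
  spec1 <- nbeats_spec(1, 1, lookback = 5, horizon = 2, width = 3, depth = 2,
                       seed = 21)
  m1 <- jitter_member(init_member(spec1), seed = 1, sd = 0.3)
  set.seed(2)
  X <- matrix(rnorm(8 * 5), 8, 5); Y <- matrix(rnorm(8 * 2), 8, 2)
  expect_lt(gradcheck_worst(m1, X, Y), 1e-4)

  # gradient flows through the residual chain (backcast heads included)
  spec2 <- nbeats_spec(2, 2, lookback = 4, horizon = 3, width = 4, depth = 2,
                       seed = 22)
  m2 <- jitter_member(init_member(spec2), seed = 5, sd = 0.3)
  set.seed(6)
  X2 <- matrix(rnorm(6 * 4), 6, 4); Y2 <- matrix(rnorm(6 * 3), 6, 3)
  expect_lt(gradcheck_worst(m2, X2, Y2), 1e-4)
})

test_that("training a constant series is an immediate degenerate fit", {
  tab <- constant_table(500, value = 7)
  sp <- chronological_split(500)
  sc <- fit_scaler(tab, sp$train)
  scaled <- synbeats:::scale_table(tab, sc)
  spec <- nbeats_spec(2, 1, lookback = 24, horizon = 6, width = 8, depth = 2,
                      seed = 4, epochs = 3, patience = 3)
  train_b <- make_windows(scaled, sp$train, 24, 6, 1)
  val_b <- eval_windows(scaled, sp$val, 24, 6, 6)
  m <- train_member(init_member(spec), train_b, val_b, sc)
  expect_lt(m$training_log$train_mse[1], 1e-4)
  fc <- predict(m, rep(7, 24))
  expect_true(all(abs(fc - 7) / 7 < 0.05))
  expect_lt(m$val_rrmse, 0.01)
})

test_that("training on a noiseless sinusoid improves the loss, reproducibly", {
  tab <- sine_table(700)
  sp <- chronological_split(700)
  sc <- fit_scaler(tab, sp$train)
  scaled <- synbeats:::scale_table(tab, sc)
  spec <- nbeats_spec(2, 1, lookback = 48, horizon = 24, covariate_count = 1,
                      width = 16, depth = 2, seed = 8, epochs = 6, patience = 6)
  train_b <- make_windows(scaled, sp$train, 48, 24, 1)
  val_b <- eval_windows(scaled, sp$val, 48, 24, 24)
  m1 <- train_member(init_member(spec), train_b, val_b, sc)
  expect_lt(tail(m1$training_log$train_mse, 1), m1$training_log$train_mse[1])
  m2 <- train_member(init_member(spec), train_b, val_b, sc)
  expect_identical(m1$val_rrmse, m2$val_rrmse)
  expect_identical(m1$params, m2$params)
})

test_that("prediction requires training and is deterministic", {
  m <- init_member(small_spec())
  expect_error(predict(m, rnorm(48)), class = "synbeats_state_error")
})

test_that("a trained 30x1 member beats the persistence baseline on most seeds", {
  wins <- 0L
  for (s in 1:5) {
    tab <- tiny_table(2000, seed = s, covariates = c("temp_avg", "wind_speed"))
    sp <- chronological_split(2000)
    sc <- fit_scaler(tab, sp$train)
    scaled <- synbeats:::scale_table(tab, sc)
    spec <- nbeats_spec(30, 1, covariate_count = 2, width = 32, seed = s,
                        epochs = 8, patience = 4)
    m <- fit_inner_validation(spec, scaled[sp$train, , drop = FALSE], sc)
    test_b <- eval_windows(tab, sp$test) # raw units
    fc <- predict(m, test_b$inputs)
    model_rrmse <- rrmse(as.vector(test_b$targets), as.vector(fc))
    pers_rrmse <- rrmse(as.vector(test_b$targets),
                        as.vector(persistence_forecast(test_b)))
    if (model_rrmse < pers_rrmse) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
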