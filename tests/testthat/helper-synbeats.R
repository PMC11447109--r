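# Shared fixtures and independent oracles for the test suite.

# Small synthetic table with a chosen target and covariate set.
tiny_table <- function(n = 600, seed = 1, regime = "mediterranean",
                       target = "PM2.5",
                       covariates = c("temp_avg", "wind_speed")) {
  p <- region_params(regime, n_hours = n, seed = seed)
  tab <- generate_pollutants(generate_meteorology(p), p)
  set_target(tab, target, covariates)
}

# Deterministic noiseless table: target is a 24 h sinusoid plus trend-free
# offset, one covariate in phase quadrature. Used for degenerate/learnable
# training checks.
sine_table <- function(n = 600, amp = 10, level = 50) {
  t <- seq_len(n)
  vals <- cbind(
    `PM2.5` = level + amp * sin(2 * pi * t / 24),
    temp_avg = 20 + 5 * cos(2 * pi * t / 24)
  )
  start <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  ts_table(seq(start, by = 3600, length.out = n), vals,
           target = "PM2.5", covariates = "temp_avg")
}

constant_table <- function(n = 500, value = 7) {
  start <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  vals <- cbind(`PM2.5` = rep(value, n))
  ts_table(seq(start, by = 3600, length.out = n), vals,
           target = "PM2.5", covariates = character())
}

# From-scratch classic Akima interpolation (independent of pracma):
# segment slopes, quadratic ghost extension, the weighted-slope rule with
# equal-weight fallback, and cubic Hermite evaluation.
akima_oracle <- function(x, y, xi) {
  n <- length(x)
  s <- diff(y) / diff(x)
  s_ext <- c(0, 0, s, 0, 0)
  s_ext[2] <- 2 * s_ext[3] - s_ext[4]
  s_ext[1] <- 2 * s_ext[2] - s_ext[3]
  s_ext[n + 2] <- 2 * s_ext[n + 1] - s_ext[n]
  s_ext[n + 3] <- 2 * s_ext[n + 2] - s_ext[n + 1]
  tt <- numeric(n)
  for (i in seq_len(n)) {
    sm2 <- s_ext[i]; sm1 <- s_ext[i + 1]; sp1 <- s_ext[i + 2]; sp2 <- s_ext[i + 3]
    w1 <- abs(sp2 - sp1); w2 <- abs(sm1 - sm2)
    tt[i] <- if (w1 + w2 > 0) (w1 * sm1 + w2 * sp1) / (w1 + w2) else (sm1 + sp1) / 2
  }
  vapply(xi, function(z) {
    i <- findInterval(z, x, rightmost.closed = TRUE)
    h <- x[i + 1] - x[i]
    dx <- z - x[i]
    sl <- s[i]
    y[i] + tt[i] * dx + (3 * sl - 2 * tt[i] - tt[i + 1]) * dx^2 / h +
      (tt[i] + tt[i + 1] - 2 * sl) * dx^3 / h^2
  }, numeric(1))
}

# Brute-force stride window enumerator (oracle for make_windows counts).
count_windows_oracle <- function(n, L, H, stride) {
  count <- 0L
  s <- 1L
  while (s + L + H - 1L <= n) {
    count <- count + 1L
    s <- s + stride
  }
  count
}

write_tiny_csv <- function(path, datetimes, values, channel = "PM2.5") {
  df <- data.frame(datetime = datetimes, v = values)
  names(df)[2] <- channel
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# Jitter a member's parameters (notably the zero-initialized biases) so no
# rectifier sits exactly at its kink; finite differences are only valid away
# from the kink.
jitter_member <- function(member, seed = 42, sd = 0.05) {
  set.seed(seed)
  member$params <- lapply(member$params, function(blk) {
    lapply(blk, function(p) p + stats::rnorm(length(p), 0, sd))
  })
  member
}

# Largest relative mismatch between analytic and central finite-difference
# gradients over (a sample of) the member's parameters.
gradcheck_worst <- function(member, X, Y, h = 1e-5, max_per_array = 6) {
  lg <- synbeats:::nbeats_loss_grad(member, X, Y)
  loss_at <- function(m) mean((model_forward(m, X)$forecast - Y)^2)
  worst <- 0
  for (k in seq_along(member$params)) {
    for (nm in names(member$params[[k]])) {
      len <- length(member$params[[k]][[nm]])
      for (i in seq_len(min(max_per_array, len))) {
        mp <- member; mp$params[[k]][[nm]][i] <- mp$params[[k]][[nm]][i] + h
        mm <- member; mm$params[[k]][[nm]][i] <- mm$params[[k]][[nm]][i] - h
        num <- (loss_at(mp) - loss_at(mm)) / (2 * h)
        ana <- lg$grads[[k]][[nm]][i]
        worst <- max(worst, abs(ana - num) / max(abs(num), abs(ana), 1e-6))
      }
    }
  }
  worst
}
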