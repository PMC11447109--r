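test_that("hourly CSV reading inserts absent hours as masked gaps", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(f, c("2021-01-01T00:00:00", "2021-01-01T01:00:00",
                      "2021-01-01T03:00:00"), c(1, 2, 4))
  tab <- read_hourly_csv(f, target = "PM2.5")
  expect_equal(nrow(tab$values), 4)
  expect_true(is.na(tab$values[3, "PM2.5"]))
  expect_equal(tab$gap_mask[, "PM2.5"], c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(as.numeric(diff(tab$timestamps), units = "hours"), rep(1, 3))
})

test_that("reader rejects duplicates, missing columns, and too-sparse targets", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(f, c("2021-01-01T00:00:00", "2021-01-01T00:00:00"), c(1, 2))
  expect_error(read_hourly_csv(f, "PM2.5"), class = "synbeats_data_error")

  write_tiny_csv(f, c("2021-01-01T00:00:00", "2021-01-01T01:00:00"), c(1, 2))
  expect_error(read_hourly_csv(f, "O3"), class = "synbeats_schema_error")

  write_tiny_csv(f, c("2021-01-01T00:00:00", "2021-01-01T01:00:00",
                      "2021-01-01T02:00:00"), c(5, NA, NA))
  expect_error(read_hourly_csv(f, "PM2.5"),
               class = "synbeats_insufficient_data_error")
})

test_that("unsorted rows are ordered by time before gridding", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(f, c("2021-01-01T02:00:00", "2021-01-01T00:00:00",
                      "2021-01-01T01:00:00"), c(3, 1, 2))
  tab <- read_hourly_csv(f, "PM2.5")
  expect_equal(unname(tab$values[, "PM2.5"]), c(1, 2, 3))
})

make_gapped <- function(y) {
  start <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  ts_table(seq(start, by = 3600, length.out = length(y)),
           cbind(`PM2.5` = y), target = "PM2.5")
}

test_that("Akima fill: straight lines, edge fill, and clamping", {
  # collinear points: interpolation reproduces the line exactly
  filled <- fill_gaps_akima(make_gapped(c(0, 1, NA, 3)))
  expect_equal(unname(filled$values[, 1]), c(0, 1, 2, 3))
  expect_equal(filled$gap_mask[, 1], c(FALSE, FALSE, TRUE, FALSE))

  # trailing gaps: nearest observed value
  f2 <- fill_gaps_akima(make_gapped(c(5, 4, NA, NA)))
  expect_equal(unname(f2$values[, 1]), c(5, 4, 4, 4))
  # leading gaps likewise
  f3 <- fill_gaps_akima(make_gapped(c(NA, NA, 2, 3)))
  expect_equal(unname(f3$values[, 1]), c(2, 2, 2, 3))

  # a pollutant dip that would interpolate negative is clamped at 0
  y <- c(8, 3, 0.2, NA, 0.1, 3, 8)
  f4 <- fill_gaps_akima(make_gapped(y))
  expect_gte(min(f4$values[, 1]), 0)

  # entirely missing channel
  expect_error(fill_gaps_akima(make_gapped(c(NA, NA, NA))),
               class = "synbeats_insufficient_data_error")
})

test_that("interior Akima fill matches an independent from-scratch oracle", {
  # t^2 sampled at t = 0..5 (hours), t = 3 missing
  y <- (0:5)^2
  y[4] <- NA
  filled <- fill_gaps_akima(make_gapped(y))
  obs_x <- c(1, 2, 3, 5, 6) # 1-based hourly index of observed points
  expect_equal(unname(filled$values[4, 1]), akima_oracle(obs_x, y[obs_x], 4),
               tolerance = 1e-12)

  # a rougher series, several interior gaps
  set.seed(5)
  z <- cumsum(rnorm(40)) + 100 # keep positive so clamping cannot trigger
  miss <- c(7, 8, 19, 30)
  z_gap <- replace(z, miss, NA)
  filled2 <- fill_gaps_akima(make_gapped(z_gap))
  obs <- which(!is.na(z_gap))
  expect_equal(unname(filled2$values[miss, 1]),
               akima_oracle(obs, z_gap[obs], miss), tolerance = 1e-10)
})

test_that("Akima fill is idempotent on complete tables", {
  tab <- tiny_table(400, seed = 2)
  expect_identical(fill_gaps_akima(tab)$values, tab$values)
})

test_that("chronological split uses floor fractions with remainder to test", {
  expect_equal(unname(lengths(chronological_split(1000))), c(760, 190, 50))
  expect_equal(unname(lengths(chronological_split(100))), c(76, 19, 5))
  expect_equal(unname(lengths(chronological_split(103))), c(78, 19, 6))
  sp <- chronological_split(1000)
  expect_equal(c(sp$train, sp$val, sp$test), 1:1000) # contiguous, ordered, covering
  expect_error(chronological_split(0), class = "synbeats_domain_error")
  expect_error(chronological_split(10, c(0.5, 0.5, 0.5)),
               class = "synbeats_domain_error")
})

test_that("split sizes always sum to n", {
  set.seed(1)
  for (n in c(1:5, sample.int(1e5, 60))) {
    expect_equal(sum(lengths(chronological_split(n))), n)
  }
})

test_that("window counts match a brute-force enumeration oracle", {
  tab <- sine_table(400)
  expect_equal(n_windows(make_windows(tab, 1:200, 120, 24, 1)), 57)
  expect_equal(n_windows(make_windows(tab, 1:144, 120, 24, 1)), 1)
  expect_equal(n_windows(make_windows(tab, 1:288, 120, 24, 24)), 7)
  set.seed(2)
  for (i in 1:25) {
    n <- sample(30:320, 1); L <- sample(5:60, 1)
    H <- sample(2:24, 1); s <- sample(1:30, 1)
    b <- suppressWarnings(make_windows(tab, 1:n, L, H, s))
    expect_equal(n_windows(b), count_windows_oracle(n, L, H, s),
                 info = sprintf("n=%d L=%d H=%d stride=%d", n, L, H, s))
  }
})

test_that("window contents are laid out target-first and left to right", {
  tab <- sine_table(200)
  b <- make_windows(tab, 1:170, L = 120, H = 24, stride = 1)
  mat <- tab$values[, c("PM2.5", "temp_avg")]
  expect_equal(b$inputs[1, 1:120], unname(mat[1:120, 1]))
  expect_equal(b$inputs[1, 121:240], unname(mat[1:120, 2]))
  expect_equal(b$targets[1, ], unname(mat[121:144, 1]))
  expect_equal(b$inputs[2, 1:120], unname(mat[2:121, 1]))
  expect_true(all(apply(b$inputs, 1, length) == 240))
})

test_that("short segments signal an explicit empty batch", {
  tab <- sine_table(200)
  expect_warning(b <- make_windows(tab, 1:100, L = 120, H = 24),
                 class = "synbeats_empty_batch")
  expect_equal(n_windows(b), 0)
})

test_that("scaler standardizes on train rows only and round-trips", {
  start <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  vals <- cbind(`PM2.5` = c(1, 2, 3, 100, 200), temp_avg = c(7, 7, 7, 7, 7))
  tab <- ts_table(seq(start, by = 3600, length.out = 5), vals,
                  "PM2.5", "temp_avg")
  sc <- fit_scaler(tab, 1:3)
  expect_equal(unname(sc$center["PM2.5"]), 2)
  expect_equal(unname(sc$scale["PM2.5"]), sqrt(2 / 3)) # population SD of 1,2,3
  expect_equal(unname(sc$scale["temp_avg"]), 1) # constant-channel fallback
  expect_equal(unname(sc$center["temp_avg"]), 7)

  # scaler parameters depend only on train rows
  tab2 <- tab
  tab2$values[4:5, ] <- 1e6
  expect_identical(fit_scaler(tab2, 1:3), sc)

  # round trip
  set.seed(3)
  m <- matrix(rnorm(20, 10, 4), 10, 2,
              dimnames = list(NULL, c("PM2.5", "temp_avg")))
  back <- invert_scaler(sc, apply_scaler(sc, m))
  expect_equal(back, m, tolerance = 1e-10)
})

test_that("written CSVs round-trip exactly through the reader", {
  tab <- tiny_table(300, seed = 9, covariates = c("temp_avg", "precip"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_hourly_csv(tab, f)
  back <- read_hourly_csv(f, target = tab$target, covariates = tab$covariates)
  expect_identical(back$values, tab$values)
  expect_equal(back$timestamps, tab$timestamps)
})
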