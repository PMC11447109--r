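#' @title Regular hourly multichannel time-series table
#'
#' @description A `ts_table` holds a strictly hourly grid of timestamps, a
#' numeric value matrix (one column per channel), the name of the target
#' pollutant channel, the covariate channel names, and a logical `gap_mask`
#' marking cells that were missing in the source data (inserted hours or
#' empty/NaN fields). After [fill_gaps_akima()] no `NA` remains; the mask
#' still records which cells were imputed.
#'
#' @param timestamps `POSIXct` vector, strictly increasing, hourly.
#' @param values numeric matrix, `length(timestamps)` rows, named columns.
#' @param target name of the target channel (must be a column of `values`).
#' @param covariates character vector of covariate channel names (0-11).
#' @param gap_mask logical matrix, same shape as `values`; `TRUE` marks cells
#'   that were originally missing. Defaults to `is.na(values)`.
#' @return An object of class `ts_table`.
#' @export
ts_table <- function(timestamps, values, target, covariates = character(),
                     gap_mask = NULL) {
  values <- as.matrix(values)
  if (!inherits(timestamps, "POSIXct")) {
    stop_schema("`timestamps` must be POSIXct")
  }
  if (nrow(values) != length(timestamps)) {
    stop_schema("`values` must have one row per timestamp")
  }
  chans <- colnames(values)
  if (is.null(chans) || anyDuplicated(chans)) {
    stop_schema("`values` must have unique column names")
  }
  missing_ch <- setdiff(c(target, covariates), chans)
  if (length(missing_ch)) {
    stop_schema(paste0("channel(s) not present: ", paste(missing_ch, collapse = ", ")))
  }
  if (length(timestamps) > 1) {
    dt <- diff(as.numeric(timestamps))
    if (any(dt <= 0)) stop_data("timestamps must be strictly increasing")
    if (any(abs(dt - 3600) > 1e-6)) {
      stop_data("timestamps must lie on an hourly grid; regularize first")
    }
  }
  if (is.null(gap_mask)) gap_mask <- is.na(values)
  storage.mode(gap_mask) <- "logical"
  structure(
    list(
      timestamps = timestamps,
      values = values,
      target = target,
      covariates = as.character(covariates),
      gap_mask = gap_mask
    ),
    class = "ts_table"
  )
}

#' @export
print.ts_table <- function(x, ...) {
  cat(sprintf(
    "<ts_table> %d hourly rows, %s to %s\n  target: %s | covariates: %s\n  missing cells: %d (%.2f%%)\n",
    nrow(x$values),
    format(x$timestamps[1]), format(x$timestamps[length(x$timestamps)]),
    x$target,
    if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)",
    sum(is.na(x$values)), 100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.ts_table <- function(x) dim(x$values)

# Channels used for modelling, in canonical input-layout order.
model_channels <- function(tab) c(tab$target, tab$covariates)

# Pollutant channels are clamped to >= 0 after imputation (concentrations).
pollutant_channels <- function() c("NO", "NO2", "NOx", "O3", "PM2.5")

#' Read an hourly multichannel CSV
#'
#' Expects a UTF-8 CSV with a `datetime` column (ISO 8601, hourly, naive local
#' time) and one numeric column per channel. Rows are sorted by time, duplicate
#' timestamps are rejected (including DST fold duplicates), absent hours are
#' inserted as missing cells, and empty or `NaN` fields are treated as missing.
#'
#' @param path path to the CSV file.
#' @param target target channel name (column in the file).
#' @param covariates covariate channel names (columns in the file).
#' @return A [ts_table()] on a complete hourly grid, with `gap_mask` marking
#'   every originally-missing cell. Gaps are *not* filled; see
#'   [fill_gaps_akima()].
#' @export
read_hourly_csv <- function(path, target, covariates = character()) {
  if (!file.exists(path)) stop_data(paste0("file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         na.strings = c("", "NA", "NaN"),
                         stringsAsFactors = FALSE)
  if (!"datetime" %in% names(raw)) stop_schema("CSV must contain a `datetime` column")
  wanted <- unique(c(target, covariates))
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols)) {
    stop_schema(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ts <- as.POSIXct(raw$datetime, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) stop_schema("unparseable `datetime` values (expect ISO 8601)")
  ord <- order(ts)
  ts <- ts[ord]
  if (anyDuplicated(as.numeric(ts))) stop_data("duplicate timestamps in input")
  keep <- setdiff(names(raw), "datetime")
  vals <- as.matrix(raw[ord, keep, drop = FALSE])
  storage.mode(vals) <- "double"

  # Regularize onto the full hourly grid; inserted hours are missing cells.
  grid <- seq(ts[1], ts[length(ts)], by = 3600)
  idx <- match(as.numeric(ts), as.numeric(grid))
  full <- matrix(NA_real_, nrow = length(grid), ncol = ncol(vals),
                 dimnames = list(NULL, colnames(vals)))
  full[idx, ] <- vals

  tab <- ts_table(grid, full, target = target, covariates = covariates)
  n_obs <- sum(!is.na(full[, target]))
  if (n_obs < 2) stop_insufficient("target channel has fewer than 2 observed values")
  tab
}

#' Write a ts_table back to the package CSV dialect
#'
#' Missing cells are written as empty fields; values keep full double
#' precision so a read/write round trip is exact.
#'
#' @param tab a [ts_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hourly_csv <- function(tab, path) {
  vals <- tab$values
  out <- data.frame(
    datetime = format(tab$timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  for (ch in colnames(vals)) {
    col <- sprintf("%.17g", vals[, ch])
    col[is.na(vals[, ch])] <- ""
    out[[ch]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
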