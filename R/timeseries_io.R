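#' @title Tabular time-series input/output
#'
#' @description Readers and writers for the delimited-text formats used by
#' the analysis: 1-minute flow series, native-resolution pressure series and
#' grab-sample tables. Writers prepend a `# rows=<n>` comment so readers can
#' reject silently truncated files. Timestamps are timezone-naive ISO-8601,
#' parsed as UTC; all series share one clock.
#'
#' @name timeseries_io
NULL

.grab_locations <- c("influent", "7cm", "22cm", "37cm", "effluent",
                     "sub-schmutzdecke")

.write_checked <- function(df, path, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rows=%d", nrow(df)), con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_checked <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  expected <- NA_integer_
  if (grepl("^# rows=", first))
    expected <- as.integer(sub("^# rows=", "", first))
  df <- read.csv(path, sep = sep, comment.char = "#",
                 stringsAsFactors = FALSE)
  if (!is.na(expected) && nrow(df) != expected)
    stop(sprintf("%s: expected %d rows, found %d (truncated file?)",
                 path, expected, nrow(df)))
  df
}

.parse_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable timestamp(s) in input")
  out
}

#' Read and write grab-sample tables
#'
#' Grab samples are delimited text with columns `time` (ISO-8601),
#' `location` (one of influent, 7cm, 22cm, 37cm, effluent,
#' sub-schmutzdecke) and any of `toc_mg_L`, `tcc_cells_mL`, `turbidity_NTU`.
#' Unknown locations and negative concentrations are rejected with the
#' offending row number.
#'
#' @param path File path.
#' @param sep Field separator (comma default, tab accepted).
#' @return `read_grab_samples()`: data.frame with parsed `time` and validated
#'   columns. `write_grab_samples()`: the path, invisibly.
#' @export
read_grab_samples <- function(path, sep = ",") {
  df <- .read_checked(path, sep)
  need <- c("time", "location")
  if (!all(need %in% names(df)))
    stop(sprintf("missing required column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  bad <- which(!df$location %in% .grab_locations)
  if (length(bad))
    stop(sprintf("unknown location '%s' in row %d", df$location[bad[1]], bad[1]))
  for (col in intersect(c("toc_mg_L", "tcc_cells_mL", "turbidity_NTU"), names(df))) {
    neg <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(neg))
      stop(sprintf("negative %s in row %d", col, neg[1]))
  }
  df$time <- .parse_time(df$time)
  df
}

#' @rdname read_grab_samples
#' @param samples data.frame of grab samples to write.
#' @export
write_grab_samples <- function(samples, path, sep = ",") {
  stopifnot(all(c("time", "location") %in% names(samples)))
  out <- samples
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S")
  .write_checked(out, path, sep)
}

#' Read and write 1-minute flow series
#'
#' @param path File path.
#' @param sep Field separator.
#' @return data.frame `time`, `flow_L_min`.
#' @export
read_flow_series <- function(path, sep = ",") {
  df <- .read_checked(path, sep)
  if (!all(c("time", "flow_L_min") %in% names(df)))
    stop("flow series needs columns time, flow_L_min")
  if (any(df$flow_L_min < 0, na.rm = TRUE)) stop("negative flow value")
  df$time <- .parse_time(df$time)
  if (is.unsorted(as.numeric(df$time), strictly = TRUE))
    stop("timestamps must be strictly increasing")
  df
}

#' @rdname read_flow_series
#' @param flow data.frame `time`, `flow_L_min`.
#' @export
write_flow_series <- function(flow, path, sep = ",") {
  out <- flow
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S")
  .write_checked(out, path, sep)
}

#' Convert a pressure head series to a 1-minute flow series
#'
#' The filter is gravity-driven, so flow is derived from the pressure head
#' above the bed through a calibrated linear head-discharge relation clipped
#' at zero, `Q = max(0, a (h - h0))`, applied per native (4-5 s) sample and
#' then averaged into minutes. The linear relation is a documented stand-in:
#' the calibration of the physical installation is site-specific.
#'
#' @param pressure data.frame `time` (native resolution), `head_mbar`.
#' @param a Calibration slope, L/min per mbar; must be > 0.
#' @param h0 Head offset at zero flow, mbar.
#' @param fill Policy for minutes without a native sample: `"zero"`
#'   (stagnant, the default), `"hold"` (carry last value) or `"na"`.
#' @return data.frame `time`, `flow_L_min` on the 1-minute grid.
#' @export
#' @examples
#' p <- data.frame(time = as.POSIXct("2020-01-01", tz = "UTC") + seq(0, 595, 5),
#'                 head_mbar = 12)
#' flow_from_pressure(p, a = 0.1, h0 = 2)  # 1 L/min for 10 minutes
flow_from_pressure <- function(pressure, a, h0 = 0, fill = "zero") {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  if (!all(c("time", "head_mbar") %in% names(pressure)))
    stop("pressure series needs columns time, head_mbar")
  h <- pressure$head_mbar
  if (all(is.na(h))) stop("pressure series is all missing; no flow derivable")
  q <- pmax(0, a * (h - h0))
  resample_to_minutes(data.frame(time = pressure$time, value = q),
                      fill = fill, value_name = "flow_L_min")
}

#' Expand a 1-minute flow series into a native pressure series
#'
#' Inverse of [flow_from_pressure()] for the synthetic closed loop: each
#' minute is expanded into `60/resolution_s` native samples at
#' `h = h0 + Q/a`.
#'
#' @param flow data.frame `time`, `flow_L_min`.
#' @param a,h0 Calibration as in [flow_from_pressure()].
#' @param resolution_s Native sampling interval, s (must divide 60).
#' @return data.frame `time`, `head_mbar`.
#' @export
pressure_from_flow <- function(flow, a, h0 = 0, resolution_s = 5) {
  stopifnot(a > 0, 60 %% resolution_s == 0)
  k <- 60 %/% resolution_s
  n <- nrow(flow)
  t0 <- rep(as.numeric(flow$time), each = k) +
    rep(seq(0, 60 - resolution_s, by = resolution_s), n)
  data.frame(time = as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"),
             head_mbar = h0 + rep(flow$flow_L_min, each = k) / a)
}

#' Resample a native-resolution series onto the 1-minute grid
#'
#' Averages native samples within each minute; minutes without a native
#' sample are filled per policy. The minute grid spans the full range of the
#' input with no gaps.
#'
#' @param series data.frame `time`, `value` (or a second column of any name).
#' @param fill `"zero"`, `"hold"` or `"na"` for empty minutes.
#' @param value_name Name of the value column in the output.
#' @return data.frame `time` (minute starts), `<value_name>`.
#' @export
resample_to_minutes <- function(series, fill = c("zero", "hold", "na"),
                                value_name = "value") {
  fill <- match.arg(fill)
  if (nrow(series) == 0)
    return(setNames(data.frame(as.POSIXct(character(), tz = "UTC"), numeric()),
                    c("time", value_name)))
  tt <- as.numeric(series$time)
  if (is.unsorted(tt)) stop("timestamps must be increasing")
  val <- series[[2]]
  minute <- floor(tt / 60)
  agg <- tapply(val, minute, mean, na.rm = TRUE)
  grid <- seq(min(minute), max(minute))
  out <- agg[as.character(grid)]
  missing <- is.na(out) | !(grid %in% minute)
  if (fill == "zero") out[missing] <- 0
  if (fill == "hold") {
    for (i in seq_along(out))
      if (missing[i] && i > 1) out[i] <- out[i - 1]
    out[is.na(out)] <- 0
  }
  res <- data.frame(time = as.POSIXct(grid * 60, origin = "1970-01-01", tz = "UTC"),
                    v = as.numeric(out))
  names(res)[2] <- value_name
  res
}
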