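#' Write a voltage trace in the portable text container
#'
#' The portable container is a pair of files: `<stem>.csv` holding
#' `time_ms,vm_mV` sample rows (17 significant digits, so the round trip
#' through [read_trace()] is bit-exact) and `<stem>.json` holding the
#' sampling interval, sweep starts, epoch, pulse windows, excluded
#' segments and units.
#'
#' @param trace A [voltage_trace()].
#' @param stem Output path without extension (or ending in `.csv`).
#' @return Invisibly, the two file paths written.
#' @export
write_trace <- function(trace, stem) {
  stopifnot(inherits(trace, "voltage_trace"))
  stem <- sub("\\.(csv|json)$", "", stem)
  csv <- paste0(stem, ".csv")
  jsn <- paste0(stem, ".json")
  n <- length(trace$samples)
  t_ms <- (seq_len(n) - 1) * trace$dt
  con <- file(csv, "w")
  on.exit(close(con), add = TRUE)
  writeLines("time_ms,vm_mV", con)
  writeLines(paste(sprintf("%.17g", t_ms), sprintf("%.17g", trace$samples),
                   sep = ","), con)
  excl <- logical_runs(trace$excluded)
  meta <- list(
    format = "minisfit-portable-trace",
    n_samples = n,
    dt_ms = trace$dt,
    sweep_starts = trace$sweeps,
    epoch = trace$epoch,
    pulse_windows = trace$pulse_windows,
    excluded_segments = excl,
    units = list(time = "ms", vm = "mV"))
  jsonlite::write_json(meta, jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, jsn))
}

## TRUE runs of a logical vector as a 0-based half-open interval matrix
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Read a voltage trace
#'
#' Reads the portable text container written by [write_trace()]: a CSV of
#' samples plus an optional JSON sidecar with sweep/epoch/pulse metadata.
#' Units are taken from the CSV header (`vm_mV` or `vm_V`); volts are
#' rescaled to mV. A header without recognizable unit metadata is an
#' error — units are never guessed.
#'
#' @param path Path to the `.csv` file (or the stem without extension).
#' @param format File dialect; only `"portable"` is supported. Axon
#'   Binary Files are not readable by this package: convert ABF data to
#'   the portable container externally.
#' @return A [voltage_trace()].
#' @export
read_trace <- function(path, format = c("portable", "abf")) {
  format <- match.arg(format)
  if (format == "abf")
    stop("ABF reading is not supported; convert the recording to the ",
         "portable CSV/JSON container (see write_trace) first")
  stem <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(stem, ".csv")
  jsn <- paste0(stem, ".json")
  if (!file.exists(csv)) stop("file not found: ", csv)
  header <- readLines(csv, n = 1L)
  cols <- strsplit(header, ",", fixed = TRUE)[[1L]]
  if (length(cols) < 2L || !grepl("^time_ms$", cols[1L]))
    stop("portable trace format error: first column must be 'time_ms', got '",
         header, "'")
  vm_col <- cols[2L]
  scale <- switch(vm_col, vm_mV = 1, vm_V = 1000,
                  stop("portable trace format error: unrecognized unit in ",
                       "column '", vm_col, "' (expected vm_mV or vm_V)"))
  dat <- utils::read.csv(csv, header = TRUE,
                         colClasses = c("numeric", "numeric"))
  if (anyNA(dat[[1L]]) || anyNA(dat[[2L]]))
    stop("portable trace format error: missing values in '", csv,
         "' (truncated file?)")
  samples <- dat[[2L]] * scale
  t_ms <- dat[[1L]]
  meta <- NULL
  if (file.exists(jsn)) meta <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  if (!is.null(meta)) {
    if (!is.null(meta$units) && !identical(meta$units$vm, "mV") &&
        vm_col == "vm_mV")
      stop("portable trace format error: sidecar unit '", meta$units$vm,
           "' disagrees with CSV column '", vm_col, "'")
    if (!is.null(meta$n_samples) && meta$n_samples != length(samples))
      stop("portable trace format error: sidecar promises ", meta$n_samples,
           " samples but CSV holds ", length(samples), " (truncated file?)")
    dt <- meta$dt_ms
  } else {
    if (length(t_ms) < 2L)
      stop("portable trace format error: cannot infer dt from a ",
           "single-sample file without a JSON sidecar")
    dts <- diff(t_ms)
    dt <- stats::median(dts)
    if (any(abs(dts - dt) > 1e-6 * dt))
      stop("portable trace format error: time column is not uniformly sampled")
  }
  excluded <- rep(FALSE, length(samples))
  pw <- NULL
  sweeps <- 0L
  epoch <- "other"
  if (!is.null(meta)) {
    if (!is.null(meta$sweep_starts)) sweeps <- as.integer(meta$sweep_starts)
    if (!is.null(meta$epoch)) epoch <- meta$epoch
    if (!is.null(meta$pulse_windows) && length(meta$pulse_windows) > 0L)
      pw <- matrix(as.integer(unlist(meta$pulse_windows)), ncol = 2L)
    ex <- meta$excluded_segments
    if (!is.null(ex) && length(ex) > 0L) {
      ex <- matrix(as.integer(unlist(ex)), ncol = 2L)
      for (i in seq_len(nrow(ex)))
        excluded[(ex[i, 1L] + 1L):ex[i, 2L]] <- TRUE
    }
  }
  voltage_trace(samples, dt, sweeps = sweeps, epoch = epoch,
                excluded = excluded, pulse_windows = pw)
}
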