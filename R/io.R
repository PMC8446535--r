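#' Read and write traces, spike trains and band tables
#'
#' Plain-text interchange: traces as two-column `time,value` CSV with the
#' sampling rate recoverable from the time column; spike trains as a
#' single `time` column in seconds (written with 6 decimal places); band
#' amplitude tables as `epoch,freq_hz,p2p_mv` CSV. Image stacks can be
#' read from multi-page TIFF via the optional `tiff` package.
#'
#' @param x Object to write.
#' @param path File path.
#' @param fs Sampling rate, Hz.
#' @param units Unit label for the reconstructed trace.
#' @name kv3noise-io
NULL

#' @rdname kv3noise-io
#' @export
write_trace_csv <- function(x, path, fs = NULL) {
  tr <- trace_values(x, fs)
  t <- (seq_along(tr$values) - 1) / tr$fs
  utils::write.csv(data.frame(time = t, value = tr$values), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname kv3noise-io
#' @export
read_trace_csv <- function(path, units = "mV") {
  d <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(d)))
    invalid_argument("trace CSV needs `time` and `value` columns")
  fs <- 1 / stats::median(diff(d$time))
  voltage_trace(d$value, fs = fs, units = units, t0 = d$time[1])
}

#' @rdname kv3noise-io
#' @export
write_spikes_csv <- function(x, path) {
  utils::write.csv(data.frame(time = sprintf("%.6f", as.numeric(x))), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname kv3noise-io
#' @export
read_spikes_csv <- function(path) {
  d <- utils::read.csv(path)
  spike_train(as.numeric(d[[1]]))
}

#' @rdname kv3noise-io
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_kv3("reading TIFF stacks requires the `tiff` package",
             "kv3noise_missing_dependency")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  simplify2array(pages)
}
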