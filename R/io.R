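#' Write a spike raster to CSV
#'
#' Headered CSV with columns `neuron_id` (0-based), `population`,
#' `spike_time_ms`, preceded by one schema comment line carrying the raster
#' metadata (`n_neurons`, `duration_ms`, `refractory_ms`, `transient_ms`)
#' so the file round-trips losslessly. Fixture rasters and simulator
#' rasters share this dialect.
#'
#' @param raster A [spike_raster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# silentnet raster v1 n_neurons=%d duration_ms=%g refractory_ms=%g transient_ms=%g labels=%s",
    raster$n_neurons, raster$duration_ms, raster$refractory_ms,
    raster$transient_ms,
    paste(as.character(raster$labels), collapse = ",")), con)
  ev <- data.frame(neuron_id = raster$events$neuron_id - 1L,
                   population = as.character(raster$labels[raster$events$neuron_id]),
                   spike_time_ms = raster$events$time_ms)
  utils::write.csv(ev, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# parse "key=value" tokens of the schema comment line
parse_header <- function(line, prefix) {
  if (!startsWith(line, prefix))
    stop("not a silentnet file (missing '", prefix, "' header)")
  toks <- strsplit(sub(prefix, "", line, fixed = TRUE), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, character(1), 1))
}

#' Read a spike raster written by [write_raster()]
#'
#' @param path Path to the CSV.
#' @return A [spike_raster()].
#' @export
read_raster <- function(path) {
  first <- readLines(path, n = 1)
  meta <- parse_header(first, "# silentnet raster v1 ")
  ev <- utils::read.csv(path, comment.char = "#")
  labels <- strsplit(meta$labels, ",", fixed = TRUE)[[1]]
  spike_raster(ev$neuron_id + 1L, ev$spike_time_ms, labels,
               duration_ms = as.numeric(meta$duration_ms),
               refractory_ms = as.numeric(meta$refractory_ms),
               transient_ms = as.numeric(meta$transient_ms))
}

#' Write simulation traces to CSV
#'
#' Headered CSV `time_ms`, `lfp`, `vm_sum` with a schema comment line.
#'
#' @param traces Data.frame with `time_ms` and at least one of `lfp`,
#'   `vm_sum` (e.g. the `traces` element of a `sim_result`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dt <- stats::median(diff(traces$time_ms))
  writeLines(sprintf("# silentnet traces v1 dt_ms=%g", dt), con)
  utils::write.csv(traces, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read traces written by [write_traces()]
#'
#' @param path Path to the CSV.
#' @return Data.frame of the stored columns.
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1)
  parse_header(first, "# silentnet traces v1 ")
  utils::read.csv(path, comment.char = "#")
}
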