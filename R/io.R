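#' Read and write tidy spike and event tables
#'
#' Spike trains are serialised as tab-separated tables with columns
#' `unit_id` and `time_s`; event/trial tables are written as-is with a
#' header. These plain-text formats are the package's exchange format with
#' acquisition pipelines.
#'
#' @param trains Named list of spike-time vectors.
#' @param path File path.
#' @return `read_spikes()` returns a named list of sorted spike-time
#'   vectors; the writers return `path` invisibly.
#' @export
write_spikes <- function(trains, path) {
  df <- data.frame(unit_id = rep(names(trains), lengths(trains)),
                   time_s = unlist(trains, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(split(df$time_s, df$unit_id), sort)
}

#' @rdname write_spikes
#' @param table A data frame (e.g. a trial table).
#' @export
write_events <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
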