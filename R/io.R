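#' Write and read multichannel LFP as flat binary with a sidecar
#'
#' The LFP matrix is stored channel-major (all samples of channel 1, then
#' channel 2, ...) as little-endian float32, with a YAML sidecar recording
#' `n_channels`, `n_samples`, `sampling_rate_hz`, `dtype`, and `order`.
#'
#' @param lfp Numeric matrix, samples x channels.
#' @param fs Sampling rate in Hz.
#' @param path Path of the binary file; the sidecar is `<path>.yaml`.
#' @return `write_lfp_bin`: the path, invisibly. `read_lfp_bin`: a list with
#'   `lfp` (matrix) and `fs`.
#' @export
write_lfp_bin <- function(lfp, fs, path) {
  stopifnot(is.matrix(lfp))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(lfp), con, size = 4, endian = "little")
  meta <- list(n_channels = ncol(lfp), n_samples = nrow(lfp),
               sampling_rate_hz = fs, dtype = "float32",
               order = "channel_major")
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_lfp_bin
#' @export
read_lfp_bin <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = meta$n_channels * meta$n_samples,
               size = 4, endian = "little")
  list(lfp = matrix(v, nrow = meta$n_samples, ncol = meta$n_channels),
       fs = meta$sampling_rate_hz)
}

#' Write and read spike tables
#'
#' Tab-separated text with columns `unit_id`, `time_s`, `amplitude`.
#'
#' @param trains Named list of spike-time vectors.
#' @param amplitudes Optional named list of per-spike amplitudes.
#' @param path File path.
#' @return `write_spike_table`: the path, invisibly; `read_spike_table`:
#'   a list with `trains` and `amplitudes` (named lists).
#' @export
write_spike_table <- function(trains, path, amplitudes = NULL) {
  ids <- names(trains)
  df <- do.call(rbind, lapply(ids, function(id) {
    amp <- if (!is.null(amplitudes)) amplitudes[[id]] else
      rep(NA_real_, length(trains[[id]]))
    if (!length(trains[[id]])) return(NULL)
    data.frame(unit_id = id, time_s = trains[[id]], amplitude = amp,
               stringsAsFactors = FALSE)
  }))
  write_table_c14n(df, path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sp <- split(df, df$unit_id)
  list(trains = lapply(sp, `[[`, "time_s"),
       amplitudes = lapply(sp, `[[`, "amplitude"))
}

#' Write and read interval files
#'
#' Three-column tab-separated text: `start_s`, `end_s`, `label`.
#'
#' @param intervals Data frame with `start_s`, `end_s` (a `label` column is
#'   added when missing).
#' @param path File path.
#' @param label Default label when the data frame has none.
#' @return `write_intervals`: the path, invisibly; `read_intervals`: a data
#'   frame.
#' @export
write_intervals <- function(intervals, path, label = "upstate") {
  df <- data.frame(start_s = intervals$start_s, end_s = intervals$end_s,
                   label = if ("label" %in% names(intervals))
                     intervals$label else label)
  write_table_c14n(df, path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# canonical table writer: fixed significant digits, tab separation, LF line
# endings, so identical inputs give byte-identical files
write_table_c14n <- function(df, path) {
  fmt <- function(col) {
    if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
  }
  out <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(out, 1, paste, collapse = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
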