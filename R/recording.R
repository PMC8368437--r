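#' Multichannel MEG sensor recording
#'
#' A `meg_recording` bundles a channels x samples matrix of magnetic field
#' values (tesla) with its sampling rate and channel identifiers.
#'
#' @param data Numeric matrix, channels x samples, in tesla. All values
#'   must be finite.
#' @param rate_hz Sampling rate in samples/s (> 0).
#' @param channel_ids Optional character vector of channel names; defaults
#'   to `MEG001`, `MEG002`, ...
#' @param t0 Time of the first sample in seconds (default 0).
#' @param units Field units; only `"T"` (tesla) is supported.
#' @return An object of class `meg_recording`.
#' @export
meg_recording <- function(data, rate_hz, channel_ids = NULL, t0 = 0, units = "T") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop_config("recording data must be a finite numeric matrix")
  if (!is_number(rate_hz) || rate_hz <= 0)
    stop_config("rate_hz must be a positive number")
  if (!identical(units, "T"))
    stop_config("unsupported field units '%s': recordings are stored in tesla ('T')", units)
  if (is.null(channel_ids)) channel_ids <- sprintf("MEG%03d", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data))
    stop_config("channel_ids length (%d) does not match channel count (%d)",
                length(channel_ids), nrow(data))
  structure(
    list(data = data, rate_hz = rate_hz, channel_ids = as.character(channel_ids),
         t0 = t0, units = "T"),
    class = "meg_recording"
  )
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %d channels x %d samples @ %g Hz (%.2f s), units T\n",
              nrow(x$data), ncol(x$data), x$rate_hz, ncol(x$data) / x$rate_hz))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

rec_duration <- function(rec) ncol(rec$data) / rec$rate_hz

#' Write / read a recording as a self-describing text container
#'
#' The container is a single file: line 1 holds a JSON header
#' (`rate_hz`, `channel_ids`, `t0`, `units`, `n_channels`, `n_samples`),
#' the remaining lines hold the sample-major TSV payload (one row per
#' sample, one column per channel) printed with 17 significant digits so
#' that `read_recording(write_recording(x))` reproduces `x` bit-exactly.
#'
#' @param rec A [meg_recording()].
#' @param path File path to write to / read from.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `meg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "meg_recording"))
  header <- jsonlite::toJSON(
    list(format = "ictalmeg-recording", version = 1L,
         rate_hz = rec$rate_hz, t0 = rec$t0, units = rec$units,
         n_channels = nrow(rec$data), n_samples = ncol(rec$data),
         channel_ids = rec$channel_ids),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(header), con)
  body <- apply(t(rec$data), 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop_config("empty recording file: %s", path)
  header <- tryCatch(jsonlite::fromJSON(lines[[1L]]),
                     error = function(e) stop_config("malformed recording header in %s", path))
  for (field in c("rate_hz", "units", "channel_ids", "n_channels", "n_samples")) {
    if (is.null(header[[field]]))
      stop_config("recording file %s is missing required header field '%s'", path, field)
  }
  if (!identical(header$units, "T"))
    stop_config("recording file %s declares units '%s'; expected tesla ('T')",
                path, header$units)
  n_ch <- header$n_channels
  body <- lines[-1L]
  if (length(body) != header$n_samples)
    stop_config("recording file %s: expected %d samples, found %d",
                path, header$n_samples, length(body))
  vals <- scan(text = body, what = numeric(), quiet = TRUE)
  data <- t(matrix(vals, nrow = length(body), ncol = n_ch, byrow = TRUE))
  meg_recording(data, rate_hz = as.numeric(header$rate_hz),
                channel_ids = header$channel_ids,
                t0 = as.numeric(header$t0 %||% 0), units = header$units)
}
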