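#' Amplitude-based artifact rejection
#'
#' Splits the recording into consecutive non-overlapping windows and marks
#' every window whose peak absolute value on any channel exceeds
#' `amplitude_limit` (default 6 pT). Rejected windows are excluded from all
#' downstream segment selection; the data themselves are left untouched so
#' the mask can be audited.
#'
#' @param rec A [meg_recording()].
#' @param amplitude_limit Rejection threshold in tesla (default `6e-12`).
#' @param window_s Window length in seconds (> 0, default 1).
#' @return A list of class `artifact_rejection` with elements
#'   `recording` (the input), `sample_mask` (logical, TRUE = rejected),
#'   `windows` (data.frame: `start_s`, `end_s`, `peak_t`, `rejected`) and
#'   `amplitude_limit`.
#' @export
reject_artifacts <- function(rec, amplitude_limit = 6e-12, window_s = 1) {
  stopifnot(inherits(rec, "meg_recording"))
  if (!is_number(window_s) || window_s <= 0)
    stop_config("window_s must be > 0")
  if (!is_number(amplitude_limit) || amplitude_limit < 0)
    stop_config("amplitude_limit must be a nonnegative field value in tesla")
  n <- n_samples(rec)
  wlen <- max(1L, as.integer(round(window_s * rec$rate_hz)))
  starts <- seq.int(1L, n, by = wlen)
  peak <- vapply(starts, function(s) {
    max(abs(rec$data[, s:min(n, s + wlen - 1L), drop = FALSE]))
  }, numeric(1L))
  rejected <- peak > amplitude_limit
  mask <- logical(n)
  for (k in which(rejected)) {
    mask[starts[k]:min(n, starts[k] + wlen - 1L)] <- TRUE
  }
  if (all(mask))
    stop_config(paste0(
      "all %d windows exceed the %.3g T artifact limit; no data remain ",
      "(peak amplitude %.3g T)"), length(starts), amplitude_limit, max(peak))
  structure(
    list(recording = rec,
         sample_mask = mask,
         windows = data.frame(
           start_s = rec$t0 + (starts - 1L) / rec$rate_hz,
           end_s = rec$t0 + pmin(n, starts + wlen - 1L) / rec$rate_hz,
           peak_t = peak, rejected = rejected),
         amplitude_limit = amplitude_limit),
    class = "artifact_rejection")
}

#' @export
print.artifact_rejection <- function(x, ...) {
  cat(sprintf("<artifact_rejection> %d/%d windows rejected (limit %.3g T)\n",
              sum(x$windows$rejected), nrow(x$windows), x$amplitude_limit))
  invisible(x)
}

#' Detect ictal spike-wave segments
#'
#' Detects runs of generalized spike-wave discharges: the recording is
#' band-passed at 1-4 Hz, the global field power (GFP, root-mean-square
#' across channels per sample) is thresholded at `median + k_mad * MAD`,
#' suprathreshold peaks recurring at the discharge rate (3 +/- 1 Hz by
#' default) are chained into runs, and runs lasting at least
#' `min_duration_s` become segments. A segment starts at the onset of its
#' first spike and ends where the 1-4 Hz GFP envelope falls back below
#' threshold after the last spike (the offset of the final slow wave).
#' Segments overlapping rejected-artifact windows are dropped.
#'
#' @param rec A [meg_recording()].
#' @param min_duration_s Minimum segment duration in seconds (default 3).
#' @param swd_rate_hz Nominal spike-wave repetition rate (default 3 Hz);
#'   inter-spike gaps up to `1/(swd_rate_hz - 1)` s stay in one run.
#' @param k_mad Threshold in MAD units above the median GFP (default 5).
#' @param artifacts Optional [reject_artifacts()] result whose mask excludes
#'   samples from thresholding and segments.
#' @return A data.frame of class `ictal_segments` with columns
#'   `start_sample`, `end_sample`, `start_s`, `end_s`, `duration_s`
#'   (possibly zero rows) and attribute `rate_hz`.
#' @export
detect_ictal_segments <- function(rec, min_duration_s = 3, swd_rate_hz = 3,
                                  k_mad = 5, artifacts = NULL) {
  stopifnot(inherits(rec, "meg_recording"))
  if (rec_duration(rec) <= min_duration_s)
    stop_config("recording (%.2f s) is not longer than min_duration_s (%g s)",
                rec_duration(rec), min_duration_s)
  mask <- if (is.null(artifacts)) logical(n_samples(rec)) else artifacts$sample_mask
  low <- bandpass(rec, band_definition("1-4", 1, 4))
  gfp <- sqrt(colMeans(low$data^2))
  ref <- gfp[!mask]
  thr <- median(ref) + k_mad * mad(ref)
  above <- gfp > thr & !mask
  segs <- empty_segments(rec$rate_hz)
  if (!any(above)) return(segs)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  peaks <- mapply(function(s, e) s - 1L + which.max(gfp[s:e]), run_start, run_end)

  max_gap <- rec$rate_hz / max(swd_rate_hz - 1, 0.5)  # samples
  grp <- cumsum(c(1L, as.integer(diff(peaks) > max_gap)))
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    s0 <- run_start[idx[1L]]                  # onset of first spike
    last <- idx[length(idx)]
    e0 <- run_end[last]                       # envelope back below threshold
    dur <- (e0 - s0 + 1L) / rec$rate_hz
    if (dur < min_duration_s) next
    if (any(mask[s0:e0])) next                # never overlap artifact windows
    out[[length(out) + 1L]] <- c(s0, e0)
  }
  if (!length(out)) return(segs)
  m <- do.call(rbind, out)
  segs <- data.frame(
    start_sample = m[, 1L], end_sample = m[, 2L],
    start_s = rec$t0 + (m[, 1L] - 1L) / rec$rate_hz,
    end_s = rec$t0 + m[, 2L] / rec$rate_hz)
  segs$duration_s <- segs$end_s - segs$start_s
  structure(segs, class = c("ictal_segments", "data.frame"), rate_hz = rec$rate_hz)
}

empty_segments <- function(rate_hz) {
  structure(
    data.frame(start_sample = integer(), end_sample = integer(),
               start_s = numeric(), end_s = numeric(), duration_s = numeric()),
    class = c("ictal_segments", "data.frame"), rate_hz = rate_hz)
}

#' Export detected segments as TSV
#'
#' Writes columns `start_s`, `end_s`, `duration_s`.
#' @param segments An `ictal_segments` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_segments <- function(segments, path) {
  write.table(segments[, c("start_s", "end_s", "duration_s")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
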