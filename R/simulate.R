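#' Specification of a synthetic ictal MEG recording
#'
#' Bundles and validates the parameters of the generator: source
#' placements, the spike-wave discharge (SWD) morphology band, seizure and
#' artifact windows, background noise level and the RNG seed. Defaults
#' emulate 3-Hz generalized spike-wave discharges. The full acquisition-scale
#' acquisition rate is 6,000 Hz; the package-wide simulation default is
#' 1,000 Hz, which resolves every analysis band up to 80-250 Hz at
#' desk-scale runtimes (the rate is a free parameter).
#'
#' @param source_locations Matrix (n x 3) or list of 3-vectors, mm, head
#'   frame (origin at the preauricular midpoint).
#' @param seizure_windows Matrix (k x 2) or list of `c(start_s, end_s)`;
#'   windows must be disjoint and inside `[0, duration_s]`.
#' @param duration_s Recording length in seconds.
#' @param rate_hz Sampling rate (default 1000); must exceed twice the upper
#'   edge of `source_band`.
#' @param source_band `c(lo, hi)` Hz; the SWD waveform is band-limited to
#'   this range (default `c(1, 40)`, covering the spike transient and its
#'   3-Hz harmonics).
#' @param swd_rate Discharge repetition rate in Hz (default 3).
#' @param amplitude Source dipole moment scale in A*m (default `1e-7`,
#'   i.e. 100 nAm, a large ictal discharge). Ignored when `snr` is given.
#' @param snr Optional target signal-to-noise ratio: the r.m.s. of the
#'   noise-free sensor signal during seizure windows divided by `noise_sd`.
#' @param noise_sd Per-channel standard deviation of the 1/f background, in
#'   tesla (default `5e-14`, i.e. 50 fT).
#' @param coupling Inter-source coupling in `[0, 1]`: pairwise correlation
#'   of the source time courses during seizures (default 0.9; generalized
#'   discharges are near-synchronous).
#' @param artifact_windows Optional matrix (m x 3): `start_s`, `end_s`,
#'   `amplitude_t` -- each window adds a half-sine transient of that peak
#'   amplitude (tesla) on a subset of channels.
#' @param seed Integer seed; the recording is fully reproducible from it.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(source_locations,
                            seizure_windows,
                            duration_s = 10,
                            rate_hz = 1000,
                            source_band = c(1, 40),
                            swd_rate = 3,
                            amplitude = 1e-7,
                            snr = NULL,
                            noise_sd = 5e-14,
                            coupling = 0.9,
                            artifact_windows = NULL,
                            seed = 1L) {
  if (is.list(source_locations)) source_locations <- do.call(rbind, source_locations)
  source_locations <- matrix(as.numeric(source_locations), ncol = 3L)
  if (is.list(seizure_windows)) seizure_windows <- do.call(rbind, seizure_windows)
  seizure_windows <- matrix(as.numeric(seizure_windows), ncol = 2L)
  if (!is_number(duration_s) || duration_s <= 0) stop_config("duration_s must be > 0")
  if (!is_number(rate_hz) || rate_hz <= 2 * source_band[2L])
    stop_config("rate_hz (%g) must exceed twice the upper source band edge (%g Hz)",
                rate_hz, source_band[2L])
  if (any(seizure_windows[, 2L] <= seizure_windows[, 1L]) ||
      any(seizure_windows < 0) || any(seizure_windows > duration_s))
    stop_config("seizure windows must satisfy 0 <= start < end <= duration_s")
  if (nrow(seizure_windows) > 1L) {
    o <- order(seizure_windows[, 1L])
    sw <- seizure_windows[o, , drop = FALSE]
    if (any(sw[-1L, 1L] < sw[-nrow(sw), 2L]))
      stop_config("seizure windows must be disjoint")
    seizure_windows <- sw
  }
  if (!is.null(artifact_windows)) {
    artifact_windows <- matrix(as.numeric(artifact_windows), ncol = 3L)
    if (any(artifact_windows[, 2L] <= artifact_windows[, 1L]))
      stop_config("artifact windows must have end > start")
  }
  if (!is_number(coupling) || coupling < 0 || coupling > 1)
    stop_config("coupling must lie in [0, 1]")
  if (!is_number(noise_sd) || noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(
    list(source_locations = source_locations, seizure_windows = seizure_windows,
         duration_s = duration_s, rate_hz = rate_hz, source_band = source_band,
         swd_rate = swd_rate, amplitude = amplitude, snr = snr,
         noise_sd = noise_sd, coupling = coupling,
         artifact_windows = artifact_windows, seed = as.integer(seed)),
    class = "simulation_spec")
}

# One spike-wave cycle sampled at `rate`: a 70 ms biphasic spike followed
# by a 250 ms half-sine slow wave (amplitude ratio 2:1).
swd_cycle_kernel <- function(rate) {
  t_spike <- seq(0, 0.07, by = 1 / rate)
  spike <- sin(2 * pi * t_spike / 0.07)
  t_slow <- seq(1 / rate, 0.25, by = 1 / rate)
  slow <- 0.5 * sin(pi * t_slow / 0.25)
  c(spike, slow)
}

# Spike-wave train over n samples with per-cycle amplitude jitter; cycles
# start at multiples of 1/swd_rate plus `phase` seconds. Uses current RNG.
swd_train <- function(n, rate, swd_rate = 3, amp_jitter = 0.15, phase = 0) {
  kernel <- swd_cycle_kernel(rate)
  period <- 1 / swd_rate
  x <- numeric(n)
  starts_s <- seq(phase, n / rate, by = period)
  for (s0 in starts_s) {
    i0 <- as.integer(round(s0 * rate)) + 1L
    if (i0 > n) break
    if (i0 + length(kernel) - 1L < 1L) next
    amp <- 1 + amp_jitter * rnorm(1L)
    idx <- i0:min(n, i0 + length(kernel) - 1L)
    x[idx] <- x[idx] + amp * kernel[seq_along(idx)]
  }
  x
}

#' Simulate an ictal MEG recording with known ground truth
#'
#' During seizure windows each source emits a band-limited spike-wave
#' train (sharp biphasic transient followed by a slow wave, repeating at
#' `spec$swd_rate`); outside the windows only 1/f background noise is
#' present. Sources share a common discharge train in proportion to
#' `spec$coupling`, so the pairwise correlation of source time courses is
#' approximately the coupling coefficient. Optional artifact windows add
#' high-amplitude transients. Everything is reproducible from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param array A [make_sensor_array()] result.
#' @param leadfield_provider Function mapping a source location (3-vector,
#'   mm) to a sensor gain vector (tesla per A*m). Defaults to the
#'   conducting-sphere model via [make_leadfield_provider()].
#' @param keep_signals Keep the source time courses in the ground truth
#'   (default TRUE; set FALSE to save memory in large cohorts).
#' @return A list of class `meg_simulation`: `recording` (a
#'   [meg_recording()]) and `truth` (source locations, gain vectors,
#'   seizure windows in seconds and samples, correlated source pairs with
#'   sign, and optionally the source signals).
#' @export
simulate_recording <- function(spec, array, leadfield_provider = NULL,
                               keep_signals = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(array, "meg_sensor_array"))
  if (is.null(leadfield_provider))
    leadfield_provider <- make_leadfield_provider(array)
  n <- as.integer(round(spec$duration_s * spec$rate_hz))
  n_src <- nrow(spec$source_locations)
  n_ch <- n_sensors(array)
  gains <- vapply(seq_len(n_src),
                  function(i) as.numeric(leadfield_provider(spec$source_locations[i, ])),
                  numeric(n_ch))  # n_ch x n_src

  with_seed(spec$seed, {
    common <- swd_train(n, spec$rate_hz, spec$swd_rate)
    src <- matrix(0, n_src, n)
    cpl <- spec$coupling
    for (i in seq_len(n_src)) {
      if (cpl >= 1) {
        src[i, ] <- common
      } else {
        own <- swd_train(n, spec$rate_hz, spec$swd_rate,
                         phase = runif(1L, 0, 1 / spec$swd_rate))
        src[i, ] <- sqrt(cpl) * common + sqrt(1 - cpl) * own
      }
    }
    # band-limit the morphology, then gate by the seizure windows
    src <- bandpass(src, band_definition("src", spec$source_band[1L], spec$source_band[2L]),
                    notch_50 = FALSE, rate_hz = spec$rate_hz)
    gate <- logical(n)
    for (k in seq_len(nrow(spec$seizure_windows))) {
      w <- window_to_samples(spec$seizure_windows[k, 1L], spec$seizure_windows[k, 2L],
                             spec$rate_hz, n)
      gate[w[1L]:w[2L]] <- TRUE
    }
    src[, !gate] <- 0

    amplitude <- spec$amplitude
    clean <- gains %*% src                      # still unit dipole scale
    if (!is.null(spec$snr) && spec$noise_sd > 0) {
      rms <- sqrt(mean(clean[, gate, drop = FALSE]^2))
      if (rms > 0) amplitude <- spec$snr * spec$noise_sd / rms
    }
    data <- amplitude * clean
    if (spec$noise_sd > 0)
      data <- data + t(pink_noise(n, n_ch, sd = spec$noise_sd))
    if (!is.null(spec$artifact_windows)) {
      n_hit <- max(1L, as.integer(ceiling(n_ch / 10)))
      for (k in seq_len(nrow(spec$artifact_windows))) {
        w <- spec$artifact_windows[k, ]
        idx <- window_to_samples(w[1L], w[2L], spec$rate_hz, n)
        ii <- idx[1L]:idx[2L]
        pulse <- w[3L] * sin(pi * seq_along(ii) / length(ii))
        ch <- sample.int(n_ch, n_hit)
        data[ch, ii] <- data[ch, ii] + rep(pulse, each = n_hit)
      }
    }
  })

  pairs <- if (n_src >= 2L) {
    cb <- t(combn(n_src, 2L))
    data.frame(source_a = cb[, 1L], source_b = cb[, 2L],
               sign = rep("positive", nrow(cb)))
  } else {
    data.frame(source_a = integer(), source_b = integer(), sign = character())
  }
  seg <- cbind(
    floor(spec$seizure_windows[, 1L] * spec$rate_hz) + 1L,
    pmin(n, ceiling(spec$seizure_windows[, 2L] * spec$rate_hz)))
  truth <- list(
    source_locations = spec$source_locations,
    gains = gains,
    amplitude = amplitude,
    seizure_windows_s = spec$seizure_windows,
    segment_boundaries = seg,
    true_correlated_pairs = pairs,
    coupling = spec$coupling)
  if (keep_signals) truth$source_signals <- amplitude * src
  structure(list(recording = meg_recording(data, spec$rate_hz,
                                           array$channel_ids),
                 truth = truth, spec = spec),
            class = "meg_simulation")
}

#' @export
print.meg_simulation <- function(x, ...) {
  cat(sprintf("<meg_simulation> %d source(s), %d seizure window(s), seed %d\n",
              nrow(x$truth$source_locations), nrow(x$spec$seizure_windows),
              x$spec$seed))
  print(x$recording)
  invisible(x)
}

#' Export simulation ground truth as JSON
#'
#' @param sim A [simulate_recording()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  truth <- sim$truth
  truth$source_signals <- NULL
  truth$gains <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
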