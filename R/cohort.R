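#' Two-group placement effect rule
#'
#' Nonresponder ictal sources are placed in a region of interest (default
#' the medial frontal cortex) with probability `p_roi_nonresp`, responders
#' with `p_roi_resp`; otherwise the source voxel is drawn uniformly from
#' the rest of the grid. `strength` interpolates linearly between the null
#' (`strength = 0`: both groups use `p_roi_resp`) and the full effect
#' (`strength = 1`). Defaults mirror the study contrast (7/11 vs 0/13
#' localized to the MFC).
#'
#' @param p_roi_nonresp,p_roi_resp Placement probabilities (defaults 0.7
#'   and 0.05).
#' @param roi Region label (default `"MFC"`).
#' @param strength Effect strength in `[0, 1]` (default 1).
#' @return A list of class `cohort_effect`.
#' @export
cohort_effect <- function(p_roi_nonresp = 0.7, p_roi_resp = 0.05,
                          roi = "MFC", strength = 1) {
  if (strength < 0 || strength > 1) stop_config("strength must lie in [0, 1]")
  p_n <- p_roi_resp + strength * (p_roi_nonresp - p_roi_resp)
  structure(list(p_roi_nonresp = p_n, p_roi_resp = p_roi_resp, roi = roi,
                 strength = strength),
            class = "cohort_effect")
}

# Clinical covariates drawn from cohort-realistic distributions:
# onset age discrete uniform on 4-10 y, 1-9 y to the scan, seizure
# duration ~ N(14.1, 4.7) truncated at 3 s, follow-up 12-74 months.
draw_clinical_record <- function(id, group) {
  onset <- sample(4:10, 1L)
  age <- onset + sample(1:9, 1L)
  dur <- round(max(3, rnorm(1L, 14.1, 4.7)), 1L)
  fup <- round(min(74, max(12, rnorm(1L, 28.7, 22))))
  gender <- sample(c("F", "M"), 1L, prob = c(20, 4) / 24)
  if (group == "responder") {
    initial <- sample(c("LTG", "VPA"), 1L, prob = c(9, 4) / 13)
    added <- "N"; free <- TRUE
  } else {
    kind <- sample(c("mono_LTG", "mono_VPA", "combo"), 1L, prob = c(2, 5, 4) / 11)
    initial <- switch(kind, mono_LTG = "LTG", mono_VPA = "VPA", combo = "LTG")
    added <- if (kind == "combo") "VPA" else "N"
    free <- kind == "combo"
  }
  data.frame(patient = id, gender = gender, age = age, onset_age = onset,
             seizure_duration_s = dur, follow_up_months = fup,
             initial_aed = initial, aeds_added = added,
             seizure_free = free, stringsAsFactors = FALSE)
}

#' Generate a two-group study cohort with known ground truth
#'
#' Simulates a full cohort of ictal recordings: each patient receives one
#' dominant spike-wave source whose location follows the group-dependent
#' placement rule of [cohort_effect()], plus clinical covariates whose
#' seizure-freedom/medication fields are generated so that
#' [classify_response()] recovers the intended group.
#'
#' @param n_responders,n_nonresponders Group sizes (both >= 1; defaults 13
#'   and 11).
#' @param effect A [cohort_effect()] (default mirrors the study contrast).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param array,grid,atlas Geometry; defaults are a 64-channel array, a
#'   15 mm / 90 mm grid and the packaged atlas (desk-scale study
#'   conditions; pass finer objects for full-scale runs).
#' @param duration_s,rate_hz,snr,noise_sd,coupling Simulation parameters
#'   forwarded to [simulation_spec()]; each recording contains one seizure
#'   window of `seizure_s` seconds.
#' @param seizure_s Seizure window length (default 4 s, > 3 s minimum).
#' @param simulate Generate sensor recordings (default TRUE). With FALSE
#'   only placements, ground truth and clinical records are produced
#'   (used for fast calibration studies of the group statistics).
#' @return Object of class `meg_cohort`: list with `patients` (one list
#'   per patient: `record`, `truth`, and `recording` when simulated),
#'   `records` (combined clinical data.frame with derived `group`),
#'   `effect`, `grid`, `array`, `atlas`, `seed`.
#' @export
make_cohort <- function(n_responders = 13L, n_nonresponders = 11L,
                        effect = cohort_effect(), seed = 1L,
                        array = NULL, grid = NULL, atlas = NULL,
                        duration_s = 10, rate_hz = 1000, snr = 5,
                        noise_sd = 5e-14, coupling = 0.9, seizure_s = 4,
                        simulate = TRUE) {
  if (n_responders < 1 || n_nonresponders < 1)
    stop_config("both group sizes must be >= 1")
  stopifnot(inherits(effect, "cohort_effect"))
  atlas <- atlas %||% region_atlas()
  grid <- grid %||% make_source_grid(spacing = 15, radius = 90)
  array <- array %||% make_sensor_array(64L, 120, seed = 1L)
  roi_vox <- region_voxels(grid, atlas, effect$roi)
  other_vox <- setdiff(seq_len(n_voxels(grid)), roi_vox)
  if (!length(roi_vox) || !length(other_vox))
    stop_config("grid does not intersect both the ROI and its complement")
  provider <- make_leadfield_provider(array)
  groups <- c(rep("responder", n_responders), rep("nonresponder", n_nonresponders))
  n_total <- length(groups)

  seeds <- with_seed(as.integer(seed), {
    list(place = sample.int(.Machine$integer.max, n_total),
         clin = sample.int(.Machine$integer.max, n_total),
         sim = sample.int(.Machine$integer.max, n_total))
  })
  win_start <- min(2, (duration_s - seizure_s) / 2)
  patients <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p_roi <- if (groups[i] == "nonresponder") effect$p_roi_nonresp else effect$p_roi_resp
    vox <- with_seed(seeds$place[i], {
      if (runif(1L) < p_roi) sample(roi_vox, 1L) else sample(other_vox, 1L)
    })
    record <- with_seed(seeds$clin[i], draw_clinical_record(i, groups[i]))
    spec <- simulation_spec(
      source_locations = grid$voxels[vox, , drop = FALSE],
      seizure_windows = matrix(c(win_start, win_start + seizure_s), 1L),
      duration_s = duration_s, rate_hz = rate_hz, snr = snr,
      noise_sd = noise_sd, coupling = coupling, seed = seeds$sim[i])
    entry <- list(record = record,
                  truth = list(source_voxel = vox,
                               source_location = grid$voxels[vox, ],
                               region = assign_regions(grid, atlas)[vox],
                               group = groups[i]),
                  spec = spec)
    if (simulate) {
      sim <- simulate_recording(spec, array, provider, keep_signals = FALSE)
      entry$recording <- sim$recording
      entry$truth$segment_boundaries <- sim$truth$segment_boundaries
    }
    patients[[i]] <- entry
  }
  records <- do.call(rbind, lapply(patients, `[[`, "record"))
  records$group <- classify_response(records)
  structure(list(patients = patients, records = records, effect = effect,
                 grid = grid, array = array, atlas = atlas, seed = seed),
            class = "meg_cohort")
}

#' @export
print.meg_cohort <- function(x, ...) {
  tb <- table(x$records$group)
  cat(sprintf("<meg_cohort> %d patients (%d responders, %d nonresponders), ROI %s, effect strength %g\n",
              nrow(x$records), tb[["responder"]], tb[["nonresponder"]],
              x$effect$roi, x$effect$strength))
  invisible(x)
}
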