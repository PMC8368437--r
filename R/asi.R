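#' Accumulated source imaging
#'
#' Sums beamformed source activity over the time points of a segment:
#' `strength(r) = sum_t |Q(r, t)|` in magnitude mode (the default) or
#' `sum_t Q(r, t)` in signed mode. Signed accumulation of a zero-mean
#' oscillatory time course cancels towards zero; magnitude mode is the
#' default and the accumulation mode is recorded in the result.
#'
#' @param src A [beamform()] result, or a voxels x samples matrix of
#'   source time courses.
#' @param mode `"magnitude"` (default) or `"signed"`.
#' @param segment_id Optional identifier stored with the map.
#' @return Object of class `asi_map`: list with `strength` (per voxel;
#'   nonnegative in magnitude mode), `n_timepoints`, `mode`, `segment_id`
#'   and `grid` (when available).
#' @export
accumulate_source_imaging <- function(src, mode = c("magnitude", "signed"),
                                      segment_id = NULL) {
  mode <- match.arg(mode)
  grid <- NULL
  if (inherits(src, "meg_source_activity")) {
    grid <- src$grid
    Q <- src$Q
  } else {
    Q <- as.matrix(src)
  }
  if (ncol(Q) < 1L) stop_config("cannot accumulate an empty segment (n = 0)")
  strength <- if (mode == "magnitude") rowSums(abs(Q)) else rowSums(Q)
  structure(list(strength = strength, n_timepoints = ncol(Q), mode = mode,
                 segment_id = segment_id, grid = grid),
            class = "asi_map")
}

#' @export
print.asi_map <- function(x, ...) {
  cat(sprintf("<asi_map> %d voxels, n = %d, mode = %s, peak strength %.3g\n",
              length(x$strength), x$n_timepoints, x$mode, max(x$strength)))
  invisible(x)
}

#' Predominant source region of an accumulated map
#'
#' Returns the atlas label of the arg-max voxel of the map. Exact ties are
#' broken by atlas priority order, then by the lowest voxel index, so the
#' result is deterministic.
#'
#' @param asi An [accumulate_source_imaging()] result carrying its grid.
#' @param atlas A [region_atlas()].
#' @param grid Optional grid if `asi` does not carry one.
#' @return List with `label`, `voxel` (index), `position` (mm) and
#'   `strength` at the peak.
#' @export
predominant_region <- function(asi, atlas, grid = NULL) {
  stopifnot(inherits(asi, "asi_map"))
  grid <- grid %||% asi$grid
  if (is.null(grid)) stop_config("no source grid associated with this map")
  s <- asi$strength
  if (all(s == 0)) stop_config("all-zero source map: no predominant source")
  smax <- max(s)
  cand <- which(s == smax)
  labels <- assign_regions(grid, atlas)
  if (length(cand) > 1L) {
    pr <- label_priority(atlas)[labels[cand]]
    cand <- cand[order(pr, cand)]
  }
  best <- cand[1L]
  list(label = labels[best], voxel = best,
       position = grid$voxels[best, ], strength = smax)
}

#' Write an accumulated source map as TSV
#'
#' Columns: `voxel`, `x`, `y`, `z`, `strength`, `region`.
#' @param asi An [accumulate_source_imaging()] result (with grid).
#' @param atlas A [region_atlas()] used for the region column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_asi_map <- function(asi, atlas, path) {
  grid <- asi$grid
  if (is.null(grid)) stop_config("no source grid associated with this map")
  df <- data.frame(voxel = seq_along(asi$strength),
                   x = grid$voxels[, 1L], y = grid$voxels[, 2L],
                   z = grid$voxels[, 3L],
                   strength = asi$strength,
                   region = assign_regions(grid, atlas))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
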