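#' Region atlas of axis-aligned boxes in the head frame
#'
#' The atlas partitions the source grid into the 13 labels used for
#' predominant-location counting: FC (frontal cortex), MFC (medial frontal
#' cortex, nested within the frontal territory), LFL (lateral frontal
#' lobe), TC (temporal cortex), TPJ (temporoparietal junction), POT
#' (parieto-occipito-temporal), Pc (precuneus), PCC (posterior cingulate
#' cortex), PL (parietal lobe), MOC (medial occipital cortex), TH
#' (thalamus), CE (cerebellum) and DBA (deep brain areas, the catch-all).
#' Regions are ordered boxes; a voxel takes the label of the
#' highest-priority box containing it (priority 1 is highest), so every
#' voxel maps to exactly one label. The default geometry ships as a
#' versioned JSON asset with synthetic, anatomy-inspired extents -- it is a
#' modelling device, not a subject atlas.
#'
#' @param path Path to an atlas JSON file; defaults to the packaged asset.
#' @return Object of class `meg_region_atlas`: a data.frame with columns
#'   `label`, `priority`, `xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax`
#'   (one row per box; labels may repeat for bilateral boxes), plus
#'   attributes `version` and `labels` (the 13 canonical labels in
#'   priority order).
#' @export
region_atlas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "region_atlas.json", package = "ictalmeg",
                        mustWork = TRUE)
  spec <- jsonlite::fromJSON(path)
  boxes <- spec$regions
  need <- c("label", "priority", "xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  if (!all(need %in% names(boxes)))
    stop_config("atlas file %s lacks required box fields", path)
  boxes <- boxes[order(boxes$priority), need]
  rownames(boxes) <- NULL
  structure(boxes, class = c("meg_region_atlas", "data.frame"),
            version = spec$version %||% "unversioned",
            labels = unique(boxes$label))
}

#' @export
print.meg_region_atlas <- function(x, ...) {
  cat(sprintf("<meg_region_atlas> v%s: %d boxes, %d labels (%s)\n",
              attr(x, "version"), nrow(x), length(attr(x, "labels")),
              paste(attr(x, "labels"), collapse = ", ")))
  invisible(x)
}

#' Canonical atlas labels
#' @param atlas A [region_atlas()].
#' @return Character vector of labels in priority order.
#' @export
atlas_labels <- function(atlas) attr(atlas, "labels")

#' Assign every grid voxel to an atlas region
#'
#' @param grid A [make_source_grid()] result.
#' @param atlas A [region_atlas()].
#' @return Character vector (length = number of voxels) of region labels.
#' @export
assign_regions <- function(grid, atlas) {
  v <- grid$voxels
  lab <- rep(NA_character_, nrow(v))
  for (k in seq_len(nrow(atlas))) {         # atlas rows already priority-sorted
    b <- atlas[k, ]
    hit <- is.na(lab) &
      v[, 1L] >= b$xmin & v[, 1L] <= b$xmax &
      v[, 2L] >= b$ymin & v[, 2L] <= b$ymax &
      v[, 3L] >= b$zmin & v[, 3L] <= b$zmax
    lab[hit] <- b$label
  }
  if (anyNA(lab))
    stop_config("atlas does not cover %d voxel(s); the catch-all box is missing",
                sum(is.na(lab)))
  lab
}

#' Voxel indices belonging to one region
#' @inheritParams assign_regions
#' @param label Region label.
#' @return Integer vector of voxel indices.
#' @export
region_voxels <- function(grid, atlas, label) {
  if (!label %in% atlas_labels(atlas))
    stop_config("unknown atlas label '%s'", label)
  which(assign_regions(grid, atlas) == label)
}

# Priority rank of each label (1 = highest); used for tie-breaking.
label_priority <- function(atlas) {
  labs <- atlas_labels(atlas)
  stats::setNames(seq_along(labs), labs)
}
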