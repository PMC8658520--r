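#' Voxel volume container
#'
#' A `voxel_volume` holds a 3D grid of CT numbers together with the voxel
#' spacing, the position of the corner of voxel (0,0,0), and a parallel
#' label grid marking each voxel as background, bone, tooth or implant.
#' Axes follow the package convention: x = mesiodistal, y = buccolingual
#' (+y = lingual), z = inferosuperior (+z = superior). Voxel indices are
#' 0-based in this convention; the centre of voxel (i,j,k) sits at
#' `origin + (c(i,j,k) + 0.5) * spacing` (mm).
#'
#' @param ct_values numeric 3D array of CT numbers (scanner units).
#' @param spacing single positive voxel edge length in mm.
#' @param origin numeric length-3, mm position of the corner of voxel (0,0,0).
#' @param labels integer 3D array with the same dimensions as `ct_values`,
#'   coded as in [label_codes()]. Defaults to all background.
#' @param tooth_ids optional integer 3D array assigning a positive id to the
#'   voxels of each individual tooth (0 elsewhere). Kept through segmentation
#'   so individual teeth can be addressed for virtual extraction.
#'
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(ct_values, spacing, origin = c(0, 0, 0),
                         labels = NULL, tooth_ids = NULL) {
  if (!is.array(ct_values) || length(dim(ct_values)) != 3L) {
    stop("`ct_values` must be a 3D array", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("`spacing` must be a single positive number (mm)", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- array(label_codes()[["background"]], dim = dim(ct_values))
  }
  if (!identical(dim(labels), dim(ct_values))) {
    stop("`labels` and `ct_values` must have identical dimensions",
         call. = FALSE)
  }
  if (!is.null(tooth_ids) && !identical(dim(tooth_ids), dim(ct_values))) {
    stop("`tooth_ids` must match the volume dimensions", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  vol <- list(
    ct_values = ct_values,
    spacing = as.numeric(spacing),
    origin = as.numeric(origin),
    labels = labels,
    tooth_ids = tooth_ids,
    placement = NULL
  )
  class(vol) <- "voxel_volume"
  vol
}

#' Label codes used in voxel volumes
#'
#' @return Named integer vector mapping region names to label codes.
#' @export
label_codes <- function() {
  c(background = 0L, bone = 1L, tooth = 2L, implant = 3L)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$ct_values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %.4g mm\n",
              d[1], d[2], d[3], x$spacing))
  counts <- label_counts(x)
  cat("  labels:", paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "), "\n")
  cat(sprintf("  CT range: [%.1f, %.1f]\n",
              min(x$ct_values), max(x$ct_values)))
  invisible(x)
}

#' Count voxels per label class
#'
#' @param volume a [voxel_volume()].
#' @return Named integer vector of voxel counts for background, bone, tooth
#'   and implant (always all four classes, zeros included).
#' @export
label_counts <- function(volume) {
  codes <- label_codes()
  counts <- tabulate(volume$labels + 1L, nbins = length(codes))
  names(counts) <- names(codes)
  counts
}

#' Voxel centre coordinates (mm) for a logical or index selection
#'
#' @param volume a [voxel_volume()].
#' @param which integer vector of linear voxel indices (1-based, R order).
#' @return Matrix with one row per voxel and columns x, y, z in mm.
#' @keywords internal
voxel_centers <- function(volume, which) {
  d <- dim(volume$ct_values)
  idx <- arrayInd(which, d) - 1L  # 0-based voxel indices
  sweep(idx * volume$spacing + 0.5 * volume$spacing, 2, volume$origin, "+")
}

#' Threshold segmentation of a CT volume
#'
#' Reproduces region-of-interest threshold processing: voxels at or above
#' `tooth_threshold` are labelled tooth, voxels in
#' `[bone_threshold, tooth_threshold)` bone, and everything else background.
#' CT values are untouched. Existing implant labels are never produced by
#' segmentation. If a threshold falls outside the CT range of the volume a
#' warning is raised and the corresponding class may be empty.
#'
#' @param volume a [voxel_volume()].
#' @param bone_threshold CT number above which a voxel counts as bone.
#' @param tooth_threshold CT number above which a voxel counts as tooth;
#'   must be strictly greater than `bone_threshold`.
#' @return The volume with its `labels` grid replaced.
#' @export
segment_roi <- function(volume, bone_threshold, tooth_threshold) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!is.finite(bone_threshold) || !is.finite(tooth_threshold)) {
    stop("thresholds must be finite", call. = FALSE)
  }
  if (tooth_threshold <= bone_threshold) {
    stop("`tooth_threshold` must be strictly greater than `bone_threshold`",
         call. = FALSE)
  }
  rng <- range(volume$ct_values)
  for (thr in c(bone = bone_threshold, tooth = tooth_threshold)) {
    if (thr < rng[1] || thr > rng[2]) {
      warning(sprintf("threshold %.1f lies outside the CT range [%.1f, %.1f]",
                      thr, rng[1], rng[2]), call. = FALSE)
    }
  }
  codes <- label_codes()
  lab <- array(codes[["background"]], dim = dim(volume$ct_values))
  lab[volume$ct_values >= bone_threshold] <- codes[["bone"]]
  lab[volume$ct_values >= tooth_threshold] <- codes[["tooth"]]
  storage.mode(lab) <- "integer"
  volume$labels <- lab
  # per-tooth ids survive only where the voxel still reads as tooth
  if (!is.null(volume$tooth_ids)) {
    ids <- volume$tooth_ids
    ids[lab != codes[["tooth"]]] <- 0L
    volume$tooth_ids <- ids
  }
  volume
}

#' Fill enclosed sub-threshold pores after segmentation
#'
#' Threshold segmentation of noisy trabecular bone leaves scattered
#' background voxels (marrow-space pores) fully enclosed in bone; imperfect
#' threshold regions are corrected before model construction. This step
#' automates that correction: every background voxel not 6-connected to the
#' volume boundary is relabelled bone. CT values are untouched, so a filled
#' pore keeps its low CT number and ends up as a near-zero-stiffness
#' element, preserving the local compliance it represents.
#'
#' @param volume a segmented [voxel_volume()].
#' @return The volume with enclosed background pores relabelled as bone.
#' @export
fill_enclosed_pores <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  codes <- label_codes()
  bg <- volume$labels == codes[["background"]]
  d <- dim(bg)
  # flood the boundary-connected background by iterative 6-neighbour dilation
  outside <- array(FALSE, dim = d)
  outside[1, , ] <- bg[1, , ]; outside[d[1], , ] <- bg[d[1], , ]
  outside[, 1, ] <- outside[, 1, ] | bg[, 1, ]
  outside[, d[2], ] <- outside[, d[2], ] | bg[, d[2], ]
  outside[, , 1] <- outside[, , 1] | bg[, , 1]
  outside[, , d[3]] <- outside[, , d[3]] | bg[, , d[3]]
  repeat {
    grown <- outside
    grown[-1, , ] <- grown[-1, , ] | outside[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | outside[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | outside[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | outside[, -1, ]
    grown[, , -1] <- grown[, , -1] | outside[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | outside[, , -1]
    grown <- grown & bg
    if (identical(grown, outside)) break
    outside <- grown
  }
  pores <- bg & !outside
  volume$labels[pores] <- codes[["bone"]]
  attr(volume, "n_pores_filled") <- sum(pores)
  volume
}
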