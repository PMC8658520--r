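# path helpers: companion files share the stem of the main path
path_stem <- function(path) {
  sub("\\.nii\\.gz$|\\.nii$|\\.json$", "", path)
}
nifti_ext <- function(path) {
  if (grepl("\\.nii\\.gz$", path)) ".nii.gz" else ".nii"
}

#' Write a voxel volume to disk
#'
#' Two formats are supported for writing. `"nifti"` stores the CT grid in
#' the named file and the label grid (plus per-tooth ids, when present) in
#' `<stem>_labels` / `<stem>_teeth` companions with the same geometry;
#' spacing is carried in the NIfTI header, the origin in the sform.
#' `"rawjson"` stores a JSON sidecar with the geometry next to raw
#' little-endian binaries. Both round-trip CT values, spacing and labels
#' exactly.
#'
#' @param volume a [voxel_volume()].
#' @param path output path: the `.nii`/`.nii.gz` file for `"nifti"`, the
#'   `.json` sidecar for `"rawjson"`.
#' @param format `"nifti"` or `"rawjson"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("nifti", "rawjson")) {
  stopifnot(inherits(volume, "voxel_volume"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  }
  if (format == "nifti") {
    h <- volume$spacing
    affine <- diag(c(h, h, h, 1))
    affine[1:3, 4] <- volume$origin
    write_one <- function(arr, p) {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- c(h, h, h)
      RNifti::sform(img) <- structure(affine, code = 2L)
      RNifti::writeNifti(img, p)
    }
    write_one(volume$ct_values, path)
    stem <- path_stem(path); ext <- nifti_ext(path)
    write_one(volume$labels, paste0(stem, "_labels", ext))
    if (!is.null(volume$tooth_ids)) {
      write_one(volume$tooth_ids, paste0(stem, "_teeth", ext))
    }
  } else {
    stem <- path_stem(path)
    d <- dim(volume$ct_values)
    meta <- list(
      dims = d, spacing = volume$spacing, origin = volume$origin,
      ct_file = basename(paste0(stem, "_ct.raw")),
      labels_file = basename(paste0(stem, "_labels.raw")),
      tooth_ids_file = if (!is.null(volume$tooth_ids))
        basename(paste0(stem, "_teeth.raw")) else NULL,
      ct_dtype = "float64le", labels_dtype = "int32le"
    )
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), path)
    writeBin(as.numeric(volume$ct_values),
             paste0(stem, "_ct.raw"), size = 8, endian = "little")
    writeBin(as.integer(volume$labels),
             paste0(stem, "_labels.raw"), size = 4, endian = "little")
    if (!is.null(volume$tooth_ids)) {
      writeBin(as.integer(volume$tooth_ids),
               paste0(stem, "_teeth.raw"), size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a voxel volume from disk
#'
#' Reads the formats written by [write_volume()] plus DICOM series (one
#' single-frame slice per file, explicit-VR little-endian). For DICOM,
#' `path` is the series directory; labels come back as background and are
#' assigned with [segment_roi()]. A DICOM series with inconsistent slice
#' spacing (e.g. a missing slice) is a hard error naming the offending
#' slice.
#'
#' @param path volume path (or DICOM directory).
#' @param format `"nifti"`, `"rawjson"` or `"dicom"`.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "rawjson", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::readNifti(path, internal = FALSE)
    hdr <- RNifti::niftiHeader(img)
    # pixdim and srow are float32 in the NIfTI-1 header; snap to the 7
    # significant digits single precision actually carries
    h <- signif(hdr$pixdim[2], 7)
    if (abs(hdr$pixdim[3] - h) > 1e-6 || abs(hdr$pixdim[4] - h) > 1e-6) {
      stop("anisotropic NIfTI voxels are not supported", call. = FALSE)
    }
    origin <- signif(c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4]), 7)
    ct <- array(as.numeric(img), dim = dim(img))
    stem <- path_stem(path); ext <- nifti_ext(path)
    labels_path <- paste0(stem, "_labels", ext)
    labels <- NULL
    if (file.exists(labels_path)) {
      labels <- array(as.integer(RNifti::readNifti(labels_path)),
                      dim = dim(ct))
    }
    teeth_path <- paste0(stem, "_teeth", ext)
    tooth_ids <- NULL
    if (file.exists(teeth_path)) {
      tooth_ids <- array(as.integer(RNifti::readNifti(teeth_path)),
                         dim = dim(ct))
    }
    voxel_volume(ct, spacing = h, origin = origin, labels = labels,
                 tooth_ids = tooth_ids)
  } else if (format == "rawjson") {
    meta <- jsonlite::fromJSON(path)
    d <- as.integer(meta$dims)
    dirn <- dirname(path)
    ct <- array(readBin(file.path(dirn, meta$ct_file), "double",
                        n = prod(d), size = 8, endian = "little"), dim = d)
    labels <- array(readBin(file.path(dirn, meta$labels_file), "integer",
                            n = prod(d), size = 4, endian = "little"),
                    dim = d)
    tooth_ids <- NULL
    if (!is.null(meta$tooth_ids_file)) {
      tooth_ids <- array(readBin(file.path(dirn, meta$tooth_ids_file),
                                 "integer", n = prod(d), size = 4,
                                 endian = "little"), dim = d)
    }
    voxel_volume(ct, spacing = meta$spacing, origin = meta$origin,
                 labels = labels, tooth_ids = tooth_ids)
  } else {
    read_dicom_series(path)
  }
}
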