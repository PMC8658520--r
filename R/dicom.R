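# Minimal DICOM support: single-frame CT slices, explicit VR little-endian
# (transfer syntax 1.2.840.10008.1.2.1). Covers what a slice series needs
# for volume reconstruction -- geometry, rescale, 16-bit pixel data -- and
# nothing else. Sequences (SQ) are skipped wholesale.

dicom_vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", basename(path),
         call. = FALSE)
  }
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  pos <- 133L
  elements <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% dicom_vr_long) {
      len <- u32(pos + 8L)
      data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      data_at <- pos + 8L
    }
    if (len < 0 || data_at + len - 1L > n) {
      stop("corrupt DICOM element in ", basename(path), call. = FALSE)
    }
    key <- sprintf("%04X%04X", group, elem)
    bytes <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0)
    elements[[key]] <- list(vr = vr, bytes = bytes)
    pos <- data_at + len
  }
  elements
}

dicom_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$bytes))
}
dicom_numbers <- function(el) {
  s <- dicom_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dicom_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", size = 2, signed = FALSE, endian = "little")
}

# Reconstruct a voxel volume from a directory of DICOM slices.
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) < 2) {
    stop("DICOM series needs at least two slices in ", dir, call. = FALSE)
  }
  slices <- lapply(files, function(f) {
    el <- parse_dicom_file(f)
    rows <- dicom_us(el[["00280010"]])
    cols <- dicom_us(el[["00280011"]])
    spacing <- dicom_numbers(el[["00280030"]])
    ipp <- dicom_numbers(el[["00200032"]])
    bits <- dicom_us(el[["00280100"]])
    signed <- dicom_us(el[["00280103"]])
    slope_el <- dicom_numbers(el[["00281053"]])
    inter_el <- dicom_numbers(el[["00281052"]])
    px <- el[["7FE00010"]]
    if (is.null(rows) || is.null(cols) || is.null(spacing) || is.null(ipp) ||
        is.null(px)) {
      stop("DICOM slice missing required attributes: ", basename(f),
           call. = FALSE)
    }
    if (!identical(bits, 16L) && !identical(bits, 16)) {
      stop("only 16-bit DICOM pixel data is supported: ", basename(f),
           call. = FALSE)
    }
    vals <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
                    signed = !identical(signed, 0L), endian = "little")
    slope <- if (is.null(slope_el)) 1 else slope_el
    inter <- if (is.null(inter_el)) 0 else inter_el
    list(file = basename(f), rows = rows, cols = cols,
         pixel_spacing = spacing, ipp = ipp,
         data = slope * vals + inter)
  })

  ref <- slices[[1]]
  for (s in slices[-1]) {
    if (s$rows != ref$rows || s$cols != ref$cols) {
      stop("DICOM slice dimensions differ at ", s$file, call. = FALSE)
    }
    if (max(abs(s$pixel_spacing - ref$pixel_spacing)) > 1e-6) {
      stop("DICOM pixel spacing differs at ", s$file, call. = FALSE)
    }
  }
  ps <- ref$pixel_spacing
  if (abs(ps[1] - ps[2]) > 1e-6) {
    stop("anisotropic DICOM pixel spacing is not supported", call. = FALSE)
  }
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  dz <- diff(z)
  gap <- which(abs(dz - stats::median(dz)) > 1e-3 * max(abs(dz)))
  if (length(gap) > 0) {
    stop(sprintf(
      "inconsistent slice spacing between %s and %s (%.4f mm vs %.4f mm)",
      slices[[gap[1]]]$file, slices[[gap[1] + 1]]$file, dz[gap[1]],
      stats::median(dz)), call. = FALSE)
  }
  if (abs(stats::median(dz) - ps[1]) > 1e-6) {
    stop("DICOM slice spacing differs from in-plane pixel spacing; ",
         "isotropic voxels required", call. = FALSE)
  }
  # pixel data is row-major (column index fastest): columns -> x, rows -> y
  ct <- array(0, dim = c(ref$cols, ref$rows, length(slices)))
  for (k in seq_along(slices)) {
    ct[, , k] <- matrix(slices[[k]]$data, nrow = ref$cols)
  }
  origin <- c(slices[[1]]$ipp[1], slices[[1]]$ipp[2], z[1])
  voxel_volume(ct, spacing = ps[1], origin = origin)
}

# Test/fixture support: write a volume's CT grid as a minimal explicit-VR
# little-endian DICOM slice series. CT values must be integers
# representable in int16.
write_dicom_slices <- function(volume, dir, drop_slices = integer(0),
                               z_jitter = numeric(0)) {
  stopifnot(inherits(volume, "voxel_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$ct_values)
  h <- volume$spacing
  u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
  u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")
  element <- function(group, elem, vr, bytes) {
    if (length(bytes) %% 2 == 1) {
      bytes <- c(bytes, if (vr %in% c("UI")) as.raw(0) else charToRaw(" "))
    }
    hdr <- c(u16raw(group), u16raw(elem), charToRaw(vr))
    if (vr %in% dicom_vr_long) {
      c(hdr, as.raw(c(0, 0)), u32raw(length(bytes)), bytes)
    } else {
      c(hdr, u16raw(length(bytes)), bytes)
    }
  }
  ds <- function(x) charToRaw(paste(format(x, trim = TRUE, digits = 10),
                                    collapse = "\\"))
  for (k in seq_len(d[3])) {
    if (k %in% drop_slices) next
    z <- volume$origin[3] + (k - 1) * h +
      if (k <= length(z_jitter)) z_jitter[k] else 0
    slice <- volume$ct_values[, , k]
    stopifnot(all(slice == round(slice)), all(abs(slice) <= 32767))
    # pixel bytes row-major (x fastest): row = y index, column = x index
    px <- writeBin(as.integer(as.vector(slice)), raw(), size = 2,
                   endian = "little")
    body <- c(
      element(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1")),
      element(0x0020, 0x0013, "IS", charToRaw(as.character(k))),
      element(0x0020, 0x0032, "DS", ds(c(volume$origin[1], volume$origin[2],
                                         z))),
      element(0x0028, 0x0010, "US", u16raw(d[2])),  # rows = y
      element(0x0028, 0x0011, "US", u16raw(d[1])),  # cols = x
      element(0x0028, 0x0030, "DS", ds(c(h, h))),
      element(0x0028, 0x0100, "US", u16raw(16)),
      element(0x0028, 0x0103, "US", u16raw(1)),
      element(0x0028, 0x1052, "DS", ds(0)),
      element(0x0028, 0x1053, "DS", ds(1)),
      element(0x7FE0, 0x0010, "OW", px)
    )
    out <- c(raw(128), charToRaw("DICM"), body)
    writeBin(out, file.path(dir, sprintf("slice_%04d.dcm", k)))
  }
  invisible(dir)
}
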