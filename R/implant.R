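#' Parametric one-piece implant specification
#'
#' The implant solid is a smooth cylinder of diameter `diameter` reaching
#' `length` mm into the bone from the ridge crest, closed by a hemispherical
#' apex, and continued above the crest by a cylindrical abutment topped with
#' a rectangular crown block. The supracrestal height is identical across
#' all designs of a sweep, mirroring the clinical situation where extra
#' implant length is gained inside the bone while the lever arm above the
#' bone margin stays fixed.
#'
#' @param diameter implant diameter d in mm.
#' @param length intrabony length l in mm (crest to apex).
#' @param supracrestal_height height of the abutment plus crown above the
#'   crest (mm), constant across a design sweep.
#' @param crown_width edge length of the square crown block (mm).
#' @param crown_height height of the crown block (mm).
#' @param cusp_offset buccal offset of the loaded cusp point from the
#'   implant axis (mm); buccal is the -y direction.
#' @return An object of class `implant_spec`.
#' @export
implant_spec <- function(diameter, length, supracrestal_height = 8,
                         crown_width = 7, crown_height = 3,
                         cusp_offset = 2.5) {
  if (diameter <= 0 || length <= 0) {
    stop("implant diameter and length must be positive", call. = FALSE)
  }
  if (supracrestal_height < crown_height) {
    stop("supracrestal height must cover the crown block", call. = FALSE)
  }
  s <- list(diameter = diameter, length = length,
            supracrestal_height = supracrestal_height,
            crown_width = crown_width, crown_height = crown_height,
            cusp_offset = cusp_offset)
  class(s) <- "implant_spec"
  s
}

#' @export
print.implant_spec <- function(x, ...) {
  cat(sprintf("<implant_spec> d = %.1f mm, l = %.1f mm (+%.1f mm supracrestal)\n",
              x$diameter, x$length, x$supracrestal_height))
  invisible(x)
}

#' Enumerate the implant design grid
#'
#' Cartesian product of diameters and lengths in deterministic
#' diameter-major order. Defaults give the 12-design sweep (3 diameters
#' by 4 lengths).
#'
#' @param diameters implant diameters in mm.
#' @param lengths intrabony lengths in mm.
#' @param ... further arguments passed to [implant_spec()].
#' @return A tibble with columns `diameter`, `length` and a list-column
#'   `spec` of [implant_spec()] objects, one row per design.
#' @export
enumerate_design_grid <- function(diameters = c(3.8, 4.3, 6.0),
                                  lengths = c(9.0, 11.0, 13.0, 16.0),
                                  ...) {
  if (length(diameters) == 0 || length(lengths) == 0) {
    stop("factor lists must be non-empty", call. = FALSE)
  }
  grid <- tibble::tibble(
    diameter = rep(diameters, each = length(lengths)),
    length = rep(lengths, times = length(diameters))
  )
  grid$spec <- lapply(seq_len(nrow(grid)), function(i) {
    implant_spec(grid$diameter[i], grid$length[i], ...)
  })
  grid
}

#' Placement frame for an implant
#'
#' @param entry numeric length-2, (x, y) of the implant axis in mm; `NULL`
#'   centres the axis on the extraction socket (buccolingual centre of the
#'   ridge at the tooth position).
#' @param axis implant axis direction (default +z, tooth-axis aligned).
#' @param tooth_id id of the target (extracted) tooth.
#' @return An object of class `placement_frame`.
#' @export
placement_frame <- function(entry = NULL, axis = c(0, 0, 1), tooth_id = 1L) {
  axis <- axis / sqrt(sum(axis^2))
  if (max(abs(axis - c(0, 0, 1))) > 1e-12) {
    stop("only tooth-axis (+z) aligned placement is supported",
         call. = FALSE)
  }
  f <- list(entry = entry, axis = axis, tooth_id = as.integer(tooth_id))
  class(f) <- "placement_frame"
  f
}

# per-tooth id grid: prefer the generator's ids, else 6-connected components
resolve_tooth_ids <- function(volume) {
  codes <- label_codes()
  tooth_mask <- volume$labels == codes[["tooth"]]
  if (!is.null(volume$tooth_ids) && any(volume$tooth_ids > 0L)) {
    return(volume$tooth_ids)
  }
  ids <- array(0L, dim = dim(volume$ct_values))
  if (!any(tooth_mask)) return(ids)
  d <- dim(tooth_mask)
  remaining <- which(tooth_mask)
  comp <- 0L
  while (length(remaining) > 0) {
    comp <- comp + 1L
    queue <- remaining[1]
    ids[queue] <- comp
    while (length(queue) > 0) {
      ijk <- arrayInd(queue, d)
      nbrs <- integer(0)
      for (ax in 1:3) {
        for (dd in c(-1L, 1L)) {
          nb <- ijk
          nb[, ax] <- nb[, ax] + dd
          ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
          if (any(ok)) {
            lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) +
              d[1] * d[2] * (nb[ok, 3] - 1L)
            nbrs <- c(nbrs, lin)
          }
        }
      }
      nbrs <- unique(nbrs)
      queue <- nbrs[tooth_mask[nbrs] & ids[nbrs] == 0L]
      ids[queue] <- comp
    }
    remaining <- which(tooth_mask & ids == 0L)
  }
  # renumber components by increasing minimal x index for determinism
  ord <- order(vapply(seq_len(comp), function(c) {
    min(arrayInd(which(ids == c), d)[, 1])
  }, numeric(1)))
  relab <- integer(comp)
  relab[ord] <- seq_len(comp)
  ids[ids > 0L] <- relab[ids[ids > 0L]]
  ids
}

#' Virtually extract a tooth and fill the socket with bone
#'
#' Sub-crestal (root) voxels of the target tooth are relabelled bone and
#' their CT values are replaced by the mean CT of trabecular bone within a
#' `shell_mm` neighbourhood of the socket; supra-crestal (crown) voxels are
#' cleared to background, emulating the extraction space being replaced by
#' bone before implant placement. The crest is the highest bone voxel plane
#' adjacent to the socket.
#'
#' @param volume a segmented [voxel_volume()].
#' @param tooth_id which tooth to extract (ids follow the generator, or
#'   6-connected components ordered mesiodistally for imported volumes).
#' @param shell_mm thickness of the peri-socket shell used to estimate the
#'   trabecular fill CT (default 2 mm).
#' @param trabecular_max_ct bone voxels at or above this CT number are
#'   treated as cortical and excluded from the fill estimate.
#' @return The volume with the tooth removed and the socket grafted.
#' @export
virtual_extraction <- function(volume, tooth_id = 1L, shell_mm = 2,
                               trabecular_max_ct = 9000) {
  stopifnot(inherits(volume, "voxel_volume"))
  codes <- label_codes()
  ids <- resolve_tooth_ids(volume)
  sel <- which(ids == tooth_id & volume$labels == codes[["tooth"]])
  if (length(sel) == 0) {
    if (!any(volume$labels == codes[["tooth"]])) {
      stop("volume contains no teeth", call. = FALSE)
    }
    stop("unknown tooth_id: ", tooth_id, call. = FALSE)
  }
  d <- dim(volume$ct_values)
  h <- volume$spacing
  ctr <- voxel_centers(volume, sel)

  # crest height: top of the bone immediately around the socket
  bone_lin <- which(volume$labels == codes[["bone"]])
  bctr <- voxel_centers(volume, bone_lin)
  rx <- range(ctr[, 1]) + c(-shell_mm, shell_mm)
  ry <- range(ctr[, 2]) + c(-shell_mm, shell_mm)
  near_sock <- bctr[, 1] >= rx[1] & bctr[, 1] <= rx[2] &
    bctr[, 2] >= ry[1] & bctr[, 2] <= ry[2]
  if (!any(near_sock)) stop("no bone adjacent to the socket", call. = FALSE)
  crest_z <- max(bctr[near_sock, 3]) + h / 2  # top face of crest voxels

  root <- ctr[, 3] < crest_z
  # trabecular fill value from the peri-socket shell
  shell_sel <- near_sock & bctr[, 3] < crest_z &
    volume$ct_values[bone_lin] < trabecular_max_ct
  if (!any(shell_sel)) {
    stop("no trabecular bone around the socket to estimate the graft CT",
         call. = FALSE)
  }
  fill_ct <- mean(volume$ct_values[bone_lin[shell_sel]])

  volume$labels[sel[root]] <- codes[["bone"]]
  volume$ct_values[sel[root]] <- fill_ct
  volume$labels[sel[!root]] <- codes[["background"]]
  volume$ct_values[sel[!root]] <- 0
  if (!is.null(volume$tooth_ids)) volume$tooth_ids[sel] <- 0L
  attr_sock <- list(
    tooth_id = tooth_id,
    center = c(mean(range(ctr[, 1])), mean(range(ctr[, 2]))),
    crest_z = crest_z,
    fill_ct = fill_ct
  )
  volume$socket <- attr_sock
  volume
}

#' Place a parametric implant into the grafted socket
#'
#' Writes the implant solid into the label grid: an intrabony cylinder of
#' the specified diameter with a hemispherical apex reaching `length` mm
#' below the crest, continued by a supracrestal abutment cylinder and a
#' square crown block. Bone and background voxels inside the solid become
#' implant; tooth voxels inside the solid are an error (extract first).
#' The buccal-cusp load target point is recorded on the returned volume.
#'
#' @param volume a [voxel_volume()] after [virtual_extraction()].
#' @param spec an [implant_spec()].
#' @param frame a [placement_frame()]; a `NULL` entry point centres the
#'   implant on the extraction socket.
#' @return The volume with implant labels and a `placement` record
#'   (entry, crest height, load target, spec).
#' @export
place_implant <- function(volume, spec, frame = placement_frame()) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(spec, "implant_spec"),
            inherits(frame, "placement_frame"))
  codes <- label_codes()
  if (is.null(frame$entry)) {
    if (is.null(volume$socket)) {
      stop("no extraction socket recorded; supply `frame$entry`",
           call. = FALSE)
    }
    entry <- volume$socket$center
    crest_z <- volume$socket$crest_z
  } else {
    entry <- frame$entry
    crest_z <- volume$socket$crest_z
    if (is.null(crest_z)) stop("no crest height available", call. = FALSE)
  }
  h <- volume$spacing
  d <- dim(volume$ct_values)
  r <- spec$diameter / 2

  # inferior overshoot check: the apex must stay above the inferior cortex
  bone_z <- voxel_centers(volume, which(volume$labels == codes[["bone"]]))[, 3]
  z_inferior <- min(bone_z) - h / 2
  apex_z <- crest_z - spec$length
  cortex <- attr(volume, "params")$shell_thickness
  if (is.null(cortex)) cortex <- 0
  floor_z <- z_inferior + cortex
  if (apex_z < floor_z) {
    stop(sprintf(
      "invalid placement: implant apex exits the inferior cortical border by %.2f mm",
      floor_z - apex_z), call. = FALSE)
  }

  all_ctr <- voxel_centers(volume, seq_along(volume$ct_values))
  cyl_top <- crest_z + spec$supracrestal_height - spec$crown_height
  # partial-volume membership: a voxel joins the solid when at least half
  # of a 2x2x2 subsample of its interior lies inside the continuous solid;
  # plain centre membership would leave single-voxel stair-step
  # protrusions on the cylinder surface that concentrate contact stress
  inside_count <- integer(length(volume$ct_values))
  for (ox in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25)) {
    for (oz in c(-0.25, 0.25)) {
      dx <- all_ctr[, 1] + ox * h - entry[1]
      dy <- all_ctr[, 2] + oy * h - entry[2]
      z <- all_ctr[, 3] + oz * h
      r2 <- dx^2 + dy^2
      in_cyl <- r2 <= r^2 & z >= apex_z + r & z <= cyl_top
      in_apex <- z < apex_z + r & z >= apex_z &
        r2 + (z - (apex_z + r))^2 <= r^2
      in_crown <- abs(dx) <= spec$crown_width / 2 &
        abs(dy) <= spec$crown_width / 2 &
        z > cyl_top & z <= crest_z + spec$supracrestal_height
      inside_count <- inside_count + (in_cyl | in_apex | in_crown)
    }
  }
  solid <- which(inside_count >= 4L)
  z <- all_ctr[, 3]

  # lateral containment: the intrabony cylinder must be surrounded by bone
  intrabony <- solid[z[solid] < crest_z]
  lab_in <- volume$labels[intrabony]
  if (any(lab_in == codes[["tooth"]])) {
    stop("implant solid intersects a tooth; perform virtual extraction first",
         call. = FALSE)
  }
  # isolated sub-threshold pores inside the solid are displaced by the
  # implant; a substantial background fraction means the body exits the bone
  bg_frac <- mean(lab_in == codes[["background"]])
  if (bg_frac > 0.05) {
    stop(sprintf(
      "invalid placement: the intrabony implant body exits the bone laterally (%.0f%% outside)",
      100 * bg_frac), call. = FALSE)
  }
  supracrestal <- setdiff(solid, intrabony)
  if (any(volume$labels[supracrestal] == codes[["tooth"]])) {
    stop("implant solid intersects a tooth crown; extract it first",
         call. = FALSE)
  }
  volume$labels[solid] <- codes[["implant"]]
  volume$placement <- list(
    entry = entry,
    crest_z = crest_z,
    apex_z = apex_z,
    spec = spec,
    load_target = c(entry[1], entry[2] - spec$cusp_offset,
                    crest_z + spec$supracrestal_height),
    solid_voxels = length(solid)
  )
  volume
}

#' Analytic volume of an implant solid (mm^3)
#'
#' Cylinder with hemispherical apex over the intrabony length, supracrestal
#' abutment cylinder, and square crown block. Used to validate the voxelised
#' placement against the continuous solid.
#'
#' @param spec an [implant_spec()].
#' @return Volume in mm^3.
#' @export
implant_solid_volume <- function(spec) {
  r <- spec$diameter / 2
  cyl_intra <- pi * r^2 * (spec$length - r)
  apex <- 2 / 3 * pi * r^3
  abutment <- pi * r^2 * (spec$supracrestal_height - spec$crown_height)
  crown <- spec$crown_width^2 * spec$crown_height
  cyl_intra + apex + abutment + crown
}
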