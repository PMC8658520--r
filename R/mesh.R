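# Local cube vertex v = 1 + dx + 2*dy + 4*dz, (dx,dy,dz) in {0,1}^3.
# Two mirror-image 5-tet decompositions of the cube; alternating them in a
# 3D checkerboard makes the face diagonals of neighbouring cubes coincide,
# so the mesh conforms. Node orderings are fixed at load time so every
# tetrahedron has positive signed volume.
cube_corners_local <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))

tet_templates <- local({
  A <- rbind(c(1, 4, 6, 7),
             c(2, 1, 4, 6),
             c(3, 1, 4, 7),
             c(5, 1, 6, 7),
             c(8, 4, 6, 7))
  B <- rbind(c(2, 3, 5, 8),
             c(1, 2, 3, 5),
             c(4, 2, 3, 8),
             c(6, 2, 5, 8),
             c(7, 3, 5, 8))
  orient <- function(tpl) {
    for (r in seq_len(nrow(tpl))) {
      p <- cube_corners_local[tpl[r, ], ]
      v <- det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))
      if (v < 0) tpl[r, c(3, 4)] <- tpl[r, c(4, 3)]
    }
    tpl
  }
  list(even = orient(A), odd = orient(B))
})

#' Convert a labelled voxel volume to a 4-node tetrahedral mesh
#'
#' Each included voxel is split into 5 tetrahedra; the cube diagonal pattern
#' alternates with voxel index parity so the faces of neighbouring voxels
#' match and the mesh is conforming. Nodes on the voxel lattice are shared
#' exactly (integer lattice keys, no tolerance needed). Elements inherit the
#' label of their voxel, and bone elements inherit the density derived from
#' the voxel CT number.
#'
#' @param volume a [voxel_volume()].
#' @param include_labels character vector of label names to mesh
#'   (default bone, tooth and implant).
#' @param table [material_table()] supplying the CT-to-density slope.
#' @return An object of class `tet_mesh` with fields `nodes` (mm), `elements`
#'   (4 node ids per row), `element_label`, `element_density` (gf/cc, bone
#'   only), `element_voxel`, `spacing`, and `placement` carried over from the
#'   volume if an implant has been placed.
#' @export
voxel_to_tets <- function(volume,
                          include_labels = c("bone", "tooth", "implant"),
                          table = material_table()) {
  stopifnot(inherits(volume, "voxel_volume"))
  codes <- label_codes()
  bad <- setdiff(include_labels, names(codes))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  vox <- which(volume$labels %in% codes[include_labels])
  if (length(vox) == 0L) {
    stop("no voxel carries an included label", call. = FALSE)
  }
  d <- dim(volume$ct_values)
  nv <- length(vox)
  idx0 <- arrayInd(vox, d) - 1L  # 0-based voxel indices

  # lattice key of each of the 8 corners of each voxel (0-based)
  nxx <- d[1] + 1L; nyy <- d[2] + 1L
  corner_keys <- matrix(0L, nv, 8L)
  for (v in 1:8) {
    dxyz <- cube_corners_local[v, ]
    corner_keys[, v] <- (idx0[, 1] + dxyz[1]) +
      nxx * ((idx0[, 2] + dxyz[2]) + nyy * (idx0[, 3] + dxyz[3]))
  }

  parity_odd <- (idx0[, 1] + idx0[, 2] + idx0[, 3]) %% 2L == 1L
  tplA <- as.vector(t(tet_templates$even))  # tet-major, 20 entries
  tplB <- as.vector(t(tet_templates$odd))
  local_ids <- matrix(rep(tplA, each = nv), nv, 20L)
  if (any(parity_odd)) {
    local_ids[parity_odd, ] <- matrix(rep(tplB, each = sum(parity_odd)),
                                      sum(parity_odd), 20L)
  }
  elem_keys <- matrix(0L, nv, 20L)
  for (col in 1:20) {
    elem_keys[, col] <- corner_keys[cbind(seq_len(nv), local_ids[, col])]
  }

  used_keys <- sort(unique(as.vector(elem_keys)))
  id_of_key <- integer(nxx * nyy * (d[3] + 1L))
  id_of_key[used_keys + 1L] <- seq_along(used_keys)

  # lattice key -> node coordinates (mm)
  kx <- used_keys %% nxx
  ky <- (used_keys %/% nxx) %% nyy
  kz <- used_keys %/% (nxx * nyy)
  nodes <- cbind(kx, ky, kz) * volume$spacing
  nodes <- sweep(nodes, 2, volume$origin, "+")
  colnames(nodes) <- c("x", "y", "z")

  elements <- matrix(0L, 5L * nv, 4L)
  for (t in 1:5) {
    rows <- (seq_len(nv) - 1L) * 5L + t
    elements[rows, ] <- id_of_key[elem_keys[, (4L * t - 3L):(4L * t)] + 1L]
  }

  lab <- volume$labels[vox]
  element_label <- rep(lab, each = 5L)
  dens <- rep(NA_real_, nv)
  is_bone <- lab == codes[["bone"]]
  dens[is_bone] <- hu_to_density(volume$ct_values[vox][is_bone],
                                 slope = table$hu_to_density_slope)
  mesh <- list(
    nodes = nodes,
    elements = elements,
    element_label = element_label,
    element_density = rep(dens, each = 5L),
    element_voxel = rep(vox, each = 5L),
    spacing = volume$spacing,
    placement = volume$placement,
    E = NULL, nu = NULL
  )
  class(mesh) <- "tet_mesh"
  vols <- tet_volumes(mesh)
  if (any(vols <= 0)) {
    stop("internal error: non-positive tetrahedron volume at element ",
         which.min(vols), call. = FALSE)
  }
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tet4 elements\n",
              nrow(x$nodes), nrow(x$elements)))
  codes <- label_codes()
  for (nm in names(codes)) {
    n <- sum(x$element_label == codes[[nm]])
    if (n > 0) cat(sprintf("  %s: %d elements\n", nm, n))
  }
  if (!is.null(x$E)) cat("  materials assigned\n")
  invisible(x)
}

#' Signed volumes of all tetrahedra in a mesh (mm^3)
#'
#' @param mesh a `tet_mesh`.
#' @return Numeric vector of signed volumes, positive for well-oriented
#'   elements.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; el <- mesh$elements
  a <- n[el[, 1], , drop = FALSE]
  e1 <- n[el[, 2], , drop = FALSE] - a
  e2 <- n[el[, 3], , drop = FALSE] - a
  e3 <- n[el[, 4], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) +
     e1[, 2] * (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) +
     e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Nodes on the fixed inferior border
#'
#' Returns every node within one voxel layer of the lowest node plane,
#' the discrete analogue of a completely fixed inferior mandibular border.
#'
#' @param mesh a `tet_mesh`.
#' @return Integer vector of node ids (non-empty).
#' @export
select_fixed_nodes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"), nrow(mesh$nodes) > 0)
  z <- mesh$nodes[, 3]
  which(z <= min(z) + mesh$spacing + 1e-9)
}

#' Node receiving the concentrated occlusal load
#'
#' Picks the implant node nearest the configured buccal-cusp target point
#' (recorded on the mesh by [place_implant()], or supplied directly).
#' Ties are broken by the lowest node id.
#'
#' @param mesh a `tet_mesh` containing implant elements.
#' @param target optional numeric length-3 target point (mm); defaults to
#'   the `load_target` recorded at implant placement.
#' @return A single node id.
#' @export
select_load_node <- function(mesh, target = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  codes <- label_codes()
  imp <- mesh$element_label == codes[["implant"]]
  if (!any(imp)) stop("mesh contains no implant elements", call. = FALSE)
  if (is.null(target)) {
    if (is.null(mesh$placement)) {
      stop("no placement information on the mesh; supply `target`",
           call. = FALSE)
    }
    target <- mesh$placement$load_target
  }
  cand <- sort(unique(as.vector(mesh$elements[imp, ])))
  d2 <- (mesh$nodes[cand, 1] - target[1])^2 +
    (mesh$nodes[cand, 2] - target[2])^2 +
    (mesh$nodes[cand, 3] - target[3])^2
  cand[which.min(d2)]  # which.min returns the first (lowest id) on ties
}
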