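# Small phantoms and meshes shared across tests. Everything is generated
# in code; nothing is read from disk.

# a fast, small mandibular segment that still fits every default implant
# laterally (but only short ones vertically)
tiny_phantom_params <- function(seed = 42L, teeth = NULL, ...) {
  if (is.null(teeth)) {
    teeth <- data.frame(x_mm = 24 * 0.39 / 2, radius = 3.1,
                        root_depth = 6, crown_height = 4)
  }
  mandible_phantom_params(
    extent = c(24L, 28L, 48L),
    ridge_width = 9.36,
    bone_height = 12.0,
    teeth = teeth,
    seed = seed,
    ...
  )
}

# segmented + extracted tiny volume, ready for placement
tiny_extracted_volume <- function(seed = 42L, ...) {
  vol <- generate_mandible_volume(tiny_phantom_params(seed = seed, ...))
  vol <- fill_enclosed_pores(segment_roi(vol, 1200, 17500))
  virtual_extraction(vol, 1L)
}

# homogeneous rectangular bar volume: nx x ny x nz voxels of bone at a
# constant CT number (deterministic densities)
bar_volume <- function(nx, ny, nz, spacing = 1, ct = 5000) {
  d <- c(nx, ny, nz)
  labels <- array(label_codes()[["bone"]], dim = d)
  voxel_volume(array(ct, dim = d), spacing = spacing, labels = labels)
}

# bar mesh with a prescribed uniform modulus
bar_mesh <- function(nx, ny, nz, spacing = 1, E = 1000, nu = 0.25) {
  mesh <- voxel_to_tets(bar_volume(nx, ny, nz, spacing))
  mesh$E <- rep(E, nrow(mesh$elements))
  mesh$nu <- rep(nu, nrow(mesh$elements))
  mesh
}

# per-DOF constrained solve used by the verification problems
solve_with_dofs <- function(mesh, f, fixed_dofs, ...) {
  K <- assemble_stiffness(mesh)
  u <- implantfem:::fem_solve(K, f, fixed_dofs, ...)
  list(u = matrix(u, ncol = 3, byrow = TRUE), K = K,
       residual = attr(u, "residual"))
}

# brute-force dense assembly from individual element blocks; the
# independent oracle for the sparse assembly path
dense_assembly <- function(mesh) {
  ndof <- 3 * nrow(mesh$nodes)
  K <- matrix(0, ndof, ndof)
  for (e in seq_len(nrow(mesh$elements))) {
    nodes <- mesh$elements[e, ]
    Ke <- element_stiffness(mesh$nodes[nodes, , drop = FALSE],
                            mesh$E[e], mesh$nu[e])
    dofs <- as.vector(rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}
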