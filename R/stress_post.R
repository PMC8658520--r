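#' Bone elements adjacent to the implant surface
#'
#' The peri-implant region is defined by node sharing: every bone element
#' with at least one node on an implant element. Deterministic for a given
#' mesh.
#'
#' @param mesh a `tet_mesh` containing implant elements.
#' @return Integer vector of bone element ids (possibly empty if the mesh
#'   has no bone).
#' @export
peri_implant_elements <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  codes <- label_codes()
  imp <- mesh$element_label == codes[["implant"]]
  if (!any(imp)) stop("mesh contains no implant elements", call. = FALSE)
  imp_nodes <- unique(as.vector(mesh$elements[imp, , drop = FALSE]))
  touch <- matrix(mesh$elements %in% imp_nodes, ncol = 4)
  which(mesh$element_label == codes[["bone"]] & rowSums(touch) > 0)
}

# neck/middle/apex by thirds of the intrabony depth; buccal/lingual by y
# relative to the implant axis
tag_region <- function(centroid, placement) {
  depth <- placement$crest_z - centroid[3]
  frac <- depth / placement$spec$length
  level <- if (frac <= 1 / 3) "neck" else if (frac <= 2 / 3) "middle" else "apex"
  side <- if (centroid[2] < placement$entry[2]) "buccal" else "lingual"
  c(level = level, side = side)
}

#' Maximum equivalent stress over an element region
#'
#' Returns the largest element-wise (unaveraged) von Mises stress over the
#' given region, the element carrying it (lowest id on ties), and a region
#' tag locating it along the implant (neck/middle/apex by thirds of the
#' intrabony depth) and buccolingually (buccal/lingual relative to the
#' implant axis).
#'
#' @param stress a `stress_state` from [recover_stress()].
#' @param region integer vector of element ids (non-empty).
#' @param mesh the `tet_mesh` the stresses belong to.
#' @param placement placement record (defaults to the one on the mesh).
#' @return A list with `value` (MPa), `element`, `level`, `side`, and the
#'   element's `principal` stresses (MPa, sorted).
#' @export
max_equivalent_stress <- function(stress, region, mesh,
                                  placement = mesh$placement) {
  stopifnot(inherits(stress, "stress_state"))
  if (length(region) == 0) stop("element region is empty", call. = FALSE)
  vm <- stress$von_mises[region]
  best <- region[which.max(vm)]  # first maximum = lowest element id
  centroid <- colMeans(mesh$nodes[mesh$elements[best, ], , drop = FALSE])
  tag <- if (!is.null(placement)) tag_region(centroid, placement) else
    c(level = NA_character_, side = NA_character_)
  list(
    value = max(vm),
    element = best,
    level = unname(tag["level"]),
    side = unname(tag["side"]),
    principal = principal_stresses(stress$tensor[best, ])
  )
}

#' Solve one implant configuration end to end
#'
#' Places the implant into the (already extracted) volume, meshes, assigns
#' materials, applies the oblique occlusal load and solves, then extracts
#' the peri-implant stress maximum.
#'
#' @param volume an extracted [voxel_volume()].
#' @param spec an [implant_spec()].
#' @param frame a [placement_frame()].
#' @param table a [material_table()].
#' @param load_magnitude force magnitude in N.
#' @param load_angle_deg angle to the implant axis in degrees.
#' @param direct_dof_limit,tol solver settings, see [solve_displacements()].
#' @return A list with the summary `row` (tibble), and the `mesh`,
#'   `displacements` and `stress` objects of the run.
#' @export
solve_configuration <- function(volume, spec, frame = placement_frame(),
                                table = material_table(),
                                load_magnitude = 50, load_angle_deg = 45,
                                direct_dof_limit = 3e5, tol = 1e-8) {
  placed <- place_implant(volume, spec, frame)
  mesh <- voxel_to_tets(placed, table = table)
  mesh <- assign_materials(mesh, table)
  fixed <- select_fixed_nodes(mesh)
  load_node <- select_load_node(mesh)
  lc <- make_load_case(load_node, fixed, magnitude = load_magnitude,
                       angle_deg = load_angle_deg)
  disp <- solve_displacements(mesh, lc, direct_dof_limit = direct_dof_limit,
                              tol = tol)
  stress <- recover_stress(mesh, disp)
  region <- peri_implant_elements(mesh)
  peak <- max_equivalent_stress(stress, region, mesh)
  row <- tibble::tibble(
    diameter = spec$diameter,
    length = spec$length,
    peak_vm = peak$value,
    level = peak$level,
    side = peak$side,
    peak_principal = peak$principal[1],
    peak_element = peak$element,
    n_nodes = nrow(mesh$nodes),
    n_elements = nrow(mesh$elements),
    n_peri_elements = length(region),
    equilibrium_gap = sqrt(sum(disp$equilibrium_gap^2)),
    residual = disp$residual
  )
  list(row = row, mesh = mesh, displacements = disp, stress = stress,
       load_case = lc)
}

#' Run the full implant design sweep
#'
#' Executes the complete pipeline (place, mesh, assign, solve, post) for
#' every design in the grid on the same extracted volume and collects the
#' per-configuration peri-implant stress maxima, sorted diameter-major.
#'
#' @param volume an extracted [voxel_volume()] (see [virtual_extraction()]).
#' @param grid design grid from [enumerate_design_grid()].
#' @param frame a [placement_frame()].
#' @param table a [material_table()].
#' @param load_magnitude,load_angle_deg occlusal load settings.
#' @param csv optional path; when given the summary is written as CSV.
#' @param quiet suppress per-design progress messages.
#' @param ... further solver settings passed to [solve_configuration()].
#' @return A `stress_summary` tibble with one row per design.
#' @export
run_sweep <- function(volume, grid = enumerate_design_grid(),
                      frame = placement_frame(), table = material_table(),
                      load_magnitude = 50, load_angle_deg = 45,
                      csv = NULL, quiet = FALSE, ...) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (nrow(grid) == 0) stop("design grid is empty", call. = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- grid$spec[[i]]
    if (!quiet) {
      message(sprintf("[sweep %d/%d] d = %.1f mm, l = %.1f mm",
                      i, nrow(grid), spec$diameter, spec$length))
    }
    res <- tryCatch(
      solve_configuration(volume, spec, frame = frame, table = table,
                          load_magnitude = load_magnitude,
                          load_angle_deg = load_angle_deg, ...),
      error = function(e) {
        stop(sprintf("design d = %.1f, l = %.1f failed: %s",
                     spec$diameter, spec$length, conditionMessage(e)),
             call. = FALSE)
      })
    rows[[i]] <- res$row
    rm(res)
    gc(FALSE)  # large factorisations; keep the footprint flat across designs
  }
  summary <- dplyr::arrange(dplyr::bind_rows(rows), .data$diameter,
                            .data$length)
  class(summary) <- c("stress_summary", class(summary))
  attr(summary, "load_magnitude") <- load_magnitude
  attr(summary, "load_angle_deg") <- load_angle_deg
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(summary), csv, row.names = FALSE)
  }
  summary
}
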