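#' Constitutive constants for bone, teeth and implant
#'
#' Collects the calibration and material constants the stress analysis uses:
#' the linear CT-to-apparent-density calibration (0.945e-4 gf/cc per CT
#' unit), the three-branch density-to-modulus law for mandibular bone with
#' Poisson ratio 0.4, and the homogeneous constants for teeth
#' (E = 4.80e4 MPa, nu = 0.23) and titanium implants (E = 11.0e4 MPa,
#' nu = 0.29). Moduli in MPa, densities in gf/cc.
#'
#' @param hu_to_density_slope density per CT unit (gf/cc).
#' @param nu_bone,E_tooth,nu_tooth,E_implant,nu_implant scalar constants.
#' @return An object of class `material_table`.
#' @export
material_table <- function(hu_to_density_slope = 0.945e-4,
                           nu_bone = 0.4,
                           E_tooth = 4.80e4, nu_tooth = 0.23,
                           E_implant = 11.0e4, nu_implant = 0.29) {
  for (nu in c(nu_bone, nu_tooth, nu_implant)) {
    if (!(nu > 0 && nu < 0.5)) {
      stop("Poisson ratios must lie strictly inside (0, 0.5)", call. = FALSE)
    }
  }
  if (E_tooth <= 0 || E_implant <= 0 || hu_to_density_slope <= 0) {
    stop("moduli and the density slope must be positive", call. = FALSE)
  }
  tab <- list(
    hu_to_density_slope = hu_to_density_slope,
    nu_bone = nu_bone,
    E_tooth = E_tooth, nu_tooth = nu_tooth,
    E_implant = E_implant, nu_implant = nu_implant
  )
  class(tab) <- "material_table"
  tab
}

#' Convert CT numbers to apparent bone density
#'
#' Linear calibration `rho = ct * 0.945e-4` (gf/cc per CT unit). Negative CT
#' numbers (air) are clamped to zero before conversion, since the bone law
#' is undefined for negative density.
#'
#' @param ct numeric vector of CT numbers.
#' @param slope calibration slope (gf/cc per CT unit).
#' @return Densities in gf/cc, same length as `ct`.
#' @export
hu_to_density <- function(ct, slope = 0.945e-4) {
  if (any(!is.finite(ct))) stop("CT values must be finite", call. = FALSE)
  pmax(ct, 0) * slope
}

#' Young's modulus of mandibular bone from apparent density
#'
#' Piecewise law (E in MPa, density p in gf/cc):
#' \deqn{E = 0.001 \ (p = 0);\quad 33900\,p^{2.20}\ (0 < p \le 0.27);\quad
#'   5507\,p + 469\ (0.27 < p < 0.6);\quad 10200\,p^{2.01}\ (p \ge 0.6)}
#' The branch boundaries follow the printed inequalities: 0.27 belongs to
#' the power-law low branch, 0.6 to the high branch. The law is monotone
#' non-decreasing; the relative jumps at the branch boundaries are below 5%.
#'
#' @param p numeric vector of apparent densities (gf/cc), all `>= 0`.
#' @return Young's moduli in MPa.
#' @export
density_to_modulus <- function(p) {
  if (any(!is.finite(p))) stop("densities must be finite", call. = FALSE)
  if (any(p < 0)) stop("densities must be non-negative", call. = FALSE)
  E <- numeric(length(p))
  zero <- p == 0
  low <- p > 0 & p <= 0.27
  mid <- p > 0.27 & p < 0.6
  high <- p >= 0.6
  E[zero] <- 0.001
  E[low] <- 33900 * p[low]^2.20
  E[mid] <- 5507 * p[mid] + 469
  E[high] <- 10200 * p[high]^2.01
  E
}

#' Assign per-element material constants to a mesh
#'
#' Bone elements receive the modulus given by [density_to_modulus()] applied
#' to their element density and the bone Poisson ratio; tooth and implant
#' elements receive the homogeneous constants of the [material_table()].
#' Every element must carry a known label.
#'
#' @param mesh a [voxel_to_tets()] mesh with per-element labels and (for
#'   bone) densities.
#' @param table a [material_table()].
#' @return The mesh with per-element fields `E` (MPa) and `nu` populated.
#' @export
assign_materials <- function(mesh, table = material_table()) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(table, "material_table"))
  codes <- label_codes()
  lab <- mesh$element_label
  known <- lab %in% codes[c("bone", "tooth", "implant")]
  if (!all(known)) {
    stop("elements with unknown label: ",
         paste(utils::head(which(!known), 10), collapse = ", "),
         call. = FALSE)
  }
  E <- numeric(length(lab))
  nu <- numeric(length(lab))
  is_bone <- lab == codes[["bone"]]
  if (any(is_bone)) {
    rho <- mesh$element_density[is_bone]
    if (any(!is.finite(rho))) {
      stop("bone elements must carry a finite density", call. = FALSE)
    }
    E[is_bone] <- density_to_modulus(rho)
    nu[is_bone] <- table$nu_bone
  }
  E[lab == codes[["tooth"]]] <- table$E_tooth
  nu[lab == codes[["tooth"]]] <- table$nu_tooth
  E[lab == codes[["implant"]]] <- table$E_implant
  nu[lab == codes[["implant"]]] <- table$nu_implant
  mesh$E <- E
  mesh$nu <- nu
  mesh
}
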