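#' Parameters of the synthetic mandibular-segment phantom
#'
#' The phantom is a curved rectangular-section prism standing in for a
#' posterior mandibular segment: a dense cortical shell wraps a noisy
#' trabecular interior, and one or more teeth (cylinders with their roots in
#' the bone and crowns above the ridge crest) sit on the arch. CT number
#' defaults are expressed on the raw scanner scale the density calibration
#' `rho = ct * 0.945e-4` expects, chosen so cortical bone lands around
#' 1.3 gf/cc (modulus ~18 GPa), trabecular bone around 0.45 gf/cc
#' (~3 GPa), and the trabecular noise spread exercises all three nonzero
#' branches of the bone constitutive law.
#'
#' @param extent integer length-3, number of voxels in x (mesiodistal),
#'   y (buccolingual) and z (inferosuperior). Minimum 20 each.
#' @param spacing voxel edge length in mm.
#' @param ridge_width buccolingual width of the bone band (mm).
#' @param bone_height height of the bone from inferior border to crest (mm).
#' @param shell_thickness cortical shell thickness (mm); applied at the
#'   buccal/lingual surfaces, the inferior border and the crest.
#' @param arch_radius radius of the dental arch the segment follows (mm);
#'   `Inf` gives a straight prism.
#' @param cortical_hu,cortical_sd mean and standard deviation of cortical CT
#'   numbers.
#' @param trabecular_hu,trabecular_sd mean and standard deviation of
#'   trabecular CT numbers.
#' @param tooth_hu CT number assigned to tooth voxels (noise-free).
#' @param noise_correlation_mm correlation length of the Gaussian CT noise
#'   field (mm). The constitutive calibration maps apparent (continuum)
#'   density, which varies smoothly at the millimetre scale; uncorrelated
#'   per-voxel noise would instead emulate unresolved trabecular
#'   microstructure. Set to 0 for white noise.
#' @param teeth data frame with one row per tooth: columns `x_mm` (position
#'   along the segment), `radius`, `root_depth`, `crown_height` (all mm).
#'   `NULL` places a single tooth at the centre of the segment.
#' @param seed integer seed driving the Gaussian CT noise.
#'
#' @return An object of class `mandible_phantom_params`.
#' @export
mandible_phantom_params <- function(extent = c(32L, 34L, 76L),
                                    spacing = 0.39,
                                    ridge_width = 11.7,
                                    bone_height = 21,
                                    shell_thickness = 1.56,
                                    arch_radius = 30,
                                    cortical_hu = 14000, cortical_sd = 700,
                                    trabecular_hu = 4800, trabecular_sd = 1600,
                                    tooth_hu = 20000,
                                    noise_correlation_mm = 1.2,
                                    teeth = NULL,
                                    seed = 1L) {
  extent <- as.integer(extent)
  if (length(extent) != 3L || any(extent < 20L)) {
    stop("`extent` must give at least 20 voxels along each axis",
         call. = FALSE)
  }
  if (cortical_hu <= trabecular_hu || trabecular_hu <= 0) {
    stop("need cortical_hu > trabecular_hu > 0", call. = FALSE)
  }
  if (shell_thickness < spacing) {
    stop("`shell_thickness` must be at least one voxel", call. = FALSE)
  }
  if (shell_thickness > min(extent) * spacing / 2) {
    stop("invalid geometry: `shell_thickness` exceeds half the smallest ",
         "extent", call. = FALSE)
  }
  if (is.null(teeth)) {
    teeth <- tibble::tibble(
      x_mm = extent[1] * spacing / 2,
      radius = 4.5, root_depth = 9, crown_height = 6
    )
  }
  teeth <- tibble::as_tibble(teeth)
  stopifnot(all(c("x_mm", "radius", "root_depth", "crown_height") %in%
                  names(teeth)))
  p <- list(
    extent = extent, spacing = spacing,
    ridge_width = ridge_width, bone_height = bone_height,
    shell_thickness = shell_thickness, arch_radius = arch_radius,
    cortical_hu = cortical_hu, cortical_sd = cortical_sd,
    trabecular_hu = trabecular_hu, trabecular_sd = trabecular_sd,
    tooth_hu = tooth_hu, noise_correlation_mm = noise_correlation_mm,
    teeth = teeth, seed = as.integer(seed)
  )
  class(p) <- "mandible_phantom_params"
  p
}

# lingual-ward offset of the arch centreline at position x (mm)
arch_center_y <- function(x_mm, params) {
  y_mid <- params$extent[2] * params$spacing / 2
  if (!is.finite(params$arch_radius)) return(rep(y_mid, length(x_mm)))
  x_mid <- params$extent[1] * params$spacing / 2
  dx <- x_mm - x_mid
  if (any(abs(dx) >= params$arch_radius)) {
    stop("`arch_radius` must exceed the half-length of the segment",
         call. = FALSE)
  }
  y_mid + (sqrt(params$arch_radius^2 - dx^2) - params$arch_radius)
}

#' Generate a synthetic mandibular-segment CT volume
#'
#' Builds the phantom described by [mandible_phantom_params()]: a closed
#' cortical shell enclosing a trabecular interior, with tooth cylinders
#' rooted in the bone, and Gaussian noise on the bone CT numbers. Output is
#' a pure function of the parameters (including their seed). The generator
#' never emits implant labels. After generation the derived densities of the
#' bone voxels are checked against the three nonzero branches of the bone
#' constitutive law; an empty branch raises a warning.
#'
#' @param params a [mandible_phantom_params()] object.
#' @return A [voxel_volume()] with labels background/bone/tooth and a
#'   `tooth_ids` grid identifying individual teeth. The per-branch bone
#'   voxel counts are attached as attribute `"branch_counts"`.
#' @export
generate_mandible_volume <- function(params = mandible_phantom_params()) {
  stopifnot(inherits(params, "mandible_phantom_params"))
  d <- params$extent
  h <- params$spacing
  # voxel centre coordinates (mm)
  cx <- (seq_len(d[1]) - 0.5) * h
  cy <- (seq_len(d[2]) - 0.5) * h
  cz <- (seq_len(d[3]) - 0.5) * h
  yc <- arch_center_y(cx, params)            # centreline per x column

  X <- array(rep(cx, times = d[2] * d[3]), dim = d)
  Yabs <- array(rep(rep(cy, each = d[1]), times = d[3]), dim = d)
  Yc <- array(rep(yc, times = d[2] * d[3]), dim = d)
  Ydev <- Yabs - Yc
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)

  half_w <- params$ridge_width / 2
  bone <- abs(Ydev) <= half_w & Z <= params$bone_height
  shell <- params$shell_thickness
  cortical <- bone & (
    Z <= shell |
      Z >= params$bone_height - shell |
      abs(Ydev) >= half_w - shell
  )

  codes <- label_codes()
  labels <- array(codes[["background"]], dim = d)
  labels[bone] <- codes[["bone"]]

  tooth_ids <- array(0L, dim = d)
  crest <- params$bone_height
  for (t in seq_len(nrow(params$teeth))) {
    tt <- params$teeth[t, ]
    yct <- arch_center_y(tt$x_mm, params)
    in_tooth <- (X - tt$x_mm)^2 + (Yabs - yct)^2 <= tt$radius^2 &
      Z >= crest - tt$root_depth & Z <= crest + tt$crown_height
    labels[in_tooth] <- codes[["tooth"]]
    tooth_ids[in_tooth] <- t
  }
  storage.mode(labels) <- "integer"

  ct <- withr::with_seed(params$seed, {
    v <- array(0, dim = d)
    is_trab <- labels == codes[["bone"]] & !cortical
    is_cort <- labels == codes[["bone"]] & cortical
    # one standardised correlated field drives both tissue classes
    S <- correlated_noise_field(d, params$noise_correlation_mm / h)
    v[is_trab] <- params$trabecular_hu + params$trabecular_sd * S[is_trab]
    v[is_cort] <- params$cortical_hu + params$cortical_sd * S[is_cort]
    v[labels == codes[["tooth"]]] <- params$tooth_hu
    v
  })

  vol <- voxel_volume(ct, spacing = h, origin = c(0, 0, 0), labels = labels,
                      tooth_ids = tooth_ids)
  # branch population check against the bone constitutive law
  rho <- hu_to_density(ct[labels == codes[["bone"]]])
  branch_counts <- c(
    low = sum(rho > 0 & rho <= 0.27),
    mid = sum(rho > 0.27 & rho < 0.6),
    high = sum(rho >= 0.6)
  )
  if (any(branch_counts == 0L)) {
    warning("bone densities do not populate all three nonzero branches of ",
            "the constitutive law (counts: ",
            paste(sprintf("%s=%d", names(branch_counts), branch_counts),
                  collapse = ", "), ")", call. = FALSE)
  }
  attr(vol, "branch_counts") <- branch_counts
  attr(vol, "params") <- params
  vol
}


# Standard-normal field with a Gaussian correlation kernel (sigma in
# voxels): separable smoothing of white noise, kernel scaled to unit l2
# norm per axis so the marginal variance is preserved away from the edges.
correlated_noise_field <- function(d, sigma_vox) {
  z <- array(stats::rnorm(prod(d)), dim = d)
  if (sigma_vox <= 0) return(z)
  half <- max(1L, ceiling(2 * sigma_vox))
  w <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  w <- w / sqrt(sum(w^2))
  shift_axis <- function(a, o, axis) {
    # shift array a by o voxels along axis, zero-padded
    idx_src <- lapply(dim(a), seq_len)
    idx_dst <- idx_src
    n <- dim(a)[axis]
    if (o > 0) { idx_dst[[axis]] <- (1 + o):n; idx_src[[axis]] <- 1:(n - o) }
    if (o < 0) { idx_dst[[axis]] <- 1:(n + o); idx_src[[axis]] <- (1 - o):n }
    out <- array(0, dim = dim(a))
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(do.call(`[`, c(list(a), idx_src)))))
    out
  }
  for (axis in 1:3) {
    acc <- array(0, dim = d)
    for (k in seq_along(w)) {
      o <- k - half - 1L
      acc <- acc + w[k] * if (o == 0) z else shift_axis(z, o, axis)
    }
    z <- acc
  }
  z
}
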