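# Shape-function gradients of every constant-strain tetrahedron, vectorised
# over elements. Returns list(gx, gy, gz) of n_elem x 4 matrices and the
# element volumes.
tet_gradients <- function(mesh) {
  n <- mesh$nodes; el <- mesh$elements
  a <- n[el[, 1], , drop = FALSE]
  e1 <- n[el[, 2], , drop = FALSE] - a
  e2 <- n[el[, 3], , drop = FALSE] - a
  e3 <- n[el[, 4], , drop = FALSE] - a
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cr(e2, e3); c31 <- cr(e3, e1); c12 <- cr(e1, e2)
  detJ <- rowSums(e1 * c23)
  if (any(detJ <= 0)) {
    stop("inverted element(s): ", paste(utils::head(which(detJ <= 0), 5),
                                        collapse = ", "), call. = FALSE)
  }
  g2 <- c23 / detJ; g3 <- c31 / detJ; g4 <- c12 / detJ
  g1 <- -(g2 + g3 + g4)
  list(
    gx = cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
    gy = cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
    gz = cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3]),
    vol = detJ / 6
  )
}

#' Stiffness matrix of a single 4-node tetrahedron
#'
#' Constant-strain formulation with exact one-point integration, for an
#' isotropic linear elastic material. The returned 12x12 block orders
#' degrees of freedom node-major (ux1, uy1, uz1, ux2, ...). It is symmetric,
#' positive semidefinite, and annihilates the six rigid-body modes.
#'
#' @param coords 4x3 matrix of node coordinates (mm), positively oriented.
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio, in (0, 0.5).
#' @return A 12x12 numeric matrix (N/mm per mm of displacement).
#' @export
element_stiffness <- function(coords, E, nu) {
  stopifnot(is.matrix(coords), nrow(coords) == 4, ncol(coords) == 3,
            E > 0, nu > 0, nu < 0.5)
  mesh <- structure(list(nodes = coords,
                         elements = matrix(1:4, 1, 4)),
                    class = "tet_mesh")
  g <- tet_gradients(mesh)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  G <- rbind(g$gx[1, ], g$gy[1, ], g$gz[1, ])  # 3 x 4, gradient of shape a
  K <- matrix(0, 12, 12)
  for (a in 1:4) {
    for (b in 1:4) {
      ga <- G[, a]; gb <- G[, b]
      block <- lam * outer(ga, gb) + mu * outer(gb, ga) +
        mu * sum(ga * gb) * diag(3)
      K[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <- g$vol[1] * block
    }
  }
  K
}

#' Assemble the global sparse stiffness matrix
#'
#' Scatters every element stiffness block additively into a symmetric sparse
#' matrix of dimension `3 * n_nodes`. Materials must have been assigned with
#' [assign_materials()].
#'
#' @param mesh a `tet_mesh` with `E` and `nu` populated.
#' @return A symmetric sparse matrix (`Matrix::dsCMatrix`).
#' @export
assemble_stiffness <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(mesh$E) || is.null(mesh$nu)) {
    stop("materials not assigned; call assign_materials() first",
         call. = FALSE)
  }
  g <- tet_gradients(mesh)
  ne <- nrow(mesh$elements)
  lam <- mesh$E * mesh$nu / ((1 + mesh$nu) * (1 - 2 * mesh$nu))
  mu <- mesh$E / (2 * (1 + mesh$nu))
  vlam <- g$vol * lam
  vmu <- g$vol * mu
  gg <- list(g$gx, g$gy, g$gz)

  # preallocated triplet buffers, upper triangle only: the lower triangle is
  # implied by symmetry, which halves the dedup work in sparseMatrix()
  N <- 144L * ne
  ii <- integer(N); jj <- integer(N); xx <- numeric(N)
  pos <- 0L
  for (a in 1:4) {
    na <- mesh$elements[, a]
    for (b in 1:4) {
      nb <- mesh$elements[, b]
      dot_ab <- g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b] +
        g$gz[, a] * g$gz[, b]
      for (i in 1:3) {
        for (j in 1:3) {
          val <- vlam * gg[[i]][, a] * gg[[j]][, b] +
            vmu * gg[[i]][, b] * gg[[j]][, a]
          if (i == j) val <- val + vmu * dot_ab
          ii[(pos + 1L):(pos + ne)] <- 3L * (na - 1L) + i
          jj[(pos + 1L):(pos + ne)] <- 3L * (nb - 1L) + j
          xx[(pos + 1L):(pos + ne)] <- val
          pos <- pos + ne
        }
      }
    }
  }
  keep <- ii <= jj
  ndof <- 3L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                       dims = c(ndof, ndof), symmetric = TRUE)
}

#' Define the concentrated occlusal load case
#'
#' A single nodal force of the configured magnitude applied at `load_node`,
#' tilted by `angle_deg` away from the implant/tooth axis, acting from the
#' buccal side toward the lingual (+y) while pressing down the axis (-z).
#' The fixed node set is clamped in all three directions.
#'
#' @param load_node node id carrying the force.
#' @param fixed_nodes integer vector of fully clamped node ids; must be
#'   non-empty and must not contain `load_node`.
#' @param magnitude force magnitude in N (default 50).
#' @param angle_deg angle between the force and the implant axis in degrees
#'   (default 45).
#' @param axis unit implant/tooth axis (default +z).
#' @param lateral unit buccal-to-lingual direction (default +y).
#' @return An object of class `load_case` with fields `load_node`, `force`
#'   (length-3, N) and `fixed_nodes`.
#' @export
make_load_case <- function(load_node, fixed_nodes, magnitude = 50,
                           angle_deg = 45, axis = c(0, 0, 1),
                           lateral = c(0, 1, 0)) {
  if (magnitude <= 0) stop("load magnitude must be positive", call. = FALSE)
  if (length(fixed_nodes) == 0) stop("fixed node set is empty", call. = FALSE)
  if (load_node %in% fixed_nodes) {
    stop("load node must not be fixed", call. = FALSE)
  }
  axis <- axis / sqrt(sum(axis^2))
  lateral <- lateral - sum(lateral * axis) * axis
  lateral <- lateral / sqrt(sum(lateral^2))
  th <- angle_deg * pi / 180
  force <- magnitude * (sin(th) * lateral - cos(th) * axis)
  lc <- list(load_node = as.integer(load_node), force = force,
             fixed_nodes = as.integer(fixed_nodes),
             magnitude = magnitude, angle_deg = angle_deg, axis = axis)
  class(lc) <- "load_case"
  lc
}

# solve K u = f with homogeneous Dirichlet conditions on fixed_dofs;
# core used by solve_displacements() and by verification tests that need
# per-DOF constraints (e.g. uniaxial patch tests).
fem_solve <- function(K, f, fixed_dofs, method = c("direct", "cg"),
                      tol = 1e-8) {
  method <- match.arg(method)
  ndof <- nrow(K)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  if (length(free) == 0) stop("all degrees of freedom are fixed",
                              call. = FALSE)
  Kff <- K[free, free]
  ff <- f[free]
  uf <- if (method == "direct") {
    out <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                             super = TRUE)
      Matrix::solve(ch, ff)
    }, error = function(e) {
      stop("constrained system is singular; the fixed set ",
           "may not constrain all rigid modes (",
           conditionMessage(e), ")", call. = FALSE)
    })
    as.numeric(out)
  } else {
    pcg_solve(Kff, ff, tol = tol)
  }
  u <- numeric(ndof)
  u[free] <- uf
  # polish: verify the free-DOF residual
  fn <- sqrt(sum(ff^2))
  if (fn > 0) {
    res <- sqrt(sum((as.numeric(Kff %*% uf) - ff)^2)) / fn
    if (res > 1e-6) {
      stop(sprintf("solver residual %.3e exceeds tolerance", res),
           call. = FALSE)
    }
    attr(u, "residual") <- res
  } else {
    attr(u, "residual") <- 0
  }
  u
}

# Jacobi-preconditioned conjugate gradients on an SPD sparse matrix.
pcg_solve <- function(A, b, tol = 1e-8, maxit = 50000L) {
  dinv <- 1 / Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bn) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warning("conjugate gradients did not reach the requested tolerance",
          call. = FALSE)
  x
}

#' Solve the linear static elasticity problem
#'
#' Assembles (or reuses) the global stiffness, applies the load case, and
#' solves for nodal displacements with the inferior-border nodes clamped.
#' A direct sparse Cholesky factorisation is used up to
#' `direct_dof_limit` degrees of freedom, and Jacobi-preconditioned
#' conjugate gradients above it.
#'
#' @param mesh a `tet_mesh` with materials assigned.
#' @param load_case a [make_load_case()] object.
#' @param K optional pre-assembled stiffness from [assemble_stiffness()].
#' @param direct_dof_limit switch-over size for the iterative solver.
#' @param tol relative residual tolerance.
#' @return An object of class `displacement_field`: list with `u` (n_nodes x
#'   3 matrix, mm), `residual`, `reactions` (forces at fixed nodes, N),
#'   `equilibrium_gap` (norm of reactions + applied load, N) and `n_dof`.
#' @export
solve_displacements <- function(mesh, load_case, K = NULL,
                                direct_dof_limit = 3e5, tol = 1e-8) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(load_case, "load_case"))
  if (is.null(K)) K <- assemble_stiffness(mesh)
  ndof <- nrow(K)
  f <- numeric(ndof)
  ln <- load_case$load_node
  f[(3 * ln - 2):(3 * ln)] <- load_case$force
  fixed_dofs <- as.vector(rbind(3L * load_case$fixed_nodes - 2L,
                                3L * load_case$fixed_nodes - 1L,
                                3L * load_case$fixed_nodes))
  method <- if (ndof <= direct_dof_limit) "direct" else "cg"
  u <- fem_solve(K, f, fixed_dofs, method = method, tol = tol)
  # reaction forces r = K u - f at the fixed DOFs
  r_all <- as.numeric(K %*% u) - f
  reactions <- matrix(r_all[fixed_dofs], ncol = 3, byrow = TRUE)
  gap <- colSums(reactions) + load_case$force
  out <- list(
    u = matrix(u, ncol = 3, byrow = TRUE),
    residual = attr(u, "residual"),
    reactions = reactions,
    equilibrium_gap = gap,
    n_dof = ndof,
    method = method
  )
  class(out) <- "displacement_field"
  out
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d DOF (%s), residual %.2e, |equilibrium gap| %.2e N\n",
    x$n_dof, x$method, x$residual, sqrt(sum(x$equilibrium_gap^2))))
  invisible(x)
}

#' Recover element stresses from a displacement field
#'
#' Applies the constant-strain operator of every tetrahedron to the nodal
#' displacements, forms the symmetric stress tensor through the isotropic
#' Hooke law, and computes the von Mises equivalent stress.
#'
#' @param mesh a `tet_mesh` with materials assigned.
#' @param displacements a `displacement_field` (or an n_nodes x 3 matrix).
#' @return An object of class `stress_state`: list with `tensor` (n_elem x 6
#'   matrix, columns xx, yy, zz, xy, yz, zx, MPa) and `von_mises`
#'   (n_elem vector, MPa).
#' @export
recover_stress <- function(mesh, displacements) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (inherits(displacements, "displacement_field")) {
    displacements <- displacements$u
  }
  g <- tet_gradients(mesh)
  el <- mesh$elements
  ux <- matrix(displacements[el, 1], ncol = 4)
  uy <- matrix(displacements[el, 2], ncol = 4)
  uz <- matrix(displacements[el, 3], ncol = 4)
  exx <- rowSums(g$gx * ux)
  eyy <- rowSums(g$gy * uy)
  ezz <- rowSums(g$gz * uz)
  gxy <- rowSums(g$gy * ux + g$gx * uy)  # engineering shear strains
  gyz <- rowSums(g$gz * uy + g$gy * uz)
  gzx <- rowSums(g$gx * uz + g$gz * ux)
  lam <- mesh$E * mesh$nu / ((1 + mesh$nu) * (1 - 2 * mesh$nu))
  mu <- mesh$E / (2 * (1 + mesh$nu))
  tr <- exx + eyy + ezz
  tensor <- cbind(
    xx = lam * tr + 2 * mu * exx,
    yy = lam * tr + 2 * mu * eyy,
    zz = lam * tr + 2 * mu * ezz,
    xy = mu * gxy,
    yz = mu * gyz,
    zx = mu * gzx
  )
  out <- list(tensor = tensor, von_mises = von_mises(tensor))
  class(out) <- "stress_state"
  out
}

#' Von Mises equivalent stress from stress tensors
#'
#' @param tensor numeric matrix with columns xx, yy, zz, xy, yz, zx (MPa),
#'   or a length-6 vector.
#' @return Numeric vector of equivalent stresses (MPa).
#' @export
von_mises <- function(tensor) {
  if (is.null(dim(tensor))) tensor <- matrix(tensor, nrow = 1)
  sqrt(0.5 * ((tensor[, 1] - tensor[, 2])^2 +
                (tensor[, 2] - tensor[, 3])^2 +
                (tensor[, 3] - tensor[, 1])^2) +
         3 * (tensor[, 4]^2 + tensor[, 5]^2 + tensor[, 6]^2))
}

#' Principal stresses of a symmetric stress tensor
#'
#' @param tensor length-6 vector (xx, yy, zz, xy, yz, zx) or a matrix with
#'   those columns (one row per element).
#' @return For a single tensor, the sorted eigenvalues (sigma1 >= sigma2 >=
#'   sigma3, MPa); for a matrix, an n x 3 matrix of sorted eigenvalues.
#' @export
principal_stresses <- function(tensor) {
  one <- function(s) {
    m <- matrix(c(s[1], s[4], s[6],
                  s[4], s[2], s[5],
                  s[6], s[5], s[3]), 3, 3)
    sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }
  if (is.null(dim(tensor))) return(one(tensor))
  t(apply(tensor, 1, one))
}

#' Consistent nodal loads for a uniform traction on a boundary plane
#'
#' Finds the boundary triangles of the mesh whose nodes all lie on the plane
#' `axis = value` and distributes the traction consistently (one third of
#' traction times triangle area to each triangle node). Used by the
#' verification problems (patch/bar and cantilever bending tests).
#'
#' @param mesh a `tet_mesh`.
#' @param axis 1, 2 or 3 (x, y, z).
#' @param value plane coordinate in mm.
#' @param traction length-3 traction vector (N/mm^2).
#' @param tol coordinate tolerance in mm.
#' @return A `3 * n_nodes` load vector (N), plus attribute `"area"` with the
#'   loaded surface area (mm^2) and `"nodes"` with the loaded node ids.
#' @export
surface_traction_loads <- function(mesh, axis, value, traction, tol = 1e-9) {
  on_plane <- abs(mesh$nodes[, axis] - value) <= tol
  faces <- rbind(mesh$elements[, c(1, 2, 3)],
                 mesh$elements[, c(1, 2, 4)],
                 mesh$elements[, c(1, 3, 4)],
                 mesh$elements[, c(2, 3, 4)])
  keep <- on_plane[faces[, 1]] & on_plane[faces[, 2]] & on_plane[faces[, 3]]
  faces <- faces[keep, , drop = FALSE]
  if (nrow(faces) == 0) stop("no boundary faces on the requested plane",
                             call. = FALSE)
  p1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  e1 <- mesh$nodes[faces[, 2], , drop = FALSE] - p1
  e2 <- mesh$nodes[faces[, 3], , drop = FALSE] - p1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  # scatter with accumulation (nodes appear in several faces)
  f <- numeric(3 * nrow(mesh$nodes))
  for (k in 1:3) {
    if (traction[k] == 0) next
    contrib <- rep(area / 3 * traction[k], times = 3)
    nd <- c(faces[, 1], faces[, 2], faces[, 3])
    agg <- rowsum(contrib, nd)
    ids <- as.integer(rownames(agg))
    f[3 * (ids - 1) + k] <- agg[, 1]
  }
  attr(f, "area") <- sum(area)
  attr(f, "nodes") <- sort(unique(as.vector(faces)))
  f
}
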