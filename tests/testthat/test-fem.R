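# independent energy-based oracle for the constant-strain tet block:
# strain energy of a linear displacement field, differentiated numerically
energy_hessian_oracle <- function(coords, E, nu) {
  grads <- solve(cbind(1, coords))[-1, ]  # rows x,y,z of shape gradients
  vol <- abs(det(cbind(1, coords))) / 6
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  energy <- function(u) {
    U <- matrix(u, 4, 3, byrow = TRUE)           # nodal displacements
    H <- grads %*% U                             # displacement gradient^T
    eps <- (H + t(H)) / 2
    vol * (lam / 2 * sum(diag(eps))^2 + mu * sum(eps * eps))
  }
  K <- matrix(0, 12, 12)
  d <- 1e-4
  for (i in 1:12) {
    for (j in i:12) {
      ei <- ej <- numeric(12); ei[i] <- d; ej[j] <- d
      K[i, j] <- K[j, i] <-
        (energy(ei + ej) - energy(ei) - energy(ej) + energy(numeric(12))) / d^2
    }
  }
  K
}

ref_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

test_that("element stiffness matches the energy-difference oracle", {
  K <- element_stiffness(ref_tet, E = 1, nu = 0.25)
  expect_equal(K, energy_hessian_oracle(ref_tet, 1, 0.25), tolerance = 1e-7)
  # a skewed tet too
  skew <- rbind(c(0, 0, 0), c(2, 0.3, 0), c(0.5, 1.5, 0.2), c(0.1, 0.4, 1.1))
  K2 <- element_stiffness(skew, E = 3200, nu = 0.4)
  expect_equal(K2, energy_hessian_oracle(skew, 3200, 0.4), tolerance = 1e-4)
})

test_that("element stiffness is symmetric PSD with a 6-dim rigid nullspace", {
  K <- element_stiffness(ref_tet, E = 1000, nu = 0.3)
  expect_equal(max(abs(K - t(K))), 0)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-9 * max(ev)))
  expect_identical(sum(abs(ev) < 1e-9 * max(ev)), 6L)
  # rigid translation produces zero force
  for (dir in 1:3) {
    u <- numeric(12); u[seq(dir, 12, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
  }
  # inverted element rejected
  inv <- ref_tet[c(1, 2, 4, 3), ]
  expect_error(element_stiffness(inv, 1, 0.25), "inverted")
})

test_that("sparse assembly equals dense brute-force assembly", {
  # single element: global equals the element block
  single <- structure(list(
    nodes = ref_tet, elements = matrix(1:4, 1, 4),
    E = 500, nu = 0.3, spacing = 1), class = "tet_mesh")
  Ks <- as.matrix(assemble_stiffness(single))
  expect_equal(Ks, element_stiffness(ref_tet, 500, 0.3), tolerance = 1e-12)

  # two disconnected elements: block diagonal
  two <- structure(list(
    nodes = rbind(ref_tet, ref_tet + 10),
    elements = rbind(1:4, 5:8),
    E = c(500, 800), nu = c(0.3, 0.2), spacing = 1), class = "tet_mesh")
  K2 <- as.matrix(assemble_stiffness(two))
  expect_equal(max(abs(K2[1:12, 13:24])), 0)
  expect_equal(K2[13:24, 13:24], element_stiffness(ref_tet + 10, 800, 0.2),
               tolerance = 1e-12)

  # 2x2x2 voxel mesh against the dense oracle
  mesh <- bar_mesh(2, 2, 2, E = 1500, nu = 0.33)
  expect_equal(as.matrix(assemble_stiffness(mesh)), dense_assembly(mesh),
               tolerance = 1e-12)
})

test_that("assembly requires materials", {
  mesh <- voxel_to_tets(bar_volume(1, 1, 1))
  expect_error(assemble_stiffness(mesh), "materials not assigned")
})

test_that("solver reproduces a dense reference solution", {
  mesh <- bar_mesh(2, 2, 2, E = 2000, nu = 0.3)  # 81 DOF
  f <- numeric(3 * nrow(mesh$nodes))
  top <- which(mesh$nodes[, 3] == 2)
  f[3 * top] <- -1
  fixed <- which(mesh$nodes[, 3] == 0)
  fixed_dofs <- as.vector(rbind(3 * fixed - 2, 3 * fixed - 1, 3 * fixed))
  sol <- solve_with_dofs(mesh, f, fixed_dofs)
  free <- setdiff(seq_along(f), fixed_dofs)
  Kd <- dense_assembly(mesh)
  u_oracle <- numeric(length(f))
  u_oracle[free] <- solve(Kd[free, free], f[free])
  expect_equal(as.vector(t(sol$u)), u_oracle, tolerance = 1e-8)
})

test_that("zero load gives zero displacement and solve flags singularity", {
  mesh <- bar_mesh(1, 1, 2)
  fixed <- select_fixed_nodes(mesh)
  lc <- make_load_case(which.max(mesh$nodes[, 3]), fixed)
  lc$force <- c(0, 0, 0) * lc$force
  f <- numeric(3 * nrow(mesh$nodes))
  fixed_dofs <- as.vector(rbind(3 * fixed - 2, 3 * fixed - 1, 3 * fixed))
  sol <- solve_with_dofs(mesh, f, fixed_dofs)
  expect_true(all(sol$u == 0))
  # under-constrained: no fixed DOFs at all
  f[5] <- 1
  suppressWarnings(
    expect_error(implantfem:::fem_solve(assemble_stiffness(mesh), f,
                                        integer(0)),
                 "singular|rigid"))
})

test_that("uniaxial bar carries exactly uniform stress F/A (patch test)", {
  mesh <- bar_mesh(2, 2, 10, E = 1000, nu = 0.25)
  # traction 1 MPa on the top face; bottom face held axially, two nodes pin
  # the lateral rigid modes so Poisson contraction stays free
  f <- surface_traction_loads(mesh, axis = 3, value = 10, c(0, 0, 1))
  area <- attr(f, "area")
  expect_equal(area, 4)
  bottom <- which(mesh$nodes[, 3] == 0)
  fixed_dofs <- 3 * bottom
  corner <- bottom[mesh$nodes[bottom, 1] == 0 & mesh$nodes[bottom, 2] == 0]
  corner2 <- bottom[mesh$nodes[bottom, 1] == 2 & mesh$nodes[bottom, 2] == 0]
  fixed_dofs <- c(fixed_dofs, 3 * corner - 2, 3 * corner - 1, 3 * corner2 - 1)
  sol <- solve_with_dofs(mesh, f, fixed_dofs)
  st <- recover_stress(mesh, sol$u)
  expect_equal(st$tensor[, 3], rep(1, nrow(mesh$elements)), tolerance = 1e-8)
  expect_lt(max(abs(st$tensor[, -3])), 1e-8)
  expect_equal(st$von_mises, rep(1, nrow(mesh$elements)), tolerance = 1e-8)
})

test_that("cantilever tip deflection approaches the beam closed form", {
  # 8x8x80 voxel beam (1 mm voxels), end shear load; Euler-Bernoulli
  # reference F L^3 / (3 E I). Constant-strain tets converge from the stiff
  # side; 8 elements through the thickness brings the error under 5%
  E <- 1000; nu <- 0.3; L <- 80; hsec <- 8
  mesh <- bar_mesh(hsec, hsec, L, E = E, nu = nu)
  f <- surface_traction_loads(mesh, axis = 3, value = L, c(1, 0, 0) * 0.01)
  Ftot <- 0.01 * attr(f, "area")
  bottom <- which(mesh$nodes[, 3] == 0)
  fixed_dofs <- as.vector(rbind(3 * bottom - 2, 3 * bottom - 1, 3 * bottom))
  sol <- solve_with_dofs(mesh, f, fixed_dofs)
  I <- hsec^4 / 12
  delta_beam <- Ftot * L^3 / (3 * E * I)
  tip <- which(mesh$nodes[, 3] == L)
  delta_fem <- mean(sol$u[tip, 1])
  expect_lt(abs(delta_fem - delta_beam) / delta_beam, 0.05)
})

test_that("solution scales linearly with load and inversely with stiffness", {
  vol <- tiny_extracted_volume()
  res <- solve_configuration(vol, implant_spec(4.3, 6, supracrestal_height = 5),
                             load_magnitude = 50)
  res2 <- solve_configuration(vol, implant_spec(4.3, 6, supracrestal_height = 5),
                              load_magnitude = 100)
  # the loaded node sits on the buccal half of the crown
  load_y <- res$mesh$nodes[res$load_case$load_node, 2]
  expect_lt(load_y, res$mesh$placement$entry[2])
  expect_equal(2 * res$displacements$u, res2$displacements$u,
               tolerance = 1e-8)
  expect_equal(2 * res$stress$von_mises, res2$stress$von_mises,
               tolerance = 1e-8)

  # scaling all moduli leaves stress unchanged, divides displacements
  mesh <- res$mesh
  beta <- 3
  mesh_b <- mesh; mesh_b$E <- beta * mesh_b$E
  lc <- res$load_case
  disp_b <- solve_displacements(mesh_b, lc)
  expect_equal(disp_b$u, res$displacements$u / beta, tolerance = 1e-7)
  st_b <- recover_stress(mesh_b, disp_b)
  expect_equal(st_b$von_mises, res$stress$von_mises, tolerance = 1e-7)
})

test_that("von Mises closed forms and invariances hold", {
  expect_equal(von_mises(c(10, 0, 0, 0, 0, 0)), 10)
  expect_equal(von_mises(c(0, 0, 0, 1, 0, 0)), sqrt(3))
  expect_equal(von_mises(c(5, 5, 5, 0, 0, 0)), 0)
  # rigid-body displacement of any mesh produces zero stress
  mesh <- bar_mesh(2, 2, 2)
  u <- cbind(rep(1, nrow(mesh$nodes)), rep(-2, nrow(mesh$nodes)),
             rep(0.5, nrow(mesh$nodes)))
  st <- recover_stress(mesh, u)
  expect_lt(max(st$von_mises), 1e-9)
  # rotation invariance under random rotations
  withr::with_seed(3, {
    for (rep in 1:5) {
      s <- runif(6, -5, 5)
      M <- matrix(c(s[1], s[4], s[6], s[4], s[2], s[5], s[6], s[5], s[3]),
                  3, 3)
      A <- matrix(rnorm(9), 3, 3)
      R <- qr.Q(qr(A))
      Mr <- R %*% M %*% t(R)
      sr <- c(Mr[1, 1], Mr[2, 2], Mr[3, 3], Mr[1, 2], Mr[2, 3], Mr[1, 3])
      expect_equal(von_mises(sr), von_mises(s), tolerance = 1e-10)
    }
  })
})

test_that("principal stresses are the ordered tensor eigenvalues", {
  expect_equal(principal_stresses(c(10, 0, 0, 0, 0, 0)), c(10, 0, 0))
  expect_equal(principal_stresses(c(5, 5, 5, 0, 0, 0)), c(5, 5, 5))
  expect_equal(principal_stresses(c(0, 0, 0, 1, 0, 0)), c(1, 0, -1))
  # matrix form returns one row per element
  P <- principal_stresses(rbind(c(10, 0, 0, 0, 0, 0), c(0, 0, 0, 1, 0, 0)))
  expect_equal(P[2, ], c(1, 0, -1))
})

test_that("oblique load case makes the configured angle with the axis", {
  lc <- make_load_case(5, 1:3, magnitude = 50, angle_deg = 45)
  expect_equal(sqrt(sum(lc$force^2)), 50, tolerance = 1e-12)
  cosang <- sum(lc$force * c(0, 0, -1)) / sqrt(sum(lc$force^2))
  expect_lt(abs(acos(cosang) - pi / 4), 1e-9)
  # buccal-to-lingual: the lateral component points to +y
  expect_gt(lc$force[2], 0)
  expect_lt(lc$force[3], 0)
  expect_error(make_load_case(1, 1:3), "not be fixed")
  expect_error(make_load_case(5, integer(0)), "empty")
  expect_error(make_load_case(5, 1:3, magnitude = -1), "positive")
})
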