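test_that("a single voxel splits into 5 positive tets filling the cube", {
  h <- 0.5
  mesh <- voxel_to_tets(bar_volume(1, 1, 1, spacing = h))
  expect_identical(nrow(mesh$elements), 5L)
  expect_identical(nrow(mesh$nodes), 8L)
  vols <- tet_volumes(mesh)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), h^3, tolerance = 1e-12)
})

test_that("a 2x1x1 block meshes conformally with shared nodes", {
  mesh <- voxel_to_tets(bar_volume(2, 1, 1))
  expect_identical(nrow(mesh$elements), 10L)
  expect_identical(nrow(mesh$nodes), 12L)  # 2 cubes sharing a 4-node face
  expect_equal(sum(tet_volumes(mesh)), 2, tolerance = 1e-12)

  # brute-force face hashing: interior faces are shared by exactly 2 tets
  faces <- rbind(mesh$elements[, c(1, 2, 3)], mesh$elements[, c(1, 2, 4)],
                 mesh$elements[, c(1, 3, 4)], mesh$elements[, c(2, 3, 4)])
  keys <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  counts <- table(keys)
  expect_true(all(counts <= 2))
  # Euler sanity: some faces are boundary (count 1), some interior (count 2)
  expect_true(any(counts == 1) && any(counts == 2))
})

test_that("mesh volume equals voxel volume on noisy multi-label volumes", {
  vol <- generate_mandible_volume(tiny_phantom_params())
  vol <- fill_enclosed_pores(segment_roi(vol, 1200, 17500))
  mesh <- voxel_to_tets(vol)
  n_vox <- sum(vol$labels != label_codes()[["background"]])
  expect_equal(sum(tet_volumes(mesh)), n_vox * vol$spacing^3,
               tolerance = 1e-10)
  # element labels inherit from voxels (5 per voxel)
  expect_identical(nrow(mesh$elements), 5L * n_vox)
  expect_true(all(mesh$element_label ==
                    rep(vol$labels[vol$labels != 0L], each = 5L)))
  # bone densities carried per element
  is_bone <- mesh$element_label == label_codes()[["bone"]]
  expect_true(all(is.finite(mesh$element_density[is_bone])))
})

test_that("cube decomposition quality is a fixed constant per voxel", {
  # min dihedral angle is identical across voxels of either parity
  min_dihedral <- function(mesh, e) {
    p <- mesh$nodes[mesh$elements[e, ], ]
    combs <- utils::combn(4, 3)
    normals <- apply(combs, 2, function(id) {
      a <- p[id[2], ] - p[id[1], ]; b <- p[id[3], ] - p[id[1], ]
      n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
      n / sqrt(sum(n^2))
    })
    ang <- c()
    for (i in 1:3) for (j in (i + 1):4) {
      ang <- c(ang, acos(pmin(1, abs(sum(normals[, i] * normals[, j])))))
    }
    min(pi - ang)
  }
  mesh <- voxel_to_tets(bar_volume(2, 2, 2))
  q <- vapply(seq_len(nrow(mesh$elements)), function(e) min_dihedral(mesh, e),
              numeric(1))
  per_voxel <- matrix(q, nrow = 5)
  expect_equal(apply(per_voxel, 2, min),
               rep(min(q), ncol(per_voxel)), tolerance = 1e-12)
})

test_that("empty label selections are rejected", {
  vol <- bar_volume(2, 2, 2)
  expect_error(voxel_to_tets(vol, include_labels = "implant"),
               "no voxel")
  expect_error(voxel_to_tets(vol, include_labels = "granite"), "unknown")
})

test_that("fixed-node selection takes the inferior voxel layer", {
  mesh <- voxel_to_tets(bar_volume(1, 1, 1))
  fixed <- select_fixed_nodes(mesh)
  # one cube: the bottom layer (z <= spacing) is all 8 nodes
  expect_identical(sort(fixed), 1:8)

  mesh3 <- voxel_to_tets(bar_volume(2, 2, 3))
  fixed3 <- select_fixed_nodes(mesh3)
  expect_true(all(mesh3$nodes[fixed3, 3] <= min(mesh3$nodes[, 3]) +
                    mesh3$spacing + 1e-9))
  expect_identical(length(fixed3), 18L)  # two node planes of 3x3

  # translation invariance in z
  shifted <- mesh3
  shifted$nodes[, 3] <- shifted$nodes[, 3] + 10
  expect_identical(length(select_fixed_nodes(shifted)), length(fixed3))
})

test_that("load node selection is deterministic and implant-bound", {
  mesh <- voxel_to_tets(bar_volume(2, 2, 2))
  expect_error(select_load_node(mesh), "no implant")

  vol <- bar_volume(2, 2, 2)
  vol$labels[] <- label_codes()[["implant"]]
  imesh <- voxel_to_tets(vol)
  # two equidistant candidates: the lower node id wins
  target <- c(0.5, 0, 2)  # between two top-edge lattice nodes
  n1 <- select_load_node(imesh, target = target)
  d2 <- colSums((t(imesh$nodes) - target)^2)
  ties <- which(abs(d2 - min(d2)) < 1e-12)
  expect_gt(length(ties), 1)
  expect_identical(n1, min(ties))
})
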