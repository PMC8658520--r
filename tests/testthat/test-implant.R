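test_that("design grid enumerates the Cartesian product diameter-major", {
  grid <- enumerate_design_grid()
  expect_identical(nrow(grid), 12L)
  expect_identical(grid$diameter, rep(c(3.8, 4.3, 6.0), each = 4))
  expect_identical(grid$length, rep(c(9, 11, 13, 16), times = 3))

  one <- enumerate_design_grid(4.0, 10.0)
  expect_identical(nrow(one), 1L)

  eight <- enumerate_design_grid(c(3.8, 4.3), c(9, 11, 13, 16))
  expect_identical(nrow(eight), 8L)
  expect_identical(eight$diameter, rep(c(3.8, 4.3), each = 4))

  expect_error(enumerate_design_grid(numeric(0)), "non-empty")

  # the supracrestal lever arm is identical across every spec of a sweep
  heights <- vapply(grid$spec, function(s) s$supracrestal_height, numeric(1))
  expect_identical(length(unique(heights)), 1L)
})

test_that("implant specs reject non-physical dimensions", {
  expect_error(implant_spec(0, 9), "positive")
  expect_error(implant_spec(4, -1), "positive")
  expect_error(implant_spec(4, 9, supracrestal_height = 1, crown_height = 3),
               "crown")
})

test_that("virtual extraction relabels the root and clears the crown", {
  vol <- generate_mandible_volume(tiny_phantom_params())
  vol <- fill_enclosed_pores(segment_roi(vol, 1200, 17500))
  codes <- label_codes()
  before <- label_counts(vol)
  crest_z <- 12.09  # top face of the crest voxel layer (31 voxels * 0.39)

  ext <- virtual_extraction(vol, 1L)
  after <- label_counts(ext)
  # all tooth voxels are gone
  expect_identical(unname(after[["tooth"]]), 0L)
  # sub-crestal root voxels became bone, supra-crestal crown background
  ctr <- implantfem:::voxel_centers(vol, which(vol$labels == codes[["tooth"]]))
  n_root <- sum(ctr[, 3] < ext$socket$crest_z)
  n_crown <- sum(ctr[, 3] >= ext$socket$crest_z)
  expect_identical(unname(after[["bone"]] - before[["bone"]]), n_root)
  expect_identical(unname(after[["background"]] - before[["background"]]),
                   n_crown)
  # total conserved
  expect_identical(sum(after), sum(before))
  # graft fill is the trabecular mean around the socket: below cortical CT
  expect_lt(ext$socket$fill_ct, 9000)
  expect_gt(ext$socket$fill_ct, 1200)

  expect_error(virtual_extraction(ext, 1L), "no teeth")
  expect_error(virtual_extraction(vol, 5L), "unknown tooth_id")
})

test_that("a root-only tooth converts voxel-for-voxel to bone", {
  # tooth fully below the crest: the classical count identity holds
  p <- tiny_phantom_params(
    teeth = data.frame(x_mm = 24 * 0.39 / 2, radius = 2.0,
                       root_depth = 5, crown_height = -0.2))
  vol <- generate_mandible_volume(p)
  vol <- fill_enclosed_pores(segment_roi(vol, 1200, 17500))
  before <- label_counts(vol)
  n_tooth <- unname(before[["tooth"]])
  expect_gt(n_tooth, 0)
  ext <- virtual_extraction(vol, 1L)
  after <- label_counts(ext)
  expect_identical(unname(after[["tooth"]]), 0L)
  expect_identical(unname(after[["bone"]] - before[["bone"]]), n_tooth)
  expect_identical(unname(after[["background"]]),
                   unname(before[["background"]]))
})

test_that("placement voxelises the analytic solid within 10%", {
  vol <- tiny_extracted_volume()
  spec <- implant_spec(3.8, 9.0, supracrestal_height = 5)
  placed <- place_implant(vol, spec)
  n_imp <- sum(placed$labels == label_codes()[["implant"]])
  expected <- implant_solid_volume(spec) / vol$spacing^3
  expect_lt(abs(n_imp - expected) / expected, 0.10)
})

test_that("placement is idempotent and conserves the voxel count", {
  vol <- tiny_extracted_volume()
  spec <- implant_spec(4.3, 6, supracrestal_height = 5)
  p1 <- place_implant(vol, spec)
  p2 <- place_implant(p1, spec)
  expect_identical(p1$labels, p2$labels)
  expect_identical(sum(label_counts(p1)), sum(label_counts(vol)))
  # labels changed only inside the implant solid
  changed <- which(p1$labels != vol$labels)
  expect_true(all(p1$labels[changed] == label_codes()[["implant"]]))
})

test_that("narrow implants fit inside the footprint of wide ones", {
  vol <- tiny_extracted_volume()
  narrow <- place_implant(vol, implant_spec(3.8, 6, supracrestal_height = 5))
  wide <- place_implant(vol, implant_spec(6.0, 6, supracrestal_height = 5))
  codes <- label_codes()
  n_set <- which(narrow$labels == codes[["implant"]])
  w_set <- which(wide$labels == codes[["implant"]])
  # intrabony footprint containment (crown blocks are identical)
  expect_true(all(n_set %in% w_set))
})

test_that("placements that exit the bone are rejected with the overshoot", {
  vol <- tiny_extracted_volume()  # 12 mm of bone
  err <- expect_error(place_implant(vol, implant_spec(3.8, 13)),
                      "inferior cortical border")
  expect_match(conditionMessage(err), "[0-9.]+ mm")
  # placement into an unextracted volume is refused
  raw <- generate_mandible_volume(tiny_phantom_params())
  raw <- fill_enclosed_pores(segment_roi(raw, 1200, 17500))
  raw$socket <- list(center = c(4.68, 5.46), crest_z = 12.09)
  expect_error(place_implant(raw, implant_spec(3.8, 6)), "tooth")
})
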