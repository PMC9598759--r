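grey_from_labels <- function(vol, fg = 800, bg = -1000, noise_sd = 0,
                             seed = 1) {
  imap <- c(air = bg, stats::setNames(rep(fg, length(vol$label_map)),
                                      names(vol$label_map)))
  add_acquisition_noise(vol, imap, noise_sd = noise_sd, seed = seed)
}

test_that("thresholding recovers the cast foreground", {
  v <- fix_raster("normal", c(0.4, 0.4, 0.6))
  g <- grey_from_labels(v)
  expect_false(any(threshold_cast(g, 900)$array))   # above the maximum
  bin <- threshold_cast(g, -100)
  expect_identical(bin$array, v$array > 0)          # noise-free: exact
  # 10% of contrast noise: voxelwise agreement at least 99%
  gn <- grey_from_labels(v, noise_sd = 180, seed = 2)
  agree <- mean(threshold_cast(gn, -100)$array == (v$array > 0))
  expect_gte(agree, 0.99)
})

test_that("component labeling is deterministic and size-filtered", {
  two <- heart_model(list(
    heart_structure("A", mesh_icosphere(1.5, 3)),
    heart_structure("B", mesh_icosphere(1, 3, c(6, 0, 0)))))
  v <- rasterize(two, spacing = 0.2, margin = 0.5)
  g <- grey_from_labels(v)
  comp <- label_components(threshold_cast(g, 0), connectivity = 6)
  expect_identical(length(comp$label_map), 2L)
  # labels ordered by descending size: component_1 is the bigger sphere
  sizes <- label_volumes(comp)
  expect_gt(sizes[["component_1"]], sizes[["component_2"]])
  # min_voxels removes a single-voxel speck
  arr <- array(FALSE, c(8, 8, 8)); arr[2, 2, 2] <- TRUE
  arr[5:7, 5:7, 5:7] <- TRUE
  b <- structure(list(array = arr, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)), class = "binary_volume")
  comp2 <- label_components(b, min_voxels = 2)
  expect_identical(length(comp2$label_map), 1L)
  expect_error(label_components(b, connectivity = 18), "connectivity")
  empty <- b; empty$array[] <- FALSE
  expect_error(label_components(empty), "empty foreground")
})

test_that("merged junctions collapse the cast into one component", {
  v <- fix_raster("normal", c(0.4, 0.4, 0.4))
  g <- grey_from_labels(v)
  comp <- label_components(threshold_cast(g, 0), connectivity = 6,
                           min_voxels = 10)
  # the blood pool is contiguous: anatomical naming needs the reference,
  # not connectivity
  expect_identical(length(comp$label_map), 1L)
})

test_that("match_labels renames components by maximal Dice overlap", {
  two <- heart_model(list(
    heart_structure("A", mesh_icosphere(1.5, 3)),
    heart_structure("B", mesh_icosphere(1, 3, c(6, 0, 0)))))
  ref <- rasterize(two, spacing = 0.2, margin = 0.5)
  comp <- label_components(threshold_cast(grey_from_labels(ref), 0))
  matched <- match_labels(comp, ref)
  expect_setequal(names(matched$label_map), c("A", "B"))
  m <- attr(matched, "matching")
  expect_equal(m$dice, c(1, 1))
  # one-voxel shift: same mapping, Dice below 1
  shifted <- comp
  shifted$array <- array(0L, dim(comp$array))
  shifted$array[-1, , ] <- comp$array[-dim(comp$array)[1], , ]
  m2 <- attr(match_labels(shifted, ref), "matching")
  expect_setequal(m2$matched, c("A", "B"))
  expect_true(all(m2$dice < 1 & m2$dice > 0.8))
  # empty reference: everything stays unmatched
  empty_ref <- ref
  empty_ref$array[] <- 0L
  empty_ref$label_map <- integer(0)
  m3 <- attr(match_labels(comp, empty_ref), "matching")
  expect_true(all(is.na(m3$matched)))
  other <- ref
  other$array <- array(0L, c(2, 2, 2))
  expect_error(match_labels(comp, other), "grids differ")
})

test_that("extracted sphere surface matches analytic area and volume", {
  sph <- heart_model(list(heart_structure(
    "S", mesh_icosphere(1, 4, c(0.013, 0.047, 0.071)))))
  v <- rasterize(sph, spacing = 0.05, margin = 0.5)
  ext <- extract_surfaces(v)
  m <- ext$structures$S$mesh
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_area(m), 4 * pi, tolerance = 0.05)
  expect_equal(mesh_volume(m), unname(label_volumes(v)["S"]),
               tolerance = 0.05)
  # no smoothing: deterministic marching-tetrahedra vertex count
  e1 <- extract_surfaces(v, smoothing_iters = 0)
  e2 <- extract_surfaces(v, smoothing_iters = 0)
  expect_identical(nrow(e1$structures$S$mesh$vertices),
                   nrow(e2$structures$S$mesh$vertices))
  expect_true(mesh_is_watertight(e1$structures$S$mesh))
})

test_that("digitization round trip recovers structure count and volumes", {
  m <- fix_model("normal")
  ref <- fix_raster("normal", c(0.4, 0.4, 0.4))
  seg <- segment_volume(threshold_cast(grey_from_labels(ref), 0), ref)
  expect_identical(seg$array, ref$array)
  ext <- extract_surfaces(seg)
  expect_identical(length(ext$structures), length(m$structures))
  vref <- label_volumes(ref)
  vext <- vapply(ext$structures, function(s) mesh_volume(s$mesh), 1)
  expect_true(all(abs(vext[names(vref)] / vref - 1) < 0.05))
  # extracted meshes feed the simulator without repair
  expect_true(all(vapply(ext$structures,
                         function(s) mesh_is_watertight(s$mesh), TRUE)))
  sim <- simulate_bmode(ext, standard_views()$four_chamber$pose,
                        default_view_probe(),
                        material_table(list(blood_pool =
                                              list(grey_value = 200))))
  expect_gt(max(sim$bmode), 0)
})

test_that("segment_volume keeps orphan foreground as numbered components", {
  arr <- array(0L, c(6, 6, 6)); arr[2:3, 2:3, 2:3] <- 1L
  ref <- label_volume(arr, c(1, 1, 1), c(0, 0, 0), c(A = 1L))
  bin <- arr > 0
  bin[5, 5, 5] <- TRUE                      # foreground with no reference
  b <- structure(list(array = bin, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)), class = "binary_volume")
  seg <- segment_volume(b, ref)
  expect_setequal(names(seg$label_map), c("A", "component_1"))
  expect_identical(sum(seg$array == seg$label_map[["component_1"]]), 1L)
})
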