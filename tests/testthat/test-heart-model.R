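write_demo_model_dir <- function(dir, open_lv = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lv <- mesh_icosphere(1, 3)
  if (open_lv) lv <- mesh(lv$vertices, lv$faces[-1, , drop = FALSE])
  write_mesh(lv, file.path(dir, "LV.stl"))
  write_mesh(mesh_icosphere(1.2, 3, c(5, 0, 0)), file.path(dir, "RV.ply"))
  yaml::write_yaml(list(
    LV = list(file = "LV.stl", material_id = "chamber", priority = 2L),
    RV = list(file = "RV.ply", material_id = "chamber", priority = 1L)),
    file.path(dir, "manifest.yaml"))
  file.path(dir, "manifest.yaml")
}

test_that("load_model assembles structures from a manifest", {
  mf <- write_demo_model_dir(withr::local_tempdir())
  m <- load_model(mf)
  expect_s3_class(m, "heart_model")
  expect_identical(structure_names(m), c("LV", "RV"))
  expect_equal(mesh_volume(m$structures$LV$mesh), 4 / 3 * pi,
               tolerance = 0.02)
  expect_identical(m$structures$LV$priority, 2L)
})

test_that("unit sphere manifest reproduces the analytic volume", {
  d <- withr::local_tempdir()
  write_mesh(mesh_icosphere(1, 4), file.path(d, "s.stl"))
  m <- load_model(list(LV = list(file = "s.stl")), dir = d)
  expect_equal(mesh_volume(m$structures$LV$mesh), 4 / 3 * pi,
               tolerance = 0.005)
})

test_that("non-watertight meshes are rejected unless repair is enabled", {
  mf <- write_demo_model_dir(withr::local_tempdir(), open_lv = TRUE)
  expect_error(load_model(mf), "not watertight")
  m <- load_model(mf, repair = TRUE)
  expect_true(mesh_is_watertight(m$structures$LV$mesh))
})

test_that("duplicate structure names are rejected", {
  s <- mesh_icosphere(1, 2)
  expect_error(heart_model(list(heart_structure("LV", s),
                                heart_structure("LV", s))), "duplicate")
})

test_that("apply_pose moves every structure rigidly", {
  m <- fix_model()
  # identity leaves vertices untouched
  expect_equal(apply_pose(m, pose_identity())$structures$LV$mesh$vertices,
               m$structures$LV$mesh$vertices)
  shifted <- apply_pose(m, pose_translate(c(10, 0, 0)))
  expect_equal(colMeans(shifted$structures$RA$mesh$vertices),
               colMeans(m$structures$RA$mesh$vertices) + c(10, 0, 0))
  # group property: two quarter turns equal a half turn
  a <- apply_pose(apply_pose(m, pose_rotate("z", 90)), pose_rotate("z", 90))
  b <- apply_pose(m, pose_rotate("z", 180))
  expect_equal(a$structures$AO$mesh$vertices, b$structures$AO$mesh$vertices,
               tolerance = 1e-9)
})

test_that("scale_structure scales one structure's volume by factor^3", {
  m <- fix_model()
  v0 <- mesh_volume(m$structures$LV$mesh)
  v_other <- mesh_volume(m$structures$RV$mesh)
  scaled <- scale_structure(m, "LV", 1.3)
  expect_equal(mesh_volume(scaled$structures$LV$mesh) / v0, 1.3^3,
               tolerance = 1e-6)
  expect_identical(mesh_volume(scaled$structures$RV$mesh), v_other)
  expect_equal(scale_structure(m, "LV", 1)$structures$LV$mesh$vertices,
               m$structures$LV$mesh$vertices)
  expect_error(scale_structure(m, "XX", 2), "unknown structure")
  expect_error(scale_structure(m, "LV", 0), "positive")
})

test_that("material tables validate grey range and resolve model ids", {
  expect_error(material_table(list(a = list(grey_value = 300))), "grey_value")
  expect_error(material_table(list(a = list(grey_value = 100,
                                            attenuation_per_mm = -1))),
               "attenuation")
  mats <- default_materials()
  expect_true(check_materials(fix_model(), mats))
  bad <- heart_model(list(heart_structure("X", mesh_icosphere(1, 2),
                                          material_id = "nope")))
  expect_error(check_materials(bad, mats), "nope")
})

test_that("write_model/load_model round-trips a generated heart", {
  d <- withr::local_tempdir()
  m <- fix_model()
  write_model(m, d)
  r <- load_model(file.path(d, "manifest.yaml"))
  expect_identical(structure_names(r), structure_names(m))
  expect_equal(mesh_volume(r$structures$DAO$mesh),
               mesh_volume(m$structures$DAO$mesh), tolerance = 1e-5)
  expect_identical(vapply(r$structures, function(s) s$priority, 1L),
                   vapply(m$structures, function(s) s$priority, 1L))
})
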