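test_that("case presets imply the malformation flags", {
  s <- synthetic_heart_spec("hrh_vsd_mga_pa")
  expect_true(s$pa_atretic)
  expect_true(s$aorta_from_rv)
  expect_gt(s$vsd_radius, 0)
  expect_lt(s$rv_lv_ratio, 1)
  n <- synthetic_heart_spec("normal")
  expect_false(n$pa_atretic || n$aorta_from_rv)
  expect_identical(n$vsd_radius, 0)
  expect_error(synthetic_heart_spec(chamber_radii = c(LV = -1)), "radii")
  expect_error(synthetic_heart_spec("hrh_vsd_mga_pa", vsd_radius = 10),
               "vsd_radius too large")
})

test_that("the normal heart contains the full anatomy vocabulary", {
  m <- fix_model("normal")
  expect_true(all(c("LA", "LAA", "RA", "RAA", "LV", "RV", "AO", "Arch",
                    "DAO", "PA", "lPA", "rPA", "DA", "SVC", "IVC") %in%
                  structure_names(m)))
  expect_true(all(vapply(m$structures,
                         function(s) mesh_is_watertight(s$mesh), TRUE)))
})

test_that("generation is deterministic for a fixed spec and seed", {
  a <- generate_heart(synthetic_heart_spec(seed = 42))
  b <- generate_heart(synthetic_heart_spec(seed = 42))
  expect_identical(a$structures$LV$mesh$vertices,
                   b$structures$LV$mesh$vertices)
  c <- generate_heart(synthetic_heart_spec(seed = 43))
  expect_false(identical(a$structures$LV$mesh$vertices,
                         c$structures$LV$mesh$vertices))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generate_heart(synthetic_heart_spec(seed = 5)))
  expect_identical(stats::runif(1), before)
})

test_that("hrh case: hypoplastic RV, septal channel, malposed arteries", {
  h <- fix_model("hrh_vsd_mga_pa")
  ratio <- mesh_volume(h$structures$RV$mesh) /
    mesh_volume(h$structures$LV$mesh)
  expect_gte(ratio, 0.3)
  expect_lte(ratio, 0.5)
  expect_true("VSD" %in% structure_names(h))
  g <- structure_adjacency(h)
  vsd_nb <- names(igraph::neighbors(g, "VSD"))
  expect_setequal(vsd_nb, c("LV", "RV"))
  # aorta arises from the right ventricle; atretic PA touches no ventricle
  expect_true("RV" %in% names(igraph::neighbors(g, "AO")))
  pa_nb <- names(igraph::neighbors(g, "PA"))
  expect_false(any(c("LV", "RV") %in% pa_nb))
  expect_true("DA" %in% pa_nb)
})

test_that("double aortic arch forms a vascular ring; other cases do not", {
  d <- fix_model("double_aortic_arch")
  expect_true(all(c("Arch", "RArch") %in% structure_names(d)))
  g <- structure_adjacency(d)
  expect_true(has_vascular_ring(g))
  # two vertex-disjoint arch paths from ascending to descending aorta
  sg <- igraph::induced_subgraph(g, c("AO", "Arch", "RArch", "DAO"))
  expect_gte(igraph::vertex_disjoint_paths(
    sg, which(igraph::V(sg)$name == "AO"),
    which(igraph::V(sg)$name == "DAO")), 2)
  expect_false(has_vascular_ring(fix_model("normal")))
  expect_false(has_vascular_ring(fix_model("hrh_vsd_mga_pa")))
})

test_that("normal vessel continuity: ductal arch and caval return", {
  g <- structure_adjacency(fix_model("normal"))
  for (edge in list(c("DA", "PA"), c("DA", "DAO"), c("SVC", "RA"),
                    c("IVC", "RA"), c("AO", "Arch"), c("Arch", "DAO"),
                    c("LV", "AO"), c("RV", "PA")))
    expect_true(igraph::are_adjacent(g, edge[1], edge[2]),
                label = paste(edge, collapse = "-"))
})

test_that("case properties hold across a 20-seed sweep", {
  for (seed in 1:20) {
    d <- generate_heart(synthetic_heart_spec("double_aortic_arch",
                                             seed = seed))
    expect_true(has_vascular_ring(d), label = paste("darch seed", seed))
    h <- generate_heart(synthetic_heart_spec("hrh_vsd_mga_pa", seed = seed))
    expect_lt(mesh_volume(h$structures$RV$mesh),
              mesh_volume(h$structures$LV$mesh))
  }
})

test_that("rasterize labels voxels by containing structure with priority", {
  # analytic volume recovery on a generic-position sphere
  sph <- heart_model(list(heart_structure(
    "S", mesh_icosphere(1, 4, c(0.013, 0.047, 0.071)))))
  v <- rasterize(sph, spacing = 0.05, margin = 0.5)
  expect_equal(unname(label_volumes(v)["S"]), 4 / 3 * pi, tolerance = 0.03)
  # requested spacing is honored
  v2 <- rasterize(sph, spacing = c(0.4, 0.4, 0.6), margin = 1)
  expect_identical(v2$spacing, c(0.4, 0.4, 0.6))
  # two disjoint spheres give exactly two labels
  two <- heart_model(list(
    heart_structure("A", mesh_icosphere(1, 3)),
    heart_structure("B", mesh_icosphere(1, 3, c(5, 0, 0)))))
  vt <- rasterize(two, spacing = 0.2, margin = 0.5)
  expect_identical(sort(unique(as.vector(vt$array))), c(0L, 1L, 2L))
  # overlap: higher priority wins
  ov <- heart_model(list(
    heart_structure("low", mesh_icosphere(2, 4, c(0.013, 0.047, 0.071)),
                    priority = 1L),
    heart_structure("high", mesh_icosphere(1, 4, c(0.013, 0.047, 0.071)),
                    priority = 5L)))
  vo <- rasterize(ov, spacing = 0.1, margin = 0.5)
  inner <- label_volumes(vo)["high"]
  expect_equal(unname(inner), 4 / 3 * pi, tolerance = 0.05)
})

test_that("acquisition noise maps labels to intensities reproducibly", {
  v <- fix_raster("normal", c(0.8, 0.8, 0.8))
  imap <- c(air = -1000,
            stats::setNames(rep(800, length(v$label_map)),
                            names(v$label_map)))
  g0 <- add_acquisition_noise(v, imap, noise_sd = 0)
  expect_setequal(unique(as.vector(g0$array)), c(-1000, 800))
  g1 <- add_acquisition_noise(v, imap, noise_sd = 25, seed = 4)
  g2 <- add_acquisition_noise(v, imap, noise_sd = 25, seed = 4)
  expect_identical(g1$array, g2$array)
  # sample means sit near the configured intensities
  expect_equal(mean(g1$array[v$array > 0]), 800, tolerance = 0.01)
  expect_equal(mean(g1$array[v$array == 0]), -1000, tolerance = 0.01)
  expect_error(add_acquisition_noise(v, imap, noise_sd = -1), ">= 0")
})
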