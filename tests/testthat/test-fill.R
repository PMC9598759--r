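fill_fixture <- function() {
  outer <- mesh_icosphere(8, 4, c(0, 20, 0))
  inner <- mesh_icosphere(5, 4, c(0, 20, 0))
  model <- heart_model(list(
    heart_structure("outer", outer, "out", 1L),
    heart_structure("inner", inner, "inn", 2L)))
  mats <- material_table(list(out = list(grey_value = 200),
                              inn = list(grey_value = 30)))
  list(model = model, mats = mats, idx = build_index(model),
       line = list(ox = 0.05, oy = 0, oz = 0.02, dx = 0, dy = 1, dz = 0,
                   length = 40, sample_spacing_mm = 0.5))
}

test_that("no crossings fill with the background grey", {
  f <- fill_fixture()
  empty <- data.frame(distance = numeric(0), structure = character(0),
                      entering = logical(0))
  res <- fill_scanline(empty, f$line, f$model, f$mats,
                       depths = seq(0, 40, 0.5))
  expect_true(all(res$intensity == 0))
  expect_true(all(res$label == 0))
})

test_that("one structure fills [enter, exit) with its grey value", {
  s <- heart_model(list(heart_structure("S", mesh_icosphere(5, 5, c(0, 20, 0)),
                                        "out", 1L)))
  mats <- material_table(list(out = list(grey_value = 200)))
  line <- list(ox = 0.05, oy = 0, oz = 0.02, dx = 0, dy = 1, dz = 0,
               length = 40, sample_spacing_mm = 1)
  cr <- intersect_scanlines(build_index(s), c(0.05, 0, 0.02), c(0, 1, 0), 40)
  d <- seq(0, 40, 1)
  res <- fill_scanline(cr, line, s, mats, depths = d)
  expect_true(all(res$intensity[d >= 15.01 & d < 24.99] == 200))
  expect_true(all(res$intensity[d < 14.99 | d >= 25.01] == 0))
})

test_that("nested spheres band as background|outer|inner|outer|background", {
  f <- fill_fixture()
  cr <- intersect_scanlines(f$idx, c(0.05, 0, 0.02), c(0, 1, 0), 40)
  d <- seq(0, 40, 0.5)
  res <- fill_scanline(cr[, -1], f$line, f$model, f$mats, depths = d)
  probe_at <- function(x) res$intensity[match(x, d)]
  expect_equal(probe_at(c(5, 13, 20, 27, 35)), c(0, 200, 30, 200, 0))
  # against an independent per-sample point-in-mesh oracle
  pts <- cbind(0.05, d, 0.02)
  in_out <- point_in_mesh(f$model$structures$outer$mesh, pts)
  in_inn <- point_in_mesh(f$model$structures$inner$mesh, pts)
  want <- ifelse(in_inn, 30, ifelse(in_out, 200, 0))
  skip_near <- apply(abs(outer(sqrt(rowSums(sweep(pts, 2, c(0, 20, 0))^2)),
                               c(5, 8), `-`)) < 0.05, 1, any)
  expect_equal(res$intensity[!skip_near], want[!skip_near])
})

test_that("a line starting inside a structure is filled from depth zero", {
  f <- fill_fixture()
  line <- list(ox = 0, oy = 20, oz = 0, dx = 0, dy = 1, dz = 0,
               length = 30, sample_spacing_mm = 1)
  cr <- intersect_scanlines(f$idx, c(0, 20, 0), c(0, 1, 0), 30)
  d <- seq(0, 30, 1)
  res <- fill_scanline(cr[, -1], line, f$model, f$mats, depths = d)
  expect_equal(res$intensity[d <= 4.9], rep(30, sum(d <= 4.9)))
  expect_equal(res$label[1], 2L)      # inner wins by priority at the origin
})

test_that("attenuation decays intensity with cumulative in-tissue path", {
  s <- heart_model(list(heart_structure("S", mesh_icosphere(10, 4, c(0, 20, 0)),
                                        "t", 1L)))
  mats <- material_table(list(t = list(grey_value = 200,
                                       attenuation_per_mm = 0.05)))
  line <- list(ox = 0.03, oy = 0, oz = 0.01, dx = 0, dy = 1, dz = 0,
               length = 40, sample_spacing_mm = 0.5)
  cr <- intersect_scanlines(build_index(s), c(0.03, 0, 0.01), c(0, 1, 0), 40)
  d <- seq(0, 40, 0.5)
  res <- fill_scanline(cr[, -1], line, s, mats, depths = d)
  inside <- res$label > 0
  expect_true(all(diff(res$intensity[inside]) < 0))
  # near-full grey at entry, and the analytic decay law holds mid-tissue
  expect_gt(max(res$intensity), 190)
  expect_lte(max(res$intensity), 200)
  t_in <- min(cr$distance)
  mid <- which(inside)[20]
  expect_equal(res$intensity[mid], 200 * exp(-0.05 * (d[mid] - t_in)),
               tolerance = 0.01)
})

test_that("inconsistent parity from an open mesh is reported", {
  hemi <- mesh_icosphere(5, 3, c(0, 20, 0))
  keep <- apply(hemi$faces, 1, function(f)
    mean(hemi$vertices[f, 2]) <= 20.5)      # cut roughly in half
  open_m <- mesh(hemi$vertices, hemi$faces[keep, , drop = FALSE])
  model <- heart_model(list(heart_structure("H", open_m, "out", 1L,
                                            check = FALSE)))
  mats <- material_table(list(out = list(grey_value = 100)))
  line <- list(ox = 0.05, oy = 0, oz = 0.02, dx = 0, dy = 1, dz = 0,
               length = 60, sample_spacing_mm = 1)
  cr <- intersect_brute(model, c(0.05, 0, 0.02), c(0, 1, 0), 60)
  expect_error(fill_scanline(cr[, -1], line, model, mats,
                             depths = seq(0, 60, 1)),
               "parity")
})
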