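test_that("the view library ships exactly eight standard presets", {
  lib <- standard_views()
  expect_identical(length(lib), 8L)
  expect_setequal(names(lib),
                  c("four_chamber", "lvot", "rvot", "three_vessel",
                    "three_vessel_trachea", "aortic_arch", "ductal",
                    "bicaval"))
  expect_true(all(c("LA", "RA", "LV", "RV") %in%
                  lib$four_chamber$required))
  expect_true(all(c("SVC", "IVC", "RA") %in% lib$bicaval$required))
  expect_true(all(c("PA", "AO", "SVC") %in% lib$three_vessel$required))
  expect_true(all(c("LV", "AO") %in% lib$lvot$required))
  expect_true(all(c("RV", "PA") %in% lib$rvot$required))
  expect_true(all(c("AO", "Arch", "DAO") %in% lib$aortic_arch$required))
  expect_true(all(c("PA", "DA", "DAO") %in% lib$ductal$required))
  for (v in lib) expect_true(is_valid_pose(v$pose))
})

test_that("all eight presets pass verification on the default normal heart", {
  m <- fix_model("normal")
  probe <- default_view_probe()
  for (v in standard_views()) {
    rep <- verify_view(simulate_bmode(m, v$pose, probe)$label, v)
    expect_true(rep$pass, label = v$name)
  }
})

test_that("verify_view applies thresholds and flags unknown names", {
  sim <- simulate_bmode(fix_model("normal"),
                        standard_views()$four_chamber$pose,
                        default_view_probe())
  v <- standard_views()$four_chamber
  expect_true(verify_view(sim$label, v)$pass)
  # empty slice fails with all-zero counts
  empty <- sim$label
  empty[] <- 0L
  rep <- verify_view(empty, v)
  expect_false(rep$pass)
  expect_true(all(rep$counts == 0))
  # monotone in min_pixels: raising it never turns fail into pass
  thresholds <- c(1, 30, 100, 400, 2000)
  passes <- vapply(thresholds,
                   function(mp) verify_view(sim$label, v, mp)$pass, TRUE)
  expect_false(any(diff(passes) > 0))
  # forbidden structures invert the test
  spec_f <- view_spec("no_lv", v$pose, required = "LA", forbidden = "LV")
  expect_false(verify_view(sim$label, spec_f)$pass)
  bad <- view_spec("x", v$pose, required = "NotAStructure")
  expect_error(verify_view(sim$label, bad), "unknown structure")
})

test_that("find_view recovers a perturbed preset within its budget", {
  m <- fix_model("normal")
  v <- standard_views()$three_vessel_trachea
  pert <- pose_compose(pose_translate(c(0, 0, 4)),
                       pose_compose(v$pose, pose_rotate("x", 5)))
  spec2 <- view_spec(v$name, pert, v$required)
  before <- verify_view(simulate_bmode(m, pert, default_view_probe())$label,
                        spec2)
  expect_false(before$pass)
  found <- find_view(m, spec2, search_budget = 200, seed = 3)
  expect_true(attr(found, "report")$pass)
  # an already-passing preset returns unchanged
  ok <- standard_views()$four_chamber
  same <- find_view(m, ok, search_budget = 50, seed = 1)
  expect_equal(unclass(same)[1:16], unclass(ok$pose)[1:16])
  # budget 1 evaluates only the preset
  one <- find_view(m, spec2, search_budget = 1, seed = 1)
  expect_equal(unclass(one)[1:16], unclass(pert)[1:16])
  expect_false(attr(one, "report")$pass)
})

test_that("lesion views demonstrate the double aortic arch", {
  d <- fix_model("double_aortic_arch")
  lv <- lesion_views("double_aortic_arch")
  expect_identical(length(lesion_views("normal")), 0L)
  probe <- default_view_probe()
  # transverse plane cephalad of 3VT: exactly two disjoint arch sections
  sl <- simulate_bmode(d, lv$darch_arch_cross_section$pose, probe)$label
  expect_true(verify_view(sl, lv$darch_arch_cross_section)$pass)
  expect_identical(count_slice_regions(sl, c("Arch", "RArch")), 2L)
  # coronal plane shows both arches joining the descending aorta
  sl2 <- simulate_bmode(d, lv$darch_ring_coronal$pose, probe)$label
  expect_true(verify_view(sl2, lv$darch_ring_coronal)$pass)
  # normal 3VT view on this model reports the extra right arch
  tvt <- standard_views()$three_vessel_trachea
  cnt <- slice_pixel_counts(simulate_bmode(d, tvt$pose, probe)$label)
  expect_gt(cnt[["RArch"]], 0)
  expect_false("RArch" %in% structure_names(fix_model("normal")))
})

test_that("lesion views demonstrate the hypoplastic right heart case", {
  h <- fix_model("hrh_vsd_mga_pa")
  lv <- lesion_views("hrh_vsd_mga_pa")
  probe <- default_view_probe()
  # four-chamber: RV pixel area below LV pixel area
  sl <- simulate_bmode(h, lv$hrh_four_chamber$pose, probe)$label
  cnt <- slice_pixel_counts(sl)
  expect_lt(cnt[["RV"]], cnt[["LV"]])
  expect_true(verify_view(sl, lv$hrh_four_chamber)$pass)
  # septal channel: LV and RV 4-connected through the defect
  sv <- simulate_bmode(h, lv$hrh_vsd$pose, probe)$label
  expect_true(slice_connected(sv, "LV", "RV", via = "VSD"))
  expect_false(slice_connected(sv, "LV", "RV"))
  # atretic pulmonary trunk: no PA pixel touches an RV pixel
  sp <- simulate_bmode(h, lv$hrh_pa_origin$pose, probe)$label
  expect_true(verify_view(sp, lv$hrh_pa_origin)$pass)
  expect_false(slice_adjacent(sp, "PA", "RV"))
  # the VSD slice, by contrast, is full of chamber-channel adjacency
  expect_true(slice_adjacent(sv, "LV", "VSD"))
  expect_error(lesion_views("not_a_case"), "unknown case")
})
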