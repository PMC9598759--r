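test_that("linear scan lines span the footprint evenly", {
  p <- probe_config("linear", n_scanlines = 2, footprint_mm = 10)
  sl <- compute_scanlines(p)
  expect_equal(sl$ox, c(-5, 5))
  expect_equal(sl$dx, c(0, 0))
  expect_equal(sl$dy, c(1, 1))
  # degenerate single line sits on the probe axis
  p1 <- probe_config("linear", n_scanlines = 1)
  expect_equal(compute_scanlines(p1)$ox, 0)
})

test_that("curvilinear lines fan evenly over the field of view", {
  p <- probe_config("curvilinear", n_scanlines = 61, fov_deg = 60,
                    transducer_radius_mm = 40)
  sl <- compute_scanlines(p)
  ang <- atan2(sl$dx, sl$dy) * 180 / pi
  expect_equal(diff(ang), rep(1, 60), tolerance = 1e-9)
  expect_equal(range(ang), c(-30, 30))
  # origins on the transducer arc (center at (0, -R))
  r <- sqrt(sl$ox^2 + (sl$oy + 40)^2)
  expect_equal(r, rep(40, 61), tolerance = 1e-9)
  # unit directions, left-to-right ordering
  expect_equal(sl$dx^2 + sl$dy^2, rep(1, 61), tolerance = 1e-12)
  expect_true(all(diff(sl$ox) > 0))
})

test_that("probe configs validate their geometry", {
  expect_error(probe_config("linear", n_scanlines = 0), ">= 1")
  expect_error(probe_config("linear", scanline_depth_mm = -1), "> 0")
  expect_error(probe_config("curvilinear", fov_deg = 190), "fov_deg")
  expect_error(probe_config("curvilinear", transducer_radius_mm = 0),
               "transducer_radius_mm")
})

test_that("identity scan conversion stacks the line arrays exactly", {
  # samples == height, lines == width, footprint/depth match pixel centers
  p <- probe_config("linear", n_scanlines = 32, scanline_depth_mm = 31 * 0.5,
                    samples_per_line = 32, image_width_px = 32,
                    image_height_px = 32, pixel_spacing_mm = 0.5,
                    footprint_mm = 31 * 0.5, interpolation = "nearest")
  set.seed(8)
  lines <- matrix(stats::runif(32 * 32, 0, 255), 32, 32)
  expect_equal(scan_convert(lines, p), lines)
})

test_that("uniform intensity stays uniform inside the imaged region", {
  pl <- probe_config("linear", n_scanlines = 50, samples_per_line = 80,
                     image_width_px = 64, image_height_px = 64,
                     pixel_spacing_mm = 0.5, footprint_mm = 32,
                     scanline_depth_mm = 32)
  img <- scan_convert(matrix(77, 80, 50), pl)
  expect_true(all(img == 77))
  pc <- probe_config("curvilinear", n_scanlines = 50, samples_per_line = 80,
                     image_width_px = 64, image_height_px = 64,
                     pixel_spacing_mm = 0.5, fov_deg = 60,
                     transducer_radius_mm = 20, scanline_depth_mm = 32)
  imgc <- scan_convert(matrix(77, 80, 50), pc)
  expect_setequal(unique(as.vector(imgc)), c(0, 77))
  # corners lie outside the fan
  expect_identical(imgc[1, 1], 0)
  expect_identical(imgc[1, 64], 0)
  expect_error(scan_convert(matrix(0, 80, 49), pc), "line count mismatch")
})

test_that("config files round-trip probe and material definitions", {
  probe <- probe_config("curvilinear", n_scanlines = 96,
                        scanline_depth_mm = 70, samples_per_line = 120,
                        image_width_px = 128, image_height_px = 160,
                        pixel_spacing_mm = 0.45, fov_deg = 72,
                        transducer_radius_mm = 35,
                        interpolation = "bilinear")
  mats <- material_table(list(
    chamber = list(grey_value = 210, attenuation_per_mm = 0.01),
    vein = list(grey_value = 140)),
    background = list(grey_value = 12))
  for (ext in c("xml", "yaml")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_config(probe, mats, f)
    r <- read_config(f)
    expect_equal(r$probe[names(r$probe) != "footprint_mm"],
                 probe[names(probe) != "footprint_mm"])
    expect_equal(r$materials$materials$chamber$attenuation_per_mm, 0.01)
    expect_equal(r$materials$background$grey_value, 12)
  }
})
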