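# Small deterministic demo scene shared by the CLI tests and the committed
# golden image.
demo_probe <- function() {
  probe_config("linear", n_scanlines = 64, scanline_depth_mm = 63 * 0.5,
               samples_per_line = 64, image_width_px = 64,
               image_height_px = 64, pixel_spacing_mm = 0.5,
               footprint_mm = 63 * 0.5, interpolation = "nearest")
}

demo_materials <- function() {
  material_table(list(out = list(grey_value = 200),
                      inn = list(grey_value = 60)))
}

demo_model <- function() {
  heart_model(list(
    heart_structure("outer", mesh_icosphere(10, 3, c(0.4, 16.2, 0.3)),
                    "out", 1L),
    heart_structure("inner", mesh_icosphere(5, 3, c(0.4, 16.2, 0.3)),
                    "inn", 2L)))
}

demo_pose <- function() pose_identity()
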