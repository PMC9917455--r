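test_that("thin-lens magnification matches closed form and rejects virtual images", {
  expect_equal(magnification(25, 150), 0.2)
  expect_equal(magnification(25, 50), 1)       # u = 2f
  expect_equal(magnification(25, 165), 25 / 140, tolerance = 1e-12)
  expect_error(magnification(25, 20), "focal length")
})

test_that("object-space FOV and array span follow the printed sensor geometry", {
  cfg <- array_preset("paper96_u150")
  fov <- object_space_fov(cfg)
  expect_equal(fov$fov_long_mm, 4320 * 1.4e-3 / 0.2, tolerance = 1e-9)  # 30.24
  expect_equal(fov$fov_short_mm, 2432 * 1.4e-3 / 0.2, tolerance = 1e-9) # 17.02
  expect_equal(fov$span_x_mm, 11 * 19 + fov$fov_long_mm, tolerance = 1e-9)
  expect_equal(fov$span_y_mm, 7 * 19 + fov$fov_short_mm, tolerance = 1e-9)
  # u = 2f makes the FOV equal the physical sensor size
  cfg2 <- array_config(camera_spec(), grid = c(1, 1), pitch_mm = 19,
                       working_distance_mm = 50)
  fov2 <- object_space_fov(cfg2)
  expect_equal(fov2$fov_long_mm, 4320 * 1.4e-3, tolerance = 1e-9)
})

test_that("overlap fractions report gaps honestly and gate the stereo guarantee", {
  cfg <- array_preset("paper96_u150")
  ov <- overlap_fractions(cfg)
  expect_equal(ov$long_axis_fraction, (30.24 - 19) / 30.24, tolerance = 1e-4)
  expect_lt(ov$short_axis_fraction, 0)       # coverage gap along the short axis
  expect_false(ov$stereo_guarantee)
  # boundary: FOV exactly equal to pitch
  cfg2 <- array_config(camera_spec(pixel_pitch_um = 20, sensor_px = c(100, 50)),
                       grid = c(1, 2), pitch_mm = 100 * 20e-3 / 0.2,
                       working_distance_mm = 150)
  expect_equal(overlap_fractions(cfg2)$long_axis_fraction, 0)
  # brute-force coverage check: fraction >= 0.5 iff every point along the
  # long axis lies in >= 2 camera FOVs (0.1 mm sampling)
  for (pitch in c(9, 10, 11)) {
    cfgp <- array_config(camera_spec(pixel_pitch_um = 20, sensor_px = c(200, 150)),
                         grid = c(1, 3), pitch_mm = pitch,
                         working_distance_mm = 150)
    fovx <- object_space_fov(cfgp)$fov_x_mm
    xs <- seq(-pitch, pitch, by = 0.1)       # central camera's neighbourhood
    centers <- (seq_len(3) - 2) * pitch
    n_seen <- sapply(xs, function(x) sum(abs(x - centers) <= fovx / 2))
    expect_equal(overlap_fractions(cfgp)$long_axis_fraction >= 0.5,
                 all(n_seen >= 2))
  }
})

test_that("raw frame volume reproduces the printed per-frame size and is linear", {
  cfg <- array_preset("paper96")
  v <- raw_frame_bytes(cfg, 8L)
  expect_identical(v$bytes, 96 * 4320 * 2432)
  expect_equal(v$mib, 961.875, tolerance = 1e-3)       # printed as 962 MB
  expect_identical(raw_frame_bytes(cfg, 8L, n_cameras = 1)$bytes, 4320 * 2432)
  expect_identical(raw_frame_bytes(cfg, 8L, n_cameras = 0)$bytes, 0)
  # linear in camera count; 16-bit doubles the volume
  expect_equal(raw_frame_bytes(cfg, 8L, n_cameras = 48)$bytes, v$bytes / 2)
  expect_equal(raw_frame_bytes(cfg, 16L)$bytes, 2 * v$bytes)
  expect_error(raw_frame_bytes(cfg, 12L), "bit depth")
})

test_that("resolution metrics give the Rayleigh formulas and object sampling", {
  cam <- camera_spec()                                   # lambda = 0.5 um
  rm <- resolution_metrics(cam, 150)
  expect_equal(rm$axial_rayleigh_mm, 0.5e-3 / (2 * 0.03^2), tolerance = 1e-12)
  expect_equal(rm$axial_rayleigh_mm, 0.278, tolerance = 0.001)
  expect_equal(rm$lateral_rayleigh_um, 0.61 * 0.5 / 0.03, tolerance = 1e-9)
  expect_equal(rm$object_pixel_um, 7, tolerance = 1e-9)
  expect_equal(rm$nyquist_full_pitch_um, 14, tolerance = 1e-9)
})

test_that("disparity-depth conversion matches the printed geometry and inverts exactly", {
  g <- depth_geometry()    # B = 19, f = 25, u0 = 150, 1.4 um px
  expect_equal(disparity_to_depth(3.8, g), 25 * (1 + 19 / 3.8), tolerance = 1e-12)
  expect_equal(disparity_to_depth(3.8, g), 150)
  # u -> Inf gives s -> 0
  expect_lt(depth_to_disparity(1e6, g), 5e-4)
  expect_error(disparity_to_depth(0, g), "positive")
  expect_error(disparity_to_depth(-1, g), "positive")
  # round trip to 1e-9 relative tolerance across (f, 1e4) mm
  us <- exp(seq(log(25.01), log(1e4), length.out = 200))
  back <- disparity_to_depth(depth_to_disparity(us, g), g)
  expect_equal(back, us, tolerance = 1e-9)
  # disparity strictly decreasing in object distance
  s <- depth_to_disparity(us, g)
  expect_true(all(diff(s) < 0))
  # one pixel of disparity near focus corresponds to ~46 um of depth
  s0 <- depth_to_disparity(150, g, unit = "px")
  dz <- disparity_to_depth(s0, g, unit = "px") -
        disparity_to_depth(s0 + 1, g, unit = "px")
  expect_equal(dz * 1000, 46, tolerance = 1)
})

test_that("array configs serialize to JSON and back", {
  cfg <- array_preset("paper96")
  path <- withr::local_tempfile(fileext = ".json")
  write_array_config(cfg, path)
  cfg2 <- read_array_config(path)
  expect_equal(cfg2, cfg)
  # packaged presets load identically
  p <- system.file("extdata", "presets", "paper96.json", package = "mcamtk")
  expect_equal(read_array_config(p), cfg)
})

test_that("constructors validate their invariants", {
  expect_error(camera_spec(numerical_aperture = 1.2), "numerical_aperture")
  expect_error(camera_spec(focal_length_mm = -1), "focal_length_mm")
  expect_error(array_config(camera_spec(), working_distance_mm = 10),
               "working_distance")
  expect_error(depth_geometry(baseline_mm = 0), "baseline_mm")
  expect_error(organism_spec("fish", length_mm = -1), "positive")
  expect_error(organism_spec("fish", articulation = 4), "pi")
})
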