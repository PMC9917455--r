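test_that("phase correlation recovers integer and sub-pixel shifts", {
  cal <- desk_calibration()
  img <- cal$frameset$frames[["r00_c00"]]
  # integer shift: exact recovery
  a <- img[1:120, 1:180]
  b <- img[4:123, 18:197]           # content shifted by (dx=17, dy=3)
  reg <- register_pair(a, b, predicted_offset_px = c(0, 0),
                       search_window_px = 24)
  expect_equal(unname(reg$offset_px), c(17, 3), tolerance = 0.01)
  expect_false(reg$low_confidence)
  # sub-pixel shift of a band-limited field, recovered within 0.1 px
  grid_x <- rep(1:160, each = 160) / 9
  grid_y <- rep(1:160, 160) / 9
  f0 <- matrix(value_noise(grid_x, grid_y, seed = 6, scale = 1), 160, 160)
  f1 <- matrix(value_noise(grid_x + 0.30 / 9, grid_y, seed = 6, scale = 1),
               160, 160)
  reg2 <- register_pair(f0, f1, predicted_offset_px = c(0, 0),
                        search_window_px = 8)
  expect_equal(unname(reg2$offset_px[1]), 0.30, tolerance = 0.1)
  expect_equal(unname(reg2$offset_px[2]), 0, tolerance = 0.1)
  # independent noise images are flagged low-confidence
  set.seed(2)
  n1 <- matrix(runif(128^2), 128, 128)
  n2 <- matrix(runif(128^2), 128, 128)
  reg3 <- register_pair(n1, n2, predicted_offset_px = c(0, 0))
  expect_true(reg3$low_confidence)
  # degenerate overlaps and NaNs are rejected
  expect_error(register_pair(a, b, predicted_offset_px = c(170, 0)), "32 px")
  nn <- a; nn[1, 1] <- NaN
  expect_error(register_pair(nn, a, predicted_offset_px = c(0, 0)), "NaN")
})

test_that("calibration recovers simulator ground-truth offsets to half a pixel", {
  cal <- desk_calibration()
  truth <- ideal_template(cal$config)
  err <- cal$template$global_offset_px - truth$global_offset_px
  expect_lt(max(abs(err)), 0.5)
  expect_lt(max(cal$template$residuals$residual_px), 1)
})

test_that("a single-camera array yields the identity template", {
  cfg <- array_config(camera_spec(pixel_pitch_um = 20, sensor_px = c(200, 150)),
                      grid = c(1, 1), pitch_mm = 10, working_distance_mm = 150)
  sc <- make_calibration_scene(extent_mm = c(25, 20), feature_density = 8,
                               seed = 2)
  fs <- render_frameset(sc, cfg, seed = 2)
  tpl <- calibrate_template(fs, cfg)
  expect_equal(unname(tpl$global_offset_px[1, ]), c(0, 0))
  expect_equal(tpl$mosaic_shape_px, c(200, 150))
})

test_that("measured pairwise offsets close around 2x2 camera loops", {
  cal <- desk_calibration()
  cfg <- cal$config
  fs <- cal$frameset
  step <- mcamtk:::.predicted_neighbor_offset(cfg)
  reg <- function(ka, kb, pred)
    register_pair(fs$frames[[ka]], fs$frames[[kb]], pred)$offset_px
  for (c0 in 0:1) {
    ka <- sprintf("r00_c%02d", c0); kb <- sprintf("r00_c%02d", c0 + 1)
    kc <- sprintf("r01_c%02d", c0); kd <- sprintf("r01_c%02d", c0 + 1)
    loop <- reg(ka, kb, c(step, 0)) + reg(kb, kd, c(0, step)) -
            reg(kc, kd, c(step, 0)) - reg(ka, kc, c(0, step))
    expect_lt(sqrt(sum(loop^2)), 1)
  }
})

test_that("template reuse places a rigid scene identically across frames", {
  # the template estimated once is frame-independent: two framesets of the
  # same rigid scene (different sensor noise) stitch to the same mosaic up
  # to the noise floor
  cal <- desk_calibration()
  fs_t1 <- render_frameset(cal$scene, cal$config, seed = 77, frame_index = 1L)
  mos_t0 <- apply_template(cal$frameset, cal$template)
  mos_t1 <- apply_template(fs_t1, cal$template)
  expect_identical(dim(mos_t1$image), dim(mos_t0$image))
  covered <- mos_t0$image > 0 & mos_t1$image > 0
  expect_lt(mean(abs(mos_t1$image[covered] - mos_t0$image[covered])), 0.02)
})

test_that("feathered blending conserves uniform fields and overwrite is exact", {
  cal <- desk_calibration()
  cfg <- cal$config
  sc <- scene_spec(extent_mm = c(60, 40),
                   background = list(level = 0.8, contrast = 0),
                   illumination = list(level = 1, vignetting = FALSE))
  fs <- render_frameset(sc, cfg, seed = 1, noise = noise_params(enabled = FALSE))
  mos <- apply_template(fs, cal$template)
  covered <- mos$image[mos$image > 0]
  expect_lt((max(covered) - min(covered)) / mean(covered), 0.005)
  # overwrite mode with one camera reproduces the input bit-exactly
  cfg1 <- array_config(camera_spec(pixel_pitch_um = 20, sensor_px = c(200, 150)),
                       grid = c(1, 1), pitch_mm = 10, working_distance_mm = 150)
  fs1 <- render_frameset(sc, cfg1, seed = 1)
  tpl1 <- ideal_template(cfg1)
  mos1 <- apply_template(fs1, tpl1, blend_mode = "overwrite")
  expect_identical(mos1$image, fs1$frames[[1]])
})

test_that("a restitched calibration scene matches a direct scene raster", {
  cal <- desk_calibration()
  cfg <- cal$config
  scene <- cal$scene
  scene$illumination$vignetting <- FALSE      # compare scene content only
  fs <- render_frameset(scene, cfg, seed = 30,
                        noise = noise_params(enabled = FALSE))
  mos <- apply_template(fs, cal$template)
  # reference: one virtual camera sampling the same area at the same scale
  shape <- dim(mos$image)                     # (rows, cols)
  ref_cfg <- array_config(camera_spec(pixel_pitch_um = 20,
                                      sensor_px = c(shape[2], shape[1])),
                          grid = c(1, 1), pitch_mm = 10,
                          working_distance_mm = 150)
  ref <- render_camera_roi(scene, ref_cfg, 0, 0,
                           noise = noise_params(enabled = FALSE))
  # absorb the global sub-pixel framing difference before comparing
  reg <- register_pair(mos$image, ref, predicted_offset_px = c(0, 0),
                       search_window_px = 4)
  h <- shape[1]; w <- shape[2]
  gx <- matrix(seq_len(w) - 1 - reg$offset_px[1], h, w, byrow = TRUE)
  gy <- matrix(seq_len(h) - 1 - reg$offset_px[2], h, w)
  ref <- matrix(mcamtk:::.bilinear_at(ref, gx, gy), h, w)
  inner <- function(m) m[30:(nrow(m) - 30), 30:(ncol(m) - 30)]
  a <- inner(mos$image); b <- inner(ref)
  ncc <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_gte(ncc, 0.99)
})

test_that("templates serialize to JSON and back", {
  cal <- desk_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_stitch_template(cal$template, path)
  tpl2 <- read_stitch_template(path)
  expect_equal(tpl2$global_offset_px, cal$template$global_offset_px,
               tolerance = 1e-9)
  expect_equal(tpl2$mosaic_shape_px, cal$template$mosaic_shape_px)
})
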