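textured_patch <- function(seed = 3, n = 128) {
  gx <- rep(1:n, each = n) / 6
  gy <- rep(1:n, n) / 6
  matrix(value_noise(gx, gy, seed = seed, scale = 1, octaves = 3), n, n)
}

test_that("feature extraction is deterministic and respects its contracts", {
  img <- textured_patch()
  f1 <- extract_features(img)
  f2 <- extract_features(img)
  expect_identical(f1, f2)
  expect_gte(nrow(f1$keypoints), 20)
  expect_identical(ncol(f1$descriptors), 256L)
  # flat region yields no keypoints
  flat <- extract_features(matrix(0.5, 100, 100))
  expect_identical(nrow(flat$keypoints), 0L)
  # region smaller than the descriptor patch is rejected
  expect_error(extract_features(img, region = c(0, 0, 20, 20)), "patch")
})

test_that("matching identical images gives zero-distance coincident matches", {
  img <- textured_patch(seed = 8)
  f <- extract_features(img)
  ms <- match_features(f, f)
  expect_gt(nrow(ms), 10)
  expect_true(all(ms$hamming == 0))
  expect_equal(ms$bx, ms$ax)
  expect_equal(ms$by, ms$ay)
})

test_that("nearest-descriptor distances equal the exhaustive-scan oracle", {
  set.seed(13)
  for (rep in 1:3) {
    da <- matrix(rbinom(40 * 256, 1, 0.5), 40, 256)
    db <- matrix(rbinom(30 * 256, 1, 0.5), 30, 256)
    H <- hamming_distance_matrix(da, db)
    expect_identical(matrix(as.integer(H), nrow(H)), hamming_oracle(da, db))
    fa <- structure(list(keypoints = cbind(seq_len(40), 1), descriptors = da),
                    class = "feature_set")
    fb <- structure(list(keypoints = cbind(seq_len(30), 1), descriptors = db),
                    class = "feature_set")
    ms <- match_features(fa, fb, max_hamming = 256, ratio_threshold = 1)
    # every reported pair is a mutual nearest neighbour of the oracle matrix
    O <- hamming_oracle(da, db)
    for (k in seq_len(nrow(ms))) {
      i <- ms$ax[k]; j <- ms$bx[k]
      expect_identical(O[i, j], min(O[i, ]))
      expect_identical(O[i, j], min(O[, j]))
    }
  }
})

test_that("a translated image pair matches with the constructed displacement", {
  img <- textured_patch(seed = 5)
  a <- img[11:110, 11:110]
  b <- img[11:110, 21:120]          # b's content is a shifted by +10 px in x
  ms <- match_features(extract_features(a), extract_features(b))
  expect_gte(nrow(ms), 5)
  expect_equal(median(ms$bx - ms$ax), -10, tolerance = 1)
  expect_equal(median(ms$by - ms$ay), 0, tolerance = 1)
})

test_that("object disparity takes a MAD-filtered mean with survivor counts", {
  mk <- function(d) data.frame(ax = seq_along(d), ay = 1, bx = seq_along(d) + d,
                               by = 1, hamming = 0)
  od <- object_disparity(mk(rep(100, 8)))
  expect_equal(od$disparity_px, 100)
  expect_equal(od$dispersion_px, 0)
  expect_identical(od$n_features, 8L)
  od2 <- object_disparity(mk(c(rep(100, 10), 300, 300)), outlier_mad_k = 3)
  expect_equal(od2$disparity_px, 100)
  expect_identical(od2$n_features, 10L)
  expect_error(object_disparity(mk(c(1, 2))), "insufficient")
})

test_that("depth estimates follow the printed geometry and its sensitivity", {
  g <- depth_geometry()
  de <- estimate_depth(2714.2857, g)
  expect_equal(de$object_distance_mm, 150, tolerance = 1e-4)
  expect_equal(de$z_mm, 0, tolerance = 1e-4)
  # +1 px of disparity near focus is ~ +46 um of z (toward the camera)
  de2 <- estimate_depth(2714.2857 + 1, g)
  expect_equal((de2$z_mm - de$z_mm) * 1000, 46, tolerance = 1)
  expect_error(estimate_depth(0, g), "positive")
  # monotone: more disparity, closer object
  ds <- seq(2000, 4000, by = 100)
  us <- sapply(ds, function(d) estimate_depth(d, g)$object_distance_mm)
  expect_true(all(diff(us) < 0))
})

test_that("simulated beads are localized in depth within the printed accuracy", {
  res <- depth_accuracy_sim(n_beads = 8, seeds = 1:2)
  expect_gte(nrow(res), 14)                 # nearly all beads measurable
  expect_lt(attr(res, "rms_um"), 100)
  expect_equal(cor(res$z_true_mm, res$z_est_mm), 1, tolerance = 0.01)
})

test_that("3-D tracking reports z in overlap zones and flags the rest", {
  cam <- camera_spec(pixel_pitch_um = 5, sensor_px = c(800L, 600L))
  cfg <- array_config(cam, grid = c(1L, 2L), pitch_mm = 10,
                      working_distance_mm = 150)
  tpl <- ideal_template(cfg)
  # stationary bead: repeatable z close to truth
  z_true <- 0.8
  dets <- list(); fss <- list()
  for (t in 1:3) {
    org <- organism_spec("point_bead", position_mm = c(0.5, 0.3), z_mm = z_true,
                         length_mm = 1.2, identity_texture_seed = 44)
    sc <- scene_spec(extent_mm = c(40, 20), organisms = list(org))
    fss[[t]] <- render_frameset(sc, cfg, seed = 100 + t)
    mp <- world_to_mosaic(c(0.5, 0.3), cfg, tpl)
    dets[[t]] <- data.frame(x0 = mp[1] - 70, y0 = mp[2] - 70,
                            x1 = mp[1] + 70, y1 = mp[2] + 70,
                            score = 1, label = "bead")
  }
  tr <- track_3d(dets, fss, tpl, cfg)
  expect_identical(unique(tr$track_id), 1L)
  expect_true(all(tr$quality == "ok"))
  expect_lt(sd(tr$z_mm), 0.05)
  expect_lt(abs(mean(tr$z_mm) - z_true), 0.15)
  expect_equal(tr$x_mm, rep(0.5, 3), tolerance = 0.1)
  # a detection outside the two-camera overlap zone keeps xy, loses z
  far <- world_to_mosaic(c(-12, 0), cfg, tpl)   # only camera 0 sees it
  org <- organism_spec("point_bead", position_mm = c(-12, 0), z_mm = 0,
                       length_mm = 1.2, identity_texture_seed = 9)
  sc <- scene_spec(extent_mm = c(40, 20), organisms = list(org))
  fs <- render_frameset(sc, cfg, seed = 7)
  tr2 <- track_3d(list(data.frame(x0 = far[1] - 60, y0 = far[2] - 60,
                                  x1 = far[1] + 60, y1 = far[2] + 60,
                                  score = 1, label = "bead")),
                  list(fs), tpl, cfg)
  expect_identical(tr2$quality, "no_stereo")
  expect_true(is.na(tr2$z_mm))
  expect_equal(tr2$x_mm, -12, tolerance = 0.2)
})
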