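test_that("occupancy maps are normalized probability grids", {
  # one stationary fish concentrates all mass in a single bin
  om <- occupancy_heatmap(matrix(rep(c(5, 5), 100), ncol = 2, byrow = TRUE),
                          arena_box = c(0, 0, 20, 10), bin_size = 2)
  expect_equal(sum(om$grid), 1)
  expect_identical(sum(om$grid > 0), 1L)
  expect_equal(max(om$grid), 1)
  # uniform positions are not rejected against uniformity (alpha = 0.01)
  set.seed(6)
  pos <- cbind(runif(10000, 0, 40), runif(10000, 0, 25))
  om2 <- occupancy_heatmap(pos, c(0, 0, 40, 25), bin_size = 5)
  expect_equal(sum(om2$grid), 1)
  p <- chisq.test(as.vector(om2$grid * om2$n_samples))$p.value
  expect_gt(p, 0.01)
  # translation invariance of the arena frame
  om3 <- occupancy_heatmap(pos + 100, c(100, 100, 140, 125), bin_size = 5)
  expect_equal(om3$grid, om2$grid)
  # clipping warns; zero positions error
  expect_warning(occupancy_heatmap(rbind(c(-1, 5), c(5, 5)), c(0, 0, 10, 10)),
                 "clipped")
  expect_error(occupancy_heatmap(matrix(numeric(), 0, 2), c(0, 0, 1, 1)),
               "positions")
})

test_that("tail traces recover straight and bent bodies from rendered truth", {
  deg <- function(x) x * 180 / pi
  straight <- tail_trace(render_fish_crop(heading = 0), n_segments = 6)
  expect_identical(straight$n_segments, 6L)
  expect_true(all(abs(deg(straight$segment_angles_rad)) <= 2))
  # a single 30-degree mid-body bend appears in the distal segments
  bent <- tail_trace(render_fish_crop(heading = 0.4, articulation = 0.5236),
                     n_segments = 6)
  distal <- deg(bent$segment_angles_rad[5:6])
  expect_true(all(abs(distal - 30) <= 3))
  # articulation sweep: recovered tip angle tracks truth with unit slope
  sweep <- seq(-60, 60, by = 20) * pi / 180
  tips <- sapply(sweep, function(a) {
    tt <- tail_trace(render_fish_crop(heading = 1.1, articulation = a),
                     n_segments = 6)
    mean(tt$segment_angles_rad[5:6])
  })
  fit <- coef(lm(tips ~ sweep))
  expect_equal(unname(fit[2]), 1, tolerance = 0.1)
  # rotation equivariance: heading change leaves relative angles unchanged
  a0 <- tail_trace(render_fish_crop(heading = 0, articulation = 0.4),
                   n_segments = 6)$segment_angles_rad
  a1 <- tail_trace(render_fish_crop(heading = 2.1, articulation = 0.4),
                   n_segments = 6)$segment_angles_rad
  expect_true(all(abs(deg(a1 - a0)) <= 3))
  expect_error(tail_trace(matrix(0.9, 60, 60)), "blob")
})

test_that("eye angles are recovered with correct left/right assignment", {
  deg <- function(x) x * 180 / pi
  # converging eyes at +/-10 degrees
  ea <- eye_angles(render_fish_crop(heading = 0, eye_angles = c(0.1745, 0.1745)))
  expect_false(ea$missing)
  expect_equal(deg(ea$left_rad), 10, tolerance = 3)
  expect_equal(deg(ea$right_rad), -10, tolerance = 3)
  # mirror-symmetric straight eyes: left ~ -right, both near zero
  ea0 <- eye_angles(render_fish_crop(heading = 0.7))
  expect_equal(deg(ea0$left_rad + ea0$right_rad), 0, tolerance = 4)
  # an eyeless blob is flagged missing
  img <- matrix(0.9, 120, 120)
  img[40:80, 30:90] <- 0.3
  ea2 <- eye_angles(img)
  expect_true(ea2$missing)
})

test_that("block-matching activity reproduces constructed motion", {
  gx <- rep(1:144, each = 144) / 8
  gy <- rep(1:144, 144) / 8
  base <- matrix(value_noise(gx, gy, seed = 2, scale = 1.5), 144, 144)
  static <- optical_flow_activity(list(base, base), block_px = 16, search_px = 4)
  expect_equal(static$activity_px, 0)
  frames <- lapply(0:3, function(t) mcamtk:::.shift_mat(base, 0, 2 * t, 0.5))
  fl <- optical_flow_activity(frames, block_px = 16, search_px = 4)
  expect_equal(fl$activity_px, rep(2, 3), tolerance = 0.1)
  # 3x faster epochs triple the epoch-mean activity
  shifts <- c(0, 1, 2, 3, 6, 9, 12)
  seq_all <- lapply(shifts, function(s) mcamtk:::.shift_mat(base, 0, s, 0.5))
  fl2 <- optical_flow_activity(seq_all, block_px = 16, search_px = 4,
                               epochs = rep(c("light", "dark"), c(3, 3)))
  ratio <- fl2$epoch_means[["dark"]] / fl2$epoch_means[["light"]]
  expect_equal(unname(ratio), 3, tolerance = 0.6)
  expect_error(optical_flow_activity(list(base), 16, 4), "2 frames")
  expect_error(optical_flow_activity(list(base, base), block_px = 500), "block")
})

test_that("component labelling matches the flood-fill oracle at both connectivities", {
  set.seed(31)
  for (rep in 1:50) {
    mask <- matrix(runif(40 * 40) < 0.35, 40, 40)
    for (conn in c(4L, 8L)) {
      got <- label_components(mask, conn)
      ora <- floodfill_oracle(mask, conn)
      expect_identical(got$n, ora$n)
      # identical partitions: the label maps are bijective on components
      fwd <- tapply(got$labels[mask], ora$labels[mask],
                    function(v) length(unique(v)))
      bwd <- tapply(ora$labels[mask], got$labels[mask],
                    function(v) length(unique(v)))
      expect_true(all(fwd == 1) && all(bwd == 1))
    }
  }
  expect_error(label_components(matrix(TRUE, 2, 2), 6L), "connectivity")
})

test_that("segment counting applies the area rule and block tiling is consistent", {
  m <- matrix(FALSE, 200, 200)
  m[10:20, 10:20] <- TRUE            # 121 px
  m[50:60, 100:110] <- TRUE
  m[150:160, 30:40] <- TRUE
  m[70:75, 150:153] <- TRUE          # 24 px, below min_area
  m[100:180, 60:150] <- TRUE         # 7371 px swarm
  img <- 0.9 - 0.7 * m
  sc <- segment_count(img, segmenter = m, scale_um_per_px = 100,
                      min_area_px = 50, swarm_area_threshold_px = 1000)
  expect_identical(sc$n_individuals, 3L)
  expect_identical(sc$n_swarms, 1L)
  expect_identical(length(sc$component_areas_px$individuals), 3L)
  # densities use the mosaic scale (200 px * 100 um = 2 cm per side -> 4 cm2)
  expect_equal(sc$arena_area_cm2, 4)
  expect_equal(sc$density_individuals_per_cm2, 3 / 4)
  # a single large blob with a low threshold is one swarm, no individuals
  big <- matrix(FALSE, 150, 150); big[20:130, 20:120] <- TRUE
  sc2 <- segment_count(0.9 - 0.7 * big, segmenter = big,
                       scale_um_per_px = 100, min_area_px = 50,
                       swarm_area_threshold_px = 1000)
  expect_identical(sc2$n_individuals, 0L)
  expect_identical(sc2$n_swarms, 1L)
  expect_error(segment_count(img, segmenter = m, connectivity = 5), "connectivity")
})

test_that("the reference segmenter recovers rendered worms", {
  cfg <- fine_config()                       # 40 um object pixels
  set.seed(8)
  orgs <- lapply(1:6, function(i)
    organism_spec("worm", c(runif(1, -9, 9), runif(1, -7, 7)),
                  heading_rad = runif(1, 0, 2 * pi), length_mm = 2,
                  width_mm = 0.3, articulation = rnorm(2, 0, 0.3),
                  identity_texture_seed = i))
  sc <- scene_spec(extent_mm = c(45, 30), organisms = orgs)
  img <- render_camera_roi(sc, cfg, 0, 0)
  counts <- segment_count(img, segmenter = reference_segmenter,
                          scale_um_per_px = 40, min_area_px = 30,
                          swarm_area_threshold_px = 1e5)
  expect_gte(counts$n_individuals, 5)        # all 6 in view, allow one merge
  expect_lte(counts$n_individuals, 7)
})

test_that("densities carry a SEM that shrinks with the block count", {
  d <- density_per_area(rep(25, 4), area_cm2 = 10)
  expect_equal(d$density_per_cm2, 10)
  expect_equal(d$sem_per_cm2, 0)
  # equal per-block density spread: SEM at 16 blocks is half that at 4
  b4 <- c(8, 12, 8, 12)                          # density sd = sigma
  b16 <- rep(c(2, 3, 2, 3), 4)                   # same density sd
  d4 <- density_per_area(b4, area_cm2 = 8)
  d16 <- density_per_area(b16, area_cm2 = 8)
  expect_equal(d16$sem_per_cm2 / d4$sem_per_cm2, 0.5, tolerance = 0.15)
  expect_equal(d4$density_per_cm2, d16$density_per_cm2)
  # empty input
  d0 <- density_per_area(integer(), 5)
  expect_equal(d0$density_per_cm2, 0)
  expect_error(density_per_area(c(1, 2), 0), "positive")
})
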