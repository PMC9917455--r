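test_that("tile plans enumerate clamped origins and cover every pixel", {
  plan <- plan_tiles(c(1000, 1000), tile_px = 512, stride_px = 384)
  expect_setequal(unique(plan$tiles[, 1]), c(0, 384, 488))
  expect_setequal(unique(plan$tiles[, 2]), c(0, 384, 488))
  expect_identical(nrow(plan$tiles), 9L)
  # tile >= mosaic collapses to a single clamped tile
  plan1 <- plan_tiles(c(300, 200), tile_px = 512)
  expect_identical(nrow(plan1$tiles), 1L)
  expect_equal(unname(plan1$tiles[1, ]), c(0, 0))
  expect_equal(plan1$tile_px, c(300, 200))
  # coverage property over random geometries
  set.seed(5)
  for (i in 1:20) {
    W <- sample(200:900, 1); H <- sample(200:900, 1)
    tw <- sample(64:256, 1); st <- sample(32:tw, 1)
    p <- plan_tiles(c(W, H), tile_px = tw, stride_px = st)
    cov <- matrix(0L, H, W)
    for (t in seq_len(nrow(p$tiles))) {
      xs <- (p$tiles[t, 1] + 1):(p$tiles[t, 1] + p$tile_px[1])
      ys <- (p$tiles[t, 2] + 1):(p$tiles[t, 2] + p$tile_px[2])
      cov[ys, xs] <- cov[ys, xs] + 1L
    }
    expect_true(all(cov >= 1L))
    # overlap bands between consecutive tiles are covered at least twice
    ox <- sort(unique(p$tiles[, 1]))
    if (tw > st && length(ox) > 1) {
      for (k in seq_len(length(ox) - 1)) {
        band <- (ox[k + 1] + 1):(ox[k] + tw)
        expect_true(all(cov[, band, drop = FALSE] >= 2L))
      }
    }
  }
  expect_error(plan_tiles(c(100, 100), tile_px = 0), "positive")
})

test_that("greedy NMS keeps the right boxes and matches the brute-force oracle", {
  two <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_identical(nms(two, c(0.5, 0.9), 0.5), 2L)     # higher score wins
  expect_identical(nms(two, c(0.7, 0.7), 0.5), 1L)     # tie -> lower index
  disj <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30), c(50, 0, 60, 10))
  expect_setequal(nms(disj, c(0.9, 0.1, 0.5), 0), 1:3)
  expect_error(nms(rbind(c(5, 0, 2, 10)), 1, 0.5), "malformed")
  # randomized equivalence with an independent O(n^2) implementation
  set.seed(9)
  for (rep in 1:5) {
    n <- 200
    x0 <- runif(n, 0, 400); y0 <- runif(n, 0, 400)
    boxes <- cbind(x0, y0, x0 + runif(n, 5, 60), y0 + runif(n, 5, 60))
    scores <- runif(n)
    expect_identical(nms(boxes, scores, 0.5), nms_oracle(boxes, scores, 0.5))
    expect_identical(nms(boxes, scores, 0.2), nms_oracle(boxes, scores, 0.2))
  }
  # threshold 1.0 keeps everything except exact duplicates
  dup <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(1, 1, 9, 9))
  expect_setequal(nms(dup, c(3, 2, 1), 1.0), c(1L, 3L))
})

test_that("the reference blob detector finds blobs and ignores flat tiles", {
  img <- matrix(0.8, 200, 200)
  yy <- row(img); xx <- col(img)
  img <- img - 0.5 * exp(-((yy - 60)^2 + (xx - 80)^2) / (2 * 8^2))
  det <- reference_blob_detector(img, scale_range_px = c(8, 40))
  expect_identical(nrow(det$boxes), 1L)
  expect_true(det$boxes[1, 1] < 80 & 80 < det$boxes[1, 3])
  expect_true(det$boxes[1, 2] < 60 & 60 < det$boxes[1, 4])
  expect_identical(nrow(reference_blob_detector(matrix(0.8, 100, 100),
                                                scale_range_px = c(8, 40))$boxes),
                   0L)
  # two blobs far apart resolve; close pairs merge (documented behaviour)
  img2 <- matrix(0.8, 200, 200) -
    0.5 * exp(-((yy - 100)^2 + (xx - 60)^2) / (2 * 8^2)) -
    0.5 * exp(-((yy - 100)^2 + (xx - 140)^2) / (2 * 8^2))
  expect_identical(nrow(reference_blob_detector(img2, c(8, 40))$boxes), 2L)
  img3 <- matrix(0.8, 200, 200) -
    0.5 * exp(-((yy - 100)^2 + (xx - 97)^2) / (2 * 8^2)) -
    0.5 * exp(-((yy - 100)^2 + (xx - 103)^2) / (2 * 8^2))
  expect_identical(nrow(reference_blob_detector(img3, c(8, 40))$boxes), 1L)
  expect_error(reference_blob_detector(img, scale_range_px = numeric()),
               "scale_range")
})

test_that("tiled detection de-duplicates boundary objects and tolerates tile failures", {
  img <- matrix(0.85, 300, 400)
  yy <- row(img); xx <- col(img)
  # object centred exactly on the boundary between two 200-px tiles
  img <- img - 0.6 * exp(-((yy - 150)^2 + (xx - 200)^2) / (2 * 10^2))
  plan <- plan_tiles(c(400, 300), tile_px = 200, stride_px = 150)
  det <- detect_tiled(img, function(t) reference_blob_detector(t, c(10, 50)),
                      plan, nms_iou = 0.4)
  expect_identical(nrow(det), 1L)
  # blank mosaic gives an empty result
  blank <- detect_tiled(matrix(0.85, 300, 400),
                        function(t) reference_blob_detector(t, c(10, 50)), plan)
  expect_identical(nrow(blank), 0L)
  # a failing tile is recorded while the others proceed
  calls <- new.env(); calls$n <- 0L
  flaky <- function(t) {
    calls$n <- calls$n + 1L
    if (calls$n == 1L) stop("boom")                # first tile fails
    reference_blob_detector(t, c(10, 50))
  }
  det2 <- detect_tiled(img, flaky, plan, nms_iou = 0.4)
  expect_identical(nrow(det2), 1L)
  expect_gt(length(attr(det2, "failed_tiles")), 0)
  expect_error(detect_tiled(matrix(0.85, 300, 400),
                            function(t) stop("dead"), plan), "every tile")
})

test_that("tiled detection is invariant to the stride choice", {
  img <- matrix(0.85, 300, 400)
  yy <- row(img); xx <- col(img)
  set.seed(3)
  for (i in 1:6) {
    cx <- runif(1, 30, 370); cy <- runif(1, 30, 270)
    img <- img - 0.6 * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * 7^2))
  }
  det_a <- detect_tiled(img, function(t) reference_blob_detector(t, c(7, 40)),
                        plan_tiles(c(400, 300), 200, 150), nms_iou = 0.4)
  det_b <- detect_tiled(img, function(t) reference_blob_detector(t, c(7, 40)),
                        plan_tiles(c(400, 300), 200, 120), nms_iou = 0.4)
  expect_identical(nrow(det_a), nrow(det_b))
  oa <- det_a[order(det_a$x0, det_a$y0), c("x0", "y0", "x1", "y1")]
  ob <- det_b[order(det_b$x0, det_b$y0), c("x0", "y0", "x1", "y1")]
  expect_true(all(abs(as.matrix(oa) - as.matrix(ob)) <= 1))
})

test_that("occlusion augmentation respects the IoU range and is deterministic", {
  bg <- matrix(0.8, 200, 200)
  crop <- list(image = matrix(0.2, 30, 30),
               mask = matrix(1, 30, 30))
  none <- occluder_augment(list(crop), bg, n_pastes = 0)
  expect_identical(none$image, bg)
  expect_identical(nrow(none$boxes), 0L)
  aug <- occluder_augment(list(crop), bg, n_pastes = 2,
                          overlap_range = c(0.2, 0.4), seed = 3)
  iou <- box_iou(aug$boxes[1, ], aug$boxes[2, , drop = FALSE])
  expect_gte(iou, 0.2)
  expect_lte(iou, 0.4)
  aug2 <- occluder_augment(list(crop), bg, n_pastes = 2,
                           overlap_range = c(0.2, 0.4), seed = 3)
  expect_identical(aug2$image, aug$image)
  # unsatisfiable constraint errors out
  expect_error(occluder_augment(list(crop), matrix(0.8, 31, 31), n_pastes = 3,
                                overlap_range = c(0, 0), max_attempts = 50),
               "attempts")
})
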