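# Shared fixtures and independent brute-force oracles used across tests.

.fix <- new.env()

# Desk-scale array used by most rendering tests.
desk_config <- function() array_preset("desk6")

# Calibration frameset + template on the desk array (built once).
desk_calibration <- function() {
  if (is.null(.fix$calib)) {
    cfg <- desk_config()
    scene <- make_calibration_scene(extent_mm = c(45, 30),
                                    feature_density = 8, seed = 11)
    fs <- render_frameset(scene, cfg, seed = 12)
    .fix$calib <- list(config = cfg, scene = scene, frameset = fs,
                       template = calibrate_template(fs, cfg))
  }
  .fix$calib
}

# Fine-sampling single-camera config for kinematics tests (40 um object px).
fine_config <- function() {
  array_config(camera_spec(pixel_pitch_um = 8, sensor_px = c(600L, 500L)),
               grid = c(1L, 1L), pitch_mm = 10, working_distance_mm = 150)
}

render_fish_crop <- function(heading = 0, articulation = numeric(),
                             eye_angles = c(0, 0), length_mm = 11,
                             width_mm = 2.4, crop_px = 360, tex_seed = 5L) {
  cfg <- fine_config()
  sc <- scene_spec(extent_mm = c(40, 30), organisms = list(
    organism_spec("fish", c(0, 0), heading_rad = heading,
                  length_mm = length_mm, width_mm = width_mm,
                  articulation = articulation, eye_angles_rad = eye_angles,
                  identity_texture_seed = tex_seed)))
  pc <- project_to_camera(c(0, 0, 0), cfg, 0, 0)
  half <- crop_px / 2
  render_camera_roi(sc, cfg, 0, 0,
                    roi = c(round(pc[1]) - half, round(pc[2]) - half,
                            crop_px, crop_px),
                    noise = noise_params(enabled = FALSE))
}

# 50 fish on a jittered grid with guaranteed body separation.
fifty_fish_scene <- function(seed = 21) {
  set.seed(seed)
  gx <- seq(-17, 17, length.out = 10)
  gy <- seq(-10, 10, length.out = 5)
  pos <- expand.grid(x = gx, y = gy)
  pos$x <- pos$x + runif(50, -0.4, 0.4)
  pos$y <- pos$y + runif(50, -0.4, 0.4)
  orgs <- lapply(1:50, function(i)
    organism_spec("fish", c(pos$x[i], pos$y[i]),
                  heading_rad = runif(1, 0, 2 * pi),
                  length_mm = 2.5, width_mm = 0.8,
                  articulation = rnorm(1, 0, 0.2),
                  identity_texture_seed = i))
  scene_spec(extent_mm = c(48, 32), organisms = orgs,
             background = list(level = 0.85, contrast = 0.08, scale_mm = 2,
                               seed = 5))
}

## ---- independent oracles ---------------------------------------------------

# Greedy NMS, written independently as a plain double loop.
nms_oracle <- function(boxes, scores, thr) {
  ord <- order(-scores, seq_along(scores))
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      ix <- max(0, min(boxes[i, 3], boxes[k, 3]) - max(boxes[i, 1], boxes[k, 1]))
      iy <- max(0, min(boxes[i, 4], boxes[k, 4]) - max(boxes[i, 2], boxes[k, 2]))
      inter <- ix * iy
      u <- (boxes[i, 3] - boxes[i, 1]) * (boxes[i, 4] - boxes[i, 2]) +
           (boxes[k, 3] - boxes[k, 1]) * (boxes[k, 4] - boxes[k, 2]) - inter
      if (inter / u > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# Exhaustive nearest-descriptor scan (per-bit sum of mismatches).
hamming_oracle <- function(da, db) {
  H <- matrix(0L, nrow(da), nrow(db))
  for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db)))
    H[i, j] <- sum(da[i, ] != db[j, ])
  H
}

# Minimum-cost assignment by explicit enumeration of all permutations.
assignment_oracle <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; bc <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < bc) { bc <- cc; best <- p }
  }
  list(assignment = best, cost = bc)
}

# Connected components by queue-based flood fill.
floodfill_oracle <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  offs <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!mask[y, x] || lab[y, x] > 0L) next
    nxt <- nxt + 1L
    q <- list(c(y, x)); lab[y, x] <- nxt
    while (length(q)) {
      p <- q[[length(q)]]; q[[length(q)]] <- NULL
      for (o in offs) {
        yy <- p[1] + o[1]; xx <- p[2] + o[2]
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
            mask[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- nxt
          q[[length(q) + 1L]] <- c(yy, xx)
        }
      }
    }
  }
  list(labels = lab, n = nxt)
}
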