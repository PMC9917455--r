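## 256-pair binary descriptor sampling pattern (fixed, generated once per
## session from a constant seed so descriptors are deterministic).
.brief_pattern_env <- new.env(parent = emptyenv())

.brief_pattern <- function(patch_radius = 15L, n_bits = 256L) {
  key <- sprintf("p%d_%d", patch_radius, n_bits)
  if (!is.null(.brief_pattern_env[[key]])) return(.brief_pattern_env[[key]])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(987654L)
  sd <- patch_radius / 2.5
  draw <- function() {
    v <- round(stats::rnorm(n_bits * 2, 0, sd))
    matrix(.clamp(v, -patch_radius, patch_radius), n_bits, 2)
  }
  pat <- list(a = draw(), b = draw(), radius = patch_radius)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  .brief_pattern_env[[key]] <- pat
  pat
}

#' Detect corner keypoints and binary descriptors
#'
#' Keypoints are local maxima of the Harris corner response; each keypoint
#' carries a 256-bit descriptor of pairwise intensity comparisons on a fixed
#' smoothed sampling pattern. Fully deterministic for a given image.
#'
#' @param image grayscale matrix.
#' @param region optional `(x0, y0, x1, y1)` half-open pixel box restricting
#'   detection.
#' @param max_keypoints keep at most this many strongest corners.
#' @param response_rel relative response threshold (fraction of the max).
#' @param patch_radius descriptor patch radius (px); region must exceed the
#'   patch.
#' @return list of class `feature_set`: `keypoints` (n x 2 matrix, 0-based
#'   `(x, y)`), `descriptors` (n x 256 0/1 matrix), `response`.
#' @export
extract_features <- function(image, region = NULL, max_keypoints = 300L,
                             response_rel = 0.01, patch_radius = 15L) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(region)) region <- c(0, 0, w, h)
  if (region[1] < 0 || region[2] < 0 || region[3] > w || region[4] > h)
    .stopf("region outside image")
  if ((region[3] - region[1]) < 2 * patch_radius + 3 ||
      (region[4] - region[2]) < 2 * patch_radius + 3)
    .stopf("region smaller than the descriptor patch")
  S <- blur_gaussian(image, 1.2)
  gx <- (.shift_mat(S, 0, -1, NA) - .shift_mat(S, 0, 1, NA)) / 2
  gy <- (.shift_mat(S, -1, 0, NA) - .shift_mat(S, 1, 0, NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  Sxx <- blur_gaussian(gx * gx, 2)
  Syy <- blur_gaussian(gy * gy, 2)
  Sxy <- blur_gaussian(gx * gy, 2)
  R <- (Sxx * Syy - Sxy^2) - 0.04 * (Sxx + Syy)^2
  # restrict to region minus the descriptor border
  b <- patch_radius + 1L
  ok <- matrix(FALSE, h, w)
  ys <- max(region[2] + 1, b + 1):min(region[4], h - b)
  xs <- max(region[1] + 1, b + 1):min(region[3], w - b)
  ok[ys, xs] <- TRUE
  # 3x3 local maxima
  ismax <- R > 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & (R >= .shift_mat(R, dy, dx, -Inf))
  }
  cand <- which(ismax & ok & R > response_rel * max(R[ok], 0))
  if (!length(cand))
    return(structure(list(keypoints = matrix(numeric(), 0, 2),
                          descriptors = matrix(0L, 0, 256),
                          response = numeric()), class = "feature_set"))
  ord <- order(R[cand], decreasing = TRUE)
  cand <- cand[ord[seq_len(min(length(ord), max_keypoints))]]
  ky <- (cand - 1) %% h + 1
  kx <- (cand - 1) %/% h + 1
  # sub-pixel corner refinement: 1-D quadratic fit on the response
  subpix <- function(rm1, r0, rp1) {
    den <- rm1 - 2 * r0 + rp1
    d <- ifelse(abs(den) > 1e-12, (rm1 - rp1) / (2 * den), 0)
    .clamp(d, -0.5, 0.5)
  }
  dxs <- subpix(R[cbind(ky, kx - 1)], R[cbind(ky, kx)], R[cbind(ky, kx + 1)])
  dys <- subpix(R[cbind(ky - 1, kx)], R[cbind(ky, kx)], R[cbind(ky + 1, kx)])
  # descriptors on a smoothed image
  D <- blur_gaussian(image, 2)
  pat <- .brief_pattern(patch_radius)
  n <- length(cand); nb <- nrow(pat$a)
  ia <- outer(ky, pat$a[, 2], `+`) + (outer(kx, pat$a[, 1], `+`) - 1) * h
  ib <- outer(ky, pat$b[, 2], `+`) + (outer(kx, pat$b[, 1], `+`) - 1) * h
  desc <- matrix(as.integer(D[ia] > D[ib]), n, nb)
  structure(list(keypoints = cbind(x = kx - 1 + dxs, y = ky - 1 + dys),
                 descriptors = desc, response = R[cand]),
            class = "feature_set")
}

#' Hamming distance matrix between binary descriptor sets
#'
#' @param da,db 0/1 matrices (n x bits, m x bits).
#' @return n x m integer matrix of Hamming distances.
#' @export
hamming_distance_matrix <- function(da, db) {
  da <- as.matrix(da); db <- as.matrix(db)
  da %*% (1 - t(db)) + (1 - da) %*% t(db)
}

#' Match features between two images by Hamming distance
#'
#' Each descriptor in `a` is paired with its minimum-Hamming-distance
#' counterpart in `b`; matches are kept iff the distance is at most
#' `max_hamming`, the best/second-best distance ratio is at most
#' `ratio_threshold`, and the pair is a mutual best match (one-to-one).
#'
#' @param features_a,features_b `feature_set` objects.
#' @param max_hamming maximum accepted Hamming distance (bits).
#' @param ratio_threshold Lowe-style distinctiveness ratio.
#' @param camera_pair optional identifier stored with the matches.
#' @return data frame of class `feature_match_set` with columns
#'   `ax, ay, bx, by, hamming`.
#' @export
match_features <- function(features_a, features_b, max_hamming = 64,
                           ratio_threshold = 0.85, camera_pair = NULL) {
  na <- nrow(features_a$keypoints); nb <- nrow(features_b$keypoints)
  empty <- structure(data.frame(ax = numeric(), ay = numeric(),
                                bx = numeric(), by = numeric(),
                                hamming = numeric()),
                     class = c("feature_match_set", "data.frame"))
  attr(empty, "camera_pair") <- camera_pair
  if (na == 0L || nb == 0L) return(empty)
  H <- hamming_distance_matrix(features_a$descriptors, features_b$descriptors)
  best_b <- max.col(-H, ties.method = "first")
  best_d <- H[cbind(seq_len(na), best_b)]
  second <- vapply(seq_len(na), function(i) {
    v <- H[i, -best_b[i]]
    if (length(v)) min(v) else Inf
  }, numeric(1))
  back <- max.col(-t(H), ties.method = "first")   # best a for each b
  keep <- best_d <= max_hamming &
    (best_d == 0 | best_d / pmax(second, 1e-9) <= ratio_threshold) &
    back[best_b] == seq_len(na)
  out <- data.frame(ax = features_a$keypoints[keep, 1],
                    ay = features_a$keypoints[keep, 2],
                    bx = features_b$keypoints[best_b[keep], 1],
                    by = features_b$keypoints[best_b[keep], 2],
                    hamming = best_d[keep])
  class(out) <- c("feature_match_set", "data.frame")
  attr(out, "camera_pair") <- camera_pair
  out
}

#' Robust object disparity from a match set
#'
#' Per-match displacement along the baseline axis, with median-absolute-
#' deviation outlier rejection at `k` MADs on both displacement components;
#' the mean over survivors is the object disparity.
#'
#' @param match_set a [match_features()] result.
#' @param outlier_mad_k MAD rejection constant `k`.
#' @param axis baseline axis, `"x"` or `"y"`.
#' @return list with `disparity_px` (mean surviving displacement),
#'   `n_features`, `dispersion_px` (sd of survivors).
#' @export
object_disparity <- function(match_set, outlier_mad_k = 3, axis = c("x", "y")) {
  axis <- match.arg(axis)
  d_main <- if (axis == "x") match_set$bx - match_set$ax else
    match_set$by - match_set$ay
  d_orth <- if (axis == "x") match_set$by - match_set$ay else
    match_set$bx - match_set$ax
  keep_mad <- function(v) {
    med <- stats::median(v)
    s <- stats::mad(v)                     # 1.4826 * MAD
    abs(v - med) <= pmax(outlier_mad_k * s, 1e-9)
  }
  if (length(d_main) >= 3) {
    keep <- keep_mad(d_main) & keep_mad(d_orth)
  } else keep <- rep(TRUE, length(d_main))
  if (sum(keep) < 3)
    .stopf("insufficient features after outlier rejection (%d survivors)",
           sum(keep))
  v <- d_main[keep]
  list(disparity_px = mean(v), n_features = sum(keep),
       dispersion_px = stats::sd(v))
}

#' Convert a measured disparity to a depth estimate
#'
#' `u = f (1 + B / s)` with `s = disparity * pixel_pitch`; the axial offset
#' from the plane of best focus is `z = u0 - u` under the z-toward-camera-
#' positive convention.
#'
#' @param disparity_px absolute sensor disparity in pixels (> 0).
#' @param geometry a [depth_geometry()].
#' @param xy_mm optional lateral world position carried through.
#' @param n_features,dispersion_px optional provenance from
#'   [object_disparity()].
#' @return list of class `depth_estimate`: `object_distance_mm`, `z_mm`,
#'   `xy_mm`, `n_features`, `dispersion_mm`.
#' @export
estimate_depth <- function(disparity_px, geometry, xy_mm = c(NA, NA),
                           n_features = NA_integer_, dispersion_px = NA_real_) {
  if (disparity_px <= 0) .stopf("disparity must be positive")
  u <- disparity_to_depth(disparity_px, geometry, unit = "px")
  z <- geometry$focus_distance_mm - u
  if (geometry$z_sign == "away_positive") z <- -z
  # local mm-per-pixel-of-disparity for the dispersion conversion
  sens <- abs(geometry$focal_length_mm * geometry$baseline_mm /
                (disparity_px * geometry$pixel_pitch_um / 1000)^2) *
    geometry$pixel_pitch_um / 1000
  structure(list(object_distance_mm = u, z_mm = z, xy_mm = xy_mm,
                 n_features = n_features,
                 dispersion_mm = dispersion_px * sens),
            class = "depth_estimate")
}

## Stereo measurement for one mosaic-coordinate box: crops the same mosaic
## region from both members of a long-axis camera pair and returns the total
## disparity in pixels (template-calibrated base + measured residual).
.stereo_box_disparity <- function(box, frameset, template, config,
                                  pad_px = 24, min_matches = 3) {
  keys <- rownames(template$global_offset_px)
  sensor <- config$camera$sensor_px
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  # find a long-axis pair whose footprints both contain the box centre
  nr <- config$grid[1]; nc <- config$grid[2]
  pair <- NULL
  for (r in seq_len(nr) - 1L) for (cl in seq_len(nc - 1L) - 1L) {
    ka <- .frameset_key(r, cl); kb <- .frameset_key(r, cl + 1L)
    oa <- template$global_offset_px[ka, ]; ob <- template$global_offset_px[kb, ]
    inside <- function(o) cx >= o[1] && cx < o[1] + sensor[1] &&
      cy >= o[2] && cy < o[2] + sensor[2]
    if (inside(oa) && inside(ob)) { pair <- list(ka = ka, kb = kb); break }
  }
  if (is.null(pair)) return(NULL)
  oa <- template$global_offset_px[pair$ka, ]
  ob <- template$global_offset_px[pair$kb, ]
  reg <- c(box[1] - pad_px, box[2] - pad_px, box[3] + pad_px, box[4] + pad_px)
  crop_local <- function(img, o) {
    x0 <- max(0, floor(reg[1] - o[1])); y0 <- max(0, floor(reg[2] - o[2]))
    x1 <- min(ncol(img), ceiling(reg[3] - o[1]))
    y1 <- min(nrow(img), ceiling(reg[4] - o[2]))
    if (x1 - x0 < 34 || y1 - y0 < 34) return(NULL)
    list(img = img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE],
         origin = c(x0, y0))
  }
  ca <- crop_local(frameset$frames[[pair$ka]], oa)
  cb <- crop_local(frameset$frames[[pair$kb]], ob)
  if (is.null(ca) || is.null(cb)) return(NULL)
  fa <- extract_features(ca$img)
  fb <- extract_features(cb$img)
  ms <- match_features(fa, fb)
  if (nrow(ms) < min_matches) return(NULL)
  # lift crop coordinates back to mosaic coordinates
  ms$ax <- ms$ax + ca$origin[1] + oa[1]; ms$ay <- ms$ay + ca$origin[2] + oa[2]
  ms$bx <- ms$bx + cb$origin[1] + ob[1]; ms$by <- ms$by + cb$origin[2] + ob[2]
  od <- tryCatch(object_disparity(ms), error = function(e) NULL)
  if (is.null(od)) return(NULL)
  base_px <- -(ob[1] - oa[1])            # template-calibrated focal-plane disparity
  od$disparity_px <- od$disparity_px + base_px
  od
}

#' Track organisms in 3-D from detections and raw framesets
#'
#' For each frame, detections are linked into tracks
#' ([link_detections()]); each detection lying in a two-camera overlap zone
#' is measured stereoscopically (feature extraction, Hamming matching,
#' MAD-filtered mean disparity, disparity-to-depth), yielding `(x, y, z, t)`
#' per track with quality flags. Detections outside any overlap zone keep
#' their lateral position with `z` unavailable.
#'
#' @param detections_per_frame list (one per frame) of `detections` data
#'   frames in mosaic coordinates.
#' @param framesets list of `raw_frameset` objects, same length.
#' @param template the `stitch_template` used to build the mosaics.
#' @param config an [array_config()].
#' @param geometry optional [depth_geometry()]; defaults to the config's
#'   long-axis pair geometry.
#' @param max_displacement_px linking gate.
#' @return data frame: `track_id, frame, x_mm, y_mm, z_mm, n_features,
#'   quality` (`"ok"` or `"no_stereo"`).
#' @export
track_3d <- function(detections_per_frame, framesets, template, config,
                     geometry = NULL, max_displacement_px = 100) {
  if (is.null(geometry))
    geometry <- depth_geometry(baseline_mm = config$pitch_mm,
                               focal_length_mm = config$camera$focal_length_mm,
                               focus_distance_mm = config$working_distance_mm,
                               pixel_pitch_um = config$camera$pixel_pitch_um)
  tracks <- NULL
  rows <- list()
  for (t in seq_along(detections_per_frame)) {
    det <- detections_per_frame[[t]]
    tracks <- link_detections(tracks, det, max_displacement_px = max_displacement_px,
                              frame = t - 1L)
    act <- tracks$assignment            # detection row -> track id for this frame
    for (i in seq_len(nrow(det))) {
      box <- as.numeric(det[i, c("x0", "y0", "x1", "y1")])
      ctr <- c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)
      wxy <- mosaic_to_world(ctr, config, template)
      od <- .stereo_box_disparity(box, framesets[[t]], template, config)
      if (is.null(od)) {
        rows[[length(rows) + 1L]] <- data.frame(
          track_id = act[i], frame = t - 1L, x_mm = wxy[1], y_mm = wxy[2],
          z_mm = NA_real_, n_features = 0L, quality = "no_stereo")
      } else {
        de <- estimate_depth(od$disparity_px, geometry, xy_mm = wxy,
                             n_features = od$n_features,
                             dispersion_px = od$dispersion_px)
        rows[[length(rows) + 1L]] <- data.frame(
          track_id = act[i], frame = t - 1L, x_mm = wxy[1], y_mm = wxy[2],
          z_mm = de$z_mm, n_features = od$n_features, quality = "ok")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulated stereoscopic depth-accuracy experiment
#'
#' Places textured point beads uniformly over an axial range in the overlap
#' zone of an adjacent long-axis camera pair, renders both cameras' sensor
#' windows with the full imaging model (defocus, vignetting, noise), runs
#' the stereo pipeline (corner features, Hamming matching, MAD-filtered mean
#' disparity, disparity-to-depth), and reports the per-bead depth errors.
#'
#' @param n_beads beads per seed.
#' @param seeds integer vector of simulation seeds.
#' @param config an [array_config()] with at least 2 columns; defaults to
#'   the printed stereo geometry (f = 25 mm, 19 mm baseline, u = 150 mm,
#'   1.4 um pixels).
#' @param z_range_mm `(lo, hi)` axial range of the beads.
#' @param roi_px sensor window size per camera.
#' @param bead_diameter_mm bead size.
#' @param noise a [noise_params()].
#' @return data frame `seed, bead, z_true_mm, z_est_mm, error_mm,
#'   n_features`, with attribute `rms_um`.
#' @export
depth_accuracy_sim <- function(n_beads = 20L, seeds = 1:5, config = NULL,
                               z_range_mm = c(-2.5, 2.5), roi_px = 256L,
                               bead_diameter_mm = 1.2,
                               noise = noise_params()) {
  if (is.null(config))
    config <- array_config(camera_spec(), grid = c(1L, 2L), pitch_mm = 19,
                           working_distance_mm = 150)
  geometry <- depth_geometry(baseline_mm = config$pitch_mm,
                             focal_length_mm = config$camera$focal_length_mm,
                             focus_distance_mm = config$working_distance_mm,
                             pixel_pitch_um = config$camera$pixel_pitch_um)
  fov <- object_space_fov(config)
  ov <- fov$fov_x_mm - config$pitch_mm       # overlap width of the pair, mm
  if (ov <= bead_diameter_mm)
    .stopf("camera pair has no usable overlap zone")
  half_x <- (ov - bead_diameter_mm) / 2 * 0.9
  half_y <- (fov$fov_y_mm - bead_diameter_mm) / 2 * 0.35
  rows <- list()
  for (sd in seeds) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(.derive_seed(sd, 41L))
    xs <- stats::runif(n_beads, -half_x, half_x)
    ys <- stats::runif(n_beads, -half_y, half_y)
    zs <- stats::runif(n_beads, z_range_mm[1], z_range_mm[2])
    texs <- sample.int(1e6, n_beads)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    for (b in seq_len(n_beads)) {
      org <- organism_spec(kind = "point_bead", position_mm = c(xs[b], ys[b]),
                           z_mm = zs[b], length_mm = bead_diameter_mm,
                           width_mm = bead_diameter_mm,
                           identity_texture_seed = texs[b])
      sc <- scene_spec(extent_mm = c(fov$span_x_mm, fov$span_y_mm) * 1.1,
                       organisms = list(org),
                       background = list(level = 0.85, contrast = 0))
      crops <- list()
      ok <- TRUE
      for (cam in 0:1) {
        pc <- project_to_camera(c(xs[b], ys[b], 0), config, 0L, cam)
        origin <- round(pc) - roi_px / 2
        origin <- .clamp(origin, 0, config$camera$sensor_px - roi_px)
        crops[[cam + 1L]] <- list(
          img = render_camera_roi(sc, config, 0L, cam,
                                  roi = c(origin[1], origin[2], roi_px, roi_px),
                                  noise = noise, seed = .derive_seed(sd, b, cam)),
          origin = origin)
      }
      fa <- extract_features(crops[[1]]$img)
      fb <- extract_features(crops[[2]]$img)
      ms <- match_features(fa, fb)
      od <- tryCatch(object_disparity(ms), error = function(e) NULL)
      if (is.null(od)) next
      # a feature images at px_b = px_a + s_px, so with window origins a0, b0
      # the measured in-window displacement is s_px - (b0 - a0)
      total_px <- od$disparity_px +
        unname(crops[[2]]$origin[1] - crops[[1]]$origin[1])
      est <- estimate_depth(total_px, geometry)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd, bead = b, z_true_mm = zs[b], z_est_mm = est$z_mm,
        error_mm = est$z_mm - zs[b], n_features = od$n_features)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rms_um") <- sqrt(mean(out$error_mm^2)) * 1000
  out
}
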