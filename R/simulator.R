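#' Organism specification for the scene simulator
#'
#' @param kind `"fish"`, `"worm"`, `"blob"`, or `"point_bead"`.
#' @param position_mm world `(x, y)` of the body centroid, mm.
#' @param z_mm signed axial offset from the plane of best focus, mm;
#'   positive toward the cameras.
#' @param heading_rad heading of the head, radians (0 = +x).
#' @param length_mm,width_mm body dimensions, mm (> 0).
#' @param articulation numeric vector of joint angles (radians, |angle| < pi)
#'   bending the body from head to tail.
#' @param identity_texture_seed integer; seeds the individual's speckle
#'   (melanophore-like) texture.
#' @param eye_angles_rad optional `(left, right)` eye orientations relative
#'   to the body axis (fish only).
#' @return an object of class `organism_spec`.
#' @export
organism_spec <- function(kind = c("fish", "worm", "blob", "point_bead"),
                          position_mm = c(0, 0), z_mm = 0, heading_rad = 0,
                          length_mm = 4, width_mm = 0.8,
                          articulation = numeric(),
                          identity_texture_seed = 1L,
                          eye_angles_rad = c(0, 0)) {
  kind <- match.arg(kind)
  if (length_mm <= 0 || width_mm <= 0) .stopf("organism sizes must be positive")
  if (length(articulation) && any(abs(articulation) >= pi))
    .stopf("articulation angles must satisfy |angle| < pi")
  structure(list(kind = kind, position_mm = as.numeric(position_mm),
                 z_mm = z_mm, heading_rad = heading_rad,
                 length_mm = length_mm, width_mm = width_mm,
                 articulation = as.numeric(articulation),
                 identity_texture_seed = as.integer(identity_texture_seed),
                 eye_angles_rad = as.numeric(eye_angles_rad)),
            class = "organism_spec")
}

#' Ground-truth world description for the simulator
#'
#' @param extent_mm `(x, y)` size of the world rectangle, centred on the
#'   array axis.
#' @param background list describing the background field: `level` (mean
#'   reflectance), `contrast`, `scale_mm`, `seed`, and optionally `features`
#'   (a data frame `x, y, size_mm, intensity` of high-contrast calibration
#'   marks).
#' @param organisms list of [organism_spec()].
#' @param illumination list: `level` (source brightness), `vignetting`
#'   (logical; cos^4 field falloff).
#' @param timestamp_s acquisition time.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(extent_mm = c(100, 100),
                       background = list(level = 0.85, contrast = 0,
                                         scale_mm = 1, seed = 0L),
                       organisms = list(),
                       illumination = list(level = 1, vignetting = TRUE),
                       timestamp_s = 0) {
  if (any(extent_mm <= 0)) .stopf("scene extent must be positive")
  half <- extent_mm / 2
  for (o in organisms) {
    if (any(abs(o$position_mm) > half))
      .stopf("organism at (%.2f, %.2f) lies outside the scene extent",
             o$position_mm[1], o$position_mm[2])
  }
  bg <- utils::modifyList(list(level = 0.85, contrast = 0, scale_mm = 1,
                               seed = 0L, features = NULL), background)
  il <- utils::modifyList(list(level = 1, vignetting = TRUE), illumination)
  structure(list(extent_mm = as.numeric(extent_mm), background = bg,
                 organisms = organisms, illumination = il,
                 timestamp_s = timestamp_s),
            class = "scene_spec")
}

#' Sensor-noise parameters for the simulator
#'
#' @param photons full-scale photon count used for Poisson shot noise.
#' @param read_sd Gaussian read-noise standard deviation (fraction of full
#'   scale).
#' @param enabled logical; `FALSE` disables all noise (rendering stays
#'   deterministic and quantization still applies).
#' @return list of class `noise_params`.
#' @export
noise_params <- function(photons = 20000, read_sd = 0.003, enabled = TRUE) {
  structure(list(photons = photons, read_sd = read_sd, enabled = enabled),
            class = "noise_params")
}

## ---------------------------------------------------------------------------
## Projection model.  For a camera centred at world c, a point at lateral
## position p and object distance u (= u0 - z) images at sensor coordinate
## s = -m(u) * (p - c) about the image centre, with m(u) = f / (u - f).
## Within one camera the model is locally telecentric (no intra-camera
## parallax); parallax enters between cameras through the baseline, which is
## exactly the disparity model s = f B / (u - f).

#' Project a world point into a camera's pixel coordinates
#'
#' @param p numeric `(x, y, z)` world position (mm; z toward cameras).
#' @param config an [array_config()].
#' @param row,col 0-based camera grid indices.
#' @return numeric `(x, y)` 0-based pixel coordinates of the point's image
#'   (may fall outside the sensor).
#' @export
project_to_camera <- function(p, config, row, col) {
  cam <- config$camera
  u <- config$working_distance_mm - p[3]
  m <- magnification(cam$focal_length_mm, u)
  cc <- .camera_center(config, row, col)
  pp_mm <- cam$pixel_pitch_um / 1000
  s_mm <- -m * (p[1:2] - cc)                     # world (x, y) -> sensor (x, y)
  c(x = s_mm[1] / pp_mm + cam$sensor_px[1] / 2 - 0.5,
    y = s_mm[2] / pp_mm + cam$sensor_px[2] / 2 - 0.5)
}

#' Back-project a camera pixel to world coordinates at a given z
#'
#' Inverse of [project_to_camera()] for a known axial offset.
#'
#' @param px numeric `(x, y)` 0-based pixel coordinates.
#' @param config an [array_config()].
#' @param row,col 0-based camera grid indices.
#' @param z_mm axial offset of the plane to intersect (default 0).
#' @return numeric `(x, y)` world mm.
#' @export
camera_to_world <- function(px, config, row, col, z_mm = 0) {
  cam <- config$camera
  u <- config$working_distance_mm - z_mm
  m <- magnification(cam$focal_length_mm, u)
  cc <- .camera_center(config, row, col)
  pp_mm <- cam$pixel_pitch_um / 1000
  s_mm <- c(px[1] - cam$sensor_px[1] / 2 + 0.5,
            px[2] - cam$sensor_px[2] / 2 + 0.5) * pp_mm
  c(x = cc[1] - s_mm[1] / m, y = cc[2] - s_mm[2] / m)
}

## Midline polyline of an organism in world coordinates: K+1 nodes from head
## to tail, articulation angles applied cumulatively, centroid at position.
.organism_midline <- function(org, n_nodes = 9L) {
  L <- org$length_mm
  K <- n_nodes - 1L
  ang <- rep(0, K)
  na <- length(org$articulation)
  if (na > 0) {
    # spread the joint angles over the nodes (head third stays straight)
    at <- floor(seq(ceiling(K / 3), K, length.out = na))
    for (i in seq_len(na)) ang[at[i]:K] <- ang[at[i]:K] + 0   # placeholder
    ang2 <- rep(0, K)
    for (i in seq_len(na)) ang2[at[i]] <- ang2[at[i]] + org$articulation[i]
    ang <- cumsum(ang2)
  }
  theta <- org$heading_rad + pi + c(0, ang)      # tailward directions
  theta <- theta[1:K]
  step <- L / K
  dx <- c(0, cumsum(cos(theta) * step))
  dy <- c(0, cumsum(sin(theta) * step))
  cx <- dx - mean(dx); cy <- dy - mean(dy)
  list(x = org$position_mm[1] + cx, y = org$position_mm[2] + cy,
       arc = seq(0, L, length.out = n_nodes))
}

## Distance from points to a polyline; returns distance and arc position of
## the nearest point.
.polyline_distance <- function(px, py, mx, my, arc) {
  n <- length(mx)
  best <- rep(Inf, length(px))
  barc <- rep(0, length(px))
  for (k in seq_len(n - 1)) {
    ax <- mx[k]; ay <- my[k]
    bx <- mx[k + 1]; by <- my[k + 1]
    vx <- bx - ax; vy <- by - ay
    vv <- vx * vx + vy * vy
    t <- .clamp(((px - ax) * vx + (py - ay) * vy) / vv, 0, 1)
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- dx * dx + dy * dy
    upd <- d2 < best
    best[upd] <- d2[upd]
    barc[upd] <- arc[k] + t[upd] * (arc[k + 1] - arc[k])
  }
  list(dist = sqrt(best), arc = barc)
}

## Fish half-width profile along the body (arc s in [0, L]).
.fish_halfwidth <- function(s, L, W) {
  w <- numeric(length(s))
  head <- s <= 0.3 * L
  w[head] <- (W / 2) * sqrt(pmax(0, 1 - ((s[head] - 0.3 * L) / (0.35 * L))^2))
  w[!head] <- (W / 2) * (1 - 0.85 * (s[!head] - 0.3 * L) / (0.7 * L))
  w
}

## Absorbance (0..1) and reflectance of one organism evaluated at world
## points (vectors wx, wy).  edge_mm controls the soft edge width.
.organism_absorbance <- function(org, wx, wy, edge_mm) {
  seed <- org$identity_texture_seed
  if (org$kind %in% c("blob", "point_bead")) {
    r <- org$length_mm / 2
    d <- sqrt((wx - org$position_mm[1])^2 + (wy - org$position_mm[2])^2)
    alpha <- .smoothstep(.clamp((r - d) / edge_mm, 0, 1))
    tex_scale <- if (org$kind == "point_bead") org$length_mm / 7 else org$length_mm / 4
    refl <- 0.05 + 0.85 * value_noise(wx - org$position_mm[1],
                                      wy - org$position_mm[2],
                                      seed = seed, scale = tex_scale, octaves = 3L)
    return(list(alpha = alpha, refl = refl))
  }
  ml <- .organism_midline(org)
  pd <- .polyline_distance(wx, wy, ml$x, ml$y, ml$arc)
  L <- org$length_mm
  hw <- if (org$kind == "fish") .fish_halfwidth(pd$arc, L, org$width_mm)
        else rep(org$width_mm / 2, length(pd$arc))
  alpha <- .smoothstep(.clamp((hw - pd$dist) / edge_mm, 0, 1))
  # melanophore-like pattern in body-local (arc, lateral) coordinates:
  # near-black pigment blotches on a lighter body
  spots <- value_noise(pd$arc, pd$dist, seed = seed, scale = L / 10,
                       octaves = 2L)
  refl <- 0.60 - 0.50 * .smoothstep(.clamp((spots - 0.45) / 0.15, 0, 1))
  if (org$kind == "fish") {
    # dark oriented eyes near the head, one on each side of the midline
    hx <- ml$x[1]; hy <- ml$y[1]
    ax <- ml$x[2] - ml$x[1]; ay <- ml$y[2] - ml$y[1]
    an <- sqrt(ax^2 + ay^2); ax <- ax / an; ay <- ay / an   # tailward unit
    # fish-left normal of the heading (image/world axes share handedness)
    nx <- ay; ny <- -ax
    s_eye <- 0.18 * L
    off <- 0.26 * org$width_mm
    er_a <- 0.15 * org$width_mm * 1.7   # eye semi-major
    er_b <- 0.15 * org$width_mm         # eye semi-minor
    body_ang <- atan2(-ay, -ax)         # headward axis angle
    for (side in c(1, -1)) {
      ei <- if (side == 1) 1L else 2L   # left, right
      eang <- body_ang + side * org$eye_angles_rad[ei]
      ex <- hx + ax * s_eye + side * nx * off
      ey <- hy + ay * s_eye + side * ny * off
      dx <- wx - ex; dy <- wy - ey
      ca <- cos(eang); sa <- sin(eang)
      xr <- dx * ca + dy * sa
      yr <- -dx * sa + dy * ca
      de <- sqrt((xr / er_a)^2 + (yr / er_b)^2)
      ea <- .smoothstep(.clamp((1 - de) * er_b / edge_mm, 0, 1))
      alpha <- pmax(alpha, ea)
      refl[ea > 0.5] <- 0.02
    }
  }
  list(alpha = alpha, refl = refl)
}

## World-extent bounding box of an organism (mm), with margin.
.organism_bbox <- function(org, margin_mm = 0) {
  if (org$kind %in% c("blob", "point_bead")) {
    r <- org$length_mm / 2 + margin_mm
    return(c(org$position_mm[1] - r, org$position_mm[2] - r,
             org$position_mm[1] + r, org$position_mm[2] + r))
  }
  ml <- .organism_midline(org)
  r <- org$width_mm + margin_mm
  c(min(ml$x) - r, min(ml$y) - r, max(ml$x) + r, max(ml$y) + r)
}

#' Render one camera's sensor window
#'
#' Renders the part of a scene seen by camera `(row, col)` restricted to a
#' sensor region of interest. [render_frameset()] uses the full sensor; the
#' stereo experiments render small windows around objects of interest so the
#' full 10-megapixel geometry stays desk-testable.
#'
#' @param scene a [scene_spec()].
#' @param config an [array_config()].
#' @param row,col 0-based camera grid indices.
#' @param roi integer `(x0, y0, w, h)` 0-based pixel window; `NULL` = full
#'   sensor.
#' @param noise a [noise_params()].
#' @param seed integer seed (with `frame_index`, `row`, `col` it determines
#'   the noise stream).
#' @param frame_index frame number used in seed derivation.
#' @param bit_depth 8 or 16.
#' @param defocus_coeff linear defocus coefficient: the blur sigma in object
#'   micrometres is `defocus_coeff * |z_mm| * 1000 * NA`.
#' @return numeric matrix `h x w` with values in \[0, 1\].
#' @export
render_camera_roi <- function(scene, config, row, col, roi = NULL,
                              noise = noise_params(), seed = 1L,
                              frame_index = 0L, bit_depth = 8L,
                              defocus_coeff = 0.5) {
  cam <- config$camera
  if (is.null(roi)) roi <- c(0L, 0L, cam$sensor_px[1], cam$sensor_px[2])
  w <- roi[3]; h <- roi[4]
  u0 <- config$working_distance_mm
  m0 <- magnification(cam$focal_length_mm, u0)
  pp_mm <- cam$pixel_pitch_um / 1000
  cc <- .camera_center(config, row, col)

  pxx <- roi[1] + seq_len(w) - 1       # 0-based pixel x
  pxy <- roi[2] + seq_len(h) - 1
  sx <- (pxx + 0.5 - cam$sensor_px[1] / 2) * pp_mm
  sy <- (pxy + 0.5 - cam$sensor_px[2] / 2) * pp_mm
  # world coordinates of each pixel's line of sight at the focus plane
  wx0 <- cc[1] - sx / m0               # length w
  wy0 <- cc[2] - sy / m0               # length h
  WX <- matrix(wx0, h, w, byrow = TRUE)
  WY <- matrix(wy0, h, w)

  # illumination x vignetting
  img <- matrix(scene$illumination$level * scene$background$level, h, w)
  if (isTRUE(scene$illumination$vignetting)) {
    r2 <- (WX - cc[1])^2 + (WY - cc[2])^2
    cth2 <- 1 / (1 + r2 / u0^2)        # cos^2(theta)
    img <- img * cth2 * cth2
  }
  # background texture
  if (scene$background$contrast > 0) {
    tx <- value_noise(as.vector(WX), as.vector(WY),
                      seed = scene$background$seed,
                      scale = scene$background$scale_mm, octaves = 3L)
    img <- img * (1 + scene$background$contrast * (matrix(tx, h, w) - 0.5))
  }
  # high-contrast calibration features (soft squares)
  fts <- scene$background$features
  if (!is.null(fts) && nrow(fts)) {
    xr <- range(wx0); yr <- range(wy0)
    keep <- fts$x + fts$size_mm >= min(xr) & fts$x - fts$size_mm <= max(xr) &
            fts$y + fts$size_mm >= min(yr) & fts$y - fts$size_mm <= max(yr)
    e_mm <- pp_mm / m0
    for (i in which(keep)) {
      dx <- abs(WX - fts$x[i]); dy <- abs(WY - fts$y[i])
      a <- .smoothstep(.clamp((fts$size_mm[i] / 2 - pmax(dx, dy)) / e_mm, 0, 1))
      img <- img * (1 + a * fts$intensity[i])
    }
  }
  # organisms: multiplicative absorbance layers, each defocus-blurred
  edge_obj_mm <- pp_mm / m0            # ~1 object pixel soft edge
  for (org in scene$organisms) {
    u_o <- u0 - org$z_mm
    m_o <- magnification(cam$focal_length_mm, u_o)
    wxo <- cc[1] - sx / m_o
    wyo <- cc[2] - sy / m_o
    bb <- .organism_bbox(org, margin_mm = 4 * edge_obj_mm)
    ix <- which(wxo >= bb[1] & wxo <= bb[3])
    iy <- which(wyo >= bb[2] & wyo <= bb[4])
    if (!length(ix) || !length(iy)) next
    WXo <- matrix(wxo[ix], length(iy), length(ix), byrow = TRUE)
    WYo <- matrix(wyo[iy], length(iy), length(ix))
    ab <- .organism_absorbance(org, as.vector(WXo), as.vector(WYo), edge_obj_mm)
    A <- matrix(ab$alpha * (1 - ab$refl), length(iy), length(ix))
    sigma_obj_um <- defocus_coeff * abs(org$z_mm) * 1000 * cam$numerical_aperture
    sigma_px <- sigma_obj_um / 1000 * m_o / pp_mm
    if (sigma_px > 0.05) A <- blur_gaussian(A, sigma_px)
    img[iy, ix] <- img[iy, ix] * (1 - A)
  }
  # sensor noise and quantization
  if (isTRUE(noise$enabled)) {
    rs <- .derive_seed(seed, frame_index, row, col, roi[1], roi[2])
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(rs)
    ph <- noise$photons
    img <- matrix(stats::rpois(length(img), .clamp(img, 0, 4) * ph) / ph,
                  nrow(img), ncol(img))
    img <- img + matrix(stats::rnorm(length(img), sd = noise$read_sd),
                        nrow(img), ncol(img))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  .quantize(img, bit_depth)
}

#' Render a full per-camera raw frameset
#'
#' Applies the array projection model (per-camera thin-lens magnification,
#' baseline parallax, cos^4 vignetting, linear defocus blur, Poisson shot and
#' Gaussian read noise, quantization) to a scene, producing one raw image per
#' camera of the grid.
#'
#' @inheritParams render_camera_roi
#' @param bayer `"none"` (grayscale) or `"RGGB"`.
#' @return an object of class `raw_frameset`: list with `frames` (list of
#'   matrices keyed `"r<row>_c<col>"`), `array_config`, `bayer_pattern`,
#'   `frame_index`, `bit_depth`, and `ground_truth` (the scene).
#' @export
render_frameset <- function(scene, config, noise = noise_params(), seed = 1L,
                            frame_index = 0L, bit_depth = 8L,
                            bayer = c("none", "RGGB"), defocus_coeff = 0.5) {
  stopifnot(inherits(scene, "scene_spec"), inherits(config, "array_config"))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .stopf("seed must be a single integer")
  bayer <- match.arg(bayer)
  frames <- list()
  for (r in seq_len(config$grid[1]) - 1L) {
    for (cl in seq_len(config$grid[2]) - 1L) {
      img <- render_camera_roi(scene, config, r, cl, roi = NULL, noise = noise,
                               seed = seed, frame_index = frame_index,
                               bit_depth = bit_depth,
                               defocus_coeff = defocus_coeff)
      if (bayer == "RGGB") img <- .apply_bayer_rggb(img)
      frames[[sprintf("r%02d_c%02d", r, cl)]] <- img
    }
  }
  structure(list(frames = frames, array_config = config,
                 bayer_pattern = bayer, frame_index = frame_index,
                 bit_depth = bit_depth, ground_truth = scene),
            class = "raw_frameset")
}

## Grayscale scene through an RGGB mosaic with slightly unequal channel
## gains (emulates a raw colour sensor looking at a neutral scene).
.apply_bayer_rggb <- function(img, gains = c(R = 0.92, G = 1.0, B = 0.85)) {
  h <- nrow(img); w <- ncol(img)
  gm <- matrix(gains["G"], h, w)
  odd_r <- seq(1, h, by = 2); even_r <- seq(2, h, by = 2)
  odd_c <- seq(1, w, by = 2); even_c <- seq(2, w, by = 2)
  gm[odd_r, odd_c] <- gains["R"]
  gm[even_r, even_c] <- gains["B"]
  img * gm
}

.frameset_key <- function(row, col) sprintf("r%02d_c%02d", row, col)

#' @export
print.raw_frameset <- function(x, ...) {
  cat(sprintf("raw_frameset: %d cameras (%dx%d grid), %dx%d px, frame %d, %s\n",
              length(x$frames), x$array_config$grid[1], x$array_config$grid[2],
              ncol(x$frames[[1]]), nrow(x$frames[[1]]), x$frame_index,
              x$bayer_pattern))
  invisible(x)
}

#' Feature-rich calibration scene
#'
#' Band-limited random background texture plus scattered high-contrast
#' square marks, used to estimate stitching templates (sparse biological
#' scenes carry too little registration signal).
#'
#' @param extent_mm world rectangle `(x, y)`, mm.
#' @param feature_density marks per cm^2 (>= 0).
#' @param seed integer seed; scenes are deterministic given the seed.
#' @return a [scene_spec()].
#' @export
make_calibration_scene <- function(extent_mm = c(60, 40), feature_density = 8,
                                   seed = 1L) {
  if (feature_density < 0) .stopf("feature_density must be >= 0")
  contrast <- if (feature_density > 0) 0.7 else 0
  feats <- NULL
  if (feature_density > 0) {
    area_cm2 <- prod(extent_mm) / 100
    n <- max(1L, round(feature_density * area_cm2))
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(.derive_seed(seed, 77L))
    feats <- data.frame(
      x = stats::runif(n, -extent_mm[1] / 2, extent_mm[1] / 2),
      y = stats::runif(n, -extent_mm[2] / 2, extent_mm[2] / 2),
      size_mm = stats::runif(n, 0.4, 1.2),
      intensity = sample(c(-0.8, 0.6), n, replace = TRUE))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  scene_spec(extent_mm = extent_mm,
             background = list(level = 0.85, contrast = contrast,
                               scale_mm = 1.2, seed = .derive_seed(seed, 3L),
                               features = feats),
             organisms = list(),
             illumination = list(level = 1, vignetting = TRUE))
}

#' Out-of-focus diffuser framesets for flat-field calibration
#'
#' Renders `n` framesets of a featureless white diffuser through the same
#' vignetting and noise model, mirroring the standard flat-field procedure
#' (five defocused full-field diffuser images by default).
#'
#' @param config an [array_config()].
#' @param n number of framesets (default 5).
#' @param seed integer seed.
#' @param noise a [noise_params()].
#' @param bit_depth 8 or 16.
#' @return list of `n` `raw_frameset` objects.
#' @export
make_diffuser_frames <- function(config, n = 5L, seed = 1L,
                                 noise = noise_params(), bit_depth = 8L) {
  if (n < 1) .stopf("n must be >= 1")
  fov <- object_space_fov(config)
  sc <- scene_spec(extent_mm = 1.2 * c(fov$span_x_mm, fov$span_y_mm),
                   background = list(level = 0.9, contrast = 0),
                   illumination = list(level = 1, vignetting = TRUE))
  lapply(seq_len(n), function(i)
    render_frameset(sc, config, noise = noise, seed = seed,
                    frame_index = i - 1L, bit_depth = bit_depth))
}

#' Simulate a multi-frame session of freely moving organisms
#'
#' Per-organism smooth random walk: heading diffuses, per-step speeds are
#' gamma-distributed around the configured mean, positions reflect at the
#' arena walls, and z performs an optional bounded random walk. Identities
#' (and their texture seeds) persist across frames.
#'
#' @param n_organisms number of organisms.
#' @param kind organism kind (see [organism_spec()]).
#' @param arena_mm `(x, y)` arena size, centred at the world origin; must fit
#'   within `extent_mm`.
#' @param motion list: `speed_mean` (mm/s), `speed_cv`, `turn_sd` (rad/sqrt s),
#'   `z_sd` (mm/sqrt s), `z_range` (mm, walk bounded to +/- this).
#' @param n_frames number of frames (>= 1).
#' @param dt frame interval, s.
#' @param seed integer seed.
#' @param extent_mm world extent (default: arena plus margin).
#' @param length_mm,width_mm organism dimensions.
#' @return list of `n_frames` [scene_spec()] objects; each organism list
#'   carries stable `identity_texture_seed`s.
#' @export
simulate_session <- function(n_organisms, kind = "fish", arena_mm = c(40, 25),
                             motion = list(), n_frames = 10L, dt = 1,
                             seed = 1L, extent_mm = NULL,
                             length_mm = 4, width_mm = 0.9) {
  if (n_frames < 1) .stopf("n_frames must be >= 1")
  mo <- utils::modifyList(list(speed_mean = 5, speed_cv = 0.3, turn_sd = 0.8,
                               z_sd = 0, z_range = 2.5), motion)
  if (is.null(extent_mm)) extent_mm <- arena_mm * 1.2
  if (any(arena_mm > extent_mm)) .stopf("arena larger than scene extent")
  half <- arena_mm / 2
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(.derive_seed(seed, 11L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  if (n_organisms > 0) {
    margin <- length_mm / 2
    st <- data.frame(
      x = stats::runif(n_organisms, -half[1] + margin, half[1] - margin),
      y = stats::runif(n_organisms, -half[2] + margin, half[2] - margin),
      z = 0,
      heading = stats::runif(n_organisms, 0, 2 * pi),
      tex = sample.int(1e6, n_organisms))
  }
  shape <- 1 / mo$speed_cv^2
  scenes <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    orgs <- list()
    if (n_organisms > 0) {
      orgs <- lapply(seq_len(n_organisms), function(i)
        organism_spec(kind = kind,
                      position_mm = c(st$x[i], st$y[i]), z_mm = st$z[i],
                      heading_rad = st$heading[i],
                      length_mm = length_mm, width_mm = width_mm,
                      articulation = stats::rnorm(2, 0, 0.15),
                      identity_texture_seed = st$tex[i]))
    }
    scenes[[t]] <- scene_spec(extent_mm = extent_mm, organisms = orgs,
                              background = list(level = 0.85, contrast = 0.08,
                                                scale_mm = 2,
                                                seed = .derive_seed(seed, 5L)),
                              timestamp_s = (t - 1) * dt)
    if (n_organisms > 0 && t < n_frames) {
      sp <- stats::rgamma(n_organisms, shape = shape,
                          scale = mo$speed_mean / shape)
      st$heading <- st$heading + stats::rnorm(n_organisms, 0,
                                              mo$turn_sd * sqrt(dt))
      st$x <- st$x + sp * dt * cos(st$heading)
      st$y <- st$y + sp * dt * sin(st$heading)
      # wall reflection (positions folded back, heading mirrored)
      for (ax in c("x", "y")) {
        hl <- half[if (ax == "x") 1 else 2]
        over <- st[[ax]] > hl
        under <- st[[ax]] < -hl
        st[[ax]][over] <- 2 * hl - st[[ax]][over]
        st[[ax]][under] <- -2 * hl - st[[ax]][under]
        if (ax == "x") st$heading[over | under] <- pi - st$heading[over | under]
        else st$heading[over | under] <- -st$heading[over | under]
        st[[ax]] <- .clamp(st[[ax]], -hl, hl)
      }
      if (mo$z_sd > 0) {
        st$z <- .clamp(st$z + stats::rnorm(n_organisms, 0, mo$z_sd * sqrt(dt)),
                       -mo$z_range, mo$z_range)
      }
    }
  }
  scenes
}
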