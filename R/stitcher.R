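## Phase correlation of two equal-size crops.  Returns the (dx, dy) shift of
## the underlying scene between A and B together with a peak-ratio
## confidence.  If b equals a shifted so that B(x) = A(x + d), the
## cross-power spectrum FA * Conj(FB), normalized to unit magnitude, has its
## inverse-FFT peak at +d.
.phase_correlate <- function(A, B, search_window_px = 64, eps = 1e-12) {
  if (any(!is.finite(A)) || any(!is.finite(B))) .stopf("NaN/Inf in inputs")
  h <- nrow(A); w <- ncol(A)
  hann <- function(n) if (n == 1) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  win <- outer(hann(h), hann(w))
  FA <- stats::fft((A - mean(A)) * win)
  FB <- stats::fft((B - mean(B)) * win)
  X <- FA * Conj(FB)
  R <- X / (Mod(X) + eps)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  # wrapped displacement grids
  dy <- c(0:(h - 1)); dy[dy > h / 2] <- dy[dy > h / 2] - h
  dx <- c(0:(w - 1)); dx[dx > w / 2] <- dx[dx > w / 2] - w
  DY <- matrix(dy, h, w); DX <- matrix(dx, h, w, byrow = TRUE)
  ok <- abs(DY) <= search_window_px & abs(DX) <= search_window_px
  rm <- r; rm[!ok] <- -Inf
  p <- which.max(rm)
  py <- (p - 1) %% h + 1; px <- (p - 1) %/% h + 1
  peak <- r[py, px]
  # second peak outside a 5x5 exclusion zone (wrapped)
  excl <- (abs(((DY - DY[py, px] + h / 2) %% h) - h / 2) <= 2) &
          (abs(((DX - DX[py, px] + w / 2) %% w) - w / 2) <= 2)
  r2 <- rm; r2[excl] <- -Inf
  second <- max(r2[is.finite(r2)], 0)
  conf <- peak / max(second, eps)
  # sub-pixel refinement: side-lobe ratio of the Dirichlet-shaped peak
  # (delta = r1 / (r1 + r0), exact for an ideal sub-pixel translation)
  sub <- function(rm1, r0, rp1) {
    if (rp1 >= rm1) {
      if (rp1 <= 0 || r0 + rp1 <= eps) return(0)
      .clamp(rp1 / (rp1 + r0), -0.5, 0.5)
    } else {
      if (rm1 <= 0 || r0 + rm1 <= eps) return(0)
      .clamp(-rm1 / (rm1 + r0), -0.5, 0.5)
    }
  }
  ym <- if (py == 1) h else py - 1; yp <- if (py == h) 1 else py + 1
  xm <- if (px == 1) w else px - 1; xp <- if (px == w) 1 else px + 1
  ddy <- sub(r[ym, px], peak, r[yp, px])
  ddx <- sub(r[py, xm], peak, r[py, xp])
  list(shift = c(x = DX[py, px] + ddx, y = DY[py, px] + ddy),
       confidence = conf, peak = peak)
}

#' Register a pair of overlapping camera images
#'
#' Estimates the translation of `image_b` relative to `image_a` by
#' normalized cross-power-spectrum (phase) correlation on the overlap crops
#' implied by the predicted offset, with quadratic sub-pixel refinement.
#' Confidence is the ratio of the correlation peak to the second-highest
#' peak outside the peak's neighbourhood.
#'
#' @param image_a,image_b numeric matrices.
#' @param predicted_offset_px numeric `(x, y)`: predicted placement of
#'   `image_b`'s origin in `image_a`'s pixel frame (e.g. from array
#'   geometry).
#' @param search_window_px half-width of the residual-shift search (px).
#' @return list with `offset_px` (refined `(x, y)` offset of b relative to
#'   a), `confidence`, and `low_confidence` (logical flag, threshold 1.5).
#' @export
register_pair <- function(image_a, image_b, predicted_offset_px,
                          search_window_px = 64) {
  ha <- nrow(image_a); wa <- ncol(image_a)
  hb <- nrow(image_b); wb <- ncol(image_b)
  rel <- round(predicted_offset_px)
  x0 <- max(0, rel[1]); x1 <- min(wa, rel[1] + wb)
  y0 <- max(0, rel[2]); y1 <- min(ha, rel[2] + hb)
  if ((x1 - x0) < 32 || (y1 - y0) < 32)
    .stopf("predicted overlap smaller than 32 px (%d x %d)", x1 - x0, y1 - y0)
  A <- image_a[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  B <- image_b[(y0 - rel[2] + 1):(y1 - rel[2]),
               (x0 - rel[1] + 1):(x1 - rel[1]), drop = FALSE]
  pc <- .phase_correlate(A, B, search_window_px = search_window_px)
  # scene shift d between the crops means b's true origin is rel + d
  list(offset_px = c(rel[1] + pc$shift[["x"]], rel[2] + pc$shift[["y"]]),
       confidence = pc$confidence,
       low_confidence = pc$confidence < 1.5)
}

## Geometry-predicted relative offset (px) between rook-adjacent cameras:
## the image of a right/down neighbour is placed -m*pitch/pixel_pitch along
## that axis (camera images are world-inverted).
.predicted_neighbor_offset <- function(config) {
  m <- magnification(config$camera$focal_length_mm, config$working_distance_mm)
  -m * config$pitch_mm / (config$camera$pixel_pitch_um / 1000)
}

#' Ideal stitching template from array geometry
#'
#' The template implied by the thin-lens model alone (no registration):
#' useful as ground truth for simulated framesets and as the initial guess
#' for [calibrate_template()].
#'
#' @param config an [array_config()].
#' @param feather_px feather ramp width for blending.
#' @return a `stitch_template`.
#' @export
ideal_template <- function(config, feather_px = 32) {
  step <- .predicted_neighbor_offset(config)
  keys <- character(); off <- NULL
  for (r in seq_len(config$grid[1]) - 1L)
    for (cl in seq_len(config$grid[2]) - 1L) {
      keys <- c(keys, .frameset_key(r, cl))
      off <- rbind(off, c(cl * step, r * step))
    }
  .finish_template(off, keys, config, feather_px,
                   residuals = data.frame(), source_hash = "geometry")
}

.finish_template <- function(off, keys, config, feather_px, residuals,
                             source_hash) {
  anchor <- off[1, ]
  shift <- c(min(off[, 1]), min(off[, 2]))
  off <- sweep(off, 2, shift)
  rownames(off) <- keys
  colnames(off) <- c("x", "y")
  sensor <- config$camera$sensor_px
  m <- magnification(config$camera$focal_length_mm, config$working_distance_mm)
  structure(list(global_offset_px = off,
                 mosaic_shape_px = c(ceiling(max(off[, 1])) + sensor[1],
                                     ceiling(max(off[, 2])) + sensor[2]),
                 anchor_offset_px = anchor - shift,
                 blend = list(feather_px = feather_px),
                 scale_um_per_px = config$camera$pixel_pitch_um / m,
                 grid = config$grid,
                 residuals = residuals,
                 source_hash = source_hash),
            class = "stitch_template")
}

#' Estimate a calibration stitching template
#'
#' Registers every rook-adjacent camera pair of a feature-rich calibration
#' frameset by phase correlation, then solves for per-camera global
#' translations by weighted least squares over the pairwise constraints with
#' camera (0,0) anchored at the origin. Pair weights equal registration
#' confidence (floored at 0.05); the template records per-pair residuals and
#' is reused for all subsequent framesets.
#'
#' @param frameset a `raw_frameset` of a feature-rich scene (see
#'   [make_calibration_scene()]).
#' @param config an [array_config()]; defaults to the frameset's.
#' @param search_window_px residual search half-width per pair.
#' @param feather_px feather width stored for blending.
#' @return a `stitch_template`.
#' @export
calibrate_template <- function(frameset, config = frameset$array_config,
                               search_window_px = 64, feather_px = 32) {
  nr <- config$grid[1]; nc <- config$grid[2]
  ncam <- nr * nc
  idx <- function(r, cl) r * nc + cl + 1L
  keys <- character(ncam)
  for (r in seq_len(nr) - 1L) for (cl in seq_len(nc) - 1L)
    keys[idx(r, cl)] <- .frameset_key(r, cl)
  if (ncam == 1L)
    return(.finish_template(matrix(0, 1, 2), keys, config, feather_px,
                            data.frame(), .hash_frameset(frameset)))
  step <- .predicted_neighbor_offset(config)
  pairs <- list()
  for (r in seq_len(nr) - 1L) for (cl in seq_len(nc) - 1L) {
    if (cl + 1L < nc)
      pairs[[length(pairs) + 1L]] <- list(i = idx(r, cl), j = idx(r, cl + 1L),
                                          pred = c(step, 0))
    if (r + 1L < nr)
      pairs[[length(pairs) + 1L]] <- list(i = idx(r, cl), j = idx(r + 1L, cl),
                                          pred = c(0, step))
  }
  meas <- matrix(NA_real_, length(pairs), 2)
  confs <- numeric(length(pairs))
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    reg <- register_pair(frameset$frames[[keys[pr$i]]],
                         frameset$frames[[keys[pr$j]]],
                         predicted_offset_px = pr$pred,
                         search_window_px = search_window_px)
    meas[p, ] <- reg$offset_px
    confs[p] <- reg$confidence
  }
  # connectivity check over all registered pairs
  parent <- seq_len(ncam)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (p in seq_along(pairs))
    parent[find(pairs[[p]]$i)] <- find(pairs[[p]]$j)
  roots <- vapply(seq_len(ncam), find, integer(1))
  if (length(unique(roots)) > 1L) {
    bad <- keys[roots != roots[1]][1]
    .stopf("camera %s has no confident constraint to the anchor component", bad)
  }
  # weighted least squares per axis, camera 1 anchored at 0
  w <- sqrt(pmax(confs, 0.05))
  Amat <- matrix(0, length(pairs), ncam - 1L)
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    if (pr$i > 1L) Amat[p, pr$i - 1L] <- -w[p]
    if (pr$j > 1L) Amat[p, pr$j - 1L] <- w[p]
  }
  off <- matrix(0, ncam, 2)
  for (ax in 1:2) {
    fit <- qr.solve(Amat, w * meas[, ax])
    off[-1L, ax] <- fit
  }
  res <- data.frame(i = keys[vapply(pairs, `[[`, 1L, "i")],
                    j = keys[vapply(pairs, `[[`, 1L, "j")],
                    confidence = confs,
                    residual_px = vapply(seq_along(pairs), function(p) {
                      pr <- pairs[[p]]
                      sqrt(sum((off[pr$j, ] - off[pr$i, ] - meas[p, ])^2))
                    }, numeric(1)))
  .finish_template(off, keys, config, feather_px, res,
                   .hash_frameset(frameset))
}

.hash_frameset <- function(frameset) {
  s <- vapply(frameset$frames, sum, numeric(1))
  sprintf("fs-%d-%.6e", length(s), sum(s))
}

#' Stitch a frameset into a mosaic using a template
#'
#' Places each camera image at its template offset and combines overlaps by
#' linear feathering (weights ramp to zero at image edges and the weighted
#' sum is renormalized, so weights form a partition of unity wherever any
#' image contributes).
#'
#' @param frameset a `raw_frameset` whose grid matches the template.
#' @param template a `stitch_template`.
#' @param blend_mode `"feather"` or `"overwrite"` (later cameras overwrite).
#' @return an object of class `mosaic_frame`: `image`, `scale_um_per_px`,
#'   `frame_index`, `template_id`.
#' @export
apply_template <- function(frameset, template,
                           blend_mode = c("feather", "overwrite")) {
  blend_mode <- match.arg(blend_mode)
  keys <- rownames(template$global_offset_px)
  if (!all(keys %in% names(frameset$frames)))
    .stopf("frameset grid does not match the stitch template")
  sensor_w <- ncol(frameset$frames[[keys[1]]])
  sensor_h <- nrow(frameset$frames[[keys[1]]])
  W <- template$mosaic_shape_px[1]; H <- template$mosaic_shape_px[2]
  feather <- max(1, template$blend$feather_px)
  wx <- pmin(pmin(seq_len(sensor_w), rev(seq_len(sensor_w))) / feather, 1)
  wy <- pmin(pmin(seq_len(sensor_h), rev(seq_len(sensor_h))) / feather, 1)
  wgt <- outer(wy, wx)
  num <- matrix(0, H, W)
  den <- matrix(0, H, W)
  for (k in keys) {
    img <- frameset$frames[[k]]
    if (nrow(img) != sensor_h || ncol(img) != sensor_w)
      .stopf("image dimensions do not match the template")
    of <- template$global_offset_px[k, ]
    o <- floor(of)
    fr <- of - o
    if (max(fr) > 0.01) {
      # sub-pixel placement: resample the image at the fractional offset
      gx <- matrix(seq_len(sensor_w) - 1 - fr[1], sensor_h, sensor_w,
                   byrow = TRUE)
      gy <- matrix(seq_len(sensor_h) - 1 - fr[2], sensor_h, sensor_w)
      img <- matrix(.bilinear_at(img, gx, gy), sensor_h, sensor_w)
    }
    ys <- (o[2] + 1):(o[2] + sensor_h)
    xs <- (o[1] + 1):(o[1] + sensor_w)
    if (blend_mode == "feather") {
      num[ys, xs] <- num[ys, xs] + wgt * img
      den[ys, xs] <- den[ys, xs] + wgt
    } else {
      num[ys, xs] <- img
      den[ys, xs] <- 1
    }
  }
  img <- num
  nz <- den > 0
  img[nz] <- num[nz] / den[nz]
  # uncovered margins carry no data; neutral fill avoids phantom dark edges
  if (any(!nz) && any(nz)) img[!nz] <- mean(img[nz])
  structure(list(image = img, scale_um_per_px = template$scale_um_per_px,
                 frame_index = frameset$frame_index,
                 template_id = template$source_hash),
            class = "mosaic_frame")
}

#' Map world coordinates to mosaic pixel coordinates (and back)
#'
#' Uses the camera nearest to the point together with its template offset.
#' The mosaic is a 180-degree-rotated rendition of the world (camera images
#' are inverted by the optics and stitched translation-only).
#'
#' @param p numeric `(x, y)` world mm (z assumed 0).
#' @param config an [array_config()].
#' @param template a `stitch_template`.
#' @return `(x, y)` 0-based mosaic pixel coordinates.
#' @export
world_to_mosaic <- function(p, config, template) {
  rc <- .nearest_camera(p, config)
  px <- project_to_camera(c(p[1], p[2], 0), config, rc[1], rc[2])
  off <- template$global_offset_px[.frameset_key(rc[1], rc[2]), ]
  c(x = unname(px[1] + off[1]), y = unname(px[2] + off[2]))
}

#' @rdname world_to_mosaic
#' @param px numeric `(x, y)` 0-based mosaic pixel coordinates.
#' @export
mosaic_to_world <- function(px, config, template) {
  keys <- rownames(template$global_offset_px)
  sensor <- config$camera$sensor_px
  ctr <- t(t(template$global_offset_px) + sensor / 2)
  d2 <- (ctr[, 1] - px[1])^2 + (ctr[, 2] - px[2])^2
  k <- keys[which.min(d2)]
  rc <- as.integer(sub("r(\\d+)_c(\\d+)", "\\1", k))
  cl <- as.integer(sub("r(\\d+)_c(\\d+)", "\\2", k))
  off <- template$global_offset_px[k, ]
  camera_to_world(c(px[1] - off[1], px[2] - off[2]), config, rc, cl)
}

.nearest_camera <- function(p, config) {
  best <- c(0L, 0L); bd <- Inf
  for (r in seq_len(config$grid[1]) - 1L)
    for (cl in seq_len(config$grid[2]) - 1L) {
      cc <- .camera_center(config, r, cl)
      d <- sum((p[1:2] - cc)^2)
      if (d < bd) { bd <- d; best <- c(r, cl) }
    }
  best
}

#' Read / write a stitch template as JSON
#' @param template a `stitch_template`.
#' @param path file path.
#' @export
write_stitch_template <- function(template, path) {
  x <- unclass(template)
  x$global_offset_px <- cbind(key = rownames(template$global_offset_px),
                              as.data.frame(template$global_offset_px))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_stitch_template
#' @export
read_stitch_template <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  off <- cbind(x = as.numeric(x$global_offset_px$x),
               y = as.numeric(x$global_offset_px$y))
  rownames(off) <- x$global_offset_px$key
  structure(list(global_offset_px = off,
                 mosaic_shape_px = x$mosaic_shape_px,
                 anchor_offset_px = x$anchor_offset_px,
                 blend = x$blend,
                 scale_um_per_px = x$scale_um_per_px,
                 grid = x$grid,
                 residuals = as.data.frame(x$residuals),
                 source_hash = x$source_hash),
            class = "stitch_template")
}
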