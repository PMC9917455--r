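#' Occupancy probability heatmap
#'
#' 2-D histogram of positions over an arena, normalized to sum to 1 (a
#' spatial probability map of finding an organism at a location).
#'
#' @param track_positions n x 2 matrix or data frame of `(x, y)` positions
#'   (mm).
#' @param arena_box `(xmin, ymin, xmax, ymax)` mm.
#' @param bin_size bin edge length, mm.
#' @return object of class `occupancy_map`: `grid` (rows = y bins),
#'   `bin_size_mm`, `arena_box_mm`, `n_samples`.
#' @export
occupancy_heatmap <- function(track_positions, arena_box, bin_size = 1) {
  pos <- as.matrix(track_positions)[, 1:2, drop = FALSE]
  if (nrow(pos) == 0L) .stopf("no positions given")
  out_of <- pos[, 1] < arena_box[1] | pos[, 1] > arena_box[3] |
            pos[, 2] < arena_box[2] | pos[, 2] > arena_box[4]
  if (any(out_of)) {
    warning(sprintf("%d positions outside the arena were clipped", sum(out_of)))
    pos[, 1] <- .clamp(pos[, 1], arena_box[1], arena_box[3])
    pos[, 2] <- .clamp(pos[, 2], arena_box[2], arena_box[4])
  }
  nx <- max(1L, ceiling((arena_box[3] - arena_box[1]) / bin_size))
  ny <- max(1L, ceiling((arena_box[4] - arena_box[2]) / bin_size))
  ix <- pmin(1L + floor((pos[, 1] - arena_box[1]) / bin_size), nx)
  iy <- pmin(1L + floor((pos[, 2] - arena_box[2]) / bin_size), ny)
  grid <- matrix(0, ny, nx)
  for (k in seq_len(nrow(pos))) grid[iy[k], ix[k]] <- grid[iy[k], ix[k]] + 1
  structure(list(grid = grid / nrow(pos), bin_size_mm = bin_size,
                 arena_box_mm = arena_box, n_samples = nrow(pos)),
            class = "occupancy_map")
}

## --- skeleton machinery -----------------------------------------------------

## Zhang-Suen thinning of a logical mask to a 1-px-wide skeleton.
.skeletonize <- function(mask) {
  img <- mask != 0
  sh <- function(m, dy, dx) .shift_mat(m * 1, dy, dx, 0)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P <- img * 1
      p2 <- sh(P, 1, 0);  p3 <- sh(P, 1, -1); p4 <- sh(P, 0, -1)
      p5 <- sh(P, -1, -1); p6 <- sh(P, -1, 0); p7 <- sh(P, -1, 1)
      p8 <- sh(P, 0, 1);  p9 <- sh(P, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { img[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

## Longest geodesic path through a skeleton (prunes short spurs); returns
## the ordered pixel path as an n x 2 matrix of (x, y), 0-based.
.skeleton_path <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  px <- which(skel)
  if (length(px) < 3) .stopf("skeleton too small")
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  nb_of <- function(i) {
    y <- (i - 1) %% h + 1; x <- (i - 1) %/% h + 1
    yy <- y + offs[, 1]; xx <- x + offs[, 2]
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    j <- (xx[ok] - 1) * h + yy[ok]
    j[skel[j]]
  }
  bfs_far <- function(start) {
    dist <- rep(NA_integer_, h * w)
    parent <- integer(h * w)
    dist[start] <- 0L
    q <- c(start); head <- 1L
    last <- start
    while (head <= length(q)) {
      cur <- q[head]; head <- head + 1L
      for (j in nb_of(cur)) if (is.na(dist[j])) {
        dist[j] <- dist[cur] + 1L
        parent[j] <- cur
        q <- c(q, j)
        last <- j
      }
    }
    list(far = last, parent = parent)
  }
  a <- bfs_far(px[1])$far
  b <- bfs_far(a)
  # walk back from the farthest point to a
  path <- integer()
  cur <- b$far
  while (cur != 0L && cur != a) { path <- c(path, cur); cur <- b$parent[cur] }
  path <- c(path, a)
  cbind(x = (path - 1) %/% h, y = (path - 1) %% h)
}

## Otsu threshold (maximum between-class variance) on a 256-bin histogram.
.otsu <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(255L, floor((x - rng[1]) / diff(rng) * 256)) + 1L, 256L)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(256) - 0.5) / 256 * diff(rng)
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256]
  bc <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

## Binarize a crop containing one dark organism; returns the largest
## component's mask.
.organism_mask <- function(crop, min_area_px = 30) {
  mask <- crop < .otsu(crop)
  lab <- label_components(mask, connectivity = 8L)
  if (lab$n == 0L) .stopf("no organism blob found in the crop")
  areas <- tabulate(lab$labels[lab$labels > 0], lab$n)
  big <- which.max(areas)
  if (areas[big] < min_area_px)
    .stopf("largest blob (%d px) is below the minimum area %d", areas[big],
           min_area_px)
  lab$labels == big
}

## Bilinear sampling of a matrix at 0-based real coordinates.
.bilinear_at <- function(M, x, y) {
  x <- as.vector(x); y <- as.vector(y)
  h <- nrow(M); w <- ncol(M)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  gx0 <- .clamp(x0 + 1, 1, w); gy0 <- .clamp(y0 + 1, 1, h)
  gx1 <- .clamp(gx0 + 1, 1, w); gy1 <- .clamp(gy0 + 1, 1, h)
  M[cbind(gy0, gx0)] * (1 - fx) * (1 - fy) +
    M[cbind(gy0, gx1)] * fx * (1 - fy) +
    M[cbind(gy1, gx0)] * (1 - fx) * fy +
    M[cbind(gy1, gx1)] * fx * fy
}

## Head-first sub-pixel body midline of the organism in a crop:
## skeletonize, orient by body width, smooth, and recentre each point on the
## distance-transform ridge along the local normal (removes the one-sided
## staircase bias of the raw thinning skeleton).
.body_midline <- function(crop, min_area_px = 30, win = 9L) {
  mask <- .organism_mask(crop, min_area_px)
  skel <- .skeletonize(mask)
  path <- .skeleton_path(skel)
  dm <- as.matrix(EBImage::distmap(mask * 1))
  wid <- dm[cbind(path[, 2] + 1, path[, 1] + 1)]
  n <- nrow(path)
  q <- max(3L, round(n * 0.2))
  if (mean(wid[seq_len(q)]) < mean(wid[(n - q + 1):n]))
    path <- path[n:1, , drop = FALSE]      # wider (head) end first
  sm <- function(v) {
    f <- stats::filter(v, rep(1 / win, win), sides = 2)
    f[is.na(f)] <- v[is.na(f)]
    as.numeric(f)
  }
  px <- sm(path[, 1]); py <- sm(path[, 2])
  tx <- sm(c(diff(px), diff(px)[n - 1])); ty <- sm(c(diff(py), diff(py)[n - 1]))
  nrm <- sqrt(tx^2 + ty^2) + 1e-12
  nx <- -ty / nrm; ny <- tx / nrm
  offs <- seq(-2, 2, by = 0.5)
  V <- sapply(offs, function(o) .bilinear_at(dm, px + o * nx, py + o * ny))
  best <- offs[max.col(V, ties.method = "first")]
  px <- sm(px + best * nx); py <- sm(py + best * ny)
  d <- sqrt(diff(px)^2 + diff(py)^2)
  s <- c(0, cumsum(d))
  L <- s[length(s)]
  if (L <= 0) .stopf("degenerate skeleton")
  list(x = px, y = py, s = s, length = L, mask = mask, dm = dm)
}

## Head-region body axis (radians, image coordinates with y down).
.body_axis <- function(ml) {
  ax <- stats::approx(ml$s, ml$x, c(0.05, 0.3) * ml$length)$y
  ay <- stats::approx(ml$s, ml$y, c(0.05, 0.3) * ml$length)$y
  atan2(ay[2] - ay[1], ax[2] - ax[1])
}

#' Tail kinematics from a single-organism crop
#'
#' Binarizes the crop, skeletonizes the largest component (Zhang-Suen
#' thinning), orients the midline with the head at the wider body end
#' (distance-transform maximum), refines it to the sub-pixel medial ridge,
#' resamples it into `n_segments` equal arc-length segments, and reports
#' each segment's chord angle relative to the head-region body axis.
#'
#' @param fish_crop grayscale crop containing one organism (dark on bright).
#' @param n_segments number of tail segments.
#' @param min_area_px minimum organism blob area.
#' @return object of class `tail_trace`: `segment_angles_rad` (head to tail,
#'   relative to the body axis), `body_axis_rad` (image coordinates, y
#'   down), `n_segments`.
#' @export
tail_trace <- function(fish_crop, n_segments = 8L, min_area_px = 30) {
  ml <- .body_midline(fish_crop, min_area_px)
  L <- ml$length
  ts <- seq(0.05 * L, 0.95 * L, length.out = n_segments + 1L)  # trim end spurs
  rx <- stats::approx(ml$s, ml$x, ts)$y
  ry <- stats::approx(ml$s, ml$y, ts)$y
  body_axis <- .body_axis(ml)
  ang <- atan2(diff(ry), diff(rx)) - body_axis
  ang <- atan2(sin(ang), cos(ang))         # wrap to (-pi, pi]
  structure(list(segment_angles_rad = unname(ang),
                 body_axis_rad = unname(body_axis),
                 n_segments = as.integer(n_segments)),
            class = "tail_trace")
}

#' Eye angles from a fish head crop
#'
#' Locates the head (as in [tail_trace()]), finds the two darkest elliptical
#' components in the head region, and reports each eye's second-moment
#' major-axis orientation relative to the body axis; left/right assignment
#' follows the sign of the cross product with the body axis.
#'
#' @param fish_crop grayscale crop containing one fish.
#' @return list with `left_rad`, `right_rad` (relative orientations, `NA`
#'   with `missing = TRUE` if fewer than two eye blobs are found).
#' @export
eye_angles <- function(fish_crop) {
  ml <- .body_midline(fish_crop)
  mask <- ml$mask
  head_xy <- c(ml$x[1], ml$y[1])
  L <- ml$length
  body_ang <- .body_axis(ml)
  body_vec <- c(cos(body_ang), sin(body_ang))
  # head region: body pixels within 35% body length of the head end
  ys <- row(mask) - 1; xs <- col(mask) - 1
  head_reg <- mask & sqrt((xs - head_xy[1])^2 + (ys - head_xy[2])^2) <= 0.35 * L
  vals <- fish_crop[head_reg]
  if (!length(vals)) return(list(left_rad = NA_real_, right_rad = NA_real_,
                                 missing = TRUE))
  eye_mask <- head_reg & fish_crop < stats::quantile(vals, 0.2) &
    fish_crop < 0.5 * stats::median(vals)
  lab <- label_components(eye_mask, connectivity = 8L)
  if (lab$n < 2) return(list(left_rad = NA_real_, right_rad = NA_real_,
                             missing = TRUE))
  areas <- tabulate(lab$labels[lab$labels > 0], lab$n)
  top2 <- order(areas, decreasing = TRUE)[1:2]
  res <- list()
  for (ei in 1:2) {
    sel <- lab$labels == top2[ei]
    ex <- xs[sel]; ey <- ys[sel]
    mx <- mean(ex); my <- mean(ey)
    mu20 <- mean((ex - mx)^2); mu02 <- mean((ey - my)^2)
    mu11 <- mean((ex - mx) * (ey - my))
    orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
    rel <- orient - body_ang
    rel <- atan2(sin(rel), cos(rel))
    if (rel > pi / 2) rel <- rel - pi
    if (rel < -pi / 2) rel <- rel + pi
    cross <- body_vec[1] * (my - head_xy[2]) - body_vec[2] * (mx - head_xy[1])
    res[[ei]] <- list(rel = rel, side = cross)
  }
  # image y is down: negative cross product = left of the heading
  left <- if (res[[1]]$side < 0) res[[1]]$rel else res[[2]]$rel
  right <- if (res[[1]]$side < 0) res[[2]]$rel else res[[1]]$rel
  list(left_rad = left, right_rad = right, missing = FALSE)
}

#' Optical-flow activity index of an image sequence
#'
#' Dense block matching between consecutive frames: each block's
#' displacement is the best-SSD integer offset within the search window;
#' frame activity is the mean displacement magnitude over textured blocks.
#'
#' @param frame_sequence list of >= 2 equal-size matrices.
#' @param block_px block edge (px).
#' @param search_px search half-width (px).
#' @param texture_threshold minimum block intensity variance for inclusion.
#' @param epochs optional labels (length `n_frames - 1`) for epoch means.
#' @return list with `activity_px` (per frame pair), `epoch_means` (named,
#'   or `NULL`).
#' @export
optical_flow_activity <- function(frame_sequence, block_px = 16L,
                                  search_px = 4L, texture_threshold = 1e-5,
                                  epochs = NULL) {
  nfr <- length(frame_sequence)
  if (nfr < 2) .stopf("need at least 2 frames")
  h <- nrow(frame_sequence[[1]]); w <- ncol(frame_sequence[[1]])
  if (block_px > h || block_px > w) .stopf("block larger than frame")
  nby <- h %/% block_px; nbx <- w %/% block_px
  hh <- nby * block_px; ww <- nbx * block_px
  # block aggregation matrices
  Gy <- matrix(0, hh, nby); Gx <- matrix(0, ww, nbx)
  for (b in seq_len(nby)) Gy[((b - 1) * block_px + 1):(b * block_px), b] <- 1
  for (b in seq_len(nbx)) Gx[((b - 1) * block_px + 1):(b * block_px), b] <- 1
  act <- numeric(nfr - 1)
  for (t in seq_len(nfr - 1)) {
    A <- frame_sequence[[t]][1:hh, 1:ww, drop = FALSE]
    B <- frame_sequence[[t + 1]][1:hh, 1:ww, drop = FALSE]
    bm <- crossprod(Gy, A %*% Gx) / block_px^2
    bv <- crossprod(Gy, A^2 %*% Gx) / block_px^2 - bm^2
    textured <- bv > texture_threshold
    best <- matrix(Inf, nby, nbx)
    mag <- matrix(0, nby, nbx)
    for (dy in -search_px:search_px) for (dx in -search_px:search_px) {
      D2 <- (A - .shift_mat(B, dy, dx, NA))^2
      # exclude pad-contaminated borders from the comparison
      D2[is.na(D2)] <- 0
      ssd <- crossprod(Gy, D2 %*% Gx)
      upd <- ssd < best
      best[upd] <- ssd[upd]
      mag[upd] <- sqrt(dy^2 + dx^2)
    }
    act[t] <- if (any(textured)) mean(mag[textured]) else 0
  }
  epoch_means <- NULL
  if (!is.null(epochs)) {
    if (length(epochs) != nfr - 1) .stopf("epochs must label each frame pair")
    epoch_means <- tapply(act, epochs, mean)
  }
  list(activity_px = act, epoch_means = epoch_means)
}

#' Label connected components of a binary mask
#'
#' 4- or 8-connectivity labelling; adjacent foreground pixels are unioned
#' via a graph-components pass.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return list with `labels` (integer matrix, 0 = background) and `n`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) .stopf("unknown connectivity %d", connectivity)
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, h, w)
  if (!length(fg)) return(list(labels = labels, n = 0L))
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- NULL
  for (o in offs) {
    nb <- .shift_mat(mask, -o[1], -o[2], FALSE)   # neighbour at (y+dy, x+dx)
    both <- mask & nb
    i <- which(both)
    if (length(i)) {
      j <- i + o[1] + o[2] * h
      edges <- rbind(edges, cbind(i, j))
    }
  }
  comp_id <- seq_along(fg)
  names(comp_id) <- fg
  if (!is.null(edges)) {
    g <- igraph::graph_from_edgelist(
      cbind(match(edges[, 1], fg), match(edges[, 2], fg)), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp_id <- igraph::components(g)$membership
  }
  # renumber components consecutively in first-pixel order
  first <- !duplicated(comp_id)
  remap <- integer(max(comp_id))
  remap[comp_id[first]] <- seq_len(sum(first))
  labels[fg] <- remap[comp_id]
  list(labels = labels, n = max(remap))
}

#' Reference threshold segmenter
#'
#' Classical mask producer satisfying the segmenter contract: adaptive
#' (local-mean) thresholding of dark objects followed by a morphological
#' opening.
#'
#' @param image grayscale matrix.
#' @param radius_px local-mean radius.
#' @param offset relative darkness required (fraction of local mean).
#' @param open_radius_px opening structuring-element radius (0 = skip).
#' @return logical mask.
#' @export
reference_segmenter <- function(image, radius_px = 25L, offset = 0.12,
                                open_radius_px = 1L) {
  local_mean <- .box_mean(image, radius_px)
  mask <- image < local_mean * (1 - offset)
  if (open_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * open_radius_px + 1L, shape = "box")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  mask
}

#' Count individuals and swarms in a segmentation mask
#'
#' Connected-component labelling of the segmenter's mask at the stated
#' connectivity; components below `min_area_px` are discarded and the rest
#' are split into individuals and swarms by an area rule. Densities use the
#' mosaic's object-space sampling.
#'
#' @param mosaic a `mosaic_frame` (or plain matrix with `scale_um_per_px`
#'   supplied).
#' @param segmenter function image -> logical mask; default
#'   [reference_segmenter()]. A precomputed logical mask is also accepted.
#' @param min_area_px discard components smaller than this.
#' @param swarm_area_threshold_px components at or above this area are
#'   swarms; `NULL` = 5x the median retained component area.
#' @param connectivity 4 or 8.
#' @param scale_um_per_px required if `mosaic` is a plain matrix.
#' @return object of class `segmentation_counts`: `n_individuals`,
#'   `n_swarms`, `component_areas_px` (list of two vectors),
#'   `density_individuals_per_cm2`, `density_swarms_per_cm2`,
#'   `arena_area_cm2`.
#' @export
segment_count <- function(mosaic, segmenter = reference_segmenter,
                          min_area_px = 50L, swarm_area_threshold_px = NULL,
                          connectivity = 8L, scale_um_per_px = NULL) {
  if (inherits(mosaic, "mosaic_frame")) {
    img <- mosaic$image
    scale_um_per_px <- mosaic$scale_um_per_px
  } else img <- mosaic
  mask <- if (is.logical(segmenter) || is.matrix(segmenter)) segmenter != 0
          else segmenter(img)
  lab <- label_components(mask, connectivity = connectivity)
  areas <- if (lab$n > 0) tabulate(lab$labels[lab$labels > 0], lab$n) else integer()
  areas <- areas[areas >= min_area_px]
  if (is.null(swarm_area_threshold_px))
    swarm_area_threshold_px <- if (length(areas)) 5 * stats::median(areas) else Inf
  ind <- areas[areas < swarm_area_threshold_px]
  sw <- areas[areas >= swarm_area_threshold_px]
  area_cm2 <- if (!is.null(scale_um_per_px))
    prod(dim(img)) * (scale_um_per_px / 1e4)^2 else NA_real_
  structure(list(n_individuals = length(ind), n_swarms = length(sw),
                 component_areas_px = list(individuals = ind, swarms = sw),
                 density_individuals_per_cm2 = if (is.na(area_cm2)) NA_real_
                   else length(ind) / area_cm2,
                 density_swarms_per_cm2 = if (is.na(area_cm2)) NA_real_
                   else length(sw) / area_cm2,
                 arena_area_cm2 = area_cm2),
            class = "segmentation_counts")
}

#' Densities with a standard error over spatial blocks
#'
#' @param block_counts object counts per arena block (the block partition is
#'   chosen by the caller, e.g. a 4x4 grid of equal-area blocks).
#' @param area_cm2 total arena area (> 0).
#' @return list with `density_per_cm2` (total count / area), `sem_per_cm2`
#'   (standard error of the per-block densities), `n_blocks`.
#' @export
density_per_area <- function(block_counts, area_cm2) {
  if (area_cm2 <= 0) .stopf("area must be positive")
  n <- length(block_counts)
  total <- sum(block_counts)
  if (n == 0L || total == 0)
    return(list(density_per_cm2 = 0, sem_per_cm2 = 0, n_blocks = n))
  block_area <- area_cm2 / n
  bd <- block_counts / block_area
  sem <- if (n > 1) stats::sd(bd) / sqrt(n) else 0
  list(density_per_cm2 = total / area_cm2, sem_per_cm2 = sem, n_blocks = n)
}
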