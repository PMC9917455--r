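#' Plan overlapping tiles over a large mosaic
#'
#' Row-major grid of tile origins at multiples of the stride; the final
#' row/column is clamped so tiles end exactly at the mosaic edge. Every
#' mosaic pixel is covered by at least one tile.
#'
#' @param mosaic_shape integer `(width, height)` px.
#' @param tile_px integer `(w, h)` tile size (scalar recycled).
#' @param stride_px integer `(sx, sy)` stride (scalar recycled; must be >= 1
#'   and <= tile).
#' @return an object of class `tile_plan`: `tile_px`, `stride_px`, `tiles`
#'   (matrix of `(x0, y0)` origins), `mosaic_shape_px`.
#' @export
plan_tiles <- function(mosaic_shape, tile_px = 1024L, stride_px = NULL) {
  if (length(tile_px) == 1L) tile_px <- rep(tile_px, 2)
  if (is.null(stride_px)) stride_px <- tile_px - 300L
  if (length(stride_px) == 1L) stride_px <- rep(stride_px, 2)
  if (any(tile_px < 1) || any(stride_px < 1))
    .stopf("tile and stride must be positive")
  tile_px <- pmin(as.integer(tile_px), as.integer(mosaic_shape))
  stride_px <- pmin(as.integer(stride_px), tile_px)
  origins_axis <- function(extent, tile, stride) {
    if (tile >= extent) return(0L)
    o <- seq(0L, extent - tile, by = stride)
    if (o[length(o)] + tile < extent) o <- c(o, extent - tile)
    o
  }
  ox <- origins_axis(mosaic_shape[1], tile_px[1], stride_px[1])
  oy <- origins_axis(mosaic_shape[2], tile_px[2], stride_px[2])
  tiles <- as.matrix(expand.grid(x0 = ox, y0 = oy))
  structure(list(tile_px = tile_px, stride_px = stride_px, tiles = tiles,
                 mosaic_shape_px = as.integer(mosaic_shape)),
            class = "tile_plan")
}

#' Intersection-over-union of axis-aligned boxes
#'
#' @param a,b numeric `(x0, y0, x1, y1)` half-open boxes, or matrices with
#'   such rows (`box_iou` is vectorized over rows of `b`).
#' @return numeric IoU values.
#' @export
box_iou <- function(a, b) {
  if (is.null(dim(b))) b <- matrix(b, 1)
  ix <- pmax(0, pmin(a[3], b[, 3]) - pmax(a[1], b[, 1]))
  iy <- pmax(0, pmin(a[4], b[, 4]) - pmax(a[2], b[, 2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (area_a + area_b - inter)
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in order of descending score (ties broken by lower box
#' index); a box is suppressed iff its IoU with an already-kept box exceeds
#' the threshold.
#'
#' @param boxes matrix with rows `(x0, y0, x1, y1)`.
#' @param scores numeric vector, one per box.
#' @param iou_threshold suppression threshold in \[0, 1\].
#' @return integer indices of kept boxes (in kept order).
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4)
  if (nrow(boxes) == 0L) return(integer())
  if (ncol(boxes) != 4L || nrow(boxes) != length(scores))
    .stopf("boxes must be n x 4 with one score per box")
  if (any(boxes[, 3] <= boxes[, 1]) || any(boxes[, 4] <= boxes[, 2]))
    .stopf("malformed boxes (x1 <= x0 or y1 <= y0)")
  if (iou_threshold < 0 || iou_threshold > 1)
    .stopf("iou_threshold must be in [0, 1]")
  ord <- order(-scores, seq_along(scores))
  kept <- integer()
  alive <- rep(TRUE, nrow(boxes))
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    if (length(kept) && any(alive)) {
      iou <- box_iou(boxes[i, ], boxes)
      # exact duplicates are always redundant, even at threshold 1
      alive <- alive & !(iou > iou_threshold | iou >= 1)
    }
  }
  kept
}

#' Classical difference-of-Gaussians blob detector
#'
#' A desk-scale reference detector satisfying the tile-detector contract:
#' band-pass the tile at the requested blob scales, threshold with the
#' requested polarity, group by connected components, and return one box per
#' component with a normalized peak-response score.
#'
#' @param image grayscale tile matrix.
#' @param scale_range_px `(min, max)` blob diameter range in px.
#' @param polarity `"dark"` (objects darker than background) or `"bright"`.
#' @param threshold absolute band-pass response threshold (intensity units);
#'   an absolute cut keeps empty tiles empty.
#' @param min_area_px discard components smaller than this.
#' @return list with `boxes` (n x 4 matrix, half-open pixel coords),
#'   `scores` (peak response, normalized per tile to \[0, 1\]), `labels`.
#' @export
reference_blob_detector <- function(image, scale_range_px = c(8, 60),
                                    polarity = c("dark", "bright"),
                                    threshold = 0.06, min_area_px = 20) {
  polarity <- match.arg(polarity)
  if (length(scale_range_px) != 2L || any(scale_range_px <= 0) ||
      diff(scale_range_px) < 0)
    .stopf("scale_range_px must be an increasing positive pair")
  x <- if (polarity == "dark") -image else image
  s1 <- scale_range_px[1] / 2.355          # FWHM -> sigma
  s2 <- scale_range_px[2] / 2.355
  resp <- blur_gaussian(x, s1) - blur_gaussian(x, s2)
  mx <- max(resp)
  empty <- list(boxes = matrix(numeric(), 0, 4), scores = numeric(),
                labels = character())
  if (mx <= threshold) return(empty)
  mask <- resp > threshold
  # close gaps so elongated bodies yield a single component
  r <- max(1L, round(scale_range_px[1] / 2))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  mask <- EBImage::closing(mask * 1, brush) > 0.5
  lab <- label_components(mask, connectivity = 8L)
  if (lab$n == 0L) return(empty)
  boxes <- NULL; scores <- numeric()
  for (i in seq_len(lab$n)) {
    px <- which(lab$labels == i)
    if (length(px) < min_area_px) next
    rr <- (px - 1) %% nrow(mask) + 1
    cc <- (px - 1) %/% nrow(mask) + 1
    boxes <- rbind(boxes, c(min(cc) - 1, min(rr) - 1, max(cc), max(rr)))
    scores <- c(scores, max(resp[px]) / mx)
  }
  if (is.null(boxes)) return(empty)
  list(boxes = boxes, scores = scores,
       labels = rep("object", nrow(boxes)))
}

#' Run a tile detector over a large mosaic
#'
#' Applies any detector satisfying the contract `function(tile_image) ->
#' list(boxes, scores, labels)` (boxes in tile pixel coordinates) to every
#' tile of a plan, lifts boxes to mosaic coordinates, clips them, and
#' de-duplicates across tiles with per-label non-maximum suppression. A
#' detector failure on one tile is recorded and the remaining tiles proceed;
#' failure on all tiles is an error.
#'
#' @param mosaic a `mosaic_frame` or plain image matrix.
#' @param detector tile-detector function.
#' @param tile_plan a [plan_tiles()] result (default: one plan over the
#'   mosaic with 1024 px tiles).
#' @param nms_iou cross-tile suppression threshold.
#' @param border_margin_px boxes within this margin of a tile's interior
#'   border defer to the neighbouring tile that contains them fully (they
#'   are truncated views of an object the neighbour sees whole).
#' @return data frame of class `detections`: `x0, y0, x1, y1, score, label,
#'   tile_x0, tile_y0`, with attribute `failed_tiles`.
#' @export
detect_tiled <- function(mosaic, detector, tile_plan = NULL, nms_iou = 0.5,
                         border_margin_px = 4) {
  img <- if (inherits(mosaic, "mosaic_frame")) mosaic$image else mosaic
  if (is.null(tile_plan)) tile_plan <- plan_tiles(c(ncol(img), nrow(img)))
  tiles <- tile_plan$tiles
  tw <- tile_plan$tile_px[1]; th <- tile_plan$tile_px[2]
  out <- list(); failed <- list()
  for (t in seq_len(nrow(tiles))) {
    x0 <- unname(tiles[t, 1]); y0 <- unname(tiles[t, 2])
    tile <- img[(y0 + 1):(y0 + th), (x0 + 1):(x0 + tw), drop = FALSE]
    det <- tryCatch(detector(tile), error = function(e) e)
    if (inherits(det, "error")) {
      failed[[length(failed) + 1L]] <- list(tile = c(x0, y0),
                                            message = conditionMessage(det))
      next
    }
    if (is.null(det$boxes) || nrow(det$boxes) == 0L) next
    b <- det$boxes
    # drop truncated boxes hugging a tile's interior border when another
    # tile contains the box completely (cross-tile deferral)
    m <- border_margin_px
    hug <- (b[, 1] <= m & x0 > 0) | (b[, 2] <= m & y0 > 0) |
           (b[, 3] >= tw - m & x0 + tw < ncol(img)) |
           (b[, 4] >= th - m & y0 + th < nrow(img))
    b[, c(1, 3)] <- .clamp(b[, c(1, 3)] + x0, 0, ncol(img))
    b[, c(2, 4)] <- .clamp(b[, c(2, 4)] + y0, 0, nrow(img))
    drop <- logical(nrow(b))
    for (i in which(hug)) {
      inside <- tiles[, 1] + m < b[i, 1] & b[i, 3] < tiles[, 1] + tw - m &
                tiles[, 2] + m < b[i, 2] & b[i, 4] < tiles[, 2] + th - m
      drop[i] <- any(inside)
    }
    b <- b[!drop, , drop = FALSE]
    if (!nrow(b)) next
    out[[length(out) + 1L]] <- data.frame(
      x0 = b[, 1], y0 = b[, 2], x1 = b[, 3], y1 = b[, 4],
      score = det$scores[!drop],
      label = if (is.null(det$labels)) "object" else det$labels[!drop],
      tile_x0 = x0, tile_y0 = y0)
  }
  if (length(failed) == nrow(tiles) && nrow(tiles) > 0L)
    .stopf("detector failed on every tile (first error: %s)",
           failed[[1]]$message)
  det <- if (length(out)) do.call(rbind, out) else
    data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
               y1 = numeric(), score = numeric(), label = character(),
               tile_x0 = numeric(), tile_y0 = numeric())
  det <- det[det$x1 > det$x0 & det$y1 > det$y0, , drop = FALSE]
  keep <- logical(nrow(det))
  for (lb in unique(det$label)) {
    sel <- which(det$label == lb)
    k <- nms(as.matrix(det[sel, c("x0", "y0", "x1", "y1")]),
             det$score[sel], iou_threshold = nms_iou)
    keep[sel[k]] <- TRUE
  }
  det <- det[keep, , drop = FALSE]
  rownames(det) <- NULL
  attr(det, "failed_tiles") <- failed
  class(det) <- c("detections", class(det))
  det
}

#' Paste organism crops with controlled occlusion
#'
#' Synthesizes occluded training examples: masked crops are pasted onto a
#' background at random positions so that every pasted pair's box IoU falls
#' within `overlap_range`; the exact ground-truth boxes (including occluded
#' ones) are returned.
#'
#' @param organism_crops list of `list(image, mask)` (matrices; mask in
#'   \[0,1\]).
#' @param background background image matrix.
#' @param n_pastes number of crops to paste (cycled through the list).
#' @param overlap_range `(lo, hi)` subset of \[0, 1\]: required pairwise box
#'   IoU for pairs that overlap; `c(0, 0)` forbids overlap entirely.
#' @param seed integer seed; identical seeds give identical composites.
#' @param max_attempts placement attempts before giving up.
#' @return list with `image` (composite) and `boxes` (n x 4 matrix).
#' @export
occluder_augment <- function(organism_crops, background, n_pastes = 2L,
                             overlap_range = c(0, 0.3), seed = 1L,
                             max_attempts = 1000L) {
  if (any(overlap_range < 0) || any(overlap_range > 1) ||
      overlap_range[1] > overlap_range[2])
    .stopf("overlap_range must be an ordered pair within [0, 1]")
  img <- background
  boxes <- NULL
  if (n_pastes == 0L) return(list(image = img, boxes = matrix(numeric(), 0, 4)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(.derive_seed(seed, 23L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  H <- nrow(background); W <- ncol(background)
  for (p in seq_len(n_pastes)) {
    crop <- organism_crops[[(p - 1L) %% length(organism_crops) + 1L]]
    ch <- nrow(crop$image); cw <- ncol(crop$image)
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      x0 <- sample.int(W - cw + 1L, 1L) - 1L
      y0 <- sample.int(H - ch + 1L, 1L) - 1L
      b <- c(x0, y0, x0 + cw, y0 + ch)
      ok <- TRUE
      if (!is.null(boxes)) {
        iou <- box_iou(b, boxes)
        # every pair must fall inside the requested IoU range
        ok <- all(iou >= overlap_range[1]) && all(iou <= overlap_range[2])
      }
      if (ok) {
        ys <- (y0 + 1):(y0 + ch); xs <- (x0 + 1):(x0 + cw)
        img[ys, xs] <- img[ys, xs] * (1 - crop$mask) + crop$image * crop$mask
        boxes <- rbind(boxes, b)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      .stopf("could not satisfy the overlap constraint in %d attempts",
             max_attempts)
  }
  rownames(boxes) <- NULL
  list(image = img, boxes = boxes)
}

#' Write detections as CSV
#' @param detections a `detections` data frame.
#' @param path file path.
#' @param frame frame index column value.
#' @export
write_detections_csv <- function(detections, path, frame = 0L) {
  df <- data.frame(frame = frame, label = detections$label,
                   x0 = detections$x0, y0 = detections$y0,
                   x1 = detections$x1, y1 = detections$y1,
                   score = detections$score)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
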