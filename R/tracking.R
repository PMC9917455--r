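#' Optimal linear-sum assignment
#'
#' Solves the square assignment problem (minimum total cost) with the
#' shortest-augmenting-path algorithm and dual potentials, O(n^3).
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `a` with `a[i]` = column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n != ncol(cost)) .stopf("cost matrix must be square")
  if (n == 0L) return(integer())
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials (index 1 = virtual column)
  p <- integer(n + 1)      # p[j]: row matched to column j-1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      cur <- cost[i0, ] - u[i0] - v[2:(n + 1)]
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cj <- cur[j - 1]
        if (cj < minv[j]) { minv[j] <- cj; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  a <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) a[p[j]] <- j - 1L
  a
}

.det_centroids <- function(det) {
  cbind((det$x0 + det$x1) / 2, (det$y0 + det$y1) / 2)
}

#' Link detections of one frame into tracks
#'
#' Optimal (Hungarian-style) assignment minimizing total centroid distance
#' on the gated cost matrix: pairs farther than `max_displacement_px` are
#' inadmissible. Unmatched detections start new tracks; unmatched active
#' tracks accumulate gap and close after `max_gap` missed frames.
#'
#' @param tracks a `track_set` from a previous call, or `NULL` to start.
#' @param detections_t `detections` data frame for one frame.
#' @param max_displacement_px assignment gate (px).
#' @param max_gap frames a track may go unseen before closing.
#' @param frame frame index of `detections_t`.
#' @return a `track_set`: list with `tracks` (each: `track_id`, `frames`,
#'   `boxes`, `gap`, `state`), `next_id`, and `assignment` (track id per row
#'   of `detections_t`).
#' @export
link_detections <- function(tracks, detections_t, max_displacement_px = 50,
                            max_gap = 2L, frame = NULL) {
  if (is.null(tracks))
    tracks <- structure(list(tracks = list(), next_id = 1L,
                             assignment = integer(), last_frame = -1L),
                        class = "track_set")
  frame <- if (is.null(frame)) tracks$last_frame + 1L else as.integer(frame)
  nd <- nrow(detections_t)
  active <- which(vapply(tracks$tracks, function(tr) tr$state == "active",
                         logical(1)))
  na <- length(active)
  assignment <- integer(nd)
  matched_tracks <- integer()
  if (na > 0L && nd > 0L) {
    last_pos <- t(vapply(tracks$tracks[active], function(tr) {
      b <- tr$boxes[nrow(tr$boxes), ]
      c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
    }, numeric(2)))
    cen <- .det_centroids(detections_t)
    D <- sqrt(outer(last_pos[, 1], cen[, 1], `-`)^2 +
              outer(last_pos[, 2], cen[, 2], `-`)^2)
    BIG <- 1e9
    Dg <- ifelse(D <= max_displacement_px, D, BIG)
    # square matrix with dummy rows/columns that price non-assignment
    n <- na + nd
    C <- matrix(BIG, n, n)
    C[seq_len(na), seq_len(nd)] <- Dg
    for (i in seq_len(na)) C[i, nd + i] <- max_displacement_px
    for (j in seq_len(nd)) C[na + j, j] <- max_displacement_px
    C[(na + 1):n, (nd + 1):n] <- 0
    a <- solve_assignment(C)
    for (i in seq_len(na)) {
      j <- a[i]
      if (j <= nd && Dg[i, j] < BIG && Dg[i, j] <= max_displacement_px) {
        ti <- active[i]
        tr <- tracks$tracks[[ti]]
        tr$frames <- c(tr$frames, frame)
        tr$boxes <- rbind(tr$boxes,
                          as.numeric(detections_t[j, c("x0", "y0", "x1", "y1")]))
        tr$gap <- 0L
        tracks$tracks[[ti]] <- tr
        assignment[j] <- tr$track_id
        matched_tracks <- c(matched_tracks, ti)
      }
    }
  }
  # unmatched active tracks age and may close
  for (ti in setdiff(active, matched_tracks)) {
    tr <- tracks$tracks[[ti]]
    tr$gap <- tr$gap + 1L
    if (tr$gap > max_gap) tr$state <- "closed"
    tracks$tracks[[ti]] <- tr
  }
  # unmatched detections start new tracks
  for (j in seq_len(nd)) {
    if (assignment[j] == 0L) {
      id <- tracks$next_id
      tracks$tracks[[length(tracks$tracks) + 1L]] <- list(
        track_id = id, frames = frame,
        boxes = matrix(as.numeric(detections_t[j, c("x0", "y0", "x1", "y1")]),
                       1, 4),
        gap = 0L, state = "active")
      tracks$next_id <- id + 1L
      assignment[j] <- id
    }
  }
  tracks$assignment <- assignment
  tracks$last_frame <- frame
  tracks
}

#' Export a track set as a data frame
#'
#' @param tracks a `track_set`.
#' @return data frame `track_id, frame, x0, y0, x1, y1`.
#' @export
tracks_to_df <- function(tracks) {
  rows <- lapply(tracks$tracks, function(tr)
    data.frame(track_id = tr$track_id, frame = tr$frames,
               x0 = tr$boxes[, 1], y0 = tr$boxes[, 2],
               x1 = tr$boxes[, 3], y1 = tr$boxes[, 4]))
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(track_id = integer(), frame = integer(),
                                      x0 = numeric(), y0 = numeric(),
                                      x1 = numeric(), y1 = numeric())
  rownames(out) <- NULL
  out
}
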