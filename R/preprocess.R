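#' Build a flat-field reference from diffuser framesets
#'
#' For each camera, the per-pixel mean across the diffuser framesets is
#' divided by its own global mean, giving a unit-mean gain image that
#' captures vignetting and pixel-to-pixel sensitivity variation. Zero or
#' near-zero pixels are floored at `eps` times the image mean and reported.
#'
#' @param diffuser_framesets list of `raw_frameset` objects (>= 1) with
#'   consistent grids and dimensions; typically from [make_diffuser_frames()].
#' @param eps floor for degenerate (dead-pixel) gain entries, as a fraction
#'   of the mean.
#' @return an object of class `flatfield_reference`: `per_camera_gain` (list
#'   of unit-mean gain matrices), `n_source_frames`, `floored` (per-camera
#'   count of floored pixels).
#' @export
build_flatfield_reference <- function(diffuser_framesets, eps = 1e-3) {
  if (!length(diffuser_framesets)) .stopf("need at least one diffuser frameset")
  keys <- names(diffuser_framesets[[1]]$frames)
  dims <- dim(diffuser_framesets[[1]]$frames[[1]])
  for (fs in diffuser_framesets) {
    if (!identical(names(fs$frames), keys) ||
        !identical(dim(fs$frames[[1]]), dims))
      .stopf("diffuser framesets have inconsistent grids or dimensions")
  }
  gains <- list()
  floored <- integer()
  for (k in keys) {
    acc <- Reduce(`+`, lapply(diffuser_framesets, function(fs) fs$frames[[k]]))
    avg <- acc / length(diffuser_framesets)
    g <- avg / mean(avg)
    low <- g < eps
    g[low] <- eps
    g <- g / mean(g)                 # renormalize to unit mean after flooring
    gains[[k]] <- g
    floored[[k]] <- sum(low)
  }
  structure(list(per_camera_gain = gains,
                 n_source_frames = length(diffuser_framesets),
                 floored = floored),
            class = "flatfield_reference")
}

#' Apply flat-field correction to a frameset
#'
#' Each pixel is divided by the reference gain for its camera, then clipped
#' to the frameset's dtype range (\[0, 1\] here); the bit depth is preserved.
#'
#' @param frameset a `raw_frameset`.
#' @param reference a [build_flatfield_reference()] result with a matching
#'   grid.
#' @return the corrected `raw_frameset`.
#' @export
flat_field_correct <- function(frameset, reference) {
  stopifnot(inherits(frameset, "raw_frameset"),
            inherits(reference, "flatfield_reference"))
  if (!identical(names(frameset$frames), names(reference$per_camera_gain)))
    .stopf("frameset and flat-field reference grids do not match")
  for (k in names(frameset$frames)) {
    if (!identical(dim(frameset$frames[[k]]),
                   dim(reference$per_camera_gain[[k]])))
      .stopf("image dimensions do not match the flat-field reference")
    frameset$frames[[k]] <-
      .clamp(frameset$frames[[k]] / reference$per_camera_gain[[k]], 0, 1)
  }
  frameset
}

#' Bilinear demosaicing of an RGGB Bayer image
#'
#' Each colour channel is interpolated at its missing sites by convolving
#' the channel-masked image with a bilinear kernel and dividing by the
#' convolved mask (exact bilinear interpolation, edge-safe).
#'
#' @param bayer_image numeric matrix with even dimensions; RGGB layout
#'   (R at (0,0), G at (0,1)/(1,0), B at (1,1), 0-based).
#' @param pattern only `"RGGB"` is supported.
#' @return numeric array `h x w x 3` (R, G, B).
#' @export
demosaic_bilinear <- function(bayer_image, pattern = "RGGB") {
  if (!identical(pattern, "RGGB")) .stopf("unknown Bayer pattern '%s'", pattern)
  h <- nrow(bayer_image); w <- ncol(bayer_image)
  if (h %% 2L || w %% 2L) .stopf("Bayer image dimensions must be even")
  masks <- list(R = matrix(0, h, w), G = matrix(0, h, w), B = matrix(0, h, w))
  odd_r <- seq(1, h, 2); even_r <- seq(2, h, 2)
  odd_c <- seq(1, w, 2); even_c <- seq(2, w, 2)
  masks$R[odd_r, odd_c] <- 1
  masks$G[odd_r, even_c] <- 1; masks$G[even_r, odd_c] <- 1
  masks$B[even_r, even_c] <- 1
  k1 <- c(0.5, 1, 0.5)
  conv_sep <- function(m) {
    # separable [0.5 1 0.5] x [0.5 1 0.5] convolution with zero padding
    my <- .shift_mat(m, -1, 0) * 0.5 + m + .shift_mat(m, 1, 0) * 0.5
    .shift_mat(my, 0, -1) * 0.5 + my + .shift_mat(my, 0, 1) * 0.5
  }
  out <- array(0, dim = c(h, w, 3))
  for (i in 1:3) {
    ch <- c("R", "G", "B")[i]
    num <- conv_sep(bayer_image * masks[[ch]])
    den <- conv_sep(masks[[ch]])
    out[, , i] <- num / den
  }
  out
}
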