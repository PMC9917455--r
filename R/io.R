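#' Write a raw frameset to disk
#'
#' One directory per camera (`cam_r<row>_c<col>/frame_<t>.tif` or `.png`)
#' plus a `frameset.json` sidecar with the array configuration, frame index
#' and bit depth.
#'
#' @param frameset a `raw_frameset`.
#' @param dir output directory (created if missing).
#' @param format `"tiff"` or `"png"`.
#' @return `dir`, invisibly.
#' @export
write_frameset <- function(frameset, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- frameset$array_config
  for (k in names(frameset$frames)) {
    sub <- file.path(dir, paste0("cam_", k))
    dir.create(sub, showWarnings = FALSE)
    fn <- file.path(sub, sprintf("frame_%06d.%s", frameset$frame_index,
                                 if (format == "tiff") "tif" else "png"))
    img <- frameset$frames[[k]]
    if (format == "tiff")
      tiff::writeTIFF(img, fn, bits.per.sample = frameset$bit_depth)
    else png::writePNG(img, fn)
  }
  meta <- list(grid = cfg$grid, frame_index = frameset$frame_index,
               bit_depth = frameset$bit_depth,
               bayer_pattern = frameset$bayer_pattern, format = format)
  jsonlite::write_json(meta, file.path(dir, "frameset.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_config(cfg, file.path(dir, "array_config.json"))
  invisible(dir)
}

#' Read a raw frameset written by [write_frameset()]
#'
#' @param dir directory containing `cam_*` subdirectories and
#'   `frameset.json`.
#' @param frame_index which frame to load.
#' @return a `raw_frameset` (without ground truth).
#' @export
read_frameset <- function(dir, frame_index = 0L) {
  meta <- jsonlite::read_json(file.path(dir, "frameset.json"),
                              simplifyVector = TRUE)
  cfg <- read_array_config(file.path(dir, "array_config.json"))
  frames <- list()
  for (r in seq_len(meta$grid[1]) - 1L) for (cl in seq_len(meta$grid[2]) - 1L) {
    k <- .frameset_key(r, cl)
    fn <- file.path(dir, paste0("cam_", k),
                    sprintf("frame_%06d.%s", frame_index,
                            if (meta$format == "tiff") "tif" else "png"))
    img <- if (meta$format == "tiff") tiff::readTIFF(fn) else png::readPNG(fn)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    frames[[k]] <- img
  }
  structure(list(frames = frames, array_config = cfg,
                 bayer_pattern = meta$bayer_pattern,
                 frame_index = meta$frame_index, bit_depth = meta$bit_depth,
                 ground_truth = NULL),
            class = "raw_frameset")
}

#' Write a mosaic frame as TIFF with its scale recorded alongside
#'
#' @param mosaic a `mosaic_frame`.
#' @param path output TIFF path; a JSON sidecar `<path>.json` stores the
#'   object-space scale.
#' @export
write_mosaic <- function(mosaic, path) {
  tiff::writeTIFF(.clamp(mosaic$image, 0, 1), path)
  jsonlite::write_json(list(scale_um_per_px = mosaic$scale_um_per_px,
                            frame_index = mosaic$frame_index,
                            template_id = mosaic$template_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
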