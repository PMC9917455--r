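#' Single-camera optical specification
#'
#' Describes one micro-camera of the array: a thin lens of focal length `f`
#' and numerical aperture NA in front of a rectangular CMOS sensor.
#'
#' @param focal_length_mm lens focal length in mm (> 0).
#' @param numerical_aperture object-side NA, in (0, 1).
#' @param pixel_pitch_um sensor pixel size in micrometres (> 0).
#' @param sensor_px integer pair `c(width_px, height_px)`.
#' @param wavelength_um illumination wavelength used by the diffraction
#'   formulas; defaults to 0.50 um (mid-visible green).
#' @return an object of class `camera_spec`.
#' @export
camera_spec <- function(focal_length_mm = 25, numerical_aperture = 0.03,
                        pixel_pitch_um = 1.4, sensor_px = c(4320L, 2432L),
                        wavelength_um = 0.50) {
  .check_num(focal_length_mm, "focal_length_mm", lo = 1e-9)
  .check_num(numerical_aperture, "numerical_aperture")
  if (numerical_aperture <= 0 || numerical_aperture >= 1)
    .stopf("numerical_aperture must be in (0, 1)")
  .check_num(pixel_pitch_um, "pixel_pitch_um", lo = 1e-9)
  .check_num(wavelength_um, "wavelength_um", lo = 1e-9)
  sensor_px <- as.integer(sensor_px)
  if (length(sensor_px) != 2L || any(sensor_px < 1L))
    .stopf("sensor_px must be two integers >= 1")
  structure(list(focal_length_mm = focal_length_mm,
                 numerical_aperture = numerical_aperture,
                 pixel_pitch_um = pixel_pitch_um,
                 sensor_px = sensor_px,
                 wavelength_um = wavelength_um),
            class = "camera_spec")
}

#' Camera-array geometry
#'
#' The single source of truth for geometric conversions: grid shape,
#' center-to-center camera pitch, and the lens-to-object working distance.
#'
#' @param camera a [camera_spec()].
#' @param grid integer pair `c(n_rows, n_cols)`.
#' @param pitch_mm camera center-to-center spacing (both axes), mm.
#' @param working_distance_mm lens-to-object distance `u`; must exceed the
#'   focal length.
#' @param long_axis `"grid_x"` if the long (width) sensor axis runs along the
#'   grid columns (world x), `"grid_y"` otherwise.
#' @return an object of class `array_config`.
#' @export
array_config <- function(camera = camera_spec(), grid = c(8L, 12L),
                         pitch_mm = 19, working_distance_mm = 150,
                         long_axis = c("grid_x", "grid_y")) {
  stopifnot(inherits(camera, "camera_spec"))
  long_axis <- match.arg(long_axis)
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) .stopf("grid must be two integers >= 1")
  .check_num(pitch_mm, "pitch_mm", lo = 1e-9)
  .check_num(working_distance_mm, "working_distance_mm")
  if (working_distance_mm <= camera$focal_length_mm)
    .stopf("working_distance_mm must exceed the focal length (no real image)")
  structure(list(camera = camera, grid = grid, pitch_mm = pitch_mm,
                 working_distance_mm = working_distance_mm,
                 long_axis = long_axis),
            class = "array_config")
}

#' Adjacent-camera stereo geometry
#'
#' @param baseline_mm center spacing of the camera pair (mm, > 0).
#' @param focal_length_mm lens focal length (mm).
#' @param focus_distance_mm object distance of the plane of best focus (mm).
#' @param pixel_pitch_um sensor pixel size (um), used to convert pixel-unit
#'   disparities.
#' @param z_sign `"toward_camera_positive"` (default) or `"away_positive"`.
#' @return an object of class `depth_geometry`.
#' @export
depth_geometry <- function(baseline_mm = 19, focal_length_mm = 25,
                           focus_distance_mm = 150, pixel_pitch_um = 1.4,
                           z_sign = c("toward_camera_positive", "away_positive")) {
  .check_num(baseline_mm, "baseline_mm", lo = 1e-9)
  .check_num(focal_length_mm, "focal_length_mm", lo = 1e-9)
  .check_num(focus_distance_mm, "focus_distance_mm")
  if (focus_distance_mm <= focal_length_mm)
    .stopf("focus_distance_mm must exceed the focal length")
  .check_num(pixel_pitch_um, "pixel_pitch_um", lo = 1e-9)
  structure(list(baseline_mm = baseline_mm, focal_length_mm = focal_length_mm,
                 focus_distance_mm = focus_distance_mm,
                 pixel_pitch_um = pixel_pitch_um,
                 z_sign = match.arg(z_sign)),
            class = "depth_geometry")
}

#' @export
print.array_config <- function(x, ...) {
  fov <- object_space_fov(x)
  cat(sprintf("array_config: %dx%d cameras, pitch %.3g mm, u = %.4g mm\n",
              x$grid[1], x$grid[2], x$pitch_mm, x$working_distance_mm))
  cat(sprintf("  sensor %dx%d px @ %.3g um, f = %.3g mm, NA = %.3g\n",
              x$camera$sensor_px[1], x$camera$sensor_px[2],
              x$camera$pixel_pitch_um, x$camera$focal_length_mm,
              x$camera$numerical_aperture))
  cat(sprintf("  per-camera FOV %.4g x %.4g mm, array span %.4g x %.4g mm\n",
              fov$fov_long_mm, fov$fov_short_mm, fov$span_x_mm, fov$span_y_mm))
  invisible(x)
}

#' Thin-lens lateral magnification
#'
#' `m = f / (u - f)`: the sensor-to-object linear scale for an object at
#' distance `u` from a thin lens of focal length `f`.
#'
#' @param focal_length_mm focal length (mm).
#' @param object_distance_mm lens-to-object distance (mm); must exceed `f`.
#' @return dimensionless magnification.
#' @export
magnification <- function(focal_length_mm, object_distance_mm) {
  if (any(object_distance_mm <= focal_length_mm))
    .stopf("object distance must exceed the focal length (no real image)")
  focal_length_mm / (object_distance_mm - focal_length_mm)
}

#' Per-camera and full-array object-space field of view
#'
#' @param config an [array_config()].
#' @return list with `fov_long_mm`, `fov_short_mm` (per camera), and
#'   `span_x_mm`, `span_y_mm` (full array: `(n-1)*pitch + FOV` per axis).
#' @export
object_space_fov <- function(config) {
  stopifnot(inherits(config, "array_config"))
  cam <- config$camera
  m <- magnification(cam$focal_length_mm, config$working_distance_mm)
  sensor_mm <- cam$sensor_px * cam$pixel_pitch_um / 1000
  fov <- sensor_mm / m                      # (width, height) in object mm
  # width axis maps to world x when long_axis == "grid_x"
  fov_x <- if (config$long_axis == "grid_x") fov[1] else fov[2]
  fov_y <- if (config$long_axis == "grid_x") fov[2] else fov[1]
  list(fov_long_mm = max(fov), fov_short_mm = min(fov),
       fov_x_mm = fov_x, fov_y_mm = fov_y,
       span_x_mm = (config$grid[2] - 1) * config$pitch_mm + fov_x,
       span_y_mm = (config$grid[1] - 1) * config$pitch_mm + fov_y)
}

#' Inter-camera field-of-view overlap fractions
#'
#' Per axis, `(FOV - pitch) / FOV`. Negative values are meaningful: they
#' signal coverage gaps between adjacent cameras. The long-axis fraction must
#' reach 0.5 for every object-plane point to be seen by at least two cameras
#' along that axis (the stereo guarantee).
#'
#' @param config an [array_config()].
#' @return list with `long_axis_fraction`, `short_axis_fraction`, and
#'   `stereo_guarantee` (logical: long-axis fraction >= 0.5).
#' @export
overlap_fractions <- function(config) {
  fov <- object_space_fov(config)
  long_f <- (fov$fov_long_mm - config$pitch_mm) / fov$fov_long_mm
  short_f <- (fov$fov_short_mm - config$pitch_mm) / fov$fov_short_mm
  list(long_axis_fraction = long_f, short_axis_fraction = short_f,
       stereo_guarantee = long_f >= 0.5)
}

#' Raw data volume of one array snapshot
#'
#' @param config an [array_config()] (or `n_cameras` overriding the grid).
#' @param bit_depth 8 or 16 bits per pixel (Bayer raw counts one value per
#'   pixel).
#' @param n_cameras optional camera-count override (e.g. 0 for none).
#' @return list with `bytes` and `mib`.
#' @export
raw_frame_bytes <- function(config, bit_depth = 8L, n_cameras = NULL) {
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) .stopf("unsupported bit depth %d", bit_depth)
  n <- if (is.null(n_cameras)) prod(config$grid) else n_cameras
  if (n < 0) .stopf("camera count must be >= 0")
  px <- prod(as.numeric(config$camera$sensor_px))
  bytes <- n * px * (bit_depth / 8)
  list(bytes = bytes, mib = bytes / 2^20)
}

#' Diffraction and sampling resolution metrics
#'
#' Lateral Rayleigh limit `0.61 lambda / NA`, axial Rayleigh depth of field
#' `lambda / (2 NA^2)`, the object-space pixel footprint `pixel / m`, and the
#' Nyquist-limited full-pitch resolution `2 * object_pixel`.
#'
#' @param camera a [camera_spec()] with wavelength set.
#' @param object_distance_mm lens-to-object distance (mm).
#' @return list with `lateral_rayleigh_um`, `axial_rayleigh_mm`,
#'   `object_pixel_um`, `nyquist_full_pitch_um`.
#' @export
resolution_metrics <- function(camera, object_distance_mm) {
  stopifnot(inherits(camera, "camera_spec"))
  na <- camera$numerical_aperture
  if (na <= 0) .stopf("numerical aperture must be positive")
  m <- magnification(camera$focal_length_mm, object_distance_mm)
  obj_px <- camera$pixel_pitch_um / m
  list(lateral_rayleigh_um = 0.61 * camera$wavelength_um / na,
       axial_rayleigh_mm = camera$wavelength_um / 1000 / (2 * na^2),
       object_pixel_um = obj_px,
       nyquist_full_pitch_um = 2 * obj_px)
}

#' Convert stereo disparity to object distance (and back)
#'
#' For two adjacent parallel-axis cameras with baseline `B`, a point at
#' object distance `u` images with sensor-plane disparity `s = f B / (u - f)`
#' so that `u = f (1 + B / s)`. The two functions are exact inverses.
#'
#' @param disparity sensor disparity; mm by default, pixels if
#'   `unit = "px"` (converted with the geometry's pixel pitch).
#' @param geometry a [depth_geometry()].
#' @param unit `"mm"` or `"px"`.
#' @return object distance `u` in mm.
#' @export
disparity_to_depth <- function(disparity, geometry, unit = c("mm", "px")) {
  stopifnot(inherits(geometry, "depth_geometry"))
  unit <- match.arg(unit)
  s <- if (unit == "px") disparity * geometry$pixel_pitch_um / 1000 else disparity
  if (any(s <= 0)) .stopf("disparity must be positive (behind-infinity)")
  geometry$focal_length_mm * (1 + geometry$baseline_mm / s)
}

#' @rdname disparity_to_depth
#' @param object_distance_mm object distance `u` in mm (> focal length).
#' @export
depth_to_disparity <- function(object_distance_mm, geometry, unit = c("mm", "px")) {
  stopifnot(inherits(geometry, "depth_geometry"))
  unit <- match.arg(unit)
  if (any(object_distance_mm <= geometry$focal_length_mm))
    .stopf("object distance must exceed the focal length")
  s <- geometry$focal_length_mm * geometry$baseline_mm /
    (object_distance_mm - geometry$focal_length_mm)
  if (unit == "px") s / (geometry$pixel_pitch_um / 1000) else s
}

## --- presets and config serialization --------------------------------------

#' Built-in array presets
#'
#' `"paper96"`: 8x12 grid of 10 MP sensors (4320x2432 at 1.4 um), f = 25 mm,
#' NA 0.03, 19 mm pitch, u = 165 mm (both axes have non-negative overlap:
#' about 43% long, about 0.2% short). `"paper96_u150"`: same hardware at
#' u = 150 mm exactly (long-axis overlap 37%, short-axis coverage gap).
#' `"desk6"`: a 2x3 toy array with 20 um pixels on 200x150 px sensors used
#' for fast desk-scale experiments.
#'
#' @param name preset name.
#' @return an [array_config()].
#' @export
array_preset <- function(name = c("paper96", "paper96_u150", "desk6")) {
  name <- match.arg(name)
  switch(name,
    paper96 = array_config(camera_spec(), grid = c(8L, 12L), pitch_mm = 19,
                           working_distance_mm = 165),
    paper96_u150 = array_config(camera_spec(), grid = c(8L, 12L), pitch_mm = 19,
                                working_distance_mm = 150),
    desk6 = array_config(camera_spec(pixel_pitch_um = 20,
                                     sensor_px = c(200L, 150L)),
                         grid = c(2L, 3L), pitch_mm = 10,
                         working_distance_mm = 150))
}

#' Read / write an array configuration as JSON
#'
#' @param config an [array_config()].
#' @param path file path.
#' @return `read_array_config` returns an [array_config()];
#'   `write_array_config` returns `path` invisibly.
#' @export
write_array_config <- function(config, path) {
  stopifnot(inherits(config, "array_config"))
  x <- list(camera = unclass(config$camera), grid = config$grid,
            pitch_mm = config$pitch_mm,
            working_distance_mm = config$working_distance_mm,
            long_axis = config$long_axis)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_array_config
#' @export
read_array_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  array_config(camera = do.call(camera_spec, as.list(x$camera)[c(
                 "focal_length_mm", "numerical_aperture", "pixel_pitch_um",
                 "sensor_px", "wavelength_um")]),
               grid = x$grid, pitch_mm = x$pitch_mm,
               working_distance_mm = x$working_distance_mm,
               long_axis = x$long_axis)
}

## Camera center in world mm (origin at array center; x along grid columns,
## y along grid rows, both increasing with index).
.camera_center <- function(config, row, col) {
  c(x = (col - (config$grid[2] - 1) / 2) * config$pitch_mm,
    y = (row - (config$grid[1] - 1) / 2) * config$pitch_mm)
}

## Sensor physical (width, height) in mm mapped to world (x, y) extents.
.sensor_world_extent <- function(config) {
  cam <- config$camera
  sensor_mm <- cam$sensor_px * cam$pixel_pitch_um / 1000
  if (config$long_axis == "grid_x") sensor_mm else rev(sensor_mm)
}
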