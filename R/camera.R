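#' Scene-camera geometry of a wearable eye tracker
#'
#' Describes the field of view and resolution of the tracker's scene camera,
#' used to convert gaze coordinates between pixels and degrees of visual
#' angle. The mapping is linear (constant pixels-per-degree on each axis),
#' the same small-angle arithmetic used when working with wide-angle scene
#' cameras such as the 1920x1080 px / 160 degree optics of commercial
#' glasses-type trackers, where 0.4 degrees corresponds to 4.8 pixels.
#'
#' @param horizontal_fov Horizontal field of view, degrees.
#' @param horizontal_resolution Horizontal resolution, pixels.
#' @param vertical_fov Vertical field of view, degrees.
#' @param vertical_resolution Vertical resolution, pixels.
#'
#' @return An object of class `camera_geometry`.
#' @examples
#' cam <- camera_geometry()
#' degrees_to_pixels(0.4, cam)  # 4.8 px
#' @export
camera_geometry <- function(horizontal_fov = 160,
                            horizontal_resolution = 1920,
                            vertical_fov = 90,
                            vertical_resolution = 1080) {
  assert_number(horizontal_fov, "horizontal_fov", lower = 0, strict_lower = TRUE)
  assert_number(horizontal_resolution, "horizontal_resolution", lower = 0, strict_lower = TRUE)
  assert_number(vertical_fov, "vertical_fov", lower = 0, strict_lower = TRUE)
  assert_number(vertical_resolution, "vertical_resolution", lower = 0, strict_lower = TRUE)
  structure(
    list(horizontal_fov = horizontal_fov,
         horizontal_resolution = horizontal_resolution,
         vertical_fov = vertical_fov,
         vertical_resolution = vertical_resolution),
    class = "camera_geometry")
}

ppd <- function(camera, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal")
    camera$horizontal_resolution / camera$horizontal_fov
  else
    camera$vertical_resolution / camera$vertical_fov
}

#' Convert between degrees of visual angle and scene-camera pixels
#'
#' Linear conversion `pixels = angle * resolution / fov` (and its exact
#' inverse). No tangent correction is applied: the constant
#' pixels-per-degree mapping matches the arithmetic commonly used with
#' wide-FOV scene cameras and is accurate for the small gaze offsets this
#' package works with.
#'
#' @param angle Angle(s) in degrees.
#' @param offset Offset(s) in pixels.
#' @param camera A [camera_geometry()] object.
#' @param axis `"horizontal"` or `"vertical"`.
#'
#' @return Numeric vector of pixels (`degrees_to_pixels`) or degrees
#'   (`pixels_to_degrees`).
#' @examples
#' cam <- camera_geometry(160, 1920)
#' degrees_to_pixels(0.4, cam)   # 4.8
#' pixels_to_degrees(4.8, cam)   # 0.4
#' @export
degrees_to_pixels <- function(angle, camera, axis = c("horizontal", "vertical")) {
  stopifnot(inherits(camera, "camera_geometry"))
  angle * ppd(camera, match.arg(axis))
}

#' @rdname degrees_to_pixels
#' @export
pixels_to_degrees <- function(offset, camera, axis = c("horizontal", "vertical")) {
  stopifnot(inherits(camera, "camera_geometry"))
  offset / ppd(camera, match.arg(axis))
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat(sprintf("Scene camera: %g x %g px, FOV %g x %g deg (%.2f / %.2f px per deg)\n",
              x$horizontal_resolution, x$vertical_resolution,
              x$horizontal_fov, x$vertical_fov,
              ppd(x, "horizontal"), ppd(x, "vertical")))
  invisible(x)
}
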