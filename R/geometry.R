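#' Screen geometry of the recording setup
#'
#' Describes the display and viewing distance used to convert between pixel and
#' degree coordinates. Defaults correspond to a 1024 x 768 px CRT of
#' 36 x 27 cm physical size viewed from 71 cm.
#'
#' Two coordinate systems are used throughout the package:
#' * *pixel space*: origin at the top-left screen corner, x rightward,
#'   y downward (0-based);
#' * *degree space*: origin at the screen centre, x rightward, y upward,
#'   with the per-axis visual angle `atan(offset_cm / distance_cm)`.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_cm,height_cm physical screen size in cm.
#' @param distance_cm viewing (eye-to-screen) distance in cm.
#' @return an object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(1024, 384, geom)  # right screen edge: ~14.2 deg
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768,
                            width_cm = 36, height_cm = 27,
                            distance_cm = 71) {
  vals <- c(width_px, height_px, width_cm, height_cm, distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen_geometry fields must be positive and finite")
  structure(list(width_px = width_px, height_px = height_px,
                 width_cm = width_cm, height_cm = height_cm,
                 distance_cm = distance_cm),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen: %d x %d px (%.1f x %.1f cm) at %.1f cm\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm, x$distance_cm))
  invisible(x)
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' @param x,y pixel coordinates (vectors of equal length).
#' @param geometry a [screen_geometry()].
#' @return a list with components `x`, `y` in degrees (origin screen centre,
#'   y upward).
#' @export
px_to_deg <- function(x, y, geometry = screen_geometry()) {
  cmx <- (x - geometry$width_px / 2) * geometry$width_cm / geometry$width_px
  cmy <- (y - geometry$height_px / 2) * geometry$height_cm / geometry$height_px
  list(x = atan(cmx / geometry$distance_cm) * 180 / pi,
       y = -atan(cmy / geometry$distance_cm) * 180 / pi)
}

#' Convert degrees of visual angle to pixel coordinates
#'
#' Exact inverse of [px_to_deg()].
#'
#' @inheritParams px_to_deg
#' @return a list with components `x`, `y` in pixels.
#' @export
deg_to_px <- function(x, y, geometry = screen_geometry()) {
  cmx <- tan(x * pi / 180) * geometry$distance_cm
  cmy <- -tan(y * pi / 180) * geometry$distance_cm
  list(x = cmx * geometry$width_px / geometry$width_cm + geometry$width_px / 2,
       y = cmy * geometry$height_px / geometry$height_cm + geometry$height_px / 2)
}

#' Convert a gaze sample stream from pixels to degrees
#'
#' @param samples a data frame with columns `t_ms`, `x`, `y`, `valid`, in
#'   pixel coordinates (attribute `unit` equal to `"px"` or absent).
#' @param geometry a [screen_geometry()].
#' @return the same data frame with `x`, `y` in degrees and attribute
#'   `unit = "deg"`.
#' @export
pixels_to_degrees <- function(samples, geometry = screen_geometry()) {
  unit <- attr(samples, "unit")
  if (!is.null(unit) && identical(unit, "deg")) return(samples)
  d <- px_to_deg(samples$x, samples$y, geometry)
  samples$x <- d$x
  samples$y <- d$y
  attr(samples, "unit") <- "deg"
  samples
}

#' Convert a gaze sample stream from degrees to pixels
#'
#' @inheritParams pixels_to_degrees
#' @export
degrees_to_pixels <- function(samples, geometry = screen_geometry()) {
  unit <- attr(samples, "unit")
  if (!is.null(unit) && identical(unit, "px")) return(samples)
  p <- deg_to_px(samples$x, samples$y, geometry)
  samples$x <- p$x
  samples$y <- p$y
  attr(samples, "unit") <- "px"
  samples
}
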