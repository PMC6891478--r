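#' Camera geometry and ground sampling distance
#'
#' The ground sampling distance (GSD) is the ground footprint of one image
#' pixel: `GSD = H * a / f`, with flying height `H`, pixel pitch
#' `a = sensor_width_mm / photo_width_px`, and focal length `f`. The pixel
#' diameter of a ground object of known size is then `object_cm / gsd_cm`;
#' a single poppy plant is about 30 cm across, which drives the scale of
#' objects in the synthetic scenes.
#'
#' @name sensor_model
NULL

#' Camera specification
#'
#' @param sensor_width_mm,sensor_height_mm photosensitive element size (mm)
#' @param focal_length_mm lens focal length (mm)
#' @param photo_width_px,photo_height_px photo size (pixels)
#' @param name optional label
#' @return an object of class `camera_spec`
#' @details Width- and height-based pixel pitches normally agree; a
#'   discrepancy above 1% (non-square pixels or a typo) triggers a warning.
#' @export
camera_spec <- function(sensor_width_mm, sensor_height_mm, focal_length_mm,
                        photo_width_px, photo_height_px, name = "camera") {
  vals <- c(sensor_width_mm, sensor_height_mm, focal_length_mm,
            photo_width_px, photo_height_px)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all camera parameters must be strictly positive")
  pw <- sensor_width_mm / photo_width_px
  ph <- sensor_height_mm / photo_height_px
  if (abs(pw - ph) / pw > 0.01)
    warning(sprintf("width/height pixel pitches differ by %.2f%% for %s",
                    100 * abs(pw - ph) / pw, name))
  structure(list(sensor_width_mm = sensor_width_mm,
                 sensor_height_mm = sensor_height_mm,
                 focal_length_mm = focal_length_mm,
                 photo_width_px = photo_width_px,
                 photo_height_px = photo_height_px,
                 name = name),
            class = "camera_spec")
}

#' @export
print.camera_spec <- function(x, ...) {
  cat(sprintf("<camera_spec: %s> sensor %.1f x %.1f mm, f = %.1f mm, %d x %d px\n",
              x$name, x$sensor_width_mm, x$sensor_height_mm,
              x$focal_length_mm, x$photo_width_px, x$photo_height_px))
  invisible(x)
}

#' Built-in camera presets
#'
#' `"dji"`: 1-inch class sensor 13.2 x 8.8 mm, f 8.8 mm, 5472 x 3648 px
#' (multirotor survey camera). `"sony_a7r2"`: full-frame 36 x 24 mm,
#' f 35 mm, 7952 x 5304 px (fixed-wing platform).
#'
#' @param name `"dji"` or `"sony_a7r2"`
#' @return a `camera_spec`
#' @export
camera_preset <- function(name = c("dji", "sony_a7r2")) {
  name <- match.arg(name)
  switch(name,
    dji = camera_spec(13.2, 8.8, 8.8, 5472L, 3648L, name = "dji"),
    sony_a7r2 = camera_spec(36, 24, 35, 7952L, 5304L, name = "sony_a7r2"))
}

#' Pixel pitch of a camera (mm per pixel)
#' @param cam a `camera_spec`
#' @export
pixel_size <- function(cam) {
  stopifnot(inherits(cam, "camera_spec"))
  cam$sensor_width_mm / cam$photo_width_px
}

#' Ground sampling distance (cm per pixel)
#'
#' @param cam a `camera_spec`
#' @param height_m flying height above ground (m)
#' @return cm of ground covered by one pixel
#' @export
gsd <- function(cam, height_m) {
  if (!is.numeric(height_m) || any(height_m <= 0))
    stop("height_m must be positive")
  # H[mm] * a[mm/px] / f[mm] -> mm/px; /10 -> cm/px
  height_m * 1000 * pixel_size(cam) / cam$focal_length_mm / 10
}

#' Pixel diameter of a ground object
#'
#' @param gsd_cm ground sampling distance (cm/px)
#' @param object_cm object diameter on the ground (cm); default 30 cm,
#'   the approximate diameter of a single poppy plant
#' @return diameter in pixels
#' @export
object_pixel_diameter <- function(gsd_cm, object_cm = 30) {
  if (any(gsd_cm <= 0)) stop("gsd_cm must be positive")
  object_cm / gsd_cm
}
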