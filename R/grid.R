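#' Imaging-grid specification
#'
#' Defines the rectangular mid-plane imaging grid. The default extent matches
#' the planar system's maximum imaging area of approximately 21 cm x 16 cm.
#' Pixel centers sit at `(i - 0.5) * pixel_mm` with the origin at the plate
#' corner; matrices are stored with rows indexing y and columns indexing x,
#' row 1 being the y = 0 edge.
#'
#' @param width_mm System extent along x (mm).
#' @param height_mm System extent along y (mm).
#' @param pixel_mm Pixel spacing (mm).
#' @return An object of class `grid_spec` with fields `width_mm`, `height_mm`,
#'   `pixel_mm`, `nx`, `ny` (pixel counts) and pixel-center coordinate vectors
#'   `x`, `y`.
#' @export
grid_spec <- function(width_mm = 210, height_mm = 160, pixel_mm = 2) {
  stopifnot(width_mm > 0, height_mm > 0, pixel_mm > 0)
  nx <- as.integer(ceiling(width_mm / pixel_mm))
  ny <- as.integer(ceiling(height_mm / pixel_mm))
  structure(
    list(
      width_mm = width_mm, height_mm = height_mm, pixel_mm = pixel_mm,
      nx = nx, ny = ny,
      x = (seq_len(nx) - 0.5) * pixel_mm,
      y = (seq_len(ny) - 0.5) * pixel_mm
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %g x %g mm, %g mm pixels (%d x %d)\n",
    x$width_mm, x$height_mm, x$pixel_mm, x$nx, x$ny
  ))
  invisible(x)
}

# Map continuous (x, y) mm coordinates to matrix indices, clamped to the grid.
grid_pixel_index <- function(grid, x, y) {
  ix <- pmin(pmax(ceiling(x / grid$pixel_mm), 1L), grid$nx)
  iy <- pmin(pmax(ceiling(y / grid$pixel_mm), 1L), grid$ny)
  cbind(iy, ix)
}

# Linear index into a ny x nx matrix for the same clamped mapping.
grid_linear_index <- function(grid, x, y) {
  idx <- grid_pixel_index(grid, x, y)
  (idx[, 2L] - 1L) * grid$ny + idx[, 1L]
}
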