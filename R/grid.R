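#' Screen grid specification
#'
#' Describes the placement grid on which object locations live: its pixel
#' dimensions and the pixel-to-centimetre scale of the monitor. The default
#' scale (38.697 px/cm) is reconstructed from the dual-unit values the task
#' reports (264.3 px corresponds to 6.83 cm).
#'
#' @param width_px Grid width in pixels (> 0).
#' @param height_px Grid height in pixels (> 0).
#' @param px_per_cm Pixels per centimetre (> 0).
#'
#' @return An object of class `wakecue_grid`: a list with `width_px`,
#'   `height_px` and `px_per_cm`.
#' @examples
#' g <- grid_spec()
#' guessing_density(g)
#' @export
grid_spec <- function(width_px = 1280L, height_px = 1024L, px_per_cm = 38.697) {
  stopifnot(
    is.numeric(width_px), length(width_px) == 1, is.finite(width_px), width_px > 0,
    is.numeric(height_px), length(height_px) == 1, is.finite(height_px), height_px > 0,
    is.numeric(px_per_cm), length(px_per_cm) == 1, is.finite(px_per_cm), px_per_cm > 0
  )
  structure(
    list(width_px = as.numeric(width_px), height_px = as.numeric(height_px),
         px_per_cm = as.numeric(px_per_cm)),
    class = "wakecue_grid"
  )
}

#' @export
print.wakecue_grid <- function(x, ...) {
  cat(sprintf("<wakecue_grid> %g x %g px (%.3f px/cm)\n",
              x$width_px, x$height_px, x$px_per_cm))
  invisible(x)
}

#' Uniform guessing density of a grid
#'
#' The density (per square pixel) of a placement drawn uniformly over the
#' whole screen: 1 / (width x height). This is the guessing component of the
#' spatial memory mixture model; for the default 1280 x 1024 grid it equals
#' 1/(1280*1024), about 7.63e-7 per px^2.
#'
#' @param grid A [grid_spec()].
#' @return A single number, the uniform density per px^2.
#' @export
guessing_density <- function(grid = grid_spec()) {
  stopifnot(inherits(grid, "wakecue_grid"))
  1 / (grid$width_px * grid$height_px)
}

#' Convert between pixels and centimetres
#'
#' @param px,cm Numeric vectors of distances.
#' @param grid A [grid_spec()] supplying the `px_per_cm` scale.
#' @return Numeric vector in the target unit.
#' @export
px_to_cm <- function(px, grid = grid_spec()) {
  stopifnot(inherits(grid, "wakecue_grid"))
  px / grid$px_per_cm
}

#' @rdname px_to_cm
#' @export
cm_to_px <- function(cm, grid = grid_spec()) {
  stopifnot(inherits(grid, "wakecue_grid"))
  cm * grid$px_per_cm
}
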