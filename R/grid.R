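#' Lattice specification for stimuli and filters
#'
#' All spatial quantities in the package are expressed in units of the
#' center Gaussian standard deviation (`sigma_c = 1`).  A `grid_spec`
#' describes the square pixel lattice shared by a stimulus image and the
#' filter kernels: the image extends `half_width` sigma_c to each side of
#' the origin, sampled at `pixels_per_sigma_c` pixels per sigma_c, with an
#' odd side length so a pixel center sits exactly at the origin.
#'
#' @param pixels_per_sigma_c positive integer; lattice resolution in pixels
#'   per sigma_c.  Resolution is the accuracy knob of the rasterized
#'   pipeline; the closed-form oracles quantify the residual error.
#' @param half_width image half-extent in sigma_c units; must be at least 2
#'   so the stimulus (diameter / width 4 sigma_c) fits in the image.
#'
#' @return An object of class `grid_spec`: a list with elements
#'   `pixels_per_sigma_c`, `half_width`, `n_half` (pixels from center to
#'   edge), `side` (side length, odd) and `coords` (pixel-center
#'   coordinates in sigma_c units).
#' @examples
#' g <- grid_spec(16, 5)
#' g$side          # odd
#' range(g$coords) # +/- half_width
#' @export
grid_spec <- function(pixels_per_sigma_c = 16, half_width = 5) {
  if (!is.numeric(pixels_per_sigma_c) || length(pixels_per_sigma_c) != 1L ||
      !is.finite(pixels_per_sigma_c) || pixels_per_sigma_c < 1)
    stop("'pixels_per_sigma_c' must be a positive scalar", call. = FALSE)
  if (!is.numeric(half_width) || length(half_width) != 1L ||
      !is.finite(half_width) || half_width < 2)
    stop("'half_width' must be >= 2 sigma_c so the 4 sigma_c stimulus fits",
         call. = FALSE)
  ppsc <- as.integer(round(pixels_per_sigma_c))
  n <- as.integer(round(half_width * ppsc))
  structure(
    list(pixels_per_sigma_c = ppsc,
         half_width = half_width,
         n_half = n,
         side = 2L * n + 1L,
         coords = seq.int(-n, n) / ppsc),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Pixel lattice: %d x %d, %d px per sigma_c, half-width %.3g sigma_c\n",
              x$side, x$side, x$pixels_per_sigma_c, x$half_width))
  invisible(x)
}

#' Default lattice for a model unit
#'
#' The default image half-width is `pad` times the largest of the three
#' Gaussian scales, so the Gaussian mass lost to truncation is below 1e-5
#' even for the widest canonical filter (sigma = 6 sigma_c at `pad = 5`).
#'
#' @param unit a [contrast_encoder()] object.
#' @param pixels_per_sigma_c lattice resolution, pixels per sigma_c.
#' @param pad half-width as a multiple of the largest filter scale.
#' @return A [grid_spec()].
#' @export
encoder_grid <- function(unit, pixels_per_sigma_c = 16, pad = 5) {
  stopifnot(inherits(unit, "contrast_encoder"))
  hw <- pad * max(unit$sigma_c, unit$sigma_s, unit$sigma_n) / unit$sigma_c
  grid_spec(pixels_per_sigma_c, half_width = hw)
}

.same_grid <- function(a, b) {
  a$side == b$side && a$pixels_per_sigma_c == b$pixels_per_sigma_c
}
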