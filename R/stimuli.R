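#' Stimulus specifications
#'
#' Constructors for the two stimulus classes used throughout: a uniform
#' disk of fixed diameter 4 sigma_c defined by its Weber contrast against
#' the background, and a uniform square of width 4 sigma_c defined by its
#' absolute target luminance.  Weber contrast is `100 * (d - b) / b` for
#' target luminance `d` on background `b`.
#'
#' @param background background luminance, > 0 (arbitrary units or cd/m^2;
#'   units are opaque scalars, never converted).
#' @param contrast_pct Weber contrast in percent, in \[-100, 100\]; -100
#'   gives a disk of luminance 0.
#' @param target_luminance luminance of the square, >= 0.
#' @return A `disk_stimulus` or `square_stimulus` object (list of fields).
#' @examples
#' disk_stimulus(100, -100)  # a black disk
#' square_stimulus(61, 120)
#' @export
disk_stimulus <- function(background, contrast_pct) {
  stopifnot(is.numeric(background), length(background) == 1L, background > 0,
            is.numeric(contrast_pct), length(contrast_pct) == 1L)
  if (contrast_pct < -100 || contrast_pct > 100)
    stop("Weber contrast must lie in [-100, 100]; ", contrast_pct,
         "% would give a disk luminance of ",
         background * (1 + contrast_pct / 100), call. = FALSE)
  structure(list(background = background, contrast_pct = contrast_pct,
                 radius = 2, shape = "disk"),
            class = "disk_stimulus")
}

#' @rdname disk_stimulus
#' @export
square_stimulus <- function(background, target_luminance) {
  stopifnot(is.numeric(background), length(background) == 1L, background > 0,
            is.numeric(target_luminance), length(target_luminance) == 1L)
  if (target_luminance < 0)
    stop("target luminance must be non-negative", call. = FALSE)
  structure(list(background = background, target_luminance = target_luminance,
                 half_width = 2, shape = "square"),
            class = "square_stimulus")
}

.luminance_image <- function(values, grid, background) {
  structure(list(values = values, grid = grid, background = background),
            class = "luminance_image")
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf("Luminance image %d x %d px, background %.4g, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$background,
              min(x$values), max(x$values)))
  invisible(x)
}

# pixel-center membership masks, binary, no anti-aliasing
.disk_mask <- function(grid, radius = 2) {
  outer(grid$coords^2, grid$coords^2, `+`) < radius^2
}

# The square's edge (+/- half_width) falls exactly on pixel centers for any
# integer resolution, and those cells are exactly bisected by the edge: a
# strict inside test would shrink the footprint by half a pixel on every
# side, an O(h) bias that dominates the discretization error.  Edge-center
# pixels are therefore included by index parity -- half in, half out along
# each edge -- which keeps membership binary per pixel while making the
# rasterized footprint unbiased (error drops to the O(h^2) interior term).
.square_mask <- function(grid, half_width = 2) {
  k <- seq.int(-grid$n_half, grid$n_half)
  lim <- half_width * grid$pixels_per_sigma_c
  kmax <- outer(abs(k), abs(k), pmax)
  inside <- kmax < lim - 1e-9
  edge <- abs(kmax - lim) <= 1e-9
  if (any(edge)) {
    parity <- outer(k, k, `+`) %% 2L == 0L
    inside | (edge & parity)
  } else {
    inside
  }
}

#' Rasterize a stimulus on a pixel lattice
#'
#' `render_disk()` draws a uniform disk of diameter 4 sigma_c at the given
#' Weber contrast on a uniform background; `render_square()` draws a
#' uniform square of width 4 sigma_c at an absolute target luminance.
#' Membership is a binary pixel-center test with no anti-aliasing:
#' resolution is the accuracy parameter, and the analytic oracles
#' ([analytic_disk_response()], [analytic_square_response()]) bound the
#' discretization error.  Disk pixels are those whose center lies strictly
#' inside the radius.  Square pixels are those whose center lies strictly
#' inside the edge, plus -- because the edge falls exactly on a row of
#' pixel centers at every integer resolution -- every second edge-center
#' pixel (index-parity tie-break), which keeps the rasterized footprint
#' unbiased instead of half a pixel small.  `render_stimulus()` dispatches
#' on a stimulus specification object.
#'
#' @param background background luminance, > 0.
#' @param contrast_pct Weber contrast of the disk, percent in \[-100, 100\].
#' @param target_luminance luminance of the square, >= 0.
#' @param grid a [grid_spec()]; must contain the stimulus
#'   (`half_width >= 2`).
#' @param spec a `disk_stimulus` or `square_stimulus`.
#' @param ... passed to the rendering function.
#' @return A `luminance_image`: list with the pixel matrix `values`, the
#'   `grid`, and the `background` level.  Pixels outside the footprint
#'   equal the background exactly.
#' @examples
#' g <- grid_spec(16, 5)
#' img <- render_disk(100, -100, g)
#' range(img$values)  # 0 inside the disk, 100 outside
#' @export
render_disk <- function(background, contrast_pct, grid) {
  spec <- disk_stimulus(background, contrast_pct)
  stopifnot(inherits(grid, "grid_spec"))
  d <- background * (1 + contrast_pct / 100)
  mask <- .disk_mask(grid, spec$radius)
  values <- background + (d - background) * mask
  .luminance_image(values, grid, background)
}

#' @rdname render_disk
#' @export
render_square <- function(background, target_luminance, grid) {
  spec <- square_stimulus(background, target_luminance)
  stopifnot(inherits(grid, "grid_spec"))
  mask <- .square_mask(grid, spec$half_width)
  values <- background + (target_luminance - background) * mask
  .luminance_image(values, grid, background)
}

#' @rdname render_disk
#' @export
render_stimulus <- function(spec, grid, ...) UseMethod("render_stimulus")

#' @export
render_stimulus.disk_stimulus <- function(spec, grid, ...) {
  render_disk(spec$background, spec$contrast_pct, grid)
}

#' @export
render_stimulus.square_stimulus <- function(spec, grid, ...) {
  render_square(spec$background, spec$target_luminance, grid)
}

#' Read and write stimulus specifications
#'
#' Stimulus specs serialize to a flat key-value YAML mapping with keys
#' `shape` (`disk` or `square`), `background`, and either `contrast_pct`
#' (disk) or `target_luminance` (square).
#'
#' @param spec a stimulus specification object.
#' @param path file path.
#' @return `read_stimulus_config()` returns the stimulus object;
#'   `write_stimulus_config()` returns `path` invisibly.
#' @export
write_stimulus_config <- function(spec, path) {
  stopifnot(inherits(spec, c("disk_stimulus", "square_stimulus")))
  fields <- if (spec$shape == "disk") {
    list(shape = "disk", background = spec$background,
         contrast_pct = spec$contrast_pct)
  } else {
    list(shape = "square", background = spec$background,
         target_luminance = spec$target_luminance)
  }
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_stimulus_config
#' @export
read_stimulus_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$shape) || !x$shape %in% c("disk", "square"))
    stop("stimulus config must have shape: disk|square", call. = FALSE)
  if (x$shape == "disk") {
    disk_stimulus(x$background, x$contrast_pct)
  } else {
    square_stimulus(x$background, x$target_luminance)
  }
}

#' Export a rendered stimulus as a 16-bit grayscale PGM
#'
#' Writes a plain-text (P2) portable graymap for visual inspection.  The
#' default `max_val` of 65535 leaves luminances up to that value unclipped
#' (an 8-bit export would clip the 120 cd/m^2 stimuli only if rescaled;
#' 16-bit avoids the question entirely).  Values are rounded to integers.
#'
#' @param image a `luminance_image`.
#' @param path output file path.
#' @param max_val PGM maximum gray value (<= 65535).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, max_val = 65535L) {
  stopifnot(inherits(image, "luminance_image"), max_val >= 1, max_val <= 65535)
  v <- round(image$values)
  if (any(v < 0) || any(v > max_val))
    stop("luminance values outside [0, max_val]; rescale before export",
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), as.character(max_val)), con)
  write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
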