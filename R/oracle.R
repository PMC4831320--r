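# Closed-form continuous-limit responses.  For a uniform figure of
# luminance d on a uniform background b, the image is b + (d - b) * 1_F
# with F the footprint, so with unit-mass kernels
#   numerator   = (d - b) * (M_c(F) - M_s(F))
#   denominator = b + (d - b) * M_n(F)
# where M_sigma(F) is the mass of the 2D Gaussian inside F.  For a
# centered disk of radius R, M = 1 - exp(-R^2 / (2 sigma^2)); for a
# centered square of half-width a, M = (2 pnorm(a / sigma) - 1)^2 by
# separability.  These are the exact continuum limits of the rasterized
# pipeline and serve as its accuracy oracle.

.disk_mass <- function(sigma, radius) 1 - exp(-radius^2 / (2 * sigma^2))
.square_mass <- function(sigma, half_width) (2 * pnorm(half_width / sigma) - 1)^2

.disk_AL <- function(unit, radius = 2) {
  sc <- unit$sigma_c
  list(A = .disk_mass(1, radius) - .disk_mass(unit$sigma_s / sc, radius),
       L = .disk_mass(unit$sigma_n / sc, radius))
}

.square_AL <- function(unit, half_width = 2) {
  sc <- unit$sigma_c
  list(A = .square_mass(1, half_width) - .square_mass(unit$sigma_s / sc, half_width),
       L = .square_mass(unit$sigma_n / sc, half_width))
}

#' Closed-form model responses to disk and square stimuli
#'
#' Continuous-limit (infinite-resolution) responses of the normalized
#' difference-of-Gaussians model, used as the independent accuracy oracle
#' for the rasterized pipeline.  For a disk of diameter 4 sigma_c at Weber
#' contrast `c` (as a fraction) the signed response is
#' `r = c * A / (1 + c * L)` where `A` is the difference of center and
#' surround Gaussian mass inside the disk and `L` the normalization-pool
#' mass inside it; 2D Gaussian mass inside a centered disk or square has a
#' closed form.  Because the stimulus is uniform inside its footprint and
#' the kernels have unit mass, these expressions are exact in the
#' continuum; the rasterized pipeline converges to them as resolution
#' grows.
#'
#' @param unit a [contrast_encoder()].
#' @param contrast_pct Weber contrast in percent, in \[-100, 100\]
#'   (vectorized).
#' @param background,target_luminance square-stimulus luminances
#'   (background > 0, target >= 0; `target_luminance` vectorized).
#' @param eps degeneracy guard on the normalization denominator, relative
#'   to the background.
#' @return Signed response(s), same length as the vectorized argument.
#' @examples
#' u <- contrast_encoder(2, 1)
#' # OFF/ON asymmetry at full contrast, in closed form:
#' abs(analytic_disk_response(u, -100)) / analytic_disk_response(u, 100)
#' @export
analytic_disk_response <- function(unit, contrast_pct, eps = 1e-12) {
  stopifnot(inherits(unit, "contrast_encoder"),
            all(contrast_pct >= -100), all(contrast_pct <= 100))
  m <- .disk_AL(unit)
  ct <- contrast_pct / 100
  den <- 1 + ct * m$L
  if (any(den <= eps))
    stop("degenerate stimulus: normalization output is not positive",
         call. = FALSE)
  ct * m$A / den
}

#' @rdname analytic_disk_response
#' @export
analytic_square_response <- function(unit, background, target_luminance,
                                     eps = 1e-12) {
  stopifnot(inherits(unit, "contrast_encoder"),
            is.numeric(background), length(background) == 1L, background > 0,
            all(target_luminance >= 0))
  m <- .square_AL(unit)
  diffs <- target_luminance - background
  den <- background + diffs * m$L
  if (any(den <= eps * background))
    stop("degenerate stimulus: normalization output is not positive",
         call. = FALSE)
  diffs * m$A / den
}
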