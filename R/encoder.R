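#' Construct a normalized difference-of-Gaussians contrast encoder
#'
#' A model unit is defined by three Gaussian standard deviations: the
#' center (`sigma_c`, the reference scale, fixed at 1 in internal units),
#' the antagonistic surround (`sigma_s > sigma_c`), and the normalization
#' pool (`sigma_n >= sigma_c`).  The signed response to a luminance image
#' `f` is
#'
#' \deqn{r = \frac{f * (g_{\sigma_c} - g_{\sigma_s})}{f * g_{\sigma_n}}}
#'
#' evaluated at the image center, where `g_sigma` is a unit-mass 2D
#' Gaussian; half-wave rectification then yields the ON channel
#' `max(r, 0)` and the OFF channel `max(-r, 0)`.
#'
#' The canonical family sweeps `sigma_s/sigma_c` over
#' \{1.25, 1.5, 2, 3, 4, 6\} and `sigma_n/sigma_c` over
#' \{1, 1.25, 1.5, 2, 3, 4, 6\}: 42 units.
#'
#' @param sigma_s surround standard deviation; must exceed `sigma_c`.
#' @param sigma_n normalization standard deviation; must be at least
#'   `sigma_c`.
#' @param sigma_c center standard deviation (the reference length; leave at
#'   1 unless you have a reason not to).
#' @return An object of class `contrast_encoder`.
#' @examples
#' u <- contrast_encoder(sigma_s = 2, sigma_n = 2)
#' coef(u)
#' @seealso [canonical_units()], [model_response()], [compute_crf()]
#' @export
contrast_encoder <- function(sigma_s, sigma_n, sigma_c = 1) {
  stopifnot(is.numeric(sigma_c), length(sigma_c) == 1L, sigma_c > 0,
            is.numeric(sigma_s), length(sigma_s) == 1L,
            is.numeric(sigma_n), length(sigma_n) == 1L)
  if (sigma_s <= sigma_c)
    stop("'sigma_s' must exceed 'sigma_c' (surround broader than center)",
         call. = FALSE)
  if (sigma_n < sigma_c)
    stop("'sigma_n' must be at least 'sigma_c'", call. = FALSE)
  structure(list(sigma_c = sigma_c, sigma_s = sigma_s, sigma_n = sigma_n),
            class = "contrast_encoder")
}

#' The canonical 42-unit model family
#'
#' All combinations of surround/center ratio in
#' \{1.25, 1.5, 2, 3, 4, 6\} and normalization/center ratio in
#' \{1, 1.25, 1.5, 2, 3, 4, 6\}.
#'
#' @param sigma_s_ratios,sigma_n_ratios scale-factor grids relative to
#'   `sigma_c`.
#' @return A list of [contrast_encoder()] objects with a `"ratios"`
#'   attribute (a data frame of the two scale factors, one row per unit).
#' @examples
#' length(canonical_units())  # 42
#' @export
canonical_units <- function(sigma_s_ratios = c(1.25, 1.5, 2, 3, 4, 6),
                            sigma_n_ratios = c(1, 1.25, 1.5, 2, 3, 4, 6)) {
  grid <- expand.grid(sigma_s_ratio = sigma_s_ratios,
                      sigma_n_ratio = sigma_n_ratios,
                      KEEP.OUT.ATTRS = FALSE)
  units <- lapply(seq_len(nrow(grid)), function(i)
    contrast_encoder(sigma_s = grid$sigma_s_ratio[i],
                     sigma_n = grid$sigma_n_ratio[i]))
  attr(units, "ratios") <- grid
  units
}

#' Sample a 2D Gaussian filter kernel on a lattice
#'
#' The kernel is the separable product of 1D Gaussians evaluated at pixel
#' centers, then renormalized so its discrete sum is exactly 1.  Discrete
#' renormalization (rather than keeping the analytic `1/(2 pi sigma^2)`
#' mass) makes two model identities hold on the lattice and not just in
#' the continuum: a uniform image produces a response of exactly zero, and
#' scaling the image leaves the normalized response unchanged.
#'
#' @param sigma standard deviation in sigma_c units, > 0.
#' @param grid a [grid_spec()]; a half-width of at least `3 * sigma` is
#'   recommended to keep truncated mass negligible.
#' @return A `side x side` matrix summing to 1.
#' @examples
#' k <- gaussian_kernel(1, grid_spec(16, 5))
#' sum(k)  # 1
#' @export
gaussian_kernel <- function(sigma, grid) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a positive scalar", call. = FALSE)
  stopifnot(inherits(grid, "grid_spec"))
  g1 <- dnorm(grid$coords, sd = sigma)
  k <- outer(g1, g1)
  k / sum(k)
}

#' Kernels of a model unit on a shared lattice
#'
#' @param unit a [contrast_encoder()].
#' @param grid a [grid_spec()].
#' @return List with elements `center`, `surround`, `norm` (matrices
#'   summing to 1) and the `grid`.
#' @export
encoder_kernels <- function(unit, grid) {
  stopifnot(inherits(unit, "contrast_encoder"))
  sc <- unit$sigma_c
  list(center = gaussian_kernel(unit$sigma_c / sc, grid),
       surround = gaussian_kernel(unit$sigma_s / sc, grid),
       norm = gaussian_kernel(unit$sigma_n / sc, grid),
       grid = grid)
}

.check_lattice <- function(image, kernels) {
  if (!.same_grid(image$grid, kernels$grid) ||
      !all(dim(image$values) == dim(kernels$center)))
    stop("image and filter kernels must share one lattice", call. = FALSE)
}

#' Model responses to a luminance image
#'
#' `model_response()` evaluates the full normalized model: the
#' difference-of-Gaussians (antagonistic) output divided by the
#' normalization-pool output, a single scalar.  Image and filters share
#' one lattice, so each "convolution" is one dot product at the image
#' center -- no sliding window.  `antagonistic_response()` returns the
#' numerator alone (the linear stage, used to show what normalization
#' adds).  `rectify()` half-wave rectifies a signed response into the ON
#' and OFF channels with no further nonlinearity.
#'
#' The response is undefined when the normalization output is not
#' positive; such degenerate inputs (an all-black image) raise an error
#' rather than returning a clamped value.  The guard threshold is
#' `eps * background`.
#'
#' @param image a `luminance_image` from [render_disk()] /
#'   [render_square()].
#' @param unit a [contrast_encoder()].
#' @param kernels optional precomputed [encoder_kernels()] on the image
#'   lattice, to amortize kernel construction over many stimuli.
#' @param eps relative degeneracy threshold for the normalization output.
#' @param r a signed response (scalar).
#' @return `model_response()` and `antagonistic_response()` return a
#'   signed scalar; `rectify()` returns `c(on = , off = )` with
#'   `on - off == r` and `on * off == 0`.
#' @examples
#' u <- contrast_encoder(2, 2)
#' g <- encoder_grid(u)
#' r <- model_response(render_disk(50, 100, g), u)
#' rectify(r)
#' @export
model_response <- function(image, unit, kernels = NULL, eps = 1e-12) {
  stopifnot(inherits(image, "luminance_image"))
  kernels <- kernels %||% encoder_kernels(unit, image$grid)
  .check_lattice(image, kernels)
  den <- sum(image$values * kernels$norm)
  if (den <= eps * image$background)
    stop("degenerate stimulus: normalization output is not positive ",
         "(local mean luminance ~ 0)", call. = FALSE)
  num <- sum(image$values * (kernels$center - kernels$surround))
  num / den
}

#' @rdname model_response
#' @export
antagonistic_response <- function(image, unit, kernels = NULL) {
  stopifnot(inherits(image, "luminance_image"))
  kernels <- kernels %||% encoder_kernels(unit, image$grid)
  .check_lattice(image, kernels)
  sum(image$values * (kernels$center - kernels$surround))
}

#' @rdname model_response
#' @export
rectify <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  c(on = max(r, 0), off = max(-r, 0))
}
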