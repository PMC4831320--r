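#' Cone photoreceptor adaptation model
#'
#' A light-adapted cone's normalized polarization in response to a
#' stimulus intensity `I_b` follows the saturating (Naka-Rushton-type)
#' function
#'
#' \deqn{V = \frac{I_b}{I_b + I_a}}
#'
#' where `I_a`, the adaptation constant, is the intensity producing half
#' the maximal response; adaptation centers the cone's dynamic range on
#' the ambient light level.  At the adapted level itself `V = 1/2` (the
#' baseline); intensities below it depolarize the cone (V below baseline),
#' intensities above it hyperpolarize it.  `temporal_weber()` re-expresses
#' a stimulus intensity as temporal Weber contrast relative to the adapted
#' level, `100 * (I_b - I_a) / I_a`.
#'
#' @param I_b stimulus intensity, >= 0 (vectorized).
#' @param I_a adaptation constant (half-saturation intensity), > 0.
#' @return `cone_polarization()`: normalized polarization in \[0, 1);
#'   `temporal_weber()`: percent contrast.
#' @examples
#' cone_polarization(100, 100)  # 0.5, the baseline
#' temporal_weber(0, 100)       # -100%
#' @export
cone_polarization <- function(I_b, I_a) {
  if (!is.numeric(I_a) || length(I_a) != 1L || I_a <= 0)
    stop("'I_a' must be a positive scalar", call. = FALSE)
  stopifnot(is.numeric(I_b), all(I_b >= 0))
  I_b / (I_b + I_a)
}

#' @rdname cone_polarization
#' @export
temporal_weber <- function(I_b, I_a) {
  if (!is.numeric(I_a) || length(I_a) != 1L || I_a <= 0)
    stop("'I_a' must be a positive scalar", call. = FALSE)
  100 * (I_b - I_a) / I_a
}

#' Cone polarization magnitude as a function of temporal Weber contrast
#'
#' Evaluates the adaptation model over a symmetric grid of temporal Weber
#' contrasts and splits the polarization change from baseline (`V = 1/2`)
#' into the depolarizing branch (dark contrasts, input to OFF bipolar
#' cells) and the hyperpolarizing branch (bright contrasts, input to ON
#' bipolar cells), both indexed by contrast magnitude.  Because the model
#' depends on intensity only through `I_b / I_a`, the contrast-domain
#' curves are exactly the same for every adaptation level.  The dark
#' branch is convex (accelerating) and everywhere above the concave
#' (decelerating) bright branch -- the same ordering and curvature the
#' normalized spatial encoder produces for OFF and ON disk responses.
#'
#' @param I_a adaptation constant; affects nothing in the contrast domain
#'   (asserted by tests) but is recorded as an attribute.
#' @param step_pct contrast step in percent; the grid is
#'   `seq(0, 100, step_pct)` for each branch.
#' @return An object of class `cone_curves`: data frame with columns
#'   `contrast` (percent magnitude), `depolarization` (|V - 1/2| for
#'   `-contrast`), `hyperpolarization` (|V - 1/2| for `+contrast`),
#'   attribute `I_a`.
#' @examples
#' cc <- polarization_vs_contrast()
#' cc[cc$contrast == 100, ]  # dark 0.5, bright 1/6: a 3:1 asymmetry
#' @export
polarization_vs_contrast <- function(I_a = 100, step_pct = 1) {
  stopifnot(step_pct > 0)
  if (!is.numeric(I_a) || length(I_a) != 1L || I_a <= 0)
    stop("'I_a' must be a positive scalar", call. = FALSE)
  contrast <- seq(0, 100, by = step_pct)
  baseline <- 0.5
  # intensities expressed in units of I_a, so the scale invariance of the
  # contrast-domain curves is structural (bitwise), not just approximate
  v_dark <- cone_polarization(1 - contrast / 100, 1)
  v_bright <- cone_polarization(1 + contrast / 100, 1)
  structure(data.frame(contrast = contrast,
                       depolarization = baseline - v_dark,
                       hyperpolarization = v_bright - baseline),
            I_a = I_a,
            class = c("cone_curves", "data.frame"))
}
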