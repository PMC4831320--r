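#' @export
print.contrast_encoder <- function(x, ...) {
  cat("Normalized difference-of-Gaussians contrast encoder\n")
  cat(sprintf("  center        sigma_c = %.4g (reference scale)\n", x$sigma_c))
  cat(sprintf("  surround      sigma_s = %.4g (%.4g x center)\n",
              x$sigma_s, x$sigma_s / x$sigma_c))
  cat(sprintf("  normalization sigma_n = %.4g (%.4g x center)\n",
              x$sigma_n, x$sigma_n / x$sigma_c))
  invisible(x)
}

#' @export
coef.contrast_encoder <- function(object, ...) {
  c(sigma_c = object$sigma_c, sigma_s = object$sigma_s,
    sigma_n = object$sigma_n)
}

#' Predict encoder responses to a stimulus image
#'
#' @param object a [contrast_encoder()].
#' @param image a `luminance_image`.
#' @param type `"rectified"` for the ON/OFF pair, `"signed"` for the raw
#'   normalized response, `"antagonistic"` for the linear stage alone.
#' @param ... unused.
#' @return `"rectified"`: named vector `c(on = , off = )`; otherwise a
#'   signed scalar.
#' @examples
#' u <- contrast_encoder(2, 2)
#' predict(u, render_disk(50, -60, encoder_grid(u)))
#' @export
predict.contrast_encoder <- function(object, image,
                                     type = c("rectified", "signed",
                                              "antagonistic"), ...) {
  type <- match.arg(type)
  switch(type,
         rectified = rectify(model_response(image, object)),
         signed = model_response(image, object),
         antagonistic = antagonistic_response(image, object))
}

#' Summarize a contrast encoder
#'
#' Computes the unit's headline statistics at the default lattice: the
#' OFF/ON response ratio at 100% contrast and the ON and OFF nonlinearity
#' indices of the disk contrast response function.
#'
#' @param object a [contrast_encoder()].
#' @param background background luminance for the contrast sweep.
#' @param pixels_per_sigma_c lattice resolution.
#' @param ... unused.
#' @return A `summary.contrast_encoder` list.
#' @export
summary.contrast_encoder <- function(object, background = 50,
                                     pixels_per_sigma_c = 16, ...) {
  grid <- encoder_grid(object, pixels_per_sigma_c)
  crf <- compute_crf(object, background, grid = grid)
  structure(list(unit = object,
                 offon_ratio_100 = offon_ratio_at_max(object, background,
                                                      grid = grid),
                 nli_on = nonlinearity_index(crf, "on"),
                 nli_off = nonlinearity_index(crf, "off")),
            class = "summary.contrast_encoder")
}

#' @export
print.summary.contrast_encoder <- function(x, ...) {
  print(x$unit)
  cat(sprintf("  OFF/ON ratio at 100%% contrast: %.3f\n", x$offon_ratio_100))
  cat(sprintf("  nonlinearity index  ON: %+.3f   OFF: %+.3f\n",
              x$nli_on, x$nli_off))
  invisible(x)
}

#' Plot a contrast response function
#'
#' ON responses as a solid red line and OFF responses as a dashed black
#' line against absolute Weber contrast, the conventional display for
#' comparing the two polarities.
#'
#' @param x a [compute_crf()] result.
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.crf <- function(x, ...) {
  graphics::plot(x$contrast, x$off, type = "l", lty = 2, col = "black",
                 xlab = "|Weber contrast| (%)", ylab = "response",
                 ylim = range(0, x$on, x$off, na.rm = TRUE), ...)
  graphics::lines(x$contrast, x$on, col = "red")
  graphics::legend("topleft", legend = c("OFF (dark)", "ON (bright)"),
                   lty = c(2, 1), col = c("black", "red"), bty = "n")
  invisible(x)
}

#' @export
plot.lrf <- function(x, ...) {
  bg <- attr(x, "background")
  graphics::plot(x$target, x$response, type = "l",
                 xlab = "target luminance", ylab = "response",
                 main = sprintf("%s responses, background %g",
                                toupper(attr(x, "polarity")), bg), ...)
  graphics::abline(v = bg, lty = 3)
  invisible(x)
}

#' @export
plot.cone_curves <- function(x, ...) {
  graphics::plot(x$contrast, x$depolarization, type = "l", lty = 2,
                 xlab = "|temporal Weber contrast| (%)",
                 ylab = "|polarization - baseline|",
                 ylim = range(0, x$depolarization, x$hyperpolarization), ...)
  graphics::lines(x$contrast, x$hyperpolarization, col = "red")
  graphics::legend("topleft",
                   legend = c("depolarization (dark -> OFF)",
                              "hyperpolarization (bright -> ON)"),
                   lty = c(2, 1), col = c("black", "red"), bty = "n")
  invisible(x)
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("Model population table: %d units\n", nrow(x)))
  fails <- attr(x, "failures")
  if (!is.null(fails) && nrow(fails) > 0)
    cat(sprintf("  (%d unit(s) failed; see attr(x, 'failures'))\n",
                nrow(fails)))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
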