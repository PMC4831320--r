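# Discrete footprint masses on the lattice.  A rendered stimulus is
# background + (target - background) * mask, and the kernels sum to 1, so
# the signed response to ANY luminance level of a fixed footprint is
#   r = (d - b) * A / (b + (d - b) * L),
# with A and L the mask-restricted kernel sums.  Computing A and L once
# per unit and sweeping the luminance algebraically is bitwise-equivalent
# (up to summation order) to re-rendering one image per level and taking
# the dot products; tests assert the equality.
.rasterized_AL <- function(unit, grid, shape = c("disk", "square"),
                           kernels = NULL) {
  shape <- match.arg(shape)
  kernels <- kernels %||% encoder_kernels(unit, grid)
  mask <- if (shape == "disk") .disk_mask(grid) else .square_mask(grid)
  list(A = sum(kernels$center[mask]) - sum(kernels$surround[mask]),
       L = sum(kernels$norm[mask]))
}

.signed_from_masses <- function(masses, background, target, eps = 1e-12) {
  den <- background + (target - background) * masses$L
  ifelse(den <= eps * background, NA_real_,
         (target - background) * masses$A / den)
}

#' Contrast response functions of a model unit
#'
#' Sweeps disk stimuli (diameter 4 sigma_c) over Weber contrast 0..100% in
#' equal steps on a uniform background, computing the rectified ON
#' response to each increment (+c) and OFF response to each decrement
#' (-c).  Points whose normalization denominator is degenerate are
#' returned as `NA` with a warning, never dropped silently.
#'
#' @param unit a [contrast_encoder()].
#' @param background background luminance (the full model's curves are
#'   identical for any background; the antagonistic stage's are not).
#' @param step_pct contrast step in percent; must divide 100.
#' @param pixels_per_sigma_c lattice resolution used when `grid` is `NULL`.
#' @param grid optional [grid_spec()] override.
#' @return An object of class `crf`: a data frame with columns `contrast`
#'   (percent), `on`, `off`, and attributes `unit` and `background`.
#' @examples
#' crf <- compute_crf(contrast_encoder(2, 2))
#' tail(crf, 3)  # OFF exceeds ON at every contrast
#' @export
compute_crf <- function(unit, background = 50, step_pct = 1,
                        pixels_per_sigma_c = 16, grid = NULL) {
  stopifnot(inherits(unit, "contrast_encoder"), background > 0,
            step_pct > 0)
  if (abs(100 / step_pct - round(100 / step_pct)) > 1e-9)
    stop("'step_pct' must divide 100", call. = FALSE)
  grid <- grid %||% encoder_grid(unit, pixels_per_sigma_c)
  m <- .rasterized_AL(unit, grid, "disk")
  contrasts <- seq(0, 100, by = step_pct)
  on <- .signed_from_masses(m, background, background * (1 + contrasts / 100))
  off <- -.signed_from_masses(m, background, background * (1 - contrasts / 100))
  if (anyNA(on) || anyNA(off))
    warning("degenerate normalization denominator at ",
            sum(is.na(on) | is.na(off)), " contrast point(s); returned NA")
  structure(data.frame(contrast = contrasts, on = on, off = off),
            unit = unit, background = background,
            class = c("crf", "data.frame"))
}

#' Nonlinearity index of a contrast response function
#'
#' The log10 ratio of the curve's slope at a high contrast (default 50%)
#' to its slope at a low contrast (default 5%), slopes estimated by
#' central finite differences on the sampled curve.  Positive values mean
#' an accelerating (expansive) response, negative a decelerating
#' (compressive) one.  For every canonical unit the OFF index exceeds the
#' ON index, and the ordering is invariant to the choice of the high
#' contrast anywhere in 20--90%.
#'
#' @param crf a [compute_crf()] result.
#' @param polarity `"on"` or `"off"`.
#' @param c_low,c_high contrasts (percent) at which slopes are taken; must
#'   be interior points of the sampled grid.
#' @return Scalar index; `NA` if either slope is not positive.
#' @export
nonlinearity_index <- function(crf, polarity = c("off", "on"),
                               c_low = 5, c_high = 50) {
  stopifnot(inherits(crf, "crf"))
  polarity <- match.arg(polarity)
  y <- crf[[polarity]]
  x <- crf$contrast
  slope_at <- function(c0) {
    i <- which(abs(x - c0) < 1e-9)
    if (length(i) != 1L || i == 1L || i == length(x))
      stop("contrast ", c0, "% must be an interior sampled point",
           call. = FALSE)
    (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  }
  s_lo <- slope_at(c_low)
  s_hi <- slope_at(c_high)
  if (is.na(s_lo) || is.na(s_hi) || s_lo <= 0 || s_hi <= 0)
    return(NA_real_)
  log10(s_hi / s_lo)
}

#' OFF/ON response ratio at full contrast
#'
#' Ratio of the rectified OFF response to a -100% contrast disk to the ON
#' response to a +100% disk.  In the continuum this equals
#' `(1 + L) / (1 - L)` where `L` is the normalization-pool mass inside the
#' disk, so it depends only on `sigma_n / sigma_c` -- the same for every
#' surround scale -- and grows without bound as the pool shrinks toward the
#' center scale.  The `sigma_n = sigma_c` endpoint is near-degenerate: the
#' -100% disk has luminance 0, so the denominator is carried almost
#' entirely by the background annulus.
#'
#' @inheritParams compute_crf
#' @return Scalar ratio (> 1 for every canonical unit).
#' @export
offon_ratio_at_max <- function(unit, background = 50,
                               pixels_per_sigma_c = 16, grid = NULL) {
  stopifnot(inherits(unit, "contrast_encoder"), background > 0)
  grid <- grid %||% encoder_grid(unit, pixels_per_sigma_c)
  m <- .rasterized_AL(unit, grid, "disk")
  on <- .signed_from_masses(m, background, 2 * background)
  off <- -.signed_from_masses(m, background, 0)
  off / on
}

#' Luminance response function of a model unit
#'
#' Sweeps square stimuli (width 4 sigma_c) of varying absolute luminance
#' on a fixed background, reporting the rectified response of one
#' polarity.  Targets default to an even grid from the background to the
#' extreme of the tested luminance range (120 for ON, 2 for OFF), both
#' endpoints included, matching flashed-square luminance protocols in
#' cd/m^2.
#'
#' @param unit a [contrast_encoder()].
#' @param background background luminance (protocol values: 2 dark, 61
#'   gray, 120 light).
#' @param polarity `"on"` (increments, toward 120) or `"off"` (decrements,
#'   toward 2).
#' @param n_targets number of evenly spaced target luminances.
#' @param targets optional explicit target luminances (overrides
#'   `n_targets`); must run from the background toward the extreme.
#' @param pixels_per_sigma_c,grid lattice controls as in [compute_crf()].
#' @return An object of class `lrf`: data frame with columns `target` and
#'   `response`, attributes `unit`, `background`, `polarity`.
#' @examples
#' lrf <- compute_luminance_response(contrast_encoder(3, 2), 61, "off")
#' saturation_summary(lrf)
#' @export
compute_luminance_response <- function(unit, background,
                                       polarity = c("on", "off"),
                                       n_targets = 60, targets = NULL,
                                       pixels_per_sigma_c = 16, grid = NULL) {
  stopifnot(inherits(unit, "contrast_encoder"), background > 0)
  polarity <- match.arg(polarity)
  extreme <- if (polarity == "on") 120 else 2
  if (is.null(targets)) {
    if ((polarity == "on" && background >= extreme) ||
        (polarity == "off" && background <= extreme))
      stop("background leaves no ", polarity, " luminance range", call. = FALSE)
    targets <- seq(background, extreme, length.out = n_targets)
  }
  grid <- grid %||% encoder_grid(unit, pixels_per_sigma_c)
  m <- .rasterized_AL(unit, grid, "square")
  signed <- .signed_from_masses(m, background, targets)
  response <- if (polarity == "on") pmax(signed, 0) else pmax(-signed, 0)
  structure(data.frame(target = targets, response = response),
            unit = unit, background = background, polarity = polarity,
            class = c("lrf", "data.frame"))
}

#' Half-saturation and maximal response of a luminance response function
#'
#' `rmax` is the response at the largest presented luminance contrast (the
#' extreme target).  `l50` is the luminance at which the response first
#' reaches `rmax / 2`, located by linear interpolation between samples and
#' expressed as a proportion of the sampled luminance range
#' `|L50 - background| / |extreme - background|`: 0.5 for a linear curve,
#' below 0.5 for a compressive (saturating) one.
#'
#' @param lrf a [compute_luminance_response()] result with at least 10
#'   sampled points.
#' @return List with elements `l50` (proportion in (0, 1\]) and `rmax`.
#' @export
saturation_summary <- function(lrf) {
  stopifnot(inherits(lrf, "lrf"))
  if (nrow(lrf) < 10)
    stop("need at least 10 sampled points to locate L50 reliably",
         call. = FALSE)
  bg <- attr(lrf, "background")
  dist <- abs(lrf$target - bg)
  o <- order(dist)
  dist <- dist[o]
  resp <- lrf$response[o]
  if (any(diff(resp) < 0))
    stop("luminance response must be monotone in |target - background|",
         call. = FALSE)
  rmax <- resp[length(resp)]
  half <- rmax / 2
  l50_dist <- approx(resp, dist, xout = half, ties = "ordered")$y
  list(l50 = l50_dist / max(dist), rmax = rmax)
}

#' Sweep the canonical family and tabulate all derived statistics
#'
#' For each unit of the canonical (or a custom) parameter grid, computes:
#' nonlinearity indices of the ON and OFF contrast response functions, the
#' OFF/ON response ratio at 100% contrast, and L50 / Rmax from luminance
#' response functions for OFF units on the light (120) and gray (61)
#' backgrounds and ON units on the dark (2) and gray backgrounds.  The
#' sweep is deterministic; per-unit failures are recorded in the
#' `"failures"` attribute and never abort the sweep.  Units whose
#' full-contrast dark disk leaves the normalization pool nearly empty
#' (`sigma_n` close to `sigma_c`) are annotated in the `near_degenerate`
#' column rather than excluded.
#'
#' @param sigma_s_ratios,sigma_n_ratios the parameter grid (defaults: the
#'   canonical 6 x 7 family).
#' @param pixels_per_sigma_c lattice resolution.
#' @param step_pct contrast step for the CRFs.
#' @param n_targets luminance samples per background.
#' @param crf_background background for the contrast sweeps.
#' @param file optional path; if given the table is also written as CSV.
#' @return A `population_table` (data frame, one row per unit) with
#'   columns `sigma_s_ratio`, `sigma_n_ratio`, `nli_on`, `nli_off`,
#'   `offon_ratio_100`, `l50_on_dark`, `l50_on_gray`, `l50_off_light`,
#'   `l50_off_gray`, `rmax_on_dark`, `rmax_on_gray`, `rmax_off_light`,
#'   `rmax_off_gray`, `near_degenerate`.
#' @examples
#' \donttest{
#' tab <- population_sweep()
#' nrow(tab)  # 42
#' summarize_background_ratios(tab)
#' }
#' @export
population_sweep <- function(sigma_s_ratios = c(1.25, 1.5, 2, 3, 4, 6),
                             sigma_n_ratios = c(1, 1.25, 1.5, 2, 3, 4, 6),
                             pixels_per_sigma_c = 16, step_pct = 1,
                             n_targets = 60, crf_background = 50,
                             file = NULL) {
  contrasts <- seq(0, 100, by = step_pct)
  for (c0 in c(5, 50))
    if (!any(abs(contrasts - c0) < 1e-9))
      stop("'step_pct' must sample the ", c0,
           "% contrast used by the nonlinearity index", call. = FALSE)
  units <- canonical_units(sigma_s_ratios, sigma_n_ratios)
  ratios <- attr(units, "ratios")
  failures <- list()
  rows <- lapply(seq_along(units), function(i) {
    unit <- units[[i]]
    row <- data.frame(sigma_s_ratio = ratios$sigma_s_ratio[i],
                      sigma_n_ratio = ratios$sigma_n_ratio[i],
                      nli_on = NA_real_, nli_off = NA_real_,
                      offon_ratio_100 = NA_real_,
                      l50_on_dark = NA_real_, l50_on_gray = NA_real_,
                      l50_off_light = NA_real_, l50_off_gray = NA_real_,
                      rmax_on_dark = NA_real_, rmax_on_gray = NA_real_,
                      rmax_off_light = NA_real_, rmax_off_gray = NA_real_,
                      near_degenerate = FALSE)
    tryCatch({
      grid <- encoder_grid(unit, pixels_per_sigma_c)
      crf <- compute_crf(unit, crf_background, step_pct, grid = grid)
      row$nli_on <- nonlinearity_index(crf, "on")
      row$nli_off <- nonlinearity_index(crf, "off")
      row$offon_ratio_100 <- offon_ratio_at_max(unit, crf_background,
                                                grid = grid)
      # flag units whose -100% disk nearly empties the normalization pool
      m <- .rasterized_AL(unit, grid, "disk")
      row$near_degenerate <- (1 - m$L) < 0.15
      lum <- function(bg, pol) {
        saturation_summary(compute_luminance_response(
          unit, bg, pol, n_targets = n_targets, grid = grid))
      }
      on_dark <- lum(2, "on"); on_gray <- lum(61, "on")
      off_light <- lum(120, "off"); off_gray <- lum(61, "off")
      row$l50_on_dark <- on_dark$l50; row$l50_on_gray <- on_gray$l50
      row$l50_off_light <- off_light$l50; row$l50_off_gray <- off_gray$l50
      row$rmax_on_dark <- on_dark$rmax; row$rmax_on_gray <- on_gray$rmax
      row$rmax_off_light <- off_light$rmax; row$rmax_off_gray <- off_gray$rmax
      row
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<- data.frame(
        sigma_s_ratio = ratios$sigma_s_ratio[i],
        sigma_n_ratio = ratios$sigma_n_ratio[i],
        message = conditionMessage(e))
      row
    })
  })
  tab <- do.call(rbind, rows)
  attr(tab, "failures") <- if (length(failures)) do.call(rbind, failures) else
    data.frame(sigma_s_ratio = numeric(), sigma_n_ratio = numeric(),
               message = character())
  class(tab) <- c("population_table", "data.frame")
  if (!is.null(file))
    write.csv(as.data.frame(tab), file, row.names = FALSE)
  tab
}

#' Population ratios of luminance statistics across backgrounds
#'
#' Aggregates, across the model family, the per-unit ratios comparing each
#' luminance statistic between background conditions: OFF L50 on the light
#' versus gray background, ON L50 dark versus gray, and the same two
#' ratios for Rmax.  OFF statistics barely move with the background (both
#' ratios near 1) while ON statistics change drastically on the dark
#' background: L50 collapses (strong compression) and Rmax grows several-
#' fold, because within a polarity the model responds to contrast, and a
#' fixed luminance is a far larger Weber contrast on a dark background.
#'
#' @param table a [population_sweep()] result.
#' @param aggregator function applied across units (default `mean`).
#' @return Named numeric vector: `off_l50_light_gray`, `on_l50_dark_gray`,
#'   `off_rmax_light_gray`, `on_rmax_dark_gray`.
#' @export
summarize_background_ratios <- function(table, aggregator = mean) {
  stopifnot(inherits(table, "population_table"))
  per_unit <- data.frame(
    off_l50_light_gray = table$l50_off_light / table$l50_off_gray,
    on_l50_dark_gray = table$l50_on_dark / table$l50_on_gray,
    off_rmax_light_gray = table$rmax_off_light / table$rmax_off_gray,
    on_rmax_dark_gray = table$rmax_on_dark / table$rmax_on_gray)
  n_missing <- sum(!stats::complete.cases(per_unit))
  if (n_missing > 0)
    message(n_missing, " unit(s) with missing statistics excluded")
  vapply(per_unit, function(x) aggregator(x[is.finite(x)]), numeric(1))
}
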