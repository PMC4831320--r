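test_that("contrast response functions have the expected structure", {
  crf <- compute_crf(unit_mid, step_pct = 5, pixels_per_sigma_c = 8)
  expect_s3_class(crf, "crf")
  expect_equal(crf$contrast, seq(0, 100, 5))
  expect_equal(crf$on[1], 0)
  expect_equal(crf$off[1], 0)
  expect_true(all(diff(crf$on) > 0))
  expect_true(all(diff(crf$off) > 0))
  expect_true(all(crf$off[-1] > crf$on[-1]))
  expect_error(compute_crf(unit_mid, step_pct = 7), "divide")
})

test_that("full-model contrast curves are identical on backgrounds 50 and 100", {
  g <- fast_grid(unit_mid)
  a <- compute_crf(unit_mid, background = 50, step_pct = 10, grid = g)
  b <- compute_crf(unit_mid, background = 100, step_pct = 10, grid = g)
  expect_equal(a$on, b$on, tolerance = 1e-12)
  expect_equal(a$off, b$off, tolerance = 1e-12)
})

test_that("the algebraic sweep equals the rendered per-stimulus pipeline", {
  g <- fast_grid(unit_mid)
  crf <- compute_crf(unit_mid, background = 50, step_pct = 20, grid = g)
  ks <- encoder_kernels(unit_mid, g)
  for (c_pct in c(20, 60, 100)) {
    i <- which(crf$contrast == c_pct)
    on <- rectify(model_response(render_disk(50, c_pct, g), unit_mid,
                                 kernels = ks))[["on"]]
    off <- rectify(model_response(render_disk(50, -c_pct, g), unit_mid,
                                  kernels = ks))[["off"]]
    expect_equal(crf$on[i], on, tolerance = 1e-10)
    expect_equal(crf$off[i], off, tolerance = 1e-10)
  }
  lrf <- compute_luminance_response(unit_mid, 61, "off", n_targets = 13,
                                    grid = g)
  for (i in c(5, 13)) {
    r <- rectify(model_response(render_square(61, lrf$target[i], g),
                                unit_mid, kernels = ks))[["off"]]
    expect_equal(lrf$response[i], r, tolerance = 1e-10)
  }
})

test_that("nonlinearity index is zero for a linear curve and flags bad slopes", {
  lin <- structure(data.frame(contrast = 0:100, on = 0:100 / 100,
                              off = 0:100 / 50),
                   class = c("crf", "data.frame"))
  expect_equal(nonlinearity_index(lin, "on"), 0)
  expect_equal(nonlinearity_index(lin, "off"), 0)
  flat <- structure(data.frame(contrast = 0:100, on = rep(0, 101),
                               off = rep(1, 101)),
                    class = c("crf", "data.frame"))
  expect_true(is.na(nonlinearity_index(flat, "on")))
  expect_error(nonlinearity_index(lin, "on", c_high = 100), "interior")
  expect_error(nonlinearity_index(lin, "on", c_low = 2.5), "interior")
})

test_that("OFF nonlinearity exceeds ON for any slope-evaluation contrast", {
  for (u in canonical_units()[c(1, 10, 22, 42)]) {
    crf <- compute_crf(u, pixels_per_sigma_c = 8)
    for (c_high in seq(20, 90, by = 10)) {
      nli_on <- nonlinearity_index(crf, "on", c_high = c_high)
      nli_off <- nonlinearity_index(crf, "off", c_high = c_high)
      expect_gt(nli_off, nli_on)
    }
    # the OFF curve accelerates, the ON curve decelerates
    expect_gt(nonlinearity_index(crf, "off"), 0)
    expect_lt(nonlinearity_index(crf, "on"), 0)
  }
})

test_that("OFF/ON ratio at 100% depends on the normalization scale only", {
  sigma_s <- c(1.25, 1.5, 2, 3, 4, 6)
  sigma_n <- c(1, 1.25, 1.5, 2, 3, 4, 6)
  ratio <- sapply(sigma_n, function(n) sapply(sigma_s, function(s)
    offon_ratio_at_max(contrast_encoder(s, n), pixels_per_sigma_c = 8)))
  expect_true(all(ratio > 1))
  # invariant across surround scales at each normalization scale
  spread <- apply(ratio, 2, function(x) diff(range(x)) / mean(x))
  expect_true(all(spread <= 0.005))
  # strictly decreasing in the normalization scale
  expect_true(all(diff(colMeans(ratio)) < 0))
})

test_that("broader surrounds give larger responses at every contrast", {
  g_ref <- NULL
  prev <- NULL
  for (s in c(1.5, 3, 6)) {
    u <- contrast_encoder(s, 2)
    crf <- compute_crf(u, step_pct = 10, pixels_per_sigma_c = 8)
    if (!is.null(prev)) {
      expect_true(all(crf$on[-1] > prev$on[-1]))
      expect_true(all(crf$off[-1] > prev$off[-1]))
    }
    prev <- crf
  }
})

test_that("luminance response functions behave across backgrounds", {
  u <- contrast_encoder(3, 2)  # example unit used for the LGN comparison
  g <- fast_grid(u)
  off_light <- compute_luminance_response(u, 120, "off", grid = g)
  off_gray <- compute_luminance_response(u, 61, "off", grid = g)
  expect_equal(off_light$response[1], 0)
  expect_true(all(diff(off_light$response) > 0))
  # OFF responses at matched proportions of the luminance range barely
  # depend on the background
  rel <- abs(off_light$response[-1] / off_gray$response[-1] - 1)
  expect_lt(max(rel), 0.1)

  # ON responses are far more compressive on the dark background
  on_dark <- saturation_summary(compute_luminance_response(u, 2, "on",
                                                           grid = g))
  on_gray <- saturation_summary(compute_luminance_response(u, 61, "on",
                                                           grid = g))
  expect_lt(on_dark$l50, 0.5 * on_gray$l50)
  expect_gt(on_dark$rmax, on_gray$rmax)

  expect_error(compute_luminance_response(u, 121, "on"), "range")
})

test_that("saturation summary recovers L50 geometry", {
  mk_lrf <- function(f) {
    target <- seq(61, 120, length.out = 61)
    u <- (target - 61) / 59
    structure(data.frame(target = target, response = f(u)),
              background = 61, polarity = "on",
              class = c("lrf", "data.frame"))
  }
  lin <- saturation_summary(mk_lrf(identity))
  expect_equal(lin$l50, 0.5, tolerance = 1e-9)
  expect_equal(lin$rmax, 1)
  expect_gt(saturation_summary(mk_lrf(function(u) u^2))$l50, 0.5)
  expect_lt(saturation_summary(mk_lrf(function(u) sqrt(u)))$l50, 0.5)
  short <- mk_lrf(identity)[1:5, ]
  attr(short, "background") <- 61
  class(short) <- c("lrf", "data.frame")
  expect_error(saturation_summary(short), "10")
})

test_that("population sweep tabulates the full family deterministically", {
  tab <- population_sweep(pixels_per_sigma_c = 8, step_pct = 5,
                          n_targets = 30)
  expect_error(population_sweep(step_pct = 2), "nonlinearity")
  expect_s3_class(tab, "population_table")
  expect_identical(nrow(tab), 42L)
  expect_identical(nrow(attr(tab, "failures")), 0L)
  expect_true(all(tab$nli_off > tab$nli_on))
  expect_true(all(tab$offon_ratio_100 > 1))
  expect_identical(tab$near_degenerate, tab$sigma_n_ratio == 1)

  file <- withr::local_tempfile(fileext = ".csv")
  small <- population_sweep(sigma_s_ratios = c(2, 3),
                            sigma_n_ratios = c(1.5, 3),
                            pixels_per_sigma_c = 8, step_pct = 5,
                            n_targets = 20, file = file)
  expect_identical(nrow(small), 4L)
  back <- read.csv(file)
  expect_identical(nrow(back), 4L)
  expect_true(all(c("sigma_s_ratio", "sigma_n_ratio", "nli_on", "nli_off",
                    "offon_ratio_100", "l50_on_dark", "l50_on_gray",
                    "l50_off_light", "l50_off_gray", "rmax_on_dark",
                    "rmax_on_gray", "rmax_off_light", "rmax_off_gray") %in%
                  names(back)))
})

test_that("population statistics agree with continuum-oracle statistics", {
  # independent route: per-unit ratios from the closed-form Gaussian masses,
  # using the exact half-response solution p = B / (2B -+ X L)
  sigma_n <- c(1, 1.25, 1.5, 2, 3, 4, 6)
  L <- ref_square_mass(sigma_n)
  oracle <- c(
    off_l50_light_gray = mean((120 / (240 - 118 * L)) / (61 / (122 - 59 * L))),
    on_l50_dark_gray = mean((2 / (4 + 118 * L)) / (61 / (122 + 59 * L))),
    off_rmax_light_gray = mean(118 * (61 - 59 * L) / (59 * (120 - 118 * L))),
    on_rmax_dark_gray = mean(118 * (61 + 59 * L) / (59 * (2 + 118 * L))))

  tab <- population_sweep(pixels_per_sigma_c = 16)
  got <- summarize_background_ratios(tab)
  expect_equal(got, oracle, tolerance = 0.02)

  # and the OFF/ON contrast ratio range against its disk-mass form
  Ld <- ref_disk_mass(sigma_n)
  expect_equal(max(tab$offon_ratio_100), max((1 + Ld) / (1 - Ld)),
               tolerance = 0.02)
  expect_equal(min(tab$offon_ratio_100), min((1 + Ld) / (1 - Ld)),
               tolerance = 0.02)

  # aggregator choice matters and is honored
  med <- summarize_background_ratios(tab, stats::median)
  expect_false(isTRUE(all.equal(got[["on_rmax_dark_gray"]],
                                med[["on_rmax_dark_gray"]])))
})
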