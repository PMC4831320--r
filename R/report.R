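#' Run configuration for report generation
#'
#' A run is a pure function of its configuration: every computation in the
#' package is deterministic (no random number is drawn anywhere), so
#' repeated runs with the same config produce identical outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param resolution lattice resolution, pixels per sigma_c.
#' @param sigma_s_ratios,sigma_n_ratios model-family scale factors.
#' @param step_pct contrast step (percent) for contrast sweeps.
#' @param n_targets luminance samples per background.
#' @param crf_background background for the contrast sweeps.
#' @param aggregator `"mean"` or `"median"` for population ratios.
#' @param cone_adapt_levels adaptation constants `I_a` for the cone
#'   curves; the contrast-domain output is identical for each, which the
#'   emitted files demonstrate.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = ".", resolution = 16,
                       sigma_s_ratios = c(1.25, 1.5, 2, 3, 4, 6),
                       sigma_n_ratios = c(1, 1.25, 1.5, 2, 3, 4, 6),
                       step_pct = 1, n_targets = 60, crf_background = 50,
                       aggregator = c("mean", "median"),
                       cone_adapt_levels = c(10, 100)) {
  aggregator <- match.arg(aggregator)
  cfg <- list(out_dir = out_dir, resolution = resolution,
              sigma_s_ratios = sigma_s_ratios,
              sigma_n_ratios = sigma_n_ratios,
              step_pct = step_pct, n_targets = n_targets,
              crf_background = crf_background, aggregator = aggregator,
              cone_adapt_levels = cone_adapt_levels)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param config a configuration list to validate / read / write.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  need <- c("out_dir", "resolution", "sigma_s_ratios", "sigma_n_ratios",
            "step_pct", "n_targets", "crf_background", "aggregator",
            "cone_adapt_levels")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!config$aggregator %in% c("mean", "median"))
    stop("aggregator must be 'mean' or 'median'", call. = FALSE)
  stopifnot(config$resolution >= 1, config$step_pct > 0,
            config$n_targets >= 10, config$crf_background > 0)
  structure(config[need], class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

.out_path <- function(config, ...) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir, ...)
}

.config_units <- function(config) {
  canonical_units(config$sigma_s_ratios, config$sigma_n_ratios)
}

.config_aggregator <- function(config) {
  switch(config$aggregator, mean = mean, median = stats::median)
}

#' Generate the contrast-sweep report
#'
#' Writes `crf_curves.csv` (one row per unit and contrast, columns
#' `sigma_s_ratio`, `sigma_n_ratio`, `contrast`, `on`, `off`) and
#' `offon_ratios.csv` (per-unit OFF/ON ratio at 100% contrast, with the
#' near-degenerate annotation), plus `failures_crf.csv` listing any units
#' whose responses were degenerate.  An empty unit grid yields empty
#' tables and a warning, not an error.
#'
#' @param config a [run_config()].
#' @return Invisibly, a named character vector of the files written.
#' @export
run_crf_sweep <- function(config) {
  config <- validate_run_config(config)
  units <- .config_units(config)
  ratios <- attr(units, "ratios")
  if (length(units) == 0L)
    warning("empty unit grid: writing empty tables")
  curves <- list()
  ratio_rows <- list()
  failures <- list()
  for (i in seq_along(units)) {
    unit <- units[[i]]
    res <- tryCatch({
      grid <- encoder_grid(unit, config$resolution)
      crf <- compute_crf(unit, config$crf_background, config$step_pct,
                         grid = grid)
      m <- .rasterized_AL(unit, grid, "disk")
      list(crf = crf, ratio = offon_ratio_at_max(
             unit, config$crf_background, grid = grid),
           near_degenerate = (1 - m$L) < 0.15)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        sigma_s_ratio = ratios$sigma_s_ratio[i],
        sigma_n_ratio = ratios$sigma_n_ratio[i],
        message = conditionMessage(res))
      next
    }
    curves[[length(curves) + 1L]] <- data.frame(
      sigma_s_ratio = ratios$sigma_s_ratio[i],
      sigma_n_ratio = ratios$sigma_n_ratio[i],
      contrast = res$crf$contrast, on = res$crf$on, off = res$crf$off)
    ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
      sigma_s_ratio = ratios$sigma_s_ratio[i],
      sigma_n_ratio = ratios$sigma_n_ratio[i],
      offon_ratio_100 = res$ratio,
      near_degenerate = res$near_degenerate)
  }
  empty_fail <- data.frame(sigma_s_ratio = numeric(),
                           sigma_n_ratio = numeric(), message = character())
  files <- c(curves = .out_path(config, "crf_curves.csv"),
             ratios = .out_path(config, "offon_ratios.csv"),
             failures = .out_path(config, "failures_crf.csv"))
  write.csv(if (length(curves)) do.call(rbind, curves) else
              data.frame(sigma_s_ratio = numeric(), sigma_n_ratio = numeric(),
                         contrast = numeric(), on = numeric(),
                         off = numeric()),
            files[["curves"]], row.names = FALSE)
  write.csv(if (length(ratio_rows)) do.call(rbind, ratio_rows) else
              data.frame(sigma_s_ratio = numeric(), sigma_n_ratio = numeric(),
                         offon_ratio_100 = numeric(),
                         near_degenerate = logical()),
            files[["ratios"]], row.names = FALSE)
  write.csv(if (length(failures)) do.call(rbind, failures) else empty_fail,
            files[["failures"]], row.names = FALSE)
  invisible(files)
}

#' Generate the luminance-sweep report
#'
#' Writes `luminance_curves.csv` (per unit, background, polarity and
#' target), `population_table.csv` (the full [population_sweep()] table)
#' and `population_ratios.json` holding exactly the four cross-background
#' population ratios.
#'
#' @param config a [run_config()].
#' @return Invisibly, a named character vector of the files written.
#' @export
run_luminance_sweep <- function(config) {
  config <- validate_run_config(config)
  tab <- population_sweep(config$sigma_s_ratios, config$sigma_n_ratios,
                          pixels_per_sigma_c = config$resolution,
                          step_pct = config$step_pct,
                          n_targets = config$n_targets,
                          crf_background = config$crf_background)
  ratios <- summarize_background_ratios(tab, .config_aggregator(config))
  units <- .config_units(config)
  fam <- attr(units, "ratios")
  curves <- list()
  conds <- list(list(bg = 120, pol = "off"), list(bg = 61, pol = "off"),
                list(bg = 2, pol = "on"), list(bg = 61, pol = "on"))
  for (i in seq_along(units)) {
    grid <- encoder_grid(units[[i]], config$resolution)
    for (cond in conds) {
      lrf <- tryCatch(compute_luminance_response(
        units[[i]], cond$bg, cond$pol, n_targets = config$n_targets,
        grid = grid), error = function(e) NULL)
      if (is.null(lrf)) next
      curves[[length(curves) + 1L]] <- data.frame(
        sigma_s_ratio = fam$sigma_s_ratio[i],
        sigma_n_ratio = fam$sigma_n_ratio[i],
        background = cond$bg, polarity = cond$pol,
        target = lrf$target, response = lrf$response)
    }
  }
  files <- c(curves = .out_path(config, "luminance_curves.csv"),
             table = .out_path(config, "population_table.csv"),
             ratios = .out_path(config, "population_ratios.json"))
  write.csv(do.call(rbind, curves), files[["curves"]], row.names = FALSE)
  write.csv(as.data.frame(tab), files[["table"]], row.names = FALSE)
  jsonlite::write_json(as.list(ratios), files[["ratios"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Generate the cone-adaptation report
#'
#' Writes one contrast-domain CSV per adaptation level
#' (`cone_curves_Ia<level>.csv`).  Because the adaptation model is scale
#' invariant, the files differ only in name -- their contents are
#' byte-identical, which doubles as a built-in check.
#'
#' @param config a [run_config()].
#' @return Invisibly, the character vector of files written.
#' @export
run_cone_curves <- function(config) {
  config <- validate_run_config(config)
  files <- character(0)
  for (ia in config$cone_adapt_levels) {
    cc <- polarization_vs_contrast(I_a = ia, step_pct = config$step_pct)
    f <- .out_path(config, sprintf("cone_curves_Ia%g.csv", ia))
    write.csv(as.data.frame(cc), f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' @rdname run_crf_sweep
#' @export
run_all_reports <- function(config) {
  config <- validate_run_config(config)
  invisible(c(run_crf_sweep(config), run_luminance_sweep(config),
              run_cone_curves(config)))
}
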