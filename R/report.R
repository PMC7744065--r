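#' Run one simulation end to end and write an artifact bundle
#'
#' Simulates the chosen model on a grid, extracts and fits the decision
#' front, classifies the pattern, and writes a self-describing bundle into
#' `outdir`: the surface as long-format and matrix CSV, the front as CSV
#' and JSON (slope, intercept, residual, pattern), the classification as
#' JSON, an optional heatmap with the front overlaid (requires ggplot2),
#' and a `config.json` echoing the full configuration, package version and
#' seed so the numeric outputs can be regenerated byte-identically.
#'
#' @param model one of `"transporter"`, `"transcription"`, `"combined"`,
#'   `"motif"`
#' @param preset preset name (see [list_presets()]; for `"combined"` a name
#'   from [combined_presets()]; ignored when `params` is given)
#' @param params optional parameter object matching `model`
#'   (a [transporter_params()], [transcription_params()],
#'   [combined_params()] or [motif_config()])
#' @param grid optional [titration_grid()]; defaults to the preset's grid
#'   or [make_log_grid()]
#' @param level front level
#' @param noise optional list with fields `cv` and `seed` for
#'   [add_measurement_noise()]
#' @param outdir output directory (created if missing)
#' @param seed integer recorded in the provenance log and used for noise
#'   when `noise$seed` is absent
#' @param plot write `heatmap.png` when ggplot2 is installed
#' @return invisibly, a list with the surface, front, fit and
#'   classification
#' @export
run_simulation <- function(model = c("transporter", "transcription",
                                     "combined", "motif"),
                           preset = NULL, params = NULL, grid = NULL,
                           level = 0.5, noise = NULL, outdir, seed = 1L,
                           plot = FALSE) {
  model <- match.arg(model)
  if (is.null(params)) {
    if (is.null(preset))
      stopf("supply a 'preset' name or a 'params' object; available presets: %s",
            paste(list_presets(), collapse = ", "))
    if (model == "combined") {
      all8 <- combined_presets()
      if (!preset %in% names(all8))
        stopf("unknown combined preset '%s'; available: %s", preset,
              paste(names(all8), collapse = ", "))
      entry <- all8[[preset]]
      params <- entry$combined
      if (is.null(grid)) grid <- entry$grid
    } else {
      entry <- load_preset(preset)
      if (entry$model != model)
        stopf("preset '%s' is a %s preset, not %s", preset, entry$model, model)
      params <- entry$params
      if (is.null(grid)) grid <- entry$grid
    }
  }
  if (is.null(grid)) grid <- make_log_grid()
  surf <- switch(model,
    transporter = simulate_transporter_grid(grid, params),
    transcription = simulate_transcription_grid(grid, params),
    combined = simulate_combined_grid(grid, params),
    motif = simulate_motif_grid(grid, params))
  if (!is.null(noise))
    surf <- add_measurement_noise(surf, noise$cv,
                                  if (is.null(noise$seed)) seed else noise$seed)
  front <- extract_decision_front(surf, level)
  fit <- if (nrow(front) >= 4L) fit_front(front) else NULL
  cls <- classify_pattern(surf, level)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_surface_csv(surf, file.path(outdir, "surface.csv"), "long")
  write_surface_csv(surf, file.path(outdir, "surface_matrix.csv"), "matrix")
  utils::write.csv(cbind(level = level, front),
                   file.path(outdir, "front.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(level = level, slope = fit$slope, intercept = fit$intercept,
         residual = fit$residual, vertical = fit$vertical,
         pattern = cls$pattern),
    file.path(outdir, "front.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(pattern = cls$pattern,
         segments = cls$segments, local_slopes = cls$local_slopes),
    file.path(outdir, "classification.json"), auto_unbox = TRUE, digits = NA)
  cfg_echo <- list(model = model, preset = preset, level = level,
                   noise = noise, seed = seed,
                   grid = list(gal = grid$gal, gluc = grid$gluc),
                   params = unclass_params(params),
                   package = "ratiosense",
                   version = as.character(utils::packageVersion("ratiosense")))
  jsonlite::write_json(cfg_echo, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("ratiosense %s | model=%s preset=%s seed=%d | config md5=%s",
                     cfg_echo$version, model, preset %||% "<custom>", seed,
                     unname(tools::md5sum(file.path(outdir, "config.json")))),
             file.path(outdir, "run.log"))
  if (plot && requireNamespace("ggplot2", quietly = TRUE))
    write_heatmap(surf, front, file.path(outdir, "heatmap.png"))
  invisible(list(surface = surf, front = front, fit = fit,
                 classification = cls, outdir = outdir))
}

unclass_params <- function(p) {
  if (inherits(p, "combined_params"))
    list(transporter = unclass(p$transporter),
         transcription = unclass(p$transcription))
  else if (inherits(p, "motif_config"))
    list(activator_state = p$activator_state,
         repressor_state = p$repressor_state,
         A0 = p$A0, R0 = p$R0, Kx = p$Kx, Ky = p$Ky,
         base = unclass(p$base))
  else unclass(p)
}

# induction heatmap with the decision front overlaid; color scale fixed to
# [0, 1] normalized induction for cross-run comparability
write_heatmap <- function(surface, front, path) {
  d <- as.data.frame(surface)
  gg <- ggplot2::ggplot(d, ggplot2::aes(log10(.data$gal), log10(.data$gluc))) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$induction)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::geom_path(data = front,
                       ggplot2::aes(.data$log_gal, .data$log_gluc),
                       colour = "white", linewidth = 0.8) +
    ggplot2::labs(x = "log10 galactose (a.u.)", y = "log10 glucose (a.u.)",
                  fill = "induction")
  grDevices::png(path, width = 1200, height = 1000, res = 150)
  print(gg)
  grDevices::dev.off()
  invisible(path)
}

#' Re-run the package's analytic benchmark checks
#'
#' Recomputes, at desk scale, the analytic predictions the models make --
#' the slope-1 front of the basic transcriptional unit, the slope-2 fronts
#' of negative auto-regulation at the repressor and of the
#' activator-inhibits-repressor coherent FFL, the slope-1/2 fronts of
#' negative auto-regulation at the activator and of the
#' repressor-inhibits-activator coherent FFL, the 25-configuration
#' enumeration, the (6, 13, 6) census partition, and full-range ratio
#' sensing of all eight concatenated preset pairs -- and tabulates
#' expected against observed. Failures are recorded, not raised.
#'
#' @param grid titration grid used for the front fits
#' @return data.frame with columns `check`, `expected`, `observed`,
#'   `pass`
#' @export
reproduce_paper_checks <- function(grid = make_log_grid()) {
  rows <- list()
  add <- function(check, expected, observed, tol) {
    pass <- if (is.na(observed)) FALSE else abs(observed - expected) <= tol
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, expected = expected, observed = observed, pass = pass)
  }
  fit_slope <- function(cfg) {
    surf <- simulate_motif_grid(grid, cfg)
    f <- classify_pattern(surf)  # reuse extraction; fit on the front
    if (is.null(f$front) || nrow(f$front) < 4L) return(NA_real_)
    fit_front(f$front)$slope
  }
  presets <- motif_census_presets(grid)
  add("basic unit front slope", 1,
      fit_slope(presets[["none.none"]]), 0.05)
  add("negative auto-regulation at repressor: slope", 2,
      fit_slope(presets[["none.negative_auto"]]), 0.1)
  add("activator inhibits repressor (coherent FFL): slope", 2,
      fit_slope(presets[["none.coherent_ffl_edge"]]), 0.1)
  add("negative auto-regulation at activator: slope", 0.5,
      fit_slope(presets[["negative_auto.none"]]), 0.05)
  add("repressor inhibits activator (coherent FFL): slope", 0.5,
      fit_slope(presets[["coherent_ffl_edge.none"]]), 0.05)
  add("configuration count", 25, nrow(enumerate_configurations()), 0)
  census <- census_slope_multipliers(presets, grid)
  counts <- attr(census, "counts")
  add("census: slope-halving configurations", 6, counts[["half"]], 0)
  add("census: slope-doubling configurations", 6, counts[["double"]], 0)
  combos <- combined_presets()
  n_ratio <- sum(vapply(combos, function(cb) {
    cls <- classify_pattern(simulate_combined_grid(cb$grid, cb$combined))
    cls$pattern == "ratio"
  }, logical(1)))
  add("concatenated pairs classified ratiometric", 8, n_ratio, 0)
  do.call(rbind, rows)
}
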