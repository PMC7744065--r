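#' Named parameter presets
#'
#' The package ships one preset per canonical regime of each layer:
#' two uptake-layer presets (`uptake_full_ratio` with the glucose binding
#' coefficient far below the titration window, `uptake_compound` with it
#' inside the window) and four transcription-layer presets
#' (`txn_full_ratio` satisfying all ratio-sensing inequalities at >= 100x
#' margins, and one preset deliberately violating each inequality:
#' `txn_activator_saturated`, `txn_weak_repression`,
#' `txn_repressor_saturated`). Presets are stored as YAML files under
#' `inst/extdata/presets` and validated against their declared regime on
#' load: a preset whose parameters no longer satisfy (or violate) what the
#' file declares is a load-time error.
#'
#' @param name preset name; `list_presets()` returns the available names
#' @return `load_preset()` returns a list with fields `name`, `model`,
#'   `description`, `params` (a [transporter_params()] or
#'   [transcription_params()]), `grid` (a [titration_grid()]),
#'   `expected_pattern` and the declared regime metadata.
#'   `fixture_presets()` returns the named list of all presets.
#' @export
load_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "ratiosense")
  if (path == "")
    stopf("unknown preset '%s'; available: %s", name,
          paste(list_presets(), collapse = ", "))
  spec <- yaml::read_yaml(path)
  g <- spec$grid
  grid <- make_log_grid(g$gal_min, g$gal_max, g$gluc_min, g$gluc_max,
                        g$n_per_axis)
  params <- switch(spec$model,
    transporter = do.call(transporter_params_from_K, spec$params),
    transcription = do.call(transcription_params, spec$params),
    stopf("preset '%s' has unknown model '%s'", name, spec$model))
  validate_preset_regime(spec, params, grid)
  list(name = spec$name, model = spec$model, description = spec$description,
       params = params, grid = grid,
       expected_pattern = spec$expected_pattern,
       expected_segment_classes = unlist(spec$expected_segment_classes),
       satisfies = unlist(spec$satisfies), violates = unlist(spec$violates))
}

#' @rdname load_preset
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "ratiosense")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' @rdname load_preset
#' @export
fixture_presets <- function() {
  nms <- list_presets()
  stats::setNames(lapply(nms, load_preset), nms)
}

# load-time check that a preset still matches its declared regime
validate_preset_regime <- function(spec, params, grid, factor = 100) {
  if (spec$model == "transcription") {
    rep <- check_ratio_regime(params, grid$gal, grid$gluc, factor = factor)
    flags <- c(galin_ll_KG = rep$galin_ll_KG,
               glucin_gg_KMoverPhiR = rep$glucin_gg_KMoverPhiR,
               glucin_ll_KM = rep$glucin_ll_KM)
    for (nm in unlist(spec$satisfies))
      if (!isTRUE(flags[[nm]]))
        stopf("preset '%s' declares '%s' satisfied but it is not (margin %.3g)",
              spec$name, nm, rep$margins[[nm]])
    for (nm in unlist(spec$violates))
      if (isTRUE(flags[[nm]]))
        stopf("preset '%s' declares '%s' violated but it holds (margin %.3g)",
              spec$name, nm, rep$margins[[nm]])
  } else if (spec$model == "transporter") {
    saturated <- params$K_gluc * factor <= min(grid$gluc)
    if (identical(spec$regime, "full_range_ratio") && !saturated)
      stopf("preset '%s' declares full-range ratio sensing but K_gluc (%.3g) is not << the glucose window",
            spec$name, params$K_gluc)
    inside <- params$K_gluc > min(grid$gluc) && params$K_gluc < max(grid$gluc)
    if (identical(spec$regime, "compound") && !inside)
      stopf("preset '%s' declares a compound regime but K_gluc (%.3g) is outside the glucose window",
            spec$name, params$K_gluc)
  }
  invisible(TRUE)
}

#' The eight concatenated preset combinations
#'
#' Pairs each uptake-layer preset with each transcription-layer preset
#' (2 x 4 design) and applies [scale_for_combination()] so every pair
#' satisfies the combined-model ratio-sensing conditions; the rescaling
#' factors are recorded in each element. All eight combinations are
#' expected to classify as full-range ratio sensing even where one layer
#' alone is compound.
#'
#' @param factor the ">>" margin used by the scaling rule
#' @return named list of 8 entries, each with `combined`
#'   (a [combined_params()]), `grid`, the member preset names and the
#'   applied `scale_KGKM` / `scale_phi` factors
#' @export
combined_presets <- function(factor = 100) {
  uptake_names <- c("uptake_full_ratio", "uptake_compound")
  txn_names <- c("txn_full_ratio", "txn_activator_saturated",
                 "txn_weak_repression", "txn_repressor_saturated")
  out <- list()
  for (un in uptake_names) {
    up <- load_preset(un)
    for (xn in txn_names) {
      tx <- load_preset(xn)
      scaled <- scale_for_combination(tx$params, up$params, up$grid,
                                      factor = factor)
      key <- paste(un, xn, sep = ".")
      out[[key]] <- list(
        combined = combined_params(up$params, scaled),
        grid = up$grid, uptake_preset = un, transcription_preset = xn,
        scale_KGKM = scaled$K_G / tx$params$K_G,
        scale_phi = scaled$phiR / tx$params$phiR)
    }
  }
  out
}
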