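#' Parameters of the concatenated two-layer model
#'
#' Chains the communal-transporter uptake layer into the transcriptional
#' competition layer: intracellular sugars computed by
#' [transporter_steady_state()] become the inputs of [active_fraction()].
#'
#' @param transporter a [transporter_params()]
#' @param transcription a [transcription_params()]
#' @return an object of class `"combined_params"`
#' @export
combined_params <- function(transporter, transcription) {
  if (!inherits(transporter, "transporter_params"))
    stopf("'transporter' must be a transporter_params object")
  if (!inherits(transcription, "transcription_params"))
    stopf("'transcription' must be a transcription_params object")
  structure(list(transporter = transporter, transcription = transcription,
                 psi = transporter$psi),
            class = "combined_params")
}

#' @export
print.combined_params <- function(x, ...) {
  cat("<combined_params>\n  uptake: "); print(x$transporter)
  cat("  transcription: "); print(x$transcription)
  invisible(x)
}

#' Induction of the concatenated model
#'
#' Active GAL1 fraction at given external sugar concentrations: the
#' uptake steady state feeds the CRE occupancy closed form. Vectorized.
#'
#' @param gal_ex,gluc_ex external sugar concentrations (a.u., >= 0)
#' @param p a [combined_params()]
#' @return fraction(s) in [0, 1]
#' @export
concatenated_response <- function(gal_ex, gluc_ex, p) {
  inner <- transporter_steady_state(gal_ex, gluc_ex, p$transporter)
  active_fraction(inner$gal_in, inner$gluc_in, p$transcription)
}

#' Sufficient conditions for ratio-sensing in the combined model
#'
#' With the uptake layer substituted into the transcriptional regime
#' inequalities, the combined system is ratiometric whenever
#' `K_G >> psi`, `K_M >> psi` and the repression capacity `phiR` is large
#' enough that `K_M / (psi * phiR)` sits far below the smallest
#' transporter-saturation fraction reached on the working grid (both
#' saturation fractions are bounded by 1, which is what makes the pooled
#' conditions sufficient).
#'
#' @param p a [combined_params()]
#' @param grid optional [titration_grid()] of external sugars used to
#'   evaluate the minimal glucose saturation fraction; defaults to the
#'   loosest bound (the fraction's theoretical maximum, 1)
#' @param factor the ">>" factor, default 100
#' @return list with the numeric ratios `KG_over_psi`, `KM_over_psi`,
#'   `phiR`, `u_gluc_min`, per-condition booleans and overall `satisfied`
#' @export
check_combined_conditions <- function(p, grid = NULL, factor = 100) {
  tp <- p$transporter; xp <- p$transcription
  u_gluc_min <- 1
  if (!is.null(grid)) {
    ss <- transporter_steady_state(max(grid$gal), min(grid$gluc), tp)
    u_gluc_min <- ss$gluc_in / tp$psi
  }
  kg <- xp$K_G / tp$psi
  km <- xp$K_M / tp$psi
  repression_margin <- u_gluc_min / (xp$K_M / (tp$psi * xp$phiR))
  ok <- c(KG_gg_psi = kg >= factor,
          KM_gg_psi = km >= factor,
          phiR_large = repression_margin >= factor)
  if (!all(ok))
    warning("combined-model ratio-sensing conditions not satisfied: ",
            paste(names(ok)[!ok], collapse = ", "), call. = FALSE)
  list(KG_over_psi = kg, KM_over_psi = km, phiR = xp$phiR,
       u_gluc_min = u_gluc_min, repression_margin = repression_margin,
       conditions = ok, factor = factor, satisfied = all(ok))
}

#' Simulate the concatenated model on a titration grid
#'
#' @param grid a [titration_grid()] of external sugar concentrations
#' @param p a [combined_params()]
#' @param normalize normalize to the maximal-induction corner (default)
#' @return a [response_surface()]
#' @export
simulate_combined_grid <- function(grid, p, normalize = TRUE) {
  uptake <- function(gal, gluc) transporter_steady_state(gal, gluc, p$transporter)
  simulate_transcription_grid(grid, p$transcription, uptake = uptake,
                              normalize = normalize)
}

#' Rescale a transcription layer to sit downstream of an uptake layer
#'
#' The stand-alone transcription presets are tuned for intracellular
#' inputs spanning the default grid; downstream of a transporter layer the
#' inputs are capped at `psi` and the ratio-sensing conditions become
#' `K_G >> psi`, `K_M >> psi` with large `phiR`. This helper applies the
#' documented co-scaling rule: multiply `K_G` and `K_M` by a common factor
#' until both clear `factor * psi`, then multiply `phiA` and `phiR` by a
#' second common factor until the repression-capacity condition clears
#' `factor` as well. Both rescalings leave the front position
#' `(phiA/phiR) * (K_M/K_G)` unchanged.
#'
#' @param transcription a [transcription_params()]
#' @param transporter a [transporter_params()]
#' @param grid the external-sugar grid the combination will run on
#' @param factor the ">>" margin, default 100
#' @return a rescaled [transcription_params()]
#' @export
scale_for_combination <- function(transcription, transporter, grid,
                                  factor = 100) {
  xp <- transcription; tp <- transporter
  s1 <- max(1, factor * tp$psi / xp$K_G, factor * tp$psi / xp$K_M)
  K_G <- xp$K_G * s1; K_M <- xp$K_M * s1
  ss <- transporter_steady_state(max(grid$gal), min(grid$gluc), tp)
  u_gluc_min <- ss$gluc_in / tp$psi
  s2 <- max(1, factor * K_M / (tp$psi * xp$phiR * u_gluc_min))
  transcription_params(K_G = K_G, K_M = K_M, K_A = xp$K_A, K_R = xp$K_R,
                       phiA = xp$phiA * s2, phiR = xp$phiR * s2,
                       GAL1_total = xp$GAL1_total)
}
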