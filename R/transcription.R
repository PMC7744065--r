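#' Parameters of the transcriptional signal-integration layer
#'
#' Intracellular galactose binds an internal sensor to form the active
#' activator (Gal3p-like); intracellular glucose forms the active
#' repressor (Mig1-like). Activator and repressor then compete for the
#' cis-regulatory element (CRE) of GAL1. Sensor binding constants
#' `K_G = krG/kfG` and `K_M = krM/kfM` (a.u.), CRE dissociation constants
#' `K_A = krA/kfA` and `K_R = krR/kfR` (a.u.), and regulator pools give
#' the activation and repression capacities
#' `phiA = Activator_total / K_A`, `phiR = Repressor_total / K_R`.
#'
#' Pools may be given either directly (`Activator_total`,
#' `Repressor_total`) or through the capacities (`phiA`, `phiR`).
#' Association rates `kfG`, `kfM`, `kfA`, `kfR` default to 1 (with the
#' dissociation rates implied by the binding constants); they only matter
#' for the dynamic mass-action oracle, not for the quasi-equilibrium
#' closed forms.
#'
#' @param K_G,K_M sensor binding constants for galactose and glucose (a.u.)
#' @param K_A,K_R CRE dissociation constants of activator and repressor (a.u.)
#' @param Activator_total,Repressor_total total sensor pools (a.u.)
#' @param phiA,phiR alternative specification of the pools as capacities
#' @param GAL1_total gene copy number (count)
#' @param kfG,kfM,kfA,kfR association rates for the dynamic oracle
#' @return an object of class `"transcription_params"` with derived
#'   `phiA`, `phiR` and all dissociation rates
#' @examples
#' p <- transcription_params(K_G = 1e6, K_M = 1e5, phiA = 1e13, phiR = 1e12)
#' p$Activator_total  # phiA * K_A = 1e13
#' @export
transcription_params <- function(K_G, K_M, K_A = 1, K_R = 1,
                                 Activator_total = NULL, Repressor_total = NULL,
                                 phiA = NULL, phiR = NULL, GAL1_total = 1,
                                 kfG = 1, kfM = 1, kfA = 1, kfR = 1) {
  for (nm in c("K_G", "K_M", "K_A", "K_R", "GAL1_total",
               "kfG", "kfM", "kfA", "kfR"))
    check_positive(get(nm), nm)
  if (is.null(Activator_total)) {
    if (is.null(phiA)) stopf("supply either 'Activator_total' or 'phiA'")
    Activator_total <- phiA * K_A
  }
  if (is.null(Repressor_total)) {
    if (is.null(phiR)) stopf("supply either 'Repressor_total' or 'phiR'")
    Repressor_total <- phiR * K_R
  }
  check_positive(Activator_total, "Activator_total")
  check_positive(Repressor_total, "Repressor_total")
  p <- list(K_G = K_G, K_M = K_M, K_A = K_A, K_R = K_R,
            Activator_total = Activator_total,
            Repressor_total = Repressor_total,
            GAL1_total = GAL1_total,
            kfG = kfG, krG = kfG * K_G, kfM = kfM, krM = kfM * K_M,
            kfA = kfA, krA = kfA * K_A, kfR = kfR, krR = kfR * K_R)
  p$phiA <- Activator_total / K_A
  p$phiR <- Repressor_total / K_R
  structure(p, class = "transcription_params")
}

#' @export
print.transcription_params <- function(x, ...) {
  cat(sprintf(
    "<transcription_params> K_G=%.3g K_M=%.3g K_A=%.3g K_R=%.3g phiA=%.3g phiR=%.3g\n",
    x$K_G, x$K_M, x$K_A, x$K_R, x$phiA, x$phiR))
  invisible(x)
}

#' Quasi-equilibrium active regulator levels
#'
#' Sugar-sensor binding is fast relative to transcription, so the active
#' regulator pools follow the instantaneous hyperbolic saturation of their
#' sugar: `Activator* = gal_in / (K_G + gal_in) * Activator_total`, and
#' the mirror for the repressor. Vectorized.
#'
#' @param gal_in,gluc_in intracellular sugar concentrations (a.u., >= 0)
#' @param p a [transcription_params()]
#' @return active regulator concentration(s), in `[0, pool total]`
#' @examples
#' p <- transcription_params(K_G = 10, K_M = 3, Activator_total = 40,
#'                           Repressor_total = 8)
#' activator_equilibrium(30, p)  # 3 K_G -> 3/4 saturation: 30
#' repressor_equilibrium(1, p)   # K_M/3 -> 1/4 saturation: 2
#' @export
activator_equilibrium <- function(gal_in, p) {
  check_nonneg(gal_in, "gal_in")
  gal_in / (p$K_G + gal_in) * p$Activator_total
}

#' @rdname activator_equilibrium
#' @export
repressor_equilibrium <- function(gluc_in, p) {
  check_nonneg(gluc_in, "gluc_in")
  gluc_in / (p$K_M + gluc_in) * p$Repressor_total
}

#' Actively transcribed GAL1 fraction
#'
#' Closed-form CRE occupancy under competitive activator/repressor
#' binding at quasi-equilibrium:
#' `1 / (1 + (1/phiA) * (K_G/gal_in + 1) * (1 + phiR / (K_M/gluc_in + 1)))`.
#' `gal_in = 0` gives 0 (no activator, nothing transcribed). Vectorized.
#'
#' @inheritParams activator_equilibrium
#' @return fraction(s) in [0, 1]
#' @export
active_fraction <- function(gal_in, gluc_in, p) {
  check_nonneg(gal_in, "gal_in"); check_nonneg(gluc_in, "gluc_in")
  a_occ <- gal_in / (p$K_G + gal_in)    # activator saturation
  r_occ <- gluc_in / (p$K_M + gluc_in)  # repressor saturation
  frac <- 1 / (1 + (1 / (p$phiA * a_occ)) * (1 + p$phiR * r_occ))
  ifelse(a_occ > 0, frac, 0)
}

#' Steady state of the transcription layer by ODE integration
#'
#' Integrates the full mass-action system -- sensor binding plus CRE
#' association/dissociation, with GAL1 copy conservation -- to steady
#' state. The independent dynamic oracle for [active_fraction()].
#'
#' @inheritParams activator_equilibrium
#' @param tol steady-state criterion on the relative derivative norm
#' @param t_chunk integration horizon per attempt
#' @param max_chunks maximum number of horizons
#' @return list with `active_fraction`, and the final `state` vector
#'   (`Activator_star`, `Repressor_star`, `GAL1_active`, `GAL1_repressed`)
#' @export
integrate_transcription <- function(gal_in, gluc_in, p, tol = 1e-9,
                                    t_chunk = NULL, max_chunks = 60) {
  check_nonneg(gal_in, "gal_in"); check_nonneg(gluc_in, "gluc_in")
  Astar_eq <- activator_equilibrium(gal_in, p)
  Rstar_eq <- repressor_equilibrium(gluc_in, p)
  rhs <- function(t, y, parms) {
    free <- p$GAL1_total - y["GAL1_active"] - y["GAL1_repressed"]
    list(c(
      Activator_star = p$kfG * gal_in * (p$Activator_total - y["Activator_star"]) -
        p$krG * y["Activator_star"],
      Repressor_star = p$kfM * gluc_in * (p$Repressor_total - y["Repressor_star"]) -
        p$krM * y["Repressor_star"],
      GAL1_active = p$kfA * free * y["Activator_star"] - p$krA * y["GAL1_active"],
      GAL1_repressed = p$kfR * free * y["Repressor_star"] - p$krR * y["GAL1_repressed"]
    ))
  }
  # the slow CRE partition mode (active <-> repressed through a depleted
  # free pool) relaxes no slower than min(krA, krR), so the bare
  # dissociation rates belong in the time-scale floor
  rates <- c(p$kfG * gal_in + p$krG, p$kfM * gluc_in + p$krM,
             p$krA, p$krR)
  if (is.null(t_chunk)) t_chunk <- 20 / min(rates[rates > 0])
  y <- c(Activator_star = 0, Repressor_star = 0,
         GAL1_active = 0, GAL1_repressed = 0)
  scale <- max(p$Activator_total, p$Repressor_total, p$GAL1_total)
  atol <- 1e-13 * scale
  for (i in seq_len(max_chunks)) {
    y_prev <- y
    out <- deSolve::lsoda(y, c(0, t_chunk), rhs, parms = NULL,
                          rtol = 1e-11, atol = atol, maxsteps = 1e5)
    y <- out[nrow(out), -1L]
    d <- unlist(rhs(0, y, NULL))
    # steady when the derivative vanishes, or (where flux cancellation
    # noise floors the derivative) the state stops moving over a chunk
    # spanning >= 20 slow relaxation times
    if (max(abs(d) / (abs(y) + atol)) < tol ||
        max(abs(y - y_prev) / (abs(y) + atol)) < tol)
      return(list(active_fraction = unname(y["GAL1_active"]) / p$GAL1_total,
                  state = y))
    t_chunk <- t_chunk * 1.5   # stretch the horizon for lingering slow modes
  }
  stopf("transcription ODE did not reach steady state within %d horizons",
        max_chunks)
}

#' Analytic decision front of the transcription layer
#'
#' In the ratio-sensing regime (`gal_in << K_G` and
#' `K_M/phiR << gluc_in << K_M`) the iso-induction contour in
#' (log10 gal_in, log10 gluc_in) space is a straight line of slope exactly
#' 1 with intercept `log10(K_M/K_G) + log10(phiA/phiR) + log10(1/level - 1)`.
#'
#' @param p a [transcription_params()]
#' @param level contour level, strictly in (0, 1)
#' @return list with `slope` (always 1), `intercept`, `level`, `regime`
#' @export
transcription_front_analytic <- function(p, level = 0.5) {
  check_level(level)
  list(slope = 1,
       intercept = log10(p$K_M / p$K_G) + log10(p$phiA / p$phiR) +
         log10(1 / level - 1),
       level = level,
       regime = "valid where gal_in << K_G and K_M/phiR << gluc_in << K_M")
}

#' Check the ratio-sensing regime inequalities
#'
#' The transcription layer is ratiometric when, over the working range of
#' intracellular sugars, `gal_in << K_G` and `K_M/phiR << gluc_in << K_M`
#' hold simultaneously. "Much smaller" is operationalized as a
#' configurable multiplicative `factor` (default 100). The report carries
#' the numeric margins so the factor can be tightened downstream, plus the
#' compound pattern predicted when a given inequality fails.
#'
#' @param p a [transcription_params()]
#' @param gal_in,gluc_in numeric ranges (vectors; extremes are used) of
#'   intracellular sugar levels the layer will see
#' @param factor the "<<" factor; `a << b` is taken as `a * factor <= b`
#' @return an object of class `"regime_report"`: booleans
#'   `galin_ll_KG`, `glucin_gg_KMoverPhiR`, `glucin_ll_KM`, their numeric
#'   margins, the factor, and a `predicted_pattern` string
#' @export
check_ratio_regime <- function(p, gal_in, gluc_in, factor = 100) {
  check_nonneg(gal_in, "gal_in"); check_nonneg(gluc_in, "gluc_in")
  check_positive(factor, "factor")
  m1 <- p$K_G / max(gal_in)                 # want >> 1
  m2 <- min(gluc_in) / (p$K_M / p$phiR)     # want >> 1
  m3 <- p$K_M / max(gluc_in)                # want >> 1
  ok <- c(galin_ll_KG = m1 >= factor,
          glucin_gg_KMoverPhiR = m2 >= factor,
          glucin_ll_KM = m3 >= factor)
  predicted <-
    if (all(ok)) "full-range ratio-sensing"
    else if (!ok[["galin_ll_KG"]])
      "ratio-sensing at low concentrations, glucose threshold sensing at high carbon source concentrations"
    else if (!ok[["glucin_ll_KM"]])
      "ratio-sensing at low concentrations, galactose threshold sensing at high carbon source concentrations"
    else
      "galactose threshold sensing at low carbon source concentrations, ratio-sensing at high"
  structure(list(galin_ll_KG = unname(ok[1L]),
                 glucin_gg_KMoverPhiR = unname(ok[2L]),
                 glucin_ll_KM = unname(ok[3L]),
                 margins = c(galin_ll_KG = m1, glucin_gg_KMoverPhiR = m2,
                             glucin_ll_KM = m3),
                 factor = factor,
                 predicted_pattern = predicted),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("<regime_report> (\"<<\" factor %g)\n", x$factor))
  for (nm in c("galin_ll_KG", "glucin_gg_KMoverPhiR", "glucin_ll_KM"))
    cat(sprintf("  %-22s %-5s (margin %.3g)\n", nm, x[[nm]], x$margins[[nm]]))
  cat("  predicted:", x$predicted_pattern, "\n")
  invisible(x)
}

#' Simulate the transcription layer on a titration grid
#'
#' Used stand-alone, the grid axes are interpreted as intracellular sugar
#' levels fed directly into the CRE occupancy closed form (identity
#' uptake). An optional `uptake` function `(gal, gluc) -> list(gal_in,
#' gluc_in)` maps grid coordinates to intracellular sugars first, which is
#' how the concatenated model reuses this routine.
#'
#' @param grid a [titration_grid()]
#' @param p a [transcription_params()]
#' @param uptake optional pass-through mapping external to intracellular
#'   sugars; defaults to identity
#' @param normalize normalize to the maximal-induction corner (default)
#' @return a [response_surface()]
#' @export
simulate_transcription_grid <- function(grid, p, uptake = NULL,
                                        normalize = TRUE) {
  if (!inherits(grid, "titration_grid")) stopf("'grid' must be a titration_grid")
  pts <- expand.grid(gal = grid$gal, gluc = grid$gluc)
  inner <- if (is.null(uptake)) list(gal_in = pts$gal, gluc_in = pts$gluc)
           else uptake(pts$gal, pts$gluc)
  f <- active_fraction(inner$gal_in, inner$gluc_in, p)
  surf <- response_surface(grid, matrix(f, nrow = length(grid$gal)))
  if (normalize) normalize_surface(surf) else surf
}
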