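#' Kinetic parameters of the communal-transporter uptake layer
#'
#' Galactose and glucose compete for a single shared transporter pool.
#' Extracellular sugar binds a free transporter (association rate `kf_*`,
#' dissociation `kr_*`); loaded transporters unload their sugar into the
#' cytoplasm at rate `k_trans`, and intracellular sugar is consumed by
#' catabolism at turn-over rate `gamma`. Derived quantities:
#' lumped binding coefficients `K_gal = (kr_gal + k_trans)/kf_gal`,
#' `K_gluc = (kr_gluc + k_trans)/kf_gluc`, and the transportation capacity
#' `psi = k_trans * T_total / gamma`, the maximal steady-state
#' intracellular sugar level. Cooperativity exponents `n_gal`, `n_gluc`
#' generalize the binding step to a Hill form: the occupancy ratio
#' `s/K` enters as `(s/K)^n`.
#'
#' @param kf_gal,kf_gluc association rates (1/(conc * time))
#' @param kr_gal,kr_gluc dissociation rates (1/time)
#' @param k_trans maximal transport (unloading) rate (1/time)
#' @param gamma intracellular sugar turn-over rate (1/time)
#' @param T_total total transporter pool (a.u.)
#' @param n_gal,n_gluc Hill cooperativity exponents (>= 1, default 1)
#' @return an object of class `"transporter_params"` carrying the inputs
#'   plus derived `K_gal`, `K_gluc`, `psi`
#' @examples
#' p <- transporter_params(kf_gal = 1, kr_gal = 1, kf_gluc = 1, kr_gluc = 1,
#'                         k_trans = 1, gamma = 1, T_total = 100)
#' p$K_gal   # 2
#' p$psi     # 100
#' @export
transporter_params <- function(kf_gal, kr_gal, kf_gluc, kr_gluc,
                               k_trans, gamma, T_total,
                               n_gal = 1, n_gluc = 1) {
  for (nm in c("kf_gal", "kr_gal", "kf_gluc", "kr_gluc",
               "k_trans", "gamma", "T_total"))
    check_positive(get(nm), nm)
  for (nm in c("n_gal", "n_gluc")) {
    n <- get(nm)
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
      stopf("'%s' must be a single number >= 1", nm)
  }
  p <- list(kf_gal = kf_gal, kr_gal = kr_gal,
            kf_gluc = kf_gluc, kr_gluc = kr_gluc,
            k_trans = k_trans, gamma = gamma, T_total = T_total,
            n_gal = n_gal, n_gluc = n_gluc)
  p$K_gal  <- (kr_gal + k_trans) / kf_gal
  p$K_gluc <- (kr_gluc + k_trans) / kf_gluc
  p$psi    <- k_trans * T_total / gamma
  stopifnot(is.finite(p$K_gal), p$K_gal > 0,
            is.finite(p$K_gluc), p$K_gluc > 0, p$psi > 0)
  structure(p, class = "transporter_params")
}

#' Construct transporter parameters from binding coefficients
#'
#' Convenience wrapper that picks association rates reproducing the
#' requested lumped `K_gal`, `K_gluc` (with `kr = k_trans` so binding and
#' unloading time scales stay comparable).
#'
#' @param K_gal,K_gluc lumped binding coefficients (a.u.)
#' @inheritParams transporter_params
#' @return a [transporter_params()] object
#' @export
transporter_params_from_K <- function(K_gal, K_gluc, k_trans = 1, gamma = 1,
                                      T_total = 100, n_gal = 1, n_gluc = 1) {
  check_positive(K_gal, "K_gal"); check_positive(K_gluc, "K_gluc")
  transporter_params(kf_gal = 2 * k_trans / K_gal, kr_gal = k_trans,
                     kf_gluc = 2 * k_trans / K_gluc, kr_gluc = k_trans,
                     k_trans = k_trans, gamma = gamma, T_total = T_total,
                     n_gal = n_gal, n_gluc = n_gluc)
}

#' @export
print.transporter_params <- function(x, ...) {
  cat(sprintf(
    "<transporter_params> K_gal=%.3g K_gluc=%.3g psi=%.3g n_gal=%g n_gluc=%g\n",
    x$K_gal, x$K_gluc, x$psi, x$n_gal, x$n_gluc))
  invisible(x)
}

#' Species levels of the uptake system
#'
#' State vector of the mass-action uptake model: intracellular sugars,
#' the two loaded transporter pools and the free pool. Loaded plus free
#' transporters are conserved at `T_total`.
#'
#' @param gal_in,gluc_in intracellular sugar concentrations (a.u.)
#' @param galT,glucT galactose- and glucose-loaded transporter pools (a.u.)
#' @param T_free free transporters (a.u.)
#' @return a named numeric vector of class `"transporter_state"`
#' @export
transporter_state <- function(gal_in = 0, gluc_in = 0, galT = 0, glucT = 0,
                              T_free) {
  s <- c(gal_in = gal_in, gluc_in = gluc_in,
         galT = galT, glucT = glucT, T_free = T_free)
  check_nonneg(s, "transporter_state")
  structure(s, class = "transporter_state")
}

# Hill-generalized association flux into the loaded-transporter pool.
# kf * K = kr + k_trans, so for n = 1 this is exactly kf * s_ex * T_free.
assoc_flux <- function(kf, K, s_ex, n, T_free) {
  kf * K * (s_ex / K)^n * T_free
}

#' Time derivatives of the uptake system
#'
#' Mass-action right-hand side of the five-species uptake model. The sum
#' of the three transporter derivatives is identically zero, so the total
#' transporter pool is conserved along any trajectory.
#'
#' @param state a [transporter_state()] (or named vector with the same fields)
#' @param gal_ex,gluc_ex external sugar concentrations (a.u., >= 0)
#' @param p a [transporter_params()]
#' @return named numeric vector of time derivatives, same names as `state`
#' @export
transporter_rhs <- function(state, gal_ex, gluc_ex, p) {
  check_nonneg(unclass(state), "state")
  check_nonneg(gal_ex, "gal_ex"); check_nonneg(gluc_ex, "gluc_ex")
  s <- as.list(unclass(state))
  fg <- if (gal_ex > 0)  assoc_flux(p$kf_gal,  p$K_gal,  gal_ex,  p$n_gal,  s$T_free) else 0
  fm <- if (gluc_ex > 0) assoc_flux(p$kf_gluc, p$K_gluc, gluc_ex, p$n_gluc, s$T_free) else 0
  d_galT  <- fg - (p$kr_gal  + p$k_trans) * s$galT
  d_glucT <- fm - (p$kr_gluc + p$k_trans) * s$glucT
  c(gal_in  = p$k_trans * s$galT  - p$gamma * s$gal_in,
    gluc_in = p$k_trans * s$glucT - p$gamma * s$gluc_in,
    galT    = d_galT,
    glucT   = d_glucT,
    T_free  = -(d_galT + d_glucT))
}

#' Closed-form steady state of the uptake layer
#'
#' Intracellular sugar levels at steady state under competitive binding to
#' the shared transporter pool:
#' `gal_in = psi / (1 + (K_gal/gal_ex)^n_gal * (1 + (gluc_ex/K_gluc)^n_gluc))`
#' and the mirrored expression for glucose. `gal_ex = 0` is handled as the
#' exact zero-influx limit. Vectorized over the sugar arguments.
#'
#' @inheritParams transporter_rhs
#' @return list with numeric fields `gal_in` and `gluc_in`
#' @export
transporter_steady_state <- function(gal_ex, gluc_ex, p) {
  check_nonneg(gal_ex, "gal_ex"); check_nonneg(gluc_ex, "gluc_ex")
  occ <- function(s, K, n) ifelse(s > 0, (s / K)^n, 0)  # Hill occupancy ratio
  og <- occ(gal_ex,  p$K_gal,  p$n_gal)
  om <- occ(gluc_ex, p$K_gluc, p$n_gluc)
  den <- 1 + og + om
  list(gal_in  = p$psi * og / den,
       gluc_in = p$psi * om / den)
}

#' Steady state of the uptake layer by ODE integration
#'
#' Integrates the mass-action system from an empty cell until the relative
#' derivative norm drops below `tol`, with a stiff-capable solver. Used as
#' the independent numerical oracle for [transporter_steady_state()].
#'
#' @inheritParams transporter_rhs
#' @param tol steady-state criterion: max |dx/dt| / (|x| + atol) < tol
#' @param t_chunk integration horizon per attempt (in 1/min-rate units)
#' @param max_chunks maximum number of horizons before giving up
#' @return list with fields `gal_in`, `gluc_in`, `state` (full final state)
#' @export
integrate_transporter <- function(gal_ex, gluc_ex, p, tol = 1e-9,
                                  t_chunk = NULL, max_chunks = 60) {
  rates <- c(p$kr_gal + p$k_trans, p$kr_gluc + p$k_trans, p$gamma)
  if (is.null(t_chunk)) t_chunk <- 20 / min(rates)
  y <- c(gal_in = 0, gluc_in = 0, galT = 0, glucT = 0, T_free = p$T_total)
  deriv <- function(t, y, parms) list(transporter_rhs(y, gal_ex, gluc_ex, p))
  atol <- 1e-12 * max(p$psi, p$T_total)
  for (i in seq_len(max_chunks)) {
    y_prev <- y
    out <- deSolve::lsoda(y, c(0, t_chunk), deriv, parms = NULL,
                          rtol = 1e-11, atol = atol, maxsteps = 1e5)
    y <- out[nrow(out), -1L]
    d <- transporter_rhs(y, gal_ex, gluc_ex, p)
    # steady when the derivative vanishes, or (where flux cancellation
    # noise floors the derivative) the state stops moving over a chunk
    # spanning >= 20 slow relaxation times
    if (max(abs(d) / (abs(y) + atol)) < tol ||
        max(abs(y - y_prev) / (abs(y) + atol)) < tol)
      return(list(gal_in = unname(y["gal_in"]), gluc_in = unname(y["gluc_in"]),
                  state = y))
    t_chunk <- t_chunk * 1.5   # stretch the horizon for lingering slow modes
  }
  stopf("uptake ODE did not reach steady state within %d horizons", max_chunks)
}

#' Analytic decision front of the uptake layer
#'
#' In the transporter-saturated regime (`gluc_ex >> K_gluc`) the
#' iso-induction contour of intracellular galactose is a straight line in
#' log10-log10 external-sugar space with slope `n_gal / n_gluc` and
#' intercept `(1/n_gluc) * (log10(K_gluc^n_gluc / K_gal^n_gal) +
#' log10(1/level - 1))`. Outside that regime the line is only an
#' asymptote; the returned object flags (does not enforce) the regime.
#'
#' @param p a [transporter_params()]
#' @param level induction level of the contour, strictly in (0, 1); the
#'   level is a fraction of the transport capacity `psi`
#' @return list with `slope`, `intercept`, `level` and a `regime` note
#' @examples
#' p <- transporter_params_from_K(1, 1)
#' transporter_front_analytic(p, 0.5)$slope      # 1
#' transporter_front_analytic(p, 0.5)$intercept  # 0: log10(1/0.5 - 1) = 0
#' @export
transporter_front_analytic <- function(p, level = 0.5) {
  check_level(level)
  cc <- log10(1 / level - 1)
  list(slope = p$n_gal / p$n_gluc,
       intercept = (p$n_gluc * log10(p$K_gluc) - p$n_gal * log10(p$K_gal) + cc) / p$n_gluc,
       level = level,
       regime = "valid where gluc_ex >> K_gluc (transporters saturated by glucose)")
}

#' Simulate the uptake layer on a titration grid
#'
#' Induction is taken proportional to the intracellular galactose level,
#' so the surface is the closed-form steady-state `gal_in` at every grid
#' point, normalized to the maximal-induction corner.
#'
#' @param grid a [titration_grid()] of external sugar concentrations
#' @param p a [transporter_params()]
#' @param normalize divide by the (max gal, min gluc) corner value (default)
#' @return a [response_surface()]
#' @export
simulate_transporter_grid <- function(grid, p, normalize = TRUE) {
  if (!inherits(grid, "titration_grid")) stopf("'grid' must be a titration_grid")
  pts <- expand.grid(gal = grid$gal, gluc = grid$gluc)
  ss <- transporter_steady_state(pts$gal, pts$gluc, p)
  surf <- response_surface(grid, matrix(ss$gal_in, nrow = length(grid$gal)))
  if (normalize) normalize_surface(surf) else surf
}
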