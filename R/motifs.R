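#' Regulatory states of the generalized signal-integration unit
#'
#' In the generalized unit the activator pool `A_total` and repressor pool
#' `R_total` need not be constants: each node can carry one of five
#' regulatory states. Auto-regulation makes a pool depend on its own
#' active form; a feedforward-loop (FFL) edge makes it depend on the other
#' node's active form. On the activator node the FFL edge comes from the
#' repressor (a coherent edge inhibits the activator, an incoherent edge
#' promotes it); on the repressor node the edge comes from the activator
#' (a coherent edge inhibits the repressor, an incoherent edge promotes
#' it). The "coherent"/"incoherent" labels describe the sign of the
#' indirect path relative to the direct one in the resulting three-node
#' loop.
#'
#' @format character vector of the five state names
#' @export
motif_states <- c("none", "positive_auto", "negative_auto",
                  "coherent_ffl_edge", "incoherent_ffl_edge")

#' Configuration of a motif-decorated signal-integration unit
#'
#' Couples a base transcription layer (supplying `K_G`, `K_M`, `K_A`,
#' `K_R`) with one regulatory state per node, baseline pool scales `A0`,
#' `R0`, and the regulatory binding constants `Kx` (for the edge into the
#' activator node) and `Ky` (edge into the repressor node). The regulating
#' species is always an active form: the node's own active form for
#' auto-regulation, the other node's for FFL edges. Regulation follows
#' saturating first-order forms -- negative: `X0 / (1 + Z/K)`; positive:
#' `X0 * (Z/K) / (1 + Z/K)` -- the minimal mass-action-consistent choices,
#' which reproduce the analytic front formulas of all eight single-motif
#' circuits (square-root and squared intercept terms, shifted arguments).
#'
#' In the basic configuration (both states `"none"`) the pools are
#' identically `A0` and `R0` and the unit reduces to the plain
#' transcription layer.
#'
#' @param activator_state,repressor_state one of [motif_states]
#' @param base a [transcription_params()]; its pool fields are ignored in
#'   favour of `A0`, `R0`
#' @param A0,R0 baseline pool scales (a.u.)
#' @param Kx,Ky regulatory binding constants (a.u.); required whenever the
#'   corresponding node state is not `"none"`
#' @return an object of class `"motif_config"`
#' @export
motif_config <- function(activator_state = "none", repressor_state = "none",
                         base, A0, R0, Kx = NA_real_, Ky = NA_real_) {
  activator_state <- match.arg(activator_state, motif_states)
  repressor_state <- match.arg(repressor_state, motif_states)
  if (!inherits(base, "transcription_params"))
    stopf("'base' must be a transcription_params object")
  check_positive(A0, "A0"); check_positive(R0, "R0")
  if (activator_state != "none") check_positive(Kx, "Kx")
  if (repressor_state != "none") check_positive(Ky, "Ky")
  structure(list(activator_state = activator_state,
                 repressor_state = repressor_state,
                 base = base, A0 = A0, R0 = R0, Kx = Kx, Ky = Ky),
            class = "motif_config")
}

#' @export
print.motif_config <- function(x, ...) {
  cat(sprintf("<motif_config> activator: %s, repressor: %s (A0=%.3g R0=%.3g Kx=%.3g Ky=%.3g)\n",
              x$activator_state, x$repressor_state, x$A0, x$R0, x$Kx, x$Ky))
  invisible(x)
}

#' Generalized actively transcribed fraction
#'
#' CRE occupancy of the generalized unit with explicit pool sizes:
#' `1 / (1 + (K_A/A_total) * (K_G/S_A + 1) * (1 + (R_total/K_R) * S_R/(K_M + S_R)))`.
#' With constant pools this is exactly the basic layer's closed form.
#' Vectorized over all numeric arguments.
#'
#' @param S_A,S_R activating and repressing input signals (a.u., >= 0);
#'   galactose and glucose in the GAL setting
#' @param A_total,R_total effective pool sizes (a.u.)
#' @param p a [transcription_params()] supplying `K_G`, `K_M`, `K_A`, `K_R`
#' @return fraction(s) in [0, 1]
#' @export
generalized_active_fraction <- function(S_A, S_R, A_total, R_total, p) {
  check_nonneg(S_A, "S_A"); check_nonneg(S_R, "S_R")
  a_occ <- S_A / (p$K_G + S_A)
  r_occ <- S_R / (p$K_M + S_R)
  act <- A_total * a_occ / p$K_A
  frac <- act / (act + 1 + R_total * r_occ / p$K_R)
  ifelse(act > 0, frac, 0)
}

# pool update given the regulating active species z
pool_update <- function(state, X0, K, z) {
  switch(state,
         none = rep_len(X0, length(z)),
         negative_auto = ,
         coherent_ffl_edge = X0 / (1 + z / K),
         positive_auto = ,
         incoherent_ffl_edge = X0 * (z / K) / (1 + z / K))
}

# which active species regulates each node
regulator_of <- function(node, state, Astar, Rstar) {
  if (state %in% c("positive_auto", "negative_auto")) {
    if (node == "A") Astar else Rstar
  } else {            # FFL edge: the other node's active form
    if (node == "A") Rstar else Astar
  }
}

# closed-form fixed point of an auto-regulated pool: x = update(occ * x)
# negative: occ x^2 / K + x - X0 = 0 (stable quadratic form);
# positive: nonzero branch X0 - K/occ when it exists, else extinct at 0
solve_auto_pool <- function(state, X0, K, occ) {
  switch(state,
         none = rep_len(X0, length(occ)),
         negative_auto = ifelse(occ > 0,
                                2 * X0 / (1 + sqrt(1 + 4 * occ * X0 / K)),
                                X0),
         positive_auto = ifelse(occ > 0 & X0 * occ > K, X0 - K / occ, 0))
}

is_ffl <- function(state) state %in% c("coherent_ffl_edge", "incoherent_ffl_edge")

#' Self-consistent effective pool sizes of a motif configuration
#'
#' The regulated pools and their active forms must satisfy a fixed-point
#' system: `A_total = f(regulator)`, `Astar = occ_A * A_total` (and the
#' repressor mirror), where `occ_A = S_A/(K_G + S_A)` and
#' `occ_R = S_R/(K_M + S_R)`. Auto-regulated nodes have exact scalar
#' solutions (a stable quadratic root for the negative form, the positive
#' form's nonzero branch where it exists); a single FFL edge is an
#' ordered evaluation (solve the regulating node first); FFL edges on
#' both nodes couple the two pools and are solved per point by a
#' bracketed monotone root solve on the active activator (the first-order
#' regulatory forms make that fixed point unique; mutual activation
#' additionally admits the extinct state, and the positive branch is
#' returned whenever it exists). Positivity holds by construction.
#' Vectorized over `S_A`, `S_R`.
#'
#' @param cfg a [motif_config()]
#' @param S_A,S_R input signals (a.u., >= 0)
#' @param tol relative tolerance of the coupled-case root solve
#' @return list with numeric fields `A_total`, `R_total`
#' @export
solve_effective_totals <- function(cfg, S_A, S_R, tol = 1e-12) {
  check_nonneg(S_A, "S_A"); check_nonneg(S_R, "S_R")
  n <- max(length(S_A), length(S_R))
  S_A <- rep_len(S_A, n); S_R <- rep_len(S_R, n)
  p <- cfg$base
  a_occ <- S_A / (p$K_G + S_A)
  r_occ <- S_R / (p$K_M + S_R)
  as_ <- cfg$activator_state; rs_ <- cfg$repressor_state
  if (!is_ffl(as_)) {
    A <- solve_auto_pool(as_, cfg$A0, cfg$Kx, a_occ)
    R <- if (!is_ffl(rs_)) solve_auto_pool(rs_, cfg$R0, cfg$Ky, r_occ)
         else pool_update(rs_, cfg$R0, cfg$Ky, a_occ * A)
    return(list(A_total = A, R_total = R))
  }
  if (!is_ffl(rs_)) {
    R <- solve_auto_pool(rs_, cfg$R0, cfg$Ky, r_occ)
    A <- pool_update(as_, cfg$A0, cfg$Kx, r_occ * R)
    return(list(A_total = A, R_total = R))
  }
  # FFL edges on both nodes: scalar root in u = Astar per grid point
  A <- numeric(n); R <- numeric(n)
  for (i in seq_len(n)) {
    a <- a_occ[i]; r <- r_occ[i]
    pool_A <- function(u) {
      v <- r * pool_update(rs_, cfg$R0, cfg$Ky, u)   # Rstar given Astar = u
      pool_update(as_, cfg$A0, cfg$Kx, v)
    }
    if (a == 0) {
      A[i] <- pool_A(0); R[i] <- pool_update(rs_, cfg$R0, cfg$Ky, 0)
      next
    }
    g <- function(u) u - a * pool_A(u)
    upper <- a * cfg$A0
    lower <- upper * 1e-12
    if (g(lower) >= 0) {
      # no positive fixed point (mutual activation below onset): extinct
      u <- 0
    } else {
      u <- stats::uniroot(g, lower = lower, upper = upper * (1 + 1e-9),
                          tol = tol * upper)$root
    }
    A[i] <- pool_A(u)
    R[i] <- pool_update(rs_, cfg$R0, cfg$Ky, u)
  }
  list(A_total = A, R_total = R)
}

# damped fixed-point iteration from (A0, R0); slower but assumption-free,
# kept as an independent cross-check of solve_effective_totals in tests
solve_totals_iterative <- function(cfg, S_A, S_R, tol = 1e-12,
                                   max_iter = 1e5, damping = 0.5) {
  n <- max(length(S_A), length(S_R))
  S_A <- rep_len(S_A, n); S_R <- rep_len(S_R, n)
  p <- cfg$base
  a_occ <- S_A / (p$K_G + S_A)
  r_occ <- S_R / (p$K_M + S_R)
  A <- rep_len(cfg$A0, n); R <- rep_len(cfg$R0, n)
  for (it in seq_len(max_iter)) {
    Astar <- a_occ * A; Rstar <- r_occ * R
    A_new <- if (cfg$activator_state == "none") A else
      pool_update(cfg$activator_state, cfg$A0, cfg$Kx,
                  regulator_of("A", cfg$activator_state, Astar, Rstar))
    R_new <- if (cfg$repressor_state == "none") R else
      pool_update(cfg$repressor_state, cfg$R0, cfg$Ky,
                  regulator_of("R", cfg$repressor_state, Astar, Rstar))
    A_next <- (1 - damping) * A + damping * A_new
    R_next <- (1 - damping) * R + damping * R_new
    delta <- max(abs(A_next - A) / (abs(A) + cfg$A0 * 1e-30),
                 abs(R_next - R) / (abs(R) + cfg$R0 * 1e-30))
    A <- A_next; R <- R_next
    if (delta < tol) return(list(A_total = A, R_total = R))
  }
  stopf("fixed point did not converge for configuration (%s, %s) after %d iterations",
        cfg$activator_state, cfg$repressor_state, max_iter)
}

#' Induction of a motif-decorated unit
#'
#' Solves the pool fixed point and evaluates the generalized active
#' fraction. Vectorized.
#'
#' @inheritParams solve_effective_totals
#' @return fraction(s) in [0, 1]
#' @export
motif_response <- function(S_A, S_R, cfg, ...) {
  tot <- solve_effective_totals(cfg, S_A, S_R, ...)
  generalized_active_fraction(S_A, S_R, tot$A_total, tot$R_total, cfg$base)
}

#' Simulate a motif configuration on a titration grid
#'
#' @param grid a [titration_grid()] of input signals `S_A` (gal axis) and
#'   `S_R` (gluc axis)
#' @param cfg a [motif_config()]
#' @param normalize normalize to the maximal-induction corner (default)
#' @return a [response_surface()]
#' @export
simulate_motif_grid <- function(grid, cfg, normalize = TRUE) {
  if (!inherits(grid, "titration_grid")) stopf("'grid' must be a titration_grid")
  pts <- expand.grid(gal = grid$gal, gluc = grid$gluc)
  f <- motif_response(pts$gal, pts$gluc, cfg)
  surf <- response_surface(grid, matrix(f, nrow = length(grid$gal)))
  if (normalize) normalize_surface(surf) else surf
}

#' Analytic decision front of a single-motif configuration
#'
#' Closed-form slope and intercept of the log10-log10 decision front for
#' each of the eight circuits with a motif on exactly one node, in the
#' deep-regulation ratio-sensing regime. The slope multiplier relative to
#' the basic unit's slope 1 is 1/2 for negative auto-regulation at the
#' activator and for the repressor-inhibits-activator coherent FFL, 2 for
#' negative auto-regulation at the repressor and for the
#' activator-inhibits-repressor coherent FFL, and 1 for the positive-auto
#' and incoherent-FFL circuits (whose fronts instead acquire shifted
#' arguments). Configurations with motifs on both nodes have no closed
#' form here and defer to the numerical path.
#'
#' @param cfg a [motif_config()] with at most one non-`"none"` state
#' @param level contour level in (0, 1)
#' @return an object of class `"motif_front"`: `slope`, `intercept`,
#'   `slope_multiplier` (0.5, 1 or 2), `shift` (list describing a shifted
#'   argument, or NULL) and `notes`
#' @export
motif_front_analytic <- function(cfg, level = 0.5) {
  check_level(level)
  p <- cfg$base
  if (cfg$activator_state != "none" && cfg$repressor_state != "none")
    stopf("no closed form for motifs on both nodes; use the numerical front")
  c10 <- log10(1 / level - 1)
  A0 <- cfg$A0; R0 <- cfg$R0; Kx <- cfg$Kx; Ky <- cfg$Ky
  base_int <- log10(p$K_M / p$K_G) + log10((p$K_R / p$K_A) * (A0 / R0))
  shift <- NULL; notes <- ""
  if (cfg$activator_state == "none" && cfg$repressor_state == "none") {
    slope <- 1; mult <- 1; intercept <- base_int + c10
    notes <- "basic unit: slope fixed at 1"
  } else if (cfg$activator_state == "negative_auto") {
    slope <- 0.5; mult <- 0.5
    intercept <- log10(p$K_M * p$K_R * sqrt(A0 * Kx) /
                         (p$K_A * R0 * sqrt(p$K_G))) + c10
    notes <- "pool ~ sqrt(A0*Kx*K_G/S_A); intercept depends on sqrt(K_G), sqrt(A0)"
  } else if (cfg$activator_state == "positive_auto") {
    slope <- 1; mult <- 1
    shift <- list(axis = "S_A", value = Kx * p$K_G / A0, sign = -1)
    intercept <- base_int + c10
    notes <- "front linear in the shifted argument S_A - Kx*K_G/A0"
  } else if (cfg$activator_state == "coherent_ffl_edge") {
    slope <- 0.5; mult <- 0.5
    intercept <- log10(p$K_M * sqrt(A0 * Kx * p$K_R / p$K_A) /
                         (R0 * sqrt(p$K_G))) + 0.5 * c10
    notes <- "repressor inhibits activator; intercept depends on sqrt(K_G), sqrt(A0)"
  } else if (cfg$activator_state == "incoherent_ffl_edge") {
    slope <- 1; mult <- 1
    shift <- list(axis = "S_R", value = Kx * p$K_M / R0, sign = +1)
    intercept <- base_int + c10
    notes <- "repressor promotes activator; front linear in S_R + Kx*K_M/R_total"
  } else if (cfg$repressor_state == "negative_auto") {
    slope <- 2; mult <- 2
    intercept <- log10((p$K_M / p$K_G^2) * (p$K_R / p$K_A)^2 * A0^2 /
                         (R0 * Ky)) + 2 * c10
    notes <- "intercept depends on the squares of K_G, K_R, K_A and A_total"
  } else if (cfg$repressor_state == "positive_auto") {
    slope <- 1; mult <- 1
    shift <- list(axis = "S_R", value = Ky * p$K_M / R0, sign = -1)
    intercept <- base_int + c10
    notes <- "front linear in the shifted argument S_R - Ky*K_M/R0"
  } else if (cfg$repressor_state == "coherent_ffl_edge") {
    slope <- 2; mult <- 2
    intercept <- log10((p$K_M / p$K_G^2) * (p$K_R / p$K_A) * A0^2 /
                         (R0 * Ky)) + c10
    notes <- "activator inhibits repressor; intercept depends on K_G^2, A_total^2"
  } else { # repressor incoherent_ffl_edge
    slope <- 1; mult <- 1
    shift <- list(axis = "S_A", value = Ky * p$K_G / A0, sign = +1)
    intercept <- base_int + c10
    notes <- "activator promotes repressor; front linear in S_A + Ky*K_G/A_total"
  }
  structure(list(slope = slope, intercept = intercept,
                 slope_multiplier = mult, shift = shift, level = level,
                 notes = notes),
            class = "motif_front")
}

#' @export
print.motif_front <- function(x, ...) {
  cat(sprintf("<motif_front> slope %.3g (multiplier %g), intercept %.4g\n",
              x$slope, x$slope_multiplier, x$intercept))
  if (!is.null(x$shift))
    cat(sprintf("  shifted argument on %s: %+.3g\n",
                x$shift$axis, x$shift$sign * x$shift$value))
  cat(" ", x$notes, "\n")
  invisible(x)
}

#' Enumerate the 25 regulatory configurations
#'
#' The activator and repressor node each take one of five regulatory
#' states independently, giving 25 configurations of the generalized
#' unit.
#'
#' @return data.frame with columns `activator_state`, `repressor_state`
#'   (25 unique rows)
#' @export
enumerate_configurations <- function() {
  g <- expand.grid(activator_state = motif_states,
                   repressor_state = motif_states,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[order(match(g$activator_state, motif_states),
          match(g$repressor_state, motif_states)), , drop = FALSE] -> g
  rownames(g) <- NULL
  g
}

#' Default per-node motif constants for the census
#'
#' Baseline pools and regulatory binding constants for each node state,
#' chosen so the deep-regulation inequalities hold at >= 100x margins
#' along fronts inside the default titration window (see the methods
#' vignette for the margin analysis).
#'
#' @return list with data.frames `activator` and `repressor`
#' @export
motif_state_constants <- function() {
  list(
    activator = data.frame(
      state = motif_states,
      A0 = c(1e13, 1e13, 1e16, 1e13, 1e13),
      Kx = c(NA, 1e-1, 1e2, 1e-1, 1e-2)),
    repressor = data.frame(
      state = motif_states,
      R0 = c(1e12, 1e12, 1e16, 1e16, 1e12),
      Ky = c(NA, 1e-1, 1e2, 1e2, 1e-2)))
}

#' Build the 25 census presets
#'
#' Combines the base transcription constants with the per-node motif
#' constants of [motif_state_constants()], then rescales each
#' configuration's repressor baseline `R0` (a monotone one-dimensional
#' root solve) so that the normalized half-maximal front passes through
#' the centre of the titration window. Centring keeps every front inside
#' the sampled region without touching the constants that set the front's
#' slope.
#'
#' @param grid the [titration_grid()] the census will run on
#' @param base a [transcription_params()] supplying the binding constants
#' @param level front level used for centring
#' @return named list of 25 [motif_config()] objects, names
#'   `"<activator_state>.<repressor_state>"`
#' @export
motif_census_presets <- function(grid = make_log_grid(),
                                 base = motif_base_params(),
                                 level = 0.5) {
  tab <- motif_state_constants()
  cfgs <- enumerate_configurations()
  center_A <- 10^mean(log10(range(grid$gal)))
  center_R <- 10^mean(log10(range(grid$gluc)))
  corner_A <- max(grid$gal); corner_R <- min(grid$gluc)
  out <- vector("list", nrow(cfgs))
  names(out) <- paste(cfgs$activator_state, cfgs$repressor_state, sep = ".")
  for (i in seq_len(nrow(cfgs))) {
    a <- tab$activator[tab$activator$state == cfgs$activator_state[i], ]
    r <- tab$repressor[tab$repressor$state == cfgs$repressor_state[i], ]
    make <- function(R0) motif_config(cfgs$activator_state[i],
                                      cfgs$repressor_state[i],
                                      base = base, A0 = a$A0, R0 = R0,
                                      Kx = a$Kx, Ky = r$Ky)
    # normalized induction at an anchor point, as a function of log10 R0;
    # NA where the circuit is extinct (no induction anywhere)
    gap_at <- function(lr0, aA, aR) {
      cfg <- make(10^lr0)
      fc <- motif_response(c(aA, corner_A), c(aR, corner_R), cfg)
      if (!is.finite(fc[2L]) || fc[2L] <= 0) return(NA_real_)
      fc[1L] / fc[2L] - level
    }
    # coarse scan for a sign-change bracket (the gap need not be monotone
    # across regulatory regimes), then refine by root solve; anchors move
    # from the window centre toward the maximal-induction corner for
    # circuits whose working region excludes the centre (e.g. extinction
    # of a positively auto-regulated pool at low input)
    lr_seq <- log10(r$R0) + seq(-8, 8, by = 0.25)
    lr0 <- NA_real_
    for (off in c(0, 0.5, 1, 1.5, -0.5, -1)) {
      aA <- center_A * 10^off; aR <- center_R * 10^(-off)
      gv <- vapply(lr_seq, gap_at, numeric(1), aA = aA, aR = aR)
      ok <- which(!is.na(gv[-length(gv)]) & !is.na(gv[-1L]) &
                    gv[-length(gv)] * gv[-1L] <= 0)
      if (length(ok) > 0L) {
        k <- ok[which.min(abs(lr_seq[ok] - log10(r$R0)))]
        lr0 <- stats::uniroot(gap_at, lower = lr_seq[k],
                              upper = lr_seq[k + 1L],
                              aA = aA, aR = aR, tol = 1e-10)$root
        break
      }
    }
    if (is.na(lr0))
      stopf("could not place the front inside the window for configuration (%s, %s)",
            cfgs$activator_state[i], cfgs$repressor_state[i])
    out[[i]] <- make(10^lr0)
  }
  out
}

#' Base transcription constants shared by the motif circuits
#'
#' Binding constants satisfying the ratio-sensing inequalities at >= 100x
#' margins over the default titration window; pool sizes are placeholders
#' (each motif configuration supplies its own `A0`, `R0`).
#'
#' @return a [transcription_params()]
#' @export
motif_base_params <- function() {
  transcription_params(K_G = 1e6, K_M = 1e5, K_A = 1, K_R = 1,
                       phiA = 1e13, phiR = 1e12)
}

#' Numerical slope census over all 25 configurations
#'
#' Simulates every configuration on the grid, extracts the half-maximal
#' front, fits the log-log slope over the window interior, and bins the
#' slope to the nearest of the multipliers 0.5, 1 and 2 within a +-20%
#' acceptance window. Fits outside every window, or with RMS residual
#' above `residual_gate`, are flagged ambiguous rather than silently
#' binned.
#'
#' @param presets named list of [motif_config()]s, e.g. from
#'   [motif_census_presets()]
#' @param grid the [titration_grid()] to simulate on
#' @param level front level
#' @param interior_trim fraction of each axis (in log units) excluded at
#'   both ends when fitting, to keep the fit off boundary-distorted front
#'   tails
#' @param residual_gate maximum RMS residual (log10 units) for an
#'   unambiguous fit
#' @return data.frame with one row per configuration: states, fitted
#'   `slope`, `residual`, `n_points`, `multiplier` (NA when ambiguous) and
#'   `ambiguous` flag; attribute `"counts"` holds the (0.5, 1, 2) tally
#' @export
census_slope_multipliers <- function(presets = NULL,
                                     grid = make_log_grid(),
                                     level = 0.5,
                                     interior_trim = 1/6,
                                     residual_gate = 0.15) {
  if (is.null(presets)) presets <- motif_census_presets(grid)
  bins <- c(0.5, 1, 2)
  rows <- lapply(names(presets), function(nm) {
    cfg <- presets[[nm]]
    surf <- simulate_motif_grid(grid, cfg)
    front <- tryCatch(extract_decision_front(surf, level),
                      error = function(e) NULL)
    if (is.null(front) || nrow(front) < 4L)
      return(data.frame(activator_state = cfg$activator_state,
                        repressor_state = cfg$repressor_state,
                        slope = NA_real_, residual = NA_real_,
                        n_points = if (is.null(front)) 0L else nrow(front),
                        multiplier = NA_real_, ambiguous = TRUE,
                        stringsAsFactors = FALSE))
    lg <- log10(range(grid$gal)); lm <- log10(range(grid$gluc))
    keep <- front$log_gal >= lg[1L] + interior_trim * diff(lg) &
      front$log_gal <= lg[2L] - interior_trim * diff(lg) &
      front$log_gluc >= lm[1L] + interior_trim * diff(lm) &
      front$log_gluc <= lm[2L] - interior_trim * diff(lm)
    sub <- front[keep, , drop = FALSE]
    if (nrow(sub) < 4L) sub <- front   # fall back to the full front
    fit <- fit_front(sub)
    slope <- fit$slope
    mult <- NA_real_; ambiguous <- TRUE
    if (!fit$vertical && is.finite(slope)) {
      k <- which.min(abs(slope - bins))
      if (abs(slope - bins[k]) <= 0.2 * bins[k] &&
          fit$residual <= residual_gate) {
        mult <- bins[k]; ambiguous <- FALSE
      }
    }
    data.frame(activator_state = cfg$activator_state,
               repressor_state = cfg$repressor_state,
               slope = slope, residual = fit$residual, n_points = fit$n,
               multiplier = mult, ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- names(presets)
  counts <- vapply(bins, function(b)
    sum(!res$ambiguous & res$multiplier == b), integer(1))
  names(counts) <- c("half", "unchanged", "double")
  attr(res, "counts") <- counts
  res
}
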