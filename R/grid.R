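#' Titration grids and response surfaces
#'
#' A titration grid holds the two log10-spaced axes of a double-sugar
#' titration: external (or intracellular) galactose along `gal` and glucose
#' along `gluc`, both in arbitrary concentration units. A response surface
#' attaches an induction value to every grid point; by convention induction
#' is normalized to the value at the maximal-induction corner (highest
#' galactose, lowest glucose), so normalized surfaces live in [0, 1].
#'
#' @param gal,gluc strictly increasing numeric vectors of concentrations (a.u.)
#' @return `titration_grid()` returns an object of class `"titration_grid"`
#'   with fields `gal` and `gluc`.
#' @seealso [make_log_grid()], [response_surface()]
#' @export
titration_grid <- function(gal, gluc) {
  for (nm in c("gal", "gluc")) {
    ax <- get(nm)
    if (!is.numeric(ax) || length(ax) < 2L || anyNA(ax) ||
        any(ax <= 0) || any(diff(ax) <= 0))
      stopf("grid axis '%s' must be a strictly increasing positive vector of length >= 2", nm)
  }
  structure(list(gal = as.numeric(gal), gluc = as.numeric(gluc)),
            class = "titration_grid")
}

#' @export
print.titration_grid <- function(x, ...) {
  cat(sprintf("<titration_grid> %d x %d points, gal [%g, %g], gluc [%g, %g] (a.u.)\n",
              length(x$gal), length(x$gluc),
              min(x$gal), max(x$gal), min(x$gluc), max(x$gluc)))
  invisible(x)
}

#' Build a log10-uniform double-titration grid
#'
#' Emulates the double-gradient titration layout of the experimental
#' induction maps: both sugar axes are log10-uniformly spaced. The default
#' window of 1e-4 to 1e2 a.u. with 30 points per axis is wide enough to
#' straddle the binding constants of every shipped transcription-layer
#' preset; uptake-layer presets use wider windows supplied explicitly.
#'
#' @param gal_min,gal_max,gluc_min,gluc_max positive axis bounds (a.u.)
#' @param n_per_axis number of points per axis (>= 2; >= 8 recommended so
#'   that decision fronts are well enough sampled for fitting)
#' @return a [titration_grid()]
#' @examples
#' make_log_grid(1, 100, 1, 100, 3)$gal  # 1, 10, 100
#' @export
make_log_grid <- function(gal_min = 1e-4, gal_max = 1e2,
                          gluc_min = 1e-4, gluc_max = 1e2,
                          n_per_axis = 30) {
  for (nm in c("gal_min", "gal_max", "gluc_min", "gluc_max"))
    check_positive(get(nm), nm)
  if (gal_min >= gal_max || gluc_min >= gluc_max)
    stopf("axis bounds must satisfy min < max")
  if (n_per_axis < 2) stopf("'n_per_axis' must be at least 2")
  lg <- function(a, b) 10^seq(log10(a), log10(b), length.out = n_per_axis)
  titration_grid(lg(gal_min, gal_max), lg(gluc_min, gluc_max))
}

#' Construct a response surface
#'
#' @param grid a [titration_grid()]
#' @param values numeric matrix of induction values, dimension
#'   `length(grid$gal) x length(grid$gluc)` (rows follow the galactose axis)
#' @param normalized logical; `TRUE` once values are scaled to the
#'   maximal-induction corner (see [normalize_surface()])
#' @return an object of class `"response_surface"`
#' @export
response_surface <- function(grid, values, normalized = FALSE) {
  if (!inherits(grid, "titration_grid")) stopf("'grid' must be a titration_grid")
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(grid$gal), length(grid$gluc))))
    stopf("'values' must be a %d x %d matrix",
          length(grid$gal), length(grid$gluc))
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stopf("surface values must be finite and non-negative")
  if (normalized && any(values > 1 + 1e-12))
    stopf("a normalized surface must lie in [0, 1]")
  structure(list(grid = grid, values = values, normalized = isTRUE(normalized)),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> %d x %d, values in [%.3g, %.3g]%s\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
as.data.frame.response_surface <- function(x, ...) {
  data.frame(gal = rep(x$grid$gal, times = length(x$grid$gluc)),
             gluc = rep(x$grid$gluc, each = length(x$grid$gal)),
             induction = as.vector(x$values))
}

#' Normalize a surface to its maximal-induction corner
#'
#' Divides all values by the value at the highest-galactose,
#' lowest-glucose grid corner -- the condition that in theory gives maximal
#' induction -- and clips the result to [0, 1]. For surfaces that are
#' monotone increasing in galactose and decreasing in glucose the corner is
#' the global maximum and clipping is a no-op.
#'
#' @param surface a [response_surface()]
#' @return the normalized surface
#' @export
normalize_surface <- function(surface) {
  if (!inherits(surface, "response_surface")) stopf("'surface' must be a response_surface")
  corner <- surface$values[nrow(surface$values), 1L]
  if (corner <= 0 || all(surface$values == 0))
    stopf("cannot normalize: maximal-induction corner value is zero")
  v <- pmin(pmax(surface$values / corner, 0), 1)
  response_surface(surface$grid, v, normalized = TRUE)
}

#' Inject multiplicative measurement noise
#'
#' Emulates measurement scatter of titration induction maps with a
#' log-normal multiplicative model: each value is multiplied by `exp(e)`,
#' `e ~ N(0, log(1 + cv))`. Induction values are positive and fold-change
#' like, so multiplicative log-normal noise is the natural scatter model.
#' Reproducible: the same `seed` always yields the same noisy surface, and
#' the session RNG state is left untouched.
#'
#' @param surface a [response_surface()]
#' @param cv coefficient of variation (>= 0); `cv = 0` returns the surface
#'   unchanged
#' @param seed integer seed
#' @return a [response_surface()]; re-clipped to [0, 1] if the input was
#'   normalized
#' @export
add_measurement_noise <- function(surface, cv, seed) {
  if (!inherits(surface, "response_surface")) stopf("'surface' must be a response_surface")
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stopf("'cv' must be a single non-negative number")
  if (cv == 0) return(surface)
  eps <- with_seed(seed, stats::rnorm(length(surface$values), 0, log1p(cv)))
  v <- surface$values * exp(eps)
  if (surface$normalized) v <- pmin(pmax(v, 0), 1)
  response_surface(surface$grid, v, normalized = surface$normalized)
}

#' Export a response surface as CSV
#'
#' @param surface a [response_surface()]
#' @param path output file path
#' @param format `"long"` writes columns `gal_ex, gluc_ex, induction`;
#'   `"matrix"` writes the dense value matrix with axis headers (first
#'   column = galactose axis, remaining column names = glucose axis).
#' @return `path`, invisibly
#' @export
write_surface_csv <- function(surface, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  if (format == "long") {
    d <- as.data.frame(surface)
    names(d) <- c("gal_ex", "gluc_ex", "induction")
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    m <- cbind(gal_ex = surface$grid$gal, surface$values)
    colnames(m) <- c("gal_ex", format(surface$grid$gluc, trim = TRUE))
    utils::write.csv(m, path, row.names = FALSE)
  }
  invisible(path)
}
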