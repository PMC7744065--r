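#' Extract the decision front from a response surface
#'
#' The decision front is the contour of a fixed induction level in
#' (log10 galactose, log10 glucose) space. Because every model surface in
#' this package is monotone increasing in galactose and decreasing in
#' glucose, the contour is found by per-glucose-row monotone linear
#' interpolation of log-induction against log10 galactose: each glucose
#' row contributes at most one crossing, which yields an ordered front
#' without a generic marching-squares pass. Rows where the level is not
#' crossed contribute no point.
#'
#' @param surface a [response_surface()]
#' @param level contour level, strictly between the surface minimum and
#'   maximum
#' @return an object of class `"decision_front"`: a data.frame with
#'   columns `log_gal`, `log_gluc` plus attributes `level` and `grid`
#' @export
extract_decision_front <- function(surface, level = 0.5) {
  if (!inherits(surface, "response_surface")) stopf("'surface' must be a response_surface")
  rng <- range(surface$values)
  if (level <= rng[1L] || level >= rng[2L])
    stopf("'level' (%g) must lie strictly inside the surface range [%g, %g]",
          level, rng[1L], rng[2L])
  structure(front_points(surface, level, direction = "row"),
            level = level, class = c("decision_front", "data.frame"))
}

# contour points scanned along one grid direction: "row" interpolates the
# crossing galactose within each glucose row (resolves vertical and
# diagonal segments well), "col" interpolates the crossing glucose within
# each galactose column (resolves horizontal and diagonal segments well)
front_points <- function(surface, level, direction = c("row", "col")) {
  direction <- match.arg(direction)
  lgal <- log10(surface$grid$gal)
  lgluc <- log10(surface$grid$gluc)
  pts_gal <- numeric(0)
  pts_gluc <- numeric(0)
  if (direction == "row") {
    for (j in seq_along(lgluc)) {
      x <- crossing_point(lgal, surface$values[, j], level)
      if (!is.na(x)) {
        pts_gal <- c(pts_gal, x)
        pts_gluc <- c(pts_gluc, lgluc[j])
      }
    }
  } else {
    for (i in seq_along(lgal)) {
      y <- crossing_point(lgluc, surface$values[i, ], level)
      if (!is.na(y)) {
        pts_gal <- c(pts_gal, lgal[i])
        pts_gluc <- c(pts_gluc, y)
      }
    }
  }
  data.frame(log_gal = pts_gal, log_gluc = pts_gluc)
}

# single level crossing of a (piecewise monotone) induction profile;
# interpolates linearly in log-induction where both bracket values are
# positive, otherwise linearly in induction
crossing_point <- function(lgal, v, level) {
  n <- length(v)
  d <- v - level
  idx <- which(d[-n] * d[-1L] <= 0 & (v[-n] != v[-1L]))
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  v0 <- v[i]; v1 <- v[i + 1L]
  if (v0 == level) return(lgal[i])
  if (v1 == level) return(lgal[i + 1L])
  if (v0 > 0 && v1 > 0) {
    w <- (log(level) - log(v0)) / (log(v1) - log(v0))
  } else {
    w <- (level - v0) / (v1 - v0)
  }
  lgal[i] + w * (lgal[i + 1L] - lgal[i])
}

#' @export
print.decision_front <- function(x, ...) {
  cat(sprintf("<decision_front> level %g, %d points\n", attr(x, "level"), nrow(x)))
  if (nrow(x) >= 4L) {
    f <- fit_front(x)
    if (f$vertical) cat("  vertical front (galactose threshold geometry)\n")
    else cat(sprintf("  slope %.4g, intercept %.4g, RMS residual %.3g\n",
                     f$slope, f$intercept, f$residual))
  }
  invisible(x)
}

#' Fit a straight line to a decision front
#'
#' Ordinary least squares of log10 glucose on log10 galactose. The slope
#' is the relative sensitivity of the circuit to the two sugars
#' (dy/dx with x = log10 galactose, y = log10 glucose). A front whose
#' galactose coordinates are numerically constant is flagged `vertical`
#' (galactose threshold geometry) instead of reporting an infinite slope.
#'
#' @param front a [extract_decision_front()] result, or any data.frame
#'   with `log_gal` and `log_gluc` columns (>= 4 points)
#' @return list with `slope`, `intercept`, `residual` (RMS deviation),
#'   `vertical` flag and `n` points
#' @export
fit_front <- function(front) {
  if (!is.data.frame(front) || !all(c("log_gal", "log_gluc") %in% names(front)))
    stopf("'front' must have columns log_gal and log_gluc")
  if (nrow(front) < 4L)
    stopf("need at least 4 front points to fit (got %d)", nrow(front))
  x <- front$log_gal; y <- front$log_gluc
  if (diff(range(x)) < 1e-8)
    return(list(slope = NA_real_, intercept = NA_real_, residual = 0,
                vertical = TRUE, n = length(x)))
  f <- ls_line(x, y)
  list(slope = f$slope, intercept = f$intercept, residual = f$residual,
       vertical = FALSE, n = length(x))
}

#' Sliding-window local slopes along a front
#'
#' Least-squares slope in a window of `window` points centred on each
#' front point (truncated at the ends). Numerically vertical windows
#' report `Inf`. Used to detect compound regimes, where the local slope
#' switches between threshold-like and ratio-like values along the front.
#'
#' @param front a decision front (see [fit_front()] for the required columns)
#' @param window odd window size, >= 3
#' @return numeric vector of local slopes, one per front point
#' @export
local_slopes <- function(front, window = 5) {
  if (window < 3) stopf("'window' must be >= 3")
  x <- front$log_gal; y <- front$log_gluc
  n <- length(x)
  h <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    k <- max(1L, i - h):min(n, i + h)
    xv <- x[k]; yv <- y[k]
    sxx <- sum((xv - mean(xv))^2)
    if (sxx < 1e-16) return(Inf)
    sum((xv - mean(xv)) * (yv - mean(yv))) / sxx
  }, numeric(1))
}

#' Classify the signal-integration pattern of a surface
#'
#' Extracts the level contour along both grid directions (per glucose row
#' and per galactose column, so that near-vertical and near-horizontal
#' segments are both well sampled), computes sliding-window local slopes,
#' and bins each contour point: |slope| > `steep` is galactose threshold
#' sensing (near-vertical front), |slope| < `shallow` is glucose
#' threshold sensing (near-horizontal), anything in between is ratio
#' sensing. If one class covers at least `dominance` of the pooled points
#' the surface gets that label; otherwise the pattern is `"compound"` and
#' the per-segment breakdown reports which modes combine (e.g. galactose
#' threshold sensing at poor nutrient conditions with ratio sensing at
#' rich conditions). The numeric thresholds are package choices -- the
#' underlying models define the limiting geometries but no sharp numeric
#' criterion.
#'
#' @param surface a [response_surface()]
#' @param level contour level
#' @param steep,shallow local-slope magnitude cutoffs for the threshold
#'   classes
#' @param dominance fraction of points a single class needs to label the
#'   whole surface
#' @param window window for [local_slopes()]
#' @return an object of class `"pattern_classification"`: fields `pattern`
#'   (one of `"ratio"`, `"galactose_threshold"`, `"glucose_threshold"`,
#'   `"compound"`, `"unclassifiable"`), `local_slopes`, `classes`, and
#'   `segments` (a data.frame of consecutive same-class runs)
#' @export
classify_pattern <- function(surface, level = 0.5, steep = 10, shallow = 0.1,
                             dominance = 0.9, window = 5) {
  front <- tryCatch(extract_decision_front(surface, level),
                    error = function(e) NULL)
  min_pts <- max(4L, window)
  rng <- range(surface$values)
  col_front <- if (level > rng[1L] && level < rng[2L])
    front_points(surface, level, "col") else NULL
  label <- function(f) {
    if (is.null(f) || nrow(f) < min_pts)
      return(list(slopes = numeric(0), classes = character(0),
                  segments = data.frame()))
    sl <- local_slopes(f, window)
    cls <- ifelse(abs(sl) > steep, "galactose_threshold",
                  ifelse(abs(sl) < shallow, "glucose_threshold", "ratio"))
    r <- rle(cls)
    ends <- cumsum(r$lengths)
    list(slopes = sl, classes = cls,
         segments = data.frame(class = r$values,
                               start = c(1L, utils::head(ends, -1L) + 1L),
                               end = ends))
  }
  by_row <- label(front)
  by_col <- label(col_front)
  cls <- c(by_row$classes, by_col$classes)
  if (length(cls) < min_pts) {
    return(structure(list(pattern = "unclassifiable",
                          local_slopes = numeric(0),
                          classes = character(0),
                          segments = data.frame(),
                          front = front),
                     class = "pattern_classification"))
  }
  tab <- table(cls) / length(cls)
  pattern <- if (max(tab) >= dominance) names(tab)[which.max(tab)] else "compound"
  segments <- rbind(
    if (nrow(by_row$segments)) cbind(by_row$segments, direction = "row"),
    if (nrow(by_col$segments)) cbind(by_col$segments, direction = "col"))
  structure(list(pattern = pattern,
                 local_slopes = c(by_row$slopes, by_col$slopes),
                 classes = cls, segments = segments, front = front),
            class = "pattern_classification")
}

#' @export
print.pattern_classification <- function(x, ...) {
  cat(sprintf("<pattern_classification> %s\n", x$pattern))
  if (nrow(x$segments) > 0) {
    agg <- x$segments
    # merge trivial single-point runs into a readable summary
    cat("  segments:", paste(sprintf("%s[%d-%d]", agg$class, agg$start, agg$end),
                             collapse = " "), "\n")
  }
  invisible(x)
}

# classes present in segments of at least `min_run` consecutive points
segment_classes <- function(classification, min_run = 3L) {
  seg <- classification$segments
  if (nrow(seg) == 0L) return(character(0))
  unique(seg$class[seg$end - seg$start + 1L >= min_run])
}
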