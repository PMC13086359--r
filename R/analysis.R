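# Post-processing: isotherm radius/depth extraction, logarithmic growth-law
# fitting, hemiellipsoid shape metrics, and surface thermogram export.
# Lengths are reported in millimetres, times in seconds.

interior_cols <- function(grid) 2:(ncol(grid$mat) - 1)
interior_rows <- function(grid) 2:(nrow(grid$mat) - 1)

#' Maximum radius of an isotherm
#'
#' Largest radial position, over all rows of the sample, where the
#' temperature crosses `level`, found per row by linear interpolation between
#' adjacent nodes.  All rows are searched (not only the surface) because
#' side-wall air cooling can make the widest frozen extent sub-surface.
#' Air and void nodes are excluded; applicator nodes count as part of the
#' frozen plug.
#'
#' @param field temperature storage matrix, degrees C.
#' @param grid a `cryo_grid` (as carried by a `cryo_result`).
#' @param level isotherm temperature, degrees C.
#' @return radius in mm, or `NA` when no sample node is at or below `level`.
#' @export
isotherm_radius <- function(field, grid, level) {
  ok <- sample_mask(grid)
  rows <- interior_rows(grid)
  cols <- interior_cols(grid)
  r <- grid$r
  best <- NA_real_
  for (i in rows) {
    v <- ok[i, cols]
    if (!any(v)) next
    Tr <- field[i, cols]
    below <- v & (Tr <= level)
    if (!any(below)) next
    j <- max(which(below))
    rc <- r[j]
    if (j < length(cols) && v[j + 1] && Tr[j + 1] > level)
      rc <- r[j] + grid$dr * (level - Tr[j]) / (Tr[j + 1] - Tr[j])
    if (is.na(best) || rc > best) best <- rc
  }
  1000 * best
}

#' Axial depth of an isotherm
#'
#' Deepest position on the axis column (the innermost cell ring, the proxy
#' for the symmetry axis on a cell-centered grid) where the temperature is at
#' or below
#' `level`, linearly interpolated between adjacent nodes.  Depth is measured
#' from the undisturbed surface `z = 0` and includes the press-in region of
#' the applicator.
#'
#' @inheritParams isotherm_radius
#' @return depth in mm, or `NA` when the isotherm is absent on the axis.
#' @export
isotherm_depth <- function(field, grid, level) {
  ok <- sample_mask(grid)
  rows <- interior_rows(grid)
  j <- 2L  # innermost ring
  v <- ok[rows, j]
  Tz <- field[rows, j]
  z <- grid$z
  below <- v & (Tz <= level)
  if (!any(below)) return(NA_real_)
  i <- max(which(below))
  zc <- z[i]
  if (i < length(rows) && v[i + 1] && Tz[i + 1] > level)
    zc <- z[i] + grid$dz * (level - Tz[i]) / (Tz[i + 1] - Tz[i])
  1000 * zc
}

#' Isotherm traces from stored snapshots
#'
#' Applies [isotherm_radius()] and [isotherm_depth()] to every snapshot of a
#' stage result.
#'
#' @param result a `cryo_result` with snapshots.
#' @param levels isotherm temperatures, degrees C; defaults to the levels the
#'   run was configured to track.
#' @return a data frame `time_s`, `level_C`, `R_mm`, `D_mm`, `present`.
#' @export
trace_isotherms <- function(result, levels = unique(result$trace$level_C)) {
  stopifnot(inherits(result, "cryo_result"), length(result$snapshots) > 0)
  rows <- lapply(seq_along(result$snapshots), function(k) {
    f <- result$snapshots[[k]]
    t <- result$snapshot_times[k]
    data.frame(time_s = t, level_C = levels,
               R_mm = vapply(levels, function(l)
                 isotherm_radius(f, result$grid, l), 0),
               D_mm = vapply(levels, function(l)
                 isotherm_depth(f, result$grid, l), 0))
  })
  out <- do.call(rbind, rows)
  out$present <- is.finite(out$R_mm) | is.finite(out$D_mm)
  out
}

#' Fit the logarithmic growth law
#'
#' During the freezing stage the isotherm radius and depth grow like
#' `value(t) = offset + slope * ln(t + 1)` with `t` in seconds.  The offset
#' is fixed, not fitted: 0 for depth, the applicator radius for radius.  The
#' slope is the least-squares solution of `(value - offset) ~ ln(t + 1)`
#' through the origin.
#'
#' @param trace a trace data frame (`time_s` plus the response column), or a
#'   numeric vector of times when `values` is given.
#' @param fixed_offset offset in mm (0 for depth fits, `r_ap` for radius).
#' @param response which column to fit when `trace` is a data frame:
#'   `"D_mm"` or `"R_mm"`.
#' @param level isotherm level to select when the trace holds several.
#' @param values numeric response vector (mm) when `trace` is a time vector.
#' @return a `cryo_growth_fit`: `slope` (mm per ln(s)), `offset` (mm),
#'   `rms` residual (mm), `n` points used.
#' @export
fit_log_growth <- function(trace, fixed_offset = 0,
                           response = c("D_mm", "R_mm"), level = NULL,
                           values = NULL) {
  if (is.data.frame(trace)) {
    response <- match.arg(response)
    if (!is.null(level)) trace <- trace[trace$level_C == level, ]
    if (length(unique(trace$level_C)) > 1)
      stop("trace holds several isotherm levels; pick one with `level`")
    times <- trace$time_s
    y <- trace[[response]]
  } else {
    times <- trace
    y <- values
  }
  keep <- is.finite(times) & is.finite(y) & times > 0
  times <- times[keep]; y <- y[keep]
  if (length(times) < 5) stop("need at least 5 finite time points to fit")
  if (max(y) - min(y) < 1e-12)
    stop("degenerate (constant) trace: nothing to fit")
  x <- log(times + 1)
  yy <- y - fixed_offset
  slope <- sum(x * yy) / sum(x * x)
  res <- yy - slope * x
  structure(list(slope = slope, offset = fixed_offset,
                 rms = sqrt(mean(res^2)), n = length(x)),
            class = "cryo_growth_fit")
}

#' @export
print.cryo_growth_fit <- function(x, ...) {
  cat(sprintf(paste0("<cryo_growth_fit> value ~ %.4g + %.4g * ln(t + 1)  ",
                     "[mm, t in s]; residual RMS %.3g mm over %d points\n"),
              x$offset, x$slope, x$rms, x$n))
  invisible(x)
}

#' Surface thermogram
#'
#' The temperature of the first sample row beneath `z = 0` as a radial
#' profile, optionally rendered as the concentric-circle 2D image a thermal
#' camera would show (polar symmetry by construction).
#'
#' @param field temperature storage matrix.
#' @param grid a `cryo_grid`.
#' @param n_px when given, also rasterize an `n_px` x `n_px` image covering
#'   `[-r_max, r_max]^2`; pixel `(x, y)` equals the profile at radius
#'   `sqrt(x^2 + y^2)`.
#' @return list with `profile` (data frame `r_mm`, `T_C`), and when requested
#'   `image` (matrix) and `px_mm` (pixel center coordinates).
#' @export
surface_thermogram <- function(field, grid, n_px = NULL) {
  i <- grid$n_air + 2L  # first interior row at z >= 0
  cols <- interior_cols(grid)
  prof <- data.frame(r_mm = 1000 * grid$r, T_C = field[i, cols])
  out <- list(profile = prof)
  if (!is.null(n_px)) {
    xy <- seq(-max(grid$r), max(grid$r), length.out = n_px)
    rr <- sqrt(outer(xy^2, xy^2, `+`))
    out$image <- matrix(stats::approx(grid$r, prof$T_C, xout = as.vector(rr),
                                      rule = 2)$y, n_px, n_px)
    out$px_mm <- 1000 * xy
  }
  out
}

#' Depth-to-radius ratio of the frozen hemiellipsoid
#'
#' Interpolates `R(t)` and `D(t)` from a trace and returns `D/R`, the shape
#' factor of the frozen zone (below 1 when depth-wise growth lags radial
#' growth, as observed under a flat applicator).
#'
#' @param trace trace data frame with `time_s`, `R_mm`, `D_mm` (one level).
#' @param t time at which to evaluate, s.
#' @param level isotherm level to select when the trace holds several.
#' @return list with `t`, `R_mm`, `D_mm` and `ratio`.
#' @export
hemiellipsoid_metrics <- function(trace, t, level = NULL) {
  if (!is.null(level)) trace <- trace[trace$level_C == level, ]
  if (length(unique(trace$level_C)) > 1)
    stop("trace holds several isotherm levels; pick one with `level`")
  ok <- is.finite(trace$R_mm) & is.finite(trace$D_mm)
  if (sum(ok) < 2 || t < min(trace$time_s[ok]) || t > max(trace$time_s[ok]))
    stop("isotherm absent (or not bracketed) at t = ", t, " s")
  R <- stats::approx(trace$time_s[ok], trace$R_mm[ok], xout = t)$y
  D <- stats::approx(trace$time_s[ok], trace$D_mm[ok], xout = t)$y
  list(t = t, R_mm = R, D_mm = D, ratio = D / R)
}
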