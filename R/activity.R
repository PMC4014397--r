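# Sliding-window least-squares machinery shared by the activity and
# growth-rate estimators. Running sums make the per-window OLS slope O(n)
# on any (not necessarily uniform) time grid.

run_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

# OLS slope of y on t within every full window of width w (odd), stride 1.
# Returns centers (indices into t) and slopes; windows containing NA give NA.
rolling_slope <- function(t, y, w) {
  n <- length(t)
  stopifnot(w >= 3, w %% 2 == 1, n >= w)
  St <- run_sum(t, w); Sy <- run_sum(y, w)
  Sty <- run_sum(t * y, w); Stt <- run_sum(t * t, w)
  slope <- (Sty - St * Sy / w) / (Stt - St * St / w)
  h <- (w - 1) / 2
  list(center = (h + 1):(n - h), slope = slope)
}

rolling_mean <- function(y, w) run_sum(y, w) / w

#' Construct an activity curve
#'
#' Holds a promoter's activity (fluorescence accumulation rate per unit OD)
#' on a generation axis for one condition set and replicate day.
#'
#' @param promoter promoter name.
#' @param condition_set canonical condition set (see [condition_set()]).
#' @param replicate_day integer day label.
#' @param generations numeric vector, non-decreasing (population doublings).
#' @param activity numeric vector, fluorescence units per OD per minute.
#' @param time_min measurement times of the window centers (for reference).
#' @return object of class `activity_curve`.
#' @export
activity_curve <- function(promoter, condition_set, replicate_day,
                           generations, activity, time_min) {
  stopifnot(length(generations) == length(activity),
            length(time_min) == length(activity))
  g_ok <- generations[!is.na(generations)]
  if (length(g_ok) && any(diff(g_ok) < -1e-9))
    stop("activity_curve: generations must be non-decreasing")
  structure(list(promoter = as.character(promoter),
                 condition_set = condition_set(condition_set),
                 replicate_day = as.integer(replicate_day),
                 generations = as.numeric(generations),
                 activity = as.numeric(activity),
                 time_min = as.numeric(time_min)),
            class = "activity_curve")
}

#' @export
print.activity_curve <- function(x, ...) {
  cat(sprintf("<activity_curve> %s | %s | day %d | %d points | generations %.2f-%.2f\n",
              x$promoter,
              if (length(x$condition_set)) condition_key(x$condition_set) else "(base)",
              x$replicate_day, length(x$activity),
              min(x$generations, na.rm = TRUE), max(x$generations, na.rm = TRUE)))
  invisible(x)
}

#' Promoter activity from a background-subtracted well series
#'
#' Promoter activity is the time derivative of GFP fluorescence accumulation
#' per unit cell density: within each sliding window of `window` consecutive
#' samples the OLS slope of fluorescence versus time is divided by the mean
#' OD over that window. One value is produced per window center; endpoints
#' where a full window does not fit are dropped. The default window of 17
#' samples (about 2 h at 8-min sampling) trades noise suppression against
#' temporal resolution; window sizes between 5 and 30 change smoothness but
#' not the downstream conclusions, and the choice is exposed as a parameter.
#'
#' @param series a [plate_series()] with background already subtracted.
#' @param window odd number of samples per regression window (default 17).
#' @param origin generation-axis origin passed to [to_generation_axis()].
#' @return an [activity_curve()] with the generation axis attached.
#' @export
promoter_activity <- function(series, window = 17L,
                              origin = c("culture_start", "first_window")) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  if (length(series$time_min) < window)
    stop("series '", series$well_id, "' shorter than window (",
         length(series$time_min), " < ", window, ")")
  rs <- rolling_slope(series$time_min, series$fluo, window)
  mean_od <- rolling_mean(series$od, window)
  act <- rs$slope / mean_od
  cur <- activity_curve(series$promoter, series$condition_set,
                        series$replicate_day,
                        generations = rep(0, length(act)),
                        activity = act,
                        time_min = series$time_min[rs$center])
  to_generation_axis(cur, series, window = window, origin = origin)
}

#' Instantaneous growth rate from a well series
#'
#' The specific growth rate d ln(OD)/dt, estimated as the OLS slope of
#' ln(OD) within each sliding window. Windows containing non-positive OD
#' yield missing values.
#'
#' @inheritParams promoter_activity
#' @return object of class `growth_rate_curve` with fields `generations`,
#'   `rate` (1/min) and `time_min`.
#' @export
growth_rate <- function(series, window = 17L,
                        origin = c("culture_start", "first_window")) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  if (length(series$time_min) < window)
    stop("series shorter than window")
  lnod <- ifelse(series$od > 0, log(series$od), NA_real_)
  rs <- rolling_slope(series$time_min, lnod, window)
  cur <- structure(list(promoter = series$promoter,
                        condition_set = series$condition_set,
                        replicate_day = series$replicate_day,
                        generations = rep(0, length(rs$slope)),
                        rate = rs$slope,
                        time_min = series$time_min[rs$center]),
                   class = "growth_rate_curve")
  to_generation_axis(cur, series, window = window, origin = origin)
}

#' @export
print.growth_rate_curve <- function(x, ...) {
  cat(sprintf("<growth_rate_curve> %s | %s | day %d | %d points\n",
              x$promoter, condition_key(x$condition_set), x$replicate_day,
              length(x$rate)))
  invisible(x)
}

# Smoothed log-OD at the window centers plus the anchor value at the first
# raw time point. Smoothing is the window mean of ln OD (the local linear
# fit evaluated at the window center), which is exact during exponential
# growth; the anchor extrapolates the first window's linear fit to t[1].
smoothed_log_od <- function(series, window) {
  lnod <- ifelse(series$od > 0, log(series$od), NA_real_)
  sm <- rolling_mean(lnod, window)
  h <- (window - 1) / 2
  centers <- (h + 1):(length(lnod) - h)
  idx <- seq_len(window)
  fit_ok <- !anyNA(lnod[idx])
  anchor <- if (fit_ok) {
    cf <- stats::coef(stats::lm.fit(cbind(1, series$time_min[idx]), lnod[idx]))
    cf[1] + cf[2] * series$time_min[1]
  } else NA_real_
  list(centers = centers, lnod_s = sm, anchor = anchor)
}

#' Place a curve on the generation axis
#'
#' Reparameterizes a curve by cumulative population doublings:
#' `generations(t) = log2( od_s(t) / od_ref )`, with `od_s` the OD smoothed
#' in the log domain by the same sliding window used for the derivative.
#' With `origin = "culture_start"` (default) the reference is the smoothed
#' OD extrapolated to the first raw time point, so that wells inoculated at
#' a common density share a common axis across conditions with different
#' growth rates; `origin = "first_window"` instead starts counting at the
#' first retained window center. A cumulative maximum enforces monotonicity
#' under OD noise; points with non-positive OD become missing.
#'
#' @param curve an [activity_curve()] or `growth_rate_curve` whose
#'   `time_min` are window centers of `series`.
#' @param series the [plate_series()] the curve was derived from.
#' @param window odd window used for smoothing (should match the curve's).
#' @param origin `"culture_start"` or `"first_window"`.
#' @return the curve with its `generations` field filled in.
#' @export
to_generation_axis <- function(curve, series, window = 17L,
                               origin = c("culture_start", "first_window")) {
  origin <- match.arg(origin)
  window <- as.integer(window)
  s <- smoothed_log_od(series, window)
  keep <- match(curve$time_min, series$time_min[s$centers])
  if (anyNA(keep))
    stop("to_generation_axis: curve time points are not window centers of the series")
  lnod_s <- s$lnod_s[keep]
  ref <- if (origin == "culture_start") s$anchor else lnod_s[which(!is.na(lnod_s))[1]]
  g <- (lnod_s - ref) / log(2)
  ok <- !is.na(g)
  g[ok] <- cummax(g[ok])
  curve$generations <- g
  curve
}

#' Resample activity curves onto a common generation grid
#'
#' Builds a uniform grid of `n_points` generations spanning the intersection
#' of all curves' generation ranges (so no curve is ever extrapolated) and
#' linearly interpolates each curve onto it. Missing values (e.g. from
#' non-positive OD) are dropped before interpolation; repeated generation
#' values (the flat axis in stationary phase) are averaged.
#'
#' @param curves list of [activity_curve()] (or `growth_rate_curve`) objects.
#' @param n_points number of grid points (default 100).
#' @param grid optional explicit generation grid; when supplied, curves are
#'   interpolated onto it (clamped at their endpoints) instead of onto the
#'   intersection grid.
#' @return list of curves of the same class, all on the identical grid.
#' @export
resample_to_common_grid <- function(curves, n_points = 100L, grid = NULL) {
  stopifnot(length(curves) >= 1L, n_points >= 2L)
  vfield <- function(cur) if (!is.null(cur$activity)) "activity" else "rate"
  rule <- if (is.null(grid)) 1 else 2
  if (is.null(grid)) {
    rng <- t(vapply(curves, function(cur) {
      ok <- !is.na(cur$generations) & !is.na(cur[[vfield(cur)]])
      range(cur$generations[ok])
    }, numeric(2)))
    lo <- max(rng[, 1]); hi <- min(rng[, 2])
    if (lo >= hi) {
      bad <- which(rng[, 1] >= hi | rng[, 2] <= lo)
      stop("resample_to_common_grid: empty generation-range intersection; ",
           "offending curves: ", paste(bad, collapse = ", "))
    }
    grid <- seq(lo, hi, length.out = n_points)
  }
  lapply(curves, function(cur) {
    f <- vfield(cur)
    ok <- !is.na(cur$generations) & !is.na(cur[[f]])
    cur[[f]] <- stats::approx(cur$generations[ok], cur[[f]][ok], xout = grid,
                              ties = mean, rule = rule)$y
    cur$time_min <- stats::approx(cur$generations[ok], cur$time_min[ok],
                                  xout = grid, ties = mean, rule = rule)$y
    cur$generations <- grid
    cur
  })
}

#' Compute activity curves for every non-control well of a collection
#'
#' Convenience wrapper: background-subtracts (when controls are present),
#' derives an activity curve per well, and optionally resamples all curves
#' of each promoter onto a shared generation grid.
#'
#' @param collection a `plate_collection`.
#' @param window sliding-window size (odd, default 17).
#' @param n_points grid size for [resample_to_common_grid()]; `NULL` skips
#'   resampling.
#' @param subtract subtract background first? Default `TRUE` when controls
#'   are present.
#' @param origin generation-axis origin (see [to_generation_axis()]).
#' @return named list (by promoter) of lists of [activity_curve()].
#' @export
activity_curves <- function(collection, window = 17L, n_points = 100L,
                            subtract = NULL,
                            origin = c("culture_start", "first_window")) {
  origin <- match.arg(origin)
  has_ctrl <- any(vapply(collection, `[[`, logical(1), "is_background_control"))
  if (is.null(subtract)) subtract <- has_ctrl
  if (subtract) {
    collection <- subtract_background_all(collection)
  } else {
    keep <- !vapply(collection, `[[`, logical(1), "is_background_control")
    collection <- collection[keep]
  }
  curves <- lapply(collection, promoter_activity, window = window, origin = origin)
  proms <- vapply(curves, `[[`, character(1), "promoter")
  out <- split(unname(curves), proms)
  if (!is.null(n_points))
    out <- lapply(out, resample_to_common_grid, n_points = n_points)
  out
}

#' Write activity curves as long-form CSV
#'
#' One row per (promoter, condition set, day, grid point), columns
#' `promoter, condition_set, day, generation, time_min, activity`.
#'
#' @param curves flat list of [activity_curve()] objects.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_activity_csv <- function(curves, path) {
  rows <- lapply(curves, function(cur) {
    data.frame(promoter = cur$promoter,
               condition_set = condition_key(cur$condition_set),
               day = cur$replicate_day,
               generation = cur$generations,
               time_min = cur$time_min,
               activity = cur$activity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
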