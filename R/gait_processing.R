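# Gait-event detection, cycle segmentation, 101-point time normalization,
# kinematic-variable extraction, and the mean absolute variability (MAV)
# statistic.  A gait cycle is the interval between adjacent right-leg heel
# strikes; normalized curves are indexed 0-100 % of the cycle.

#' Detect right heel strikes (coordinate-based)
#'
#' Heel strikes are located at local maxima of the heel's anteroposterior
#' (X) position relative to the pelvis — the standard coordinate-based rule
#' used when force-platform events are unavailable.  Externally annotated
#' events, when supplied, pass through untouched.
#'
#' @param heel Heel marker trajectory: n x 3 matrix (mm) or numeric vector
#'   of anteroposterior positions.
#' @param pelvis Pelvis reference trajectory, same form (e.g., the mean of
#'   the four pelvis markers).
#' @param times Frame times, s.
#' @param events Optional numeric vector of annotated heel-strike times;
#'   returned verbatim with `source = "annotated"`.
#' @param min_excursion Minimum peak-to-peak excursion (mm) of the relative
#'   position below which no events are reported; default 10.
#' @param min_separation Minimum time between successive events, s (noise
#'   peaks closer than this are merged, keeping the more anterior one);
#'   default 0.4.
#' @return List of class `gait_events`: `times` (s, increasing), `source`.
#' @export
detect_heel_strikes <- function(heel, pelvis, times, events = NULL,
                                min_excursion = 10, min_separation = 0.4) {
  if (!is.null(events)) {
    events <- sort(as.numeric(events))
    return(structure(list(times = events, source = "annotated"),
                     class = "gait_events"))
  }
  hx <- if (is.matrix(heel)) heel[, 1] else as.numeric(heel)
  px <- if (is.matrix(pelvis)) pelvis[, 1] else as.numeric(pelvis)
  if (length(hx) != length(times) || length(px) != length(times))
    stop("heel, pelvis and times must have equal length")
  rel <- hx - px
  hits <- integer(0)
  if (length(rel) >= 3 && diff(range(rel)) > min_excursion) {
    n <- length(rel)
    i <- 2:(n - 1)
    hits <- i[rel[i] > rel[i - 1] & rel[i] >= rel[i + 1]]
    # suppress ripple: keep peaks exceeding mid-range, then merge peaks
    # closer than min_separation (keep the more anterior one)
    hits <- hits[rel[hits] > mean(range(rel))]
    if (length(hits) > 1) {
      keep <- hits[1]
      for (h in hits[-1]) {
        if (times[h] - times[keep[length(keep)]] < min_separation) {
          if (rel[h] > rel[keep[length(keep)]]) keep[length(keep)] <- h
        } else keep <- c(keep, h)
      }
      hits <- keep
    }
  }
  if (!length(hits))
    warning("no heel-strike events detected")
  structure(list(times = times[hits], source = "detected"),
            class = "gait_events")
}

#' Time-normalize joint angles over one gait cycle
#'
#' Resamples each angle onto 101 equispaced points spanning 0-100 % of the
#' cycle using natural cubic-spline interpolation.
#'
#' @param series Joint-angle series: data.frame with a `time` column and
#'   angle columns (from [solve_trajectory()]).
#' @param cycle Numeric length-2: `c(t_heel_strike, t_next_heel_strike)`, s;
#'   must lie within the series and contain at least 4 frames.
#' @param angles Angle columns to normalize (default: all non-bookkeeping
#'   columns).
#' @return Data.frame with 101 rows (attribute `percent` = 0:100), one
#'   column per angle, deg.
#' @export
time_normalize <- function(series, cycle, angles = NULL) {
  if (length(cycle) != 2 || cycle[2] <= cycle[1])
    stop("cycle must be c(t_start, t_end) with t_end > t_start")
  tt <- series$time
  if (cycle[1] < min(tt) - 1e-9 || cycle[2] > max(tt) + 1e-9)
    stop("cycle [", cycle[1], ", ", cycle[2], "] outside data time span")
  inside <- tt >= cycle[1] - 1e-9 & tt <= cycle[2] + 1e-9
  if (sum(inside) < 4)
    stop("cycle spans fewer than 4 frames; cubic spline needs at least 4")
  if (is.null(angles))
    angles <- setdiff(names(series),
                      c("time", "residual_rms", "n_markers", "converged"))
  xout <- seq(cycle[1], cycle[2], length.out = 101)
  out <- vapply(angles, function(a) {
    y <- series[[a]]
    if (any(!is.finite(y[inside])))
      stop("angle '", a, "' has non-finite values inside the cycle")
    stats::spline(tt, y, xout = xout, method = "natural")$y
  }, numeric(101))
  out <- as.data.frame(out)
  attr(out, "percent") <- 0:100
  out
}

#' Extract kinematic variables from a normalized cycle
#'
#' Initial angle (value at right heel strike = point 0), peak maximum, peak
#' minimum, and range of motion (max - min).
#'
#' @param curve A 101-point numeric vector, or a data.frame of normalized
#'   curves (one column per angle, as from [time_normalize()]).
#' @return For a vector: one-row data.frame with `initial_angle`,
#'   `peak_max`, `peak_min`, `rom` (deg).  For a data.frame: one row per
#'   angle with an `angle` column prepended.
#' @export
extract_variables <- function(curve) {
  if (is.data.frame(curve)) {
    out <- do.call(rbind, lapply(names(curve), function(a)
      cbind(angle = a, extract_variables(curve[[a]]))))
    rownames(out) <- NULL
    return(out)
  }
  v <- as.numeric(curve)
  if (length(v) != 101) stop("normalized cycle must have exactly 101 points")
  if (any(!is.finite(v))) stop("normalized cycle contains non-finite values")
  data.frame(initial_angle = v[1], peak_max = max(v), peak_min = min(v),
             rom = max(v) - min(v))
}

#' Mean absolute variability (MAV)
#'
#' Intra-subject variability of repeated trials for one angle: at each of
#' the 101 normalized points, the across-trial maximum minus minimum, then
#' averaged over the gait cycle.  A single trial gives 0 by definition.
#'
#' @param trial_curves The subject's trial curves for one angle: a matrix
#'   (trials x 101), a list of 101-point vectors, or a data.frame with one
#'   column per trial.
#' @return MAV, deg (scalar, >= 0).
#' @export
mav <- function(trial_curves) {
  if (is.data.frame(trial_curves)) trial_curves <- t(as.matrix(trial_curves))
  if (is.list(trial_curves)) {
    len <- lengths(trial_curves)
    if (length(unique(len)) > 1) stop("curves of unequal length")
    trial_curves <- do.call(rbind, trial_curves)
  }
  trial_curves <- as.matrix(trial_curves)
  if (ncol(trial_curves) != 101)
    stop("normalized curves must have exactly 101 points, got ",
         ncol(trial_curves))
  if (any(!is.finite(trial_curves))) stop("curves contain non-finite values")
  if (nrow(trial_curves) < 2) return(0)
  mean(apply(trial_curves, 2, max) - apply(trial_curves, 2, min))
}

# Complete cycles (event pairs fully inside the series, >= 4 frames each).
complete_cycles <- function(series, events) {
  et <- if (inherits(events, "gait_events")) events$times else as.numeric(events)
  et <- sort(et)
  if (length(et) < 2) return(list())
  out <- list()
  for (k in seq_len(length(et) - 1)) {
    cyc <- c(et[k], et[k + 1])
    ok <- cyc[1] >= min(series$time) - 1e-9 &&
          cyc[2] <= max(series$time) + 1e-9 &&
          sum(series$time >= cyc[1] - 1e-9 & series$time <= cyc[2] + 1e-9) >= 4
    if (ok) out[[length(out) + 1]] <- cyc
  }
  out
}
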