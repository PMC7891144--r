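# Rhythm analysis: peaks, periods, ratios, phase shifts, profiles.

# indices of the final full 24-hr cycle
final_cycle_window <- function(trajectory, hours = 24) {
  t_end <- trajectory$time[length(trajectory$time)]
  if (t_end - trajectory$time[1] < hours - 1e-9) {
    stop("trajectory must cover at least one full ", hours, " hr cycle",
      call. = FALSE
    )
  }
  which(trajectory$time >= t_end - hours - 1e-9)
}

get_variable <- function(trajectory, variable) {
  if (!variable %in% colnames(trajectory$state)) {
    stop("unknown variable '", variable, "'; available: ",
      paste(colnames(trajectory$state), collapse = ", "),
      call. = FALSE
    )
  }
  trajectory$state[, variable]
}

# discrete argmax refined by a local quadratic through three points
refine_extremum <- function(t, x, i, maximum = TRUE) {
  if (i <= 1 || i >= length(x)) {
    return(t[i])
  }
  y <- x[(i - 1):(i + 1)]
  den <- y[1] - 2 * y[2] + y[3]
  ok <- if (maximum) den < 0 else den > 0
  if (!ok) {
    return(t[i])
  }
  t[i] + 0.5 * (t[i + 1] - t[i]) * (y[1] - y[3]) / den
}

is_flat <- function(x) {
  pk <- max(abs(x))
  pk == 0 || (max(x) - min(x)) < 1e-9 * pk
}

#' Peak Zeitgeber time on the final cycle
#'
#' Locates the maximum of a variable over the final full 24-hr cycle,
#' refines it by local quadratic interpolation (sub-grid accuracy), and
#' returns it modulo 24 as Zeitgeber time (ZT; lights-on at ZT0). A
#' reporting offset can relabel the phase for other tissues, e.g.
#' [ventral_striatum_offset()]; the dynamics are unaffected.
#'
#' @param trajectory a `clock_trajectory` covering at least one full cycle
#'   at grid spacing <= 0.05 hr.
#' @param variable state variable name, e.g. `"PC_N"`.
#' @param zt_offset reporting offset (hr) added to the ZT label.
#' @return Peak time in ZT hours (`[0, 24)`), or `NA` for a flat
#'   (arrhythmic) signal.
#' @export
peak_time <- function(trajectory, variable, zt_offset = 0) {
  w <- final_cycle_window(trajectory)
  t <- trajectory$time[w]
  x <- get_variable(trajectory, variable)[w]
  if (is_flat(x)) {
    return(NA_real_)
  }
  tp <- refine_extremum(t, x, which.max(x))
  (tp + zt_offset) %% 24
}

#' Trough Zeitgeber time on the final cycle
#'
#' @inheritParams peak_time
#' @return Trough time in ZT hours, or `NA` for a flat signal.
#' @export
trough_time <- function(trajectory, variable, zt_offset = 0) {
  w <- final_cycle_window(trajectory)
  t <- trajectory$time[w]
  x <- get_variable(trajectory, variable)[w]
  if (is_flat(x)) {
    return(NA_real_)
  }
  tp <- refine_extremum(t, x, which.min(x), maximum = FALSE)
  (tp + zt_offset) %% 24
}

# refined local maxima of a series, with a midrange prominence filter to
# ignore numerical ripple
find_peaks <- function(t, x) {
  i <- which(diff(sign(diff(x))) == -2) + 1
  if (!length(i)) {
    return(numeric(0))
  }
  thr <- min(x) + 0.3 * (max(x) - min(x))
  i <- i[x[i] > thr]
  vapply(i, function(j) refine_extremum(t, x, j), numeric(1))
}

#' Period estimate from peak-to-peak intervals
#'
#' Finds successive refined peaks of a variable and returns the mean of the
#' last two peak-to-peak intervals. Requires at least three peaks (>= 3
#' cycles of data).
#'
#' @inheritParams peak_time
#' @return Period (hr), or `NA` for an arrhythmic signal.
#' @export
period_estimate <- function(trajectory, variable) {
  t <- trajectory$time
  x <- get_variable(trajectory, variable)
  if (is_flat(x)) {
    return(NA_real_)
  }
  pk <- find_peaks(t, x)
  if (length(pk) < 3) {
    return(NA_real_)
  }
  iv <- diff(pk)
  mean(utils::tail(iv, 2))
}

#' Trough-to-peak ratio on the final cycle
#'
#' @inheritParams peak_time
#' @return `min/max` over the final cycle, in `[0, 1]`; `NA` when the peak
#'   is not positive.
#' @export
trough_peak_ratio <- function(trajectory, variable) {
  w <- final_cycle_window(trajectory)
  x <- get_variable(trajectory, variable)[w]
  if (max(x) <= 0) {
    return(NA_real_)
  }
  min(x) / max(x)
}

#' Windowed phase shift between two trajectories
#'
#' Compares the peak times of a variable in a treated and a control
#' trajectory within successive 24-hr windows of their common time range.
#' Shifts are wrapped to `(-12, 12]` hr; positive values are delays
#' (rightward shifts). Windows in which either signal is flat get `NA`.
#'
#' @param treated,control `clock_trajectory` objects on a common grid
#'   covering at least one full window.
#' @param variable state variable, default nuclear PER.
#' @param window window length (hr).
#' @return Data frame with one row per complete window: `window`,
#'   `t_start`, `control_peak`, `treated_peak`, `shift_hr`.
#' @export
phase_shift <- function(treated, control, variable = "P_N", window = 24) {
  t0 <- max(treated$time[1], control$time[1])
  t1 <- min(
    treated$time[length(treated$time)],
    control$time[length(control$time)]
  )
  if (t1 - t0 < window - 1e-9) {
    stop("trajectories must share at least one full window", call. = FALSE)
  }
  n_win <- floor((t1 - t0) / window + 1e-9)
  res <- data.frame(
    window = seq_len(n_win),
    t_start = t0 + (seq_len(n_win) - 1) * window,
    control_peak = NA_real_, treated_peak = NA_real_,
    shift_hr = NA_real_
  )
  wpeak <- function(tr, a, b) {
    w <- tr$time >= a - 1e-9 & tr$time <= b + 1e-9
    x <- get_variable(tr, variable)[w]
    if (is_flat(x)) {
      return(NA_real_)
    }
    refine_extremum(tr$time[w], x, which.max(x))
  }
  for (k in seq_len(n_win)) {
    a <- res$t_start[k]
    b <- a + window
    pc <- wpeak(control, a, b)
    pt <- wpeak(treated, a, b)
    res$control_peak[k] <- pc
    res$treated_peak[k] <- pt
    if (!is.na(pc) && !is.na(pt)) {
      res$shift_hr[k] <- wrap_half_period(pt - pc, window)
    }
  }
  res
}

wrap_half_period <- function(x, period = 24) {
  h <- period / 2
  w <- ((x + h) %% period) - h
  ifelse(w == -h, h, w) # report exactly half a period as +h, not -h
}

#' Days until re-entrainment after a perturbation
#'
#' Scans the windowed [phase_shift()] series and returns the number of full
#' days before the absolute shift first drops below `tol_hr` and stays
#' below for the rest of the record. A treated run identical to its control
#' re-entrains in 0 days; a run whose phase never settles returns `NA`
#' (the arrhythmicity sentinel).
#'
#' @inheritParams phase_shift
#' @param tol_hr phase tolerance (hr) defining "back in phase".
#' @return Days (integer-valued numeric), or `NA` if the shift never
#'   settles within the simulated horizon.
#' @export
reentrainment_time <- function(treated, control, variable = "P_N",
                               tol_hr = 0.5) {
  ps <- phase_shift(treated, control, variable)
  ok <- !is.na(ps$shift_hr) & abs(ps$shift_hr) < tol_hr
  ok[is.na(ps$shift_hr)] <- FALSE
  # first window from which every later window is in phase
  sustained <- rev(cumprod(rev(ok))) == 1
  if (!any(sustained)) {
    return(NA_real_)
  }
  which(sustained)[1] - 1
}

#' Scaled TH and MAO expression profiles
#'
#' Extracts the final entrained cycle of tyrosine hydroxylase and monoamine
#' oxidase, resamples it on a uniform Zeitgeber grid, and scales each curve
#' to a maximum of exactly 1. These profiles are the model's output
#' contract for driving an external dopamine synthesis/release/reuptake
#' model: multiply that model's TH Vmax by `ETH(t)` and its MAO Vmax by
#' `EMAO(t)` over the day.
#'
#' @param trajectory an entrained `clock_trajectory`.
#' @param dt grid spacing of the output profile (hr).
#' @return An `expression_profile`: data frame with columns `ZT_hr`
#'   (`[0, 24]`), `ETH`, `EMAO`; both curves have maximum 1.
#' @export
expression_profiles <- function(trajectory, dt = 0.05) {
  w <- final_cycle_window(trajectory)
  t <- trajectory$time[w]
  zt_grid <- seq(0, 24, by = dt)
  resample <- function(v) {
    x <- trajectory$state[w, v]
    zt <- t %% 24
    # wrap the cycle onto [0, 24]: order by ZT, duplicate the seam
    o <- order(zt)
    zto <- zt[o]
    xo <- x[o]
    ztx <- c(zto[length(zto)] - 24, zto, zto[1] + 24)
    xx <- c(xo[length(xo)], xo, xo[1])
    y <- stats::approx(ztx, xx, xout = zt_grid, ties = "ordered")$y
    y / max(y)
  }
  structure(
    data.frame(
      ZT_hr = zt_grid,
      ETH = resample("TH"),
      EMAO = resample("MAO")
    ),
    class = c("expression_profile", "data.frame")
  )
}

#' Root mean squared error
#'
#' `sqrt(mean((model - data)^2))` between paired model and data points,
#' used for comparing simulated curves with sparse experimental
#' time-value measurements.
#'
#' @param model_points,data_points numeric vectors of equal length >= 1.
#' @return RMSE value.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(25/2)
#' @export
rmse <- function(model_points, data_points) {
  if (length(model_points) != length(data_points)) {
    stop("model and data vectors must have equal length", call. = FALSE)
  }
  if (length(model_points) < 1) stop("need at least one point", call. = FALSE)
  sqrt(mean((model_points - data_points)^2))
}

#' Per-variable rhythm summary
#'
#' Summarises the final entrained cycle of each state variable: period
#' (peak-to-peak), peak and trough Zeitgeber times, trough-to-peak ratio
#' and amplitude (peak minus trough, nM).
#'
#' @param trajectory a `clock_trajectory` covering >= 3 cycles for the
#'   period column (otherwise period is `NA`).
#' @param variables variables to include (default: all).
#' @param zt_offset reporting offset applied to the ZT labels, e.g. from
#'   [ventral_striatum_offset()].
#' @return Data frame with columns `variable`, `period_hr`, `peak_ZT`,
#'   `trough_ZT`, `trough_peak_ratio`, `amplitude_nM`.
#' @export
rhythm_summary <- function(trajectory,
                           variables = colnames(trajectory$state),
                           zt_offset = 0) {
  w <- final_cycle_window(trajectory)
  rows <- lapply(variables, function(v) {
    x <- trajectory$state[w, v]
    data.frame(
      variable = v,
      period_hr = period_estimate(trajectory, v),
      peak_ZT = peak_time(trajectory, v, zt_offset),
      trough_ZT = trough_time(trajectory, v, zt_offset),
      trough_peak_ratio = trough_peak_ratio(trajectory, v),
      amplitude_nM = max(x) - min(x)
    )
  })
  do.call(rbind, rows)
}

#' Ventral-striatum phase relabelling offset
#'
#' Circadian peak times differ between tissues; comparisons with
#' ventral-striatum expression data place the REV-ERB peak at ZT14. This
#' returns the reporting offset (hr) that maps the entrained REV-ERB peak
#' to ZT14. It relabels ZT axes only; the dynamics are unchanged.
#'
#' @param entrained an entrained `clock_trajectory`.
#' @param target_rev_peak_ZT ZT at which REV-ERB should appear to peak.
#' @return Offset in hours, to pass as `zt_offset`.
#' @export
ventral_striatum_offset <- function(entrained, target_rev_peak_ZT = 14) {
  (target_rev_peak_ZT - peak_time(entrained, "REV")) %% 24
}
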