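#' Light schedules
#'
#' A light schedule maps simulation time to the light multiplier applied to
#' the PER production rate. Three modes:
#' \describe{
#'   \item{`"LD"`}{12:12 light-dark, the sinusoid [light_input()] with
#'     amplitude `xi`; ZT0 = lights-on, dark spans ZT12-24.}
#'   \item{`"DD"`}{constant darkness: a constant multiplier `dd_level`.
#'     The default `dd_level = 1` is the sinusoid's mean, removing the
#'     diurnal modulation without changing the mean drive.}
#'   \item{`"custom"`}{piecewise-linear interpolation of a breakpoint table
#'     with columns `time` (hr) and `l` (multiplier), held constant beyond
#'     the table's range.}
#' }
#' The multiplier must stay positive: `xi < 1` and `dd_level > 0` are
#' enforced.
#'
#' @param mode one of `"LD"`, `"DD"`, `"custom"`.
#' @param xi sinusoid amplitude for LD mode.
#' @param dd_level constant multiplier for DD mode.
#' @param breakpoints data frame with columns `time` and `l` (custom mode).
#' @return An object of class `light_schedule`.
#' @examples
#' ld <- light_schedule("LD")
#' light_value(ld, c(0, 6, 12, 18)) # 1, 5/3, 1, 1/3
#' @export
light_schedule <- function(mode = c("LD", "DD", "custom"), xi = 2 / 3,
                           dd_level = 1, breakpoints = NULL) {
  mode <- match.arg(mode)
  if (mode == "LD" && (xi < 0 || xi >= 1)) {
    stop("xi must lie in [0, 1) so that the light multiplier stays positive",
      call. = FALSE
    )
  }
  if (mode == "DD" && dd_level <= 0) {
    stop("dd_level must be > 0", call. = FALSE)
  }
  if (mode == "custom") {
    if (is.null(breakpoints) ||
      !all(c("time", "l") %in% names(breakpoints)) ||
      nrow(breakpoints) < 1) {
      stop("custom mode needs a breakpoints data frame with columns ",
        "'time' and 'l'",
        call. = FALSE
      )
    }
    if (any(breakpoints$l <= 0)) {
      stop("custom light multipliers must be > 0", call. = FALSE)
    }
    breakpoints <- breakpoints[order(breakpoints$time), , drop = FALSE]
  }
  structure(
    list(
      mode = mode, xi = xi, dd_level = dd_level,
      breakpoints = breakpoints
    ),
    class = "light_schedule"
  )
}

#' Evaluate a light schedule
#'
#' @param schedule a [light_schedule()].
#' @param t time (hr), vectorized. Simulation time is Zeitgeber-anchored:
#'   `t %% 24` is the Zeitgeber time.
#' @return Light multiplier at `t`.
#' @export
light_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "light_schedule"))
  switch(schedule$mode,
    LD = light_input(t, schedule$xi),
    DD = rep_len(schedule$dd_level, length(t)),
    custom = stats::approx(
      schedule$breakpoints$time, schedule$breakpoints$l,
      xout = t, rule = 2
    )$y
  )
}

# fast closure for the integrator hot loop
light_function <- function(schedule) {
  switch(schedule$mode,
    LD = {
      xi <- schedule$xi
      function(t) xi * sin(pi * t / 12) + 1
    },
    DD = {
      lv <- schedule$dd_level
      function(t) lv
    },
    custom = {
      bp <- schedule$breakpoints
      function(t) stats::approx(bp$time, bp$l, xout = t, rule = 2)$y
    }
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  desc <- switch(x$mode,
    LD = sprintf("12:12 sinusoidal light-dark, xi = %.4g", x$xi),
    DD = sprintf("constant darkness, l = %.4g", x$dd_level),
    custom = sprintf("custom, %d breakpoints", nrow(x$breakpoints))
  )
  cat("<light_schedule> ", desc, "\n", sep = "")
  invisible(x)
}
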