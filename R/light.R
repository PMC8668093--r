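#' Define a six-property periodic light waveform
#'
#' Constructs and validates the light profile used throughout the package: a
#' smooth periodic square-ish wave parameterised by period, photoperiod, phase
#' of dawn, twilight duration, amplitude and a constant offset.  The waveform
#' is a sum of hyperbolic-tangent sigmoids, so the light/dark transitions have
#' a finite width (`tw_hours`) instead of an instantaneous switch.
#'
#' The default arguments are the nominal growth-chamber schedule: a 24 h day
#' with 12 h of light at full intensity, sharp (0.05 h) twilights, dawn at
#' t = 0 and no background light.
#'
#' @param pr_hours period of the cycle \eqn{P_r} in hours (> 0).
#' @param ph_hours photoperiod \eqn{P_h} in hours, the light-ON duration per
#'   cycle (0 <= Ph <= Pr).
#' @param dw_hours phase of dawn \eqn{D_w} in hours; positive values advance
#'   the waveform (light begins earlier in clock time).
#' @param tw_hours duration of twilight \eqn{T_w} in hours (> 0); the width of
#'   the sigmoidal light/dark transition.  Use `1e-4` for an effectively ideal
#'   square wave.
#' @param amplitude peak relative intensity \eqn{A} (>= 0, nominal 1 = 100%).
#' @param offset constant background intensity \eqn{\Delta l} (>= 0).
#'
#' @return An object of class `light_profile`: a named list with the six
#'   properties.
#' @examples
#' nominal <- light_profile()
#' evaluate_light(c(0, 6, 18), nominal)
#' @export
light_profile <- function(pr_hours = 24, ph_hours = 12, dw_hours = 0,
                          tw_hours = 0.05, amplitude = 1, offset = 0) {
  p <- list(pr_hours = pr_hours, ph_hours = ph_hours, dw_hours = dw_hours,
            tw_hours = tw_hours, amplitude = amplitude, offset = offset)
  validate_light_profile(p)
  structure(p, class = "light_profile")
}

# Stops with the name of the violated invariant; used by every entry point
# that accepts a profile (including deserialised configs).
validate_light_profile <- function(p) {
  need <- c("pr_hours", "ph_hours", "dw_hours", "tw_hours", "amplitude", "offset")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("light profile is missing field(s): ", paste(missing, collapse = ", "))
  for (f in need) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("light profile field '", f, "' must be a single finite number")
  }
  if (p$pr_hours <= 0) stop("invalid light profile: requires pr_hours > 0")
  if (p$ph_hours < 0 || p$ph_hours > p$pr_hours)
    stop("invalid light profile: requires 0 <= ph_hours <= pr_hours")
  if (p$tw_hours <= 0)
    stop("invalid light profile: requires tw_hours > 0 (use 1e-4 for a square wave)")
  if (p$amplitude < 0) stop("invalid light profile: requires amplitude >= 0")
  if (p$offset < 0) stop("invalid light profile: requires offset >= 0")
  invisible(TRUE)
}

#' Replace properties of a light profile
#'
#' Convenience for sweep construction: returns a copy of `profile` with the
#' named properties substituted and the result re-validated.
#'
#' @param profile a [light_profile()].
#' @param ... named replacements among `pr_hours`, `ph_hours`, `dw_hours`,
#'   `tw_hours`, `amplitude`, `offset`.
#' @return A new `light_profile`.
#' @export
modify_profile <- function(profile, ...) {
  stopifnot(inherits(profile, "light_profile"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(profile))
  if (length(bad)) stop("unknown light profile field(s): ", paste(bad, collapse = ", "))
  profile[names(repl)] <- repl
  validate_light_profile(profile)
  structure(profile, class = "light_profile")
}

#' Evaluate the light waveform
#'
#' Computes the relative light intensity at times `t` (hours).  Writing
#' \eqn{\phi} for the fractional part of \eqn{(t + D_w)/P_r}, the intensity is
#' \deqn{L(t) = \Delta l
#'   + \frac{A}{2}\left[1 + \tanh\frac{P_r\phi}{T_w}\right]
#'   - \frac{A}{2}\left[1 + \tanh\frac{P_r\phi - P_h}{T_w}\right]
#'   + \frac{A}{2}\left[1 + \tanh\frac{P_r\phi - P_r}{T_w}\right],}
#' which plateaus at \eqn{\Delta l + A} during the photoperiod and at
#' \eqn{\Delta l} during the dark phase, with sigmoidal transitions of width
#' about \eqn{T_w} at dawn and dusk.  The third term restores the value at the
#' end-of-period seam so the function is periodic and continuous.
#'
#' @param t numeric vector of times in hours (any real values; the function is
#'   periodic with period `pr_hours`).
#' @param profile a [light_profile()].
#' @return Numeric vector of relative intensities, same length as `t`.
#' @export
evaluate_light <- function(t, profile) {
  validate_light_profile(profile)
  pr <- profile$pr_hours; ph <- profile$ph_hours; tw <- profile$tw_hours
  a <- profile$amplitude; dl <- profile$offset
  phase <- ((t + profile$dw_hours) / pr) %% 1   # fractional part, in [0, 1)
  x <- pr * phase
  dl + (a / 2) * (1 + tanh(x / tw)) -
    (a / 2) * (1 + tanh((x - ph) / tw)) +
    (a / 2) * (1 + tanh((x - pr) / tw))
}

#' Sample the light waveform on a regular grid
#'
#' @param profile a [light_profile()].
#' @param t_start,t_end window in hours (`t_end > t_start`).
#' @param dt grid spacing in hours (> 0).
#' @return A data frame with columns `t_hours` and `intensity`; the grid
#'   starts at `t_start` and steps by `dt` up to `t_end` (inclusive when the
#'   window is a multiple of `dt`).
#' @export
sample_light <- function(profile, t_start, t_end, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  if (t_end <= t_start) stop("t_end must exceed t_start")
  t <- seq(t_start, t_end, by = dt)
  data.frame(t_hours = t, intensity = evaluate_light(t, profile))
}

#' @export
print.light_profile <- function(x, ...) {
  cat("Light profile (relative intensity, hours):\n")
  cat(sprintf("  period Pr = %g h, photoperiod Ph = %g h (duty %.1f%%)\n",
              x$pr_hours, x$ph_hours, 100 * x$ph_hours / x$pr_hours))
  cat(sprintf("  dawn Dw = %g h, twilight Tw = %g h\n", x$dw_hours, x$tw_hours))
  cat(sprintf("  amplitude A = %g, offset dl = %g\n", x$amplitude, x$offset))
  invisible(x)
}

#' @export
as.data.frame.light_profile <- function(x, ...) {
  data.frame(pr_hours = x$pr_hours, ph_hours = x$ph_hours,
             dw_hours = x$dw_hours, tw_hours = x$tw_hours,
             amplitude = x$amplitude, offset = x$offset)
}

#' @export
plot.light_profile <- function(x, t_start = 0, t_end = 2 * x$pr_hours,
                               dt = min(x$tw_hours / 4, 0.05), ...) {
  s <- sample_light(x, t_start, t_end, dt)
  graphics::plot(s$t_hours, s$intensity, type = "l",
                 xlab = "time (h)", ylab = "relative intensity", ...)
  invisible(s)
}
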