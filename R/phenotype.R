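#' Phenotype conversion parameters
#'
#' Constants of the two trajectory-to-phenotype maps.  Hypocotyl length (mm)
#' is \eqn{a_1 \int_0^{P_r} (z(t) - a_2)\,dt} with `z` the ATHB2 expression
#' clamped at \eqn{a_3}; days to flower is the hyperbola
#' \eqn{d_0 + a_4 / (1 - \mathrm{FT}_{area}/a_5)} of the period-integral of
#' FT.  The defaults are the published calibration against photoperiod
#' experiments and are used unchanged throughout.
#'
#' @param d0 asymptotic days to flower at large FT area (days).
#' @param a1 hypocotyl scale (mm per expression-hour).
#' @param a2 ATHB2 baseline subtracted before integration.
#' @param a3 ATHB2 saturation clamp (> 0).
#' @param a4 hyperbola scale for days to flower (days; negative).
#' @param a5 FT-area scale at the hyperbola pole (> 0).
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(d0 = 16.55, a1 = 0.9, a2 = 0.03103, a3 = 0.8,
                             a4 = -2308.141, a5 = 0.02) {
  if (a3 <= 0) stop("a3 must be > 0")
  if (a5 <= 0) stop("a5 must be > 0")
  structure(list(d0 = d0, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5),
            class = "phenotype_params")
}

#' Clamp expression at the saturation level
#'
#' Returns `x` where `x < a3` and `a3` elsewhere, modelling saturation of the
#' downstream response to ATHB2.
#'
#' @param x expression level(s).
#' @param a3 saturation level (> 0).
#' @return Clamped value(s).
#' @export
clamp_expression <- function(x, a3 = 0.8) {
  if (a3 <= 0) stop("a3 must be > 0")
  pmin(x, a3)
}

#' Hypocotyl length from an entrained trajectory
#'
#' Trapezoidal quadrature of the clamped, baseline-subtracted ATHB2 channel
#' over one period, scaled to millimetres:
#' \eqn{a_1 \int_0^{P_r} (\min(ATHB2(t), a_3) - a_2)\,dt}.
#'
#' @param traj a `clock_trajectory` exposing an `ATHB2` species.
#' @param params a [phenotype_params()].
#' @return Length in mm.
#' @export
hypocotyl_length <- function(traj, params = phenotype_params()) {
  z <- clamp_expression(trajectory_species(traj, "ATHB2"), params$a3)
  params$a1 * pracma::trapz(traj$times, z - params$a2)
}

#' Area under the FT expression curve over one period
#'
#' @param traj a `clock_trajectory` exposing an `FT` species.
#' @return Trapezoidal integral of FT(t) over `[0, Pr]` (expression-hours).
#' @export
ft_area <- function(traj) {
  pracma::trapz(traj$times, trajectory_species(traj, "FT"))
}

#' Days to flower from an FT period-integral
#'
#' Evaluates the hyperbolic map
#' \eqn{d_0 + a_4 / (1 - \mathrm{FT}_{area}/a_5)}.  For FT areas above
#' \eqn{a_5} the map decreases monotonically towards the floor \eqn{d_0};
#' below \eqn{a_5} (abnormally low FT, e.g. near-zero photoperiod) the value
#' is negative, outside the calibration range of the constants.  Such values
#' are returned unmodified and flagged, never suppressed.
#'
#' @param ft_area_value non-negative FT period-integral (expression-hours).
#' @param params a [phenotype_params()].
#' @return A list with `days` (numeric) and `flags` (character vector,
#'   subset of `"NEGATIVE_DAYS"`, `"FT_AREA_BELOW_A5"`).
#' @export
days_to_flower <- function(ft_area_value, params = phenotype_params()) {
  if (ft_area_value < 0) stop("ft_area_value must be >= 0")
  if (abs(ft_area_value - params$a5) < 1e-12)
    stop("FT area coincides with the pole of the flowering-time map (a5 = ",
         params$a5, ")")
  days <- params$d0 + params$a4 / (1 - ft_area_value / params$a5)
  flags <- character(0)
  if (ft_area_value < params$a5) flags <- c(flags, "FT_AREA_BELOW_A5")
  if (days < 0) flags <- c(flags, "NEGATIVE_DAYS")
  list(days = days, flags = flags)
}

#' Convert a trajectory to its phenotypes
#'
#' Bundles [ft_area()], [days_to_flower()] and [hypocotyl_length()], and —
#' when the trajectory carries its light profile — the effective light
#' duration and LED energy consumption of the schedule.
#'
#' @param traj a `clock_trajectory`.
#' @param params a [phenotype_params()].
#' @param energy an [energy_params()] used for the annual energy figure.
#' @return An object of class `phenotype_result` with fields
#'   `days_to_flower`, `hypocotyl_mm`, `ft_area`, `eldf_hours`,
#'   `energy_mwh_per_year` and `flags`.
#' @export
phenotypes <- function(traj, params = phenotype_params(),
                       energy = energy_params()) {
  area <- ft_area(traj)
  dtf <- days_to_flower(area, params)
  hyp <- hypocotyl_length(traj, params)
  pr <- traj$profile$pr_hours
  ph <- traj$profile$ph_hours
  structure(list(
    days_to_flower = dtf$days,
    hypocotyl_mm = hyp,
    ft_area = area,
    eldf_hours = effective_light_duration(dtf$days, ph, pr),
    energy_mwh_per_year = energy_consumption(traj$profile$amplitude, ph, pr, energy),
    flags = dtf$flags,
    profile = traj$profile
  ), class = "phenotype_result")
}

#' @export
print.phenotype_result <- function(x, ...) {
  cat(sprintf("Days to flower : %.2f days%s\n", x$days_to_flower,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]") else ""))
  cat(sprintf("Hypocotyl      : %.2f mm\n", x$hypocotyl_mm))
  cat(sprintf("FT area        : %.4f expression-hours\n", x$ft_area))
  cat(sprintf("Effective light: %.2f h of light-ON until flowering\n", x$eldf_hours))
  cat(sprintf("LED energy     : %.2f MWh/year\n", x$energy_mwh_per_year))
  invisible(x)
}

#' @export
as.data.frame.phenotype_result <- function(x, ...) {
  data.frame(days_to_flower = x$days_to_flower, hypocotyl_mm = x$hypocotyl_mm,
             ft_area = x$ft_area, eldf_hours = x$eldf_hours,
             energy_mwh_per_year = x$energy_mwh_per_year,
             flags = paste(x$flags, collapse = ";"))
}

#' Effective light duration for flowering
#'
#' Total light-ON hours accumulated until flowering: days to flower converted
#' to hours and scaled by the duty cycle, `days * 24 * (ph/pr)`.
#'
#' @param days_to_flower days to flower (finite).
#' @param ph photoperiod in hours (0 <= ph <= pr).
#' @param pr period in hours (> 0).
#' @return Hours of light.
#' @export
effective_light_duration <- function(days_to_flower, ph, pr) {
  if (pr <= 0) stop("pr must be > 0")
  if (ph < 0 || ph > pr) stop("requires 0 <= ph <= pr")
  if (!is.finite(days_to_flower)) stop("days_to_flower must be finite")
  days_to_flower * 24 * (ph / pr)
}

#' LED driver parameters for the energy model
#'
#' Defaults describe a 500 W constant-voltage LED driver: 48 V rated output,
#' 10.5 A maximum current, 90.5% AC-DC conversion efficiency, evaluated over
#' a 365-day year.
#'
#' @param v_out rated output voltage (V).
#' @param i_out maximum rated current (A).
#' @param eta_led conversion efficiency in (0, 1].
#' @param n_days days per year.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(v_out = 48, i_out = 10.5, eta_led = 0.905,
                          n_days = 365) {
  if (eta_led <= 0 || eta_led > 1) stop("eta_led must lie in (0, 1]")
  structure(list(v_out = v_out, i_out = i_out, eta_led = eta_led,
                 n_days = n_days), class = "energy_params")
}

#' Annual LED energy consumption of a light schedule
#'
#' \deqn{E_c = \frac{V_{out} I_{out} A (P_h/P_r) (N \times 24)}
#'                  {\eta_{LED} \times 10^6}\ \mathrm{MWh/year}.}
#' Intensity is assumed proportional to drive current, so the amplitude
#' scales the electrical power linearly; offset and twilight do not enter.
#'
#' @param amplitude relative light intensity A (>= 0).
#' @param ph photoperiod in hours.
#' @param pr period in hours (> 0).
#' @param params an [energy_params()].
#' @return Energy in MWh/year.
#' @export
energy_consumption <- function(amplitude, ph, pr, params = energy_params()) {
  if (pr <= 0) stop("pr must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (params$eta_led <= 0 || params$eta_led > 1) stop("eta_led must lie in (0, 1]")
  params$v_out * params$i_out * amplitude * (ph / pr) * (params$n_days * 24) /
    (params$eta_led * 1e6)
}
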