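#' Simulation settings for the entrainment protocol
#'
#' @param entrain_cycles minimum number of light cycles integrated before the
#'   recorded period (>= 1).
#' @param max_cycles upper bound on cycles while waiting for cycle-to-cycle
#'   convergence.
#' @param convergence_tol relative sup-norm tolerance between consecutive
#'   cycle-start states declaring the limit cycle reached.
#' @param solver_rel_tol,solver_abs_tol relative/absolute tolerances passed to
#'   the stiff-capable integrator ([deSolve::lsoda]).
#' @param output_dt output grid spacing in hours for the recorded period;
#'   0.05 h resolves the sharpest default twilight.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(entrain_cycles = 12, max_cycles = 40,
                         convergence_tol = 1e-4,
                         solver_rel_tol = 1e-6, solver_abs_tol = 1e-9,
                         output_dt = 0.05) {
  if (entrain_cycles < 1) stop("entrain_cycles must be >= 1")
  if (max_cycles < entrain_cycles) stop("max_cycles must be >= entrain_cycles")
  if (convergence_tol <= 0) stop("convergence_tol must be > 0")
  if (output_dt <= 0) stop("output_dt must be > 0")
  structure(list(entrain_cycles = as.integer(entrain_cycles),
                 max_cycles = as.integer(max_cycles),
                 convergence_tol = convergence_tol,
                 solver_rel_tol = solver_rel_tol,
                 solver_abs_tol = solver_abs_tol,
                 output_dt = output_dt),
            class = "sim_settings")
}

#' Relative sup-norm difference between two cycle-start states
#'
#' The convergence measure of the entrainment loop:
#' `max_i |a_i - b_i| / (1 + |a_i|)`.  Zero if and only if the states are
#' identical.
#'
#' @param cycle_a,cycle_b numeric state vectors of equal length.
#' @return A single non-negative number.
#' @export
entrainment_residual <- function(cycle_a, cycle_b) {
  if (length(cycle_a) != length(cycle_b))
    stop("state length mismatch: ", length(cycle_a), " vs ", length(cycle_b))
  if (!length(cycle_a)) return(0)
  max(abs(cycle_a - cycle_b) / (1 + abs(cycle_a)))
}

# One period of integration with dense output on the settings grid.
integrate_cycle <- function(state, profile, model, settings, record = FALSE) {
  pr <- profile$pr_hours
  times <- if (record) {
    grid <- seq(0, pr, by = settings$output_dt)
    if (grid[length(grid)] < pr) grid <- c(grid, pr)
    grid
  } else c(0, pr)
  light_fun <- function(t) evaluate_light(t, profile)
  rhs_fun <- function(t, y, parms) list(model$rhs(t, y, light_fun(t), parms))
  # cap the internal step so the solver can never leap over a light/dark
  # transition of width ~Tw (error control then resolves it)
  hmax <- min(0.25, max(profile$tw_hours, 0.01))
  sol <- deSolve::lsoda(y = state, times = times, func = rhs_fun,
                        parms = model$params,
                        rtol = settings$solver_rel_tol,
                        atol = settings$solver_abs_tol,
                        hmax = hmax)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed (lsoda istate ", attr(sol, "istate")[1L], ")")
  sol
}

#' Simulate a clock model entrained to a light profile
#'
#' Runs the entrain-and-record protocol: integrate from the model's
#' documented initial state one light cycle at a time, monitor the relative
#' sup-norm difference between consecutive cycle-start states
#' ([entrainment_residual()]), and once at least `entrain_cycles` cycles have
#' elapsed and the residual has dropped below `convergence_tol` (extending up
#' to `max_cycles` if needed) record one final period on the dense output
#' grid.  Species are floored at zero after each cycle to absorb solver
#' undershoot within the absolute tolerance.
#'
#' @param profile a [light_profile()].
#' @param settings a [sim_settings()].
#' @param model a [clock_model()] or built-in model name (see
#'   [get_clock_model()]); default is the compact coincidence model.
#' @return An object of class `clock_trajectory`: a list with `times` (hours
#'   over one period `[0, Pr]`), `species` (time x species matrix), `labels`,
#'   `profile`, and the entrainment diagnostics `cycles` and `residual`.
#' @examples
#' traj <- simulate_entrained(light_profile(), model = "toy",
#'                            settings = sim_settings(output_dt = 0.1))
#' phenotypes(traj)
#' @export
simulate_entrained <- function(profile, settings = sim_settings(),
                               model = "coincidence") {
  validate_light_profile(profile)
  stopifnot(inherits(settings, "sim_settings"))
  model <- get_clock_model(model)

  state <- model$init
  residual <- Inf
  cycles <- 0L
  while (cycles < settings$max_cycles) {
    sol <- integrate_cycle(state, profile, model, settings)
    new_state <- sol[nrow(sol), -1L]
    new_state[new_state < 0] <- 0          # solver undershoot floor
    cycles <- cycles + 1L
    residual <- entrainment_residual(state, new_state)
    state <- new_state
    if (cycles >= settings$entrain_cycles && residual < settings$convergence_tol)
      break
  }
  if (residual >= settings$convergence_tol)
    stop(sprintf(
      "entrainment did not converge within %d cycles (final residual %.3g > tol %.3g)",
      settings$max_cycles, residual, settings$convergence_tol))

  sol <- integrate_cycle(state, profile, model, settings, record = TRUE)
  species <- sol[, -1L, drop = FALSE]
  species[species < 0] <- 0
  colnames(species) <- model$species
  structure(list(times = sol[, 1L], species = species, labels = model$species,
                 profile = profile, model_name = model$name,
                 cycles = cycles, residual = residual, settings = settings),
            class = "clock_trajectory")
}

#' Extract one species' time course from a trajectory
#'
#' @param traj a `clock_trajectory` (from [simulate_entrained()] or
#'   [make_trajectory()]).
#' @param label species label, e.g. `"FT"` or `"ATHB2"`.
#' @return Numeric vector over `traj$times`.
#' @export
trajectory_species <- function(traj, label) {
  stopifnot(inherits(traj, "clock_trajectory"))
  if (!label %in% traj$labels)
    stop("trajectory has no species labelled '", label, "'")
  traj$species[, label]
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat(sprintf("Entrained trajectory: model '%s', %d species, one period of %g h (%d points)\n",
              x$model_name, ncol(x$species), x$profile$pr_hours, length(x$times)))
  if (!is.null(x$cycles))
    cat(sprintf("  entrained after %d cycles, residual %.3g\n", x$cycles, x$residual))
  invisible(x)
}

#' @export
summary.clock_trajectory <- function(object, ...) {
  rng <- t(apply(object$species, 2L, range))
  colnames(rng) <- c("min", "max")
  out <- list(profile = object$profile, model = object$model_name,
              cycles = object$cycles, residual = object$residual,
              species_range = rng)
  class(out) <- "summary.clock_trajectory"
  out
}

#' @export
print.summary.clock_trajectory <- function(x, ...) {
  cat(sprintf("Model '%s' entrained to Pr = %g h, Ph = %g h (%d cycles, residual %.3g)\n",
              x$model, x$profile$pr_hours, x$profile$ph_hours, x$cycles, x$residual))
  print(round(x$species_range, 5))
  invisible(x)
}

#' @export
plot.clock_trajectory <- function(x, species = c("FT", "ATHB2"), ...) {
  species <- intersect(species, x$labels)
  y <- x$species[, species, drop = FALSE]
  graphics::matplot(x$times, y, type = "l", lty = 1,
                    xlab = "time in cycle (h)", ylab = "relative expression", ...)
  graphics::legend("topleft", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

#' @export
as.data.frame.clock_trajectory <- function(x, ...) {
  data.frame(t_hours = x$times, x$species, check.names = FALSE)
}
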