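#' Generate a synthetic expression trajectory
#'
#' Builds a `clock_trajectory` whose `FT` and `ATHB2` channels follow a
#' waveform with an analytically known period-integral, so the phenotype
#' converters and the sweep machinery can be tested without any ODE model.
#' Kinds:
#' \describe{
#'   \item{`constant`}{both channels identically `mean`; area `mean * period`.}
#'   \item{`sinusoid`}{`mean + amplitude * sin(2*pi*(t - phase)/period)`;
#'     area `mean * period`.}
#'   \item{`triangle`}{symmetric triangle wave oscillating between
#'     `mean - amplitude` and `mean + amplitude`; area `mean * period`.}
#'   \item{`toy_clock`}{delegates to [make_toy_clock_trajectory()] with the
#'     supplied `profile`.}
#' }
#' Optional seeded Gaussian noise is added independently to both channels and
#' the result is clipped at zero (for noiseless specs keep `mean >=
#' amplitude` so clipping never engages and the quoted area is exact).
#'
#' @param kind one of `"constant"`, `"sinusoid"`, `"triangle"`, `"toy_clock"`.
#' @param mean,amplitude waveform level and half-range (expression units).
#' @param phase horizontal shift in hours.
#' @param period period in hours (> 0).
#' @param dt grid spacing in hours (> 0).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed integer seed used when `noise_sd > 0`.
#' @param profile light profile attached to the trajectory (and, for
#'   `toy_clock`, driving the dynamics); defaults to a half-`period`
#'   photoperiod schedule.
#' @param k relaxation rate for the `toy_clock` kind.
#' @return A `clock_trajectory`; for the closed-form kinds the element
#'   `known_area` holds the analytic period-integral of each channel.
#' @export
make_trajectory <- function(kind = c("constant", "sinusoid", "triangle", "toy_clock"),
                            mean = 0.1, amplitude = 0.05, phase = 0,
                            period = 24, dt = 0.05, noise_sd = 0, seed = 1L,
                            profile = NULL, k = 1) {
  choices <- c("constant", "sinusoid", "triangle", "toy_clock")
  if (!is.character(kind) || !all(kind %in% choices))
    stop("unknown trajectory kind: ", deparse(kind))
  kind <- match.arg(kind, choices)
  if (period <= 0) stop("period must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(profile))
    profile <- light_profile(pr_hours = period, ph_hours = period / 2)

  if (kind == "toy_clock")
    return(make_toy_clock_trajectory(profile, k = k, dt = dt))

  t <- seq(0, period, by = dt)
  if (t[length(t)] < period) t <- c(t, period)
  base <- switch(kind,
    constant = rep(mean, length(t)),
    sinusoid = mean + amplitude * sin(2 * pi * (t - phase) / period),
    triangle = {
      u <- ((t - phase) / period) %% 1
      mean + amplitude * (4 * abs(u - 0.5) - 1)
    })
  chan <- cbind(FT = base, ATHB2 = base)
  if (noise_sd > 0) {
    rs <- local_seed(seed)
    on.exit(restore_seed(rs), add = TRUE)
    chan <- chan + matrix(stats::rnorm(length(chan), sd = noise_sd), nrow(chan))
  }
  chan[chan < 0] <- 0
  structure(list(times = t, species = chan, labels = c("FT", "ATHB2"),
                 profile = profile, model_name = paste0("synthetic_", kind),
                 cycles = NA_integer_, residual = 0,
                 known_area = c(FT = mean * period, ATHB2 = mean * period)),
            class = "clock_trajectory")
}

# Seed the RNG locally and hand back whatever state the caller had.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Toy driven-clock trajectory at periodic steady state
#'
#' Integrates the miniature entrainment testbed `dx/dt = k (L(t) - x)` under
#' the given light profile until the cycle-to-cycle state change is
#' negligible, then records one period.  Used to exercise every downstream
#' stage with dynamics whose steady state is known in closed form (duty-cycle
#' mean for a square wave; dawn-shift equivariance exactly).
#'
#' @param profile a [light_profile()].
#' @param k relaxation rate in 1/h (> 0).
#' @param dt output grid spacing in hours.
#' @return A `clock_trajectory` with `FT` and `ATHB2` both equal to `x(t)`.
#' @export
make_toy_clock_trajectory <- function(profile, k = 1, dt = 0.05) {
  stopifnot(k > 0)
  # per-cycle contraction is exp(-k * Pr); size max_cycles so even slow rates
  # reach the 1e-8 residual
  cycles_needed <- ceiling(20 / max(k * profile$pr_hours, 1e-3)) + 10
  simulate_entrained(profile,
                     settings = sim_settings(entrain_cycles = 3,
                                             max_cycles = max(60, cycles_needed),
                                             convergence_tol = 1e-8,
                                             output_dt = dt),
                     model = toy_clock_model(k))
}

#' Cartesian grid of light profiles
#'
#' Expands per-property value lists against a baseline profile, dropping
#' combinations that violate the profile invariants (in particular
#' `ph_hours <= pr_hours`).  Ordering is the standard row-major expansion of
#' the value lists, so grids are stable across runs.
#'
#' @param ranges named list of value vectors; names among `pr_hours`,
#'   `ph_hours`, `dw_hours`, `tw_hours`, `amplitude`, `offset`.
#' @param baseline profile supplying the unswept properties.
#' @param ph_half_pr if `TRUE`, ignore any `ph_hours` entry and set
#'   `ph_hours = pr_hours / 2` for every combination (the equal light-dark
#'   convention for period sweeps).
#' @return A list of [light_profile()] objects with attribute `n_skipped`
#'   counting invalid combinations.
#' @export
make_profile_grid <- function(ranges, baseline = light_profile(),
                              ph_half_pr = FALSE) {
  stopifnot(is.list(ranges))
  bad <- setdiff(names(ranges), names(baseline))
  if (length(bad)) stop("unknown light profile field(s): ", paste(bad, collapse = ", "))
  if (any(!lengths(ranges))) stop("each range must be non-empty")
  combos <- expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE)[rev(names(ranges))]
  profiles <- list()
  skipped <- 0L
  for (i in seq_len(nrow(combos))) {
    repl <- as.list(combos[i, , drop = FALSE])
    if (ph_half_pr) {
      pr <- if ("pr_hours" %in% names(repl)) repl$pr_hours else baseline$pr_hours
      repl$ph_hours <- pr / 2
    }
    p <- tryCatch(do.call(modify_profile, c(list(baseline), repl)),
                  error = function(e) NULL)
    if (is.null(p)) skipped <- skipped + 1L else profiles[[length(profiles) + 1L]] <- p
  }
  attr(profiles, "n_skipped") <- skipped
  profiles
}
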