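#' Define a clock model for the simulation driver
#'
#' A clock model bundles everything [simulate_entrained()] needs: the species
#' labels, the right-hand side of the ODE system, a documented initial state
#' and a parameter set.  Light enters the dynamics only through the waveform
#' value `L(t)` supplied by [evaluate_light()], so any model definition —
#' including a user transcription of a published gene-network model — can be
#' driven by the same entrainment protocol.  Two definitions ship with the
#' package: [toy_clock_model()] and [coincidence_model()].
#'
#' @param name short identifier.
#' @param species character vector of species labels; must contain `"FT"` and
#'   `"ATHB2"` for the phenotype converters to work.
#' @param rhs `function(t, state, light, params)` returning `d(state)/dt`;
#'   `light` is the scalar waveform value at `t`.
#' @param init named numeric vector, the documented initial state (names must
#'   equal `species`).
#' @param params named list of kinetic parameters passed to `rhs`.
#' @param description one-line provenance note.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, species, rhs, init, params = list(),
                        description = "") {
  stopifnot(is.character(species), length(species) >= 1,
            is.function(rhs), is.numeric(init))
  if (!all(c("FT", "ATHB2") %in% species))
    stop("clock model must expose species 'FT' and 'ATHB2'")
  if (length(init) != length(species))
    stop("init length (", length(init), ") must match species count (",
         length(species), ")")
  names(init) <- species
  structure(list(name = name, species = species, rhs = rhs, init = init,
                 params = params, description = description),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Clock model '", x$name, "': ", length(x$species), " species\n", sep = "")
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a model's right-hand side under a light profile
#'
#' Thin validated wrapper used by the integrator and by tests: computes
#' `d(state)/dt` at time `t` with the light value taken from
#' [evaluate_light()].
#'
#' @param t time in hours.
#' @param state numeric state vector; length must match the model.
#' @param profile a [light_profile()].
#' @param model a [clock_model()].
#' @return Numeric derivative vector of the same length as `state`.
#' @export
ode_rhs <- function(t, state, profile, model) {
  stopifnot(inherits(model, "clock_model"))
  if (length(state) != length(model$species))
    stop("state length (", length(state), ") does not match model species count (",
         length(model$species), ")")
  model$rhs(t, state, evaluate_light(t, profile), model$params)
}

#' Toy driven relaxation clock
#'
#' The minimal entrainable system `dx/dt = k (L(t) - x)`: a single species
#' relaxing towards the instantaneous light level.  Its periodic steady state
#' is known analytically (for an ideal square wave the cycle mean of `x`
#' equals the duty-cycle mean of the light, `offset + amplitude * Ph/Pr`),
#' which makes it the workhorse for testing the entrainment driver, the
#' phenotype converters and the sweep engine independently of any
#' gene-network model.  Both the `FT` and `ATHB2` channels report `x`.
#'
#' @param k relaxation rate in 1/h (> 0).
#' @return A [clock_model()] with species `FT` and `ATHB2` slaved to the one
#'   dynamical variable.
#' @export
toy_clock_model <- function(k = 1) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  clock_model(
    name = "toy",
    species = c("FT", "ATHB2"),
    rhs = function(t, state, light, params) {
      d <- params$k * (light - state[1L])
      c(d, d)
    },
    init = c(FT = 0, ATHB2 = 0),
    params = list(k = k),
    description = "linear driven relaxation dx/dt = k (L(t) - x); analytic testbed"
  )
}

# Default kinetic parameters of the compact coincidence model.  Units: rates
# in 1/h, thresholds in the relative expression units of the state variables.
# Calibrated once against canonical Arabidopsis photoperiod physiology (see
# the methods vignette); not adjusted thereafter.
coincidence_default_params <- function() {
  list(
    # light responses
    k_light     = 0.02,  # half-saturation of the saturating photoreceptor response
    k_acute     = 0.01,  # half-saturation of the steep response (PIF arm)
    k_co_gate   = 0.80,  # threshold of the strong-light gate on the CO protein
    # dark accumulator
    p_dark      = 0.30, p_lightdeg = 6.0,
    # morning gene (LHY/CCA1-like): sharp acute dawn pulse
    v_m0        = 0.05, v_m_acute = 8.0, K_E = 0.25, d_mm = 1.00,
    t_m         = 1.0,  d_m = 0.60,
    # timer chain (low-pass of the morning protein)
    k_timer     = 0.22,
    # evening complex
    v_e         = 2.40, K_T = 0.25, d_em = 0.60,
    t_e         = 1.0,  d_e0 = 0.60, k_e_light = 3.0,
    # CO transcription window (late day: timer high, morning protein and
    # evening complex both low)
    v_co        = 1.50, K_T2 = 0.25, K_M = 0.25, K_E3 = 0.30, d_com = 0.45,
    # CO protein: translated in strong light, degraded otherwise
    t_co        = 1.0,  g_co_light = 0.25, g_co_dark = 2.5,
    # FT output
    v_ft        = 1.45, K_ft = 0.80, v_ft0 = 0.0004, d_ft = 0.50,
    # PIF arm (slow night accumulation, light-degraded)
    v_pif       = 0.28, K_E2 = 0.25, d_pif = 0.05, d_pif_light = 6.0,
    # ATHB2 output
    v_a         = 0.70, K_a = 2.50, v_a0 = 0.062, d_a = 0.80
  )
}

coincidence_rhs <- function(t, y, light, p) {
  P <- y[1L]; Mm <- y[2L]; M <- y[3L]; T1 <- y[4L]; T2 <- y[5L]
  Em <- y[6L]; E <- y[7L]; COm <- y[8L]; CO <- y[9L]
  FT <- y[10L]; PIF <- y[11L]; A2 <- y[12L]

  ls  <- light / (p$k_light + light)   # saturating photoreceptor signal
  la  <- light / (p$k_acute + light)   # steep signal: sensitive to faint light
  l8 <- light^8
  lg  <- l8 / (p$k_co_gate^8 + l8)     # high-threshold gate (strong light only)

  hill2 <- function(x, K) { x2 <- x * x; x2 / (K * K + x2) }
  rep2  <- function(x, K) { K2 <- K * K; K2 / (K2 + x * x) }

  dP   <- p$p_dark * (1 - P) * (1 - ls) - p$p_lightdeg * P * ls
  dMm  <- (p$v_m0 + p$v_m_acute * ls * P) * rep2(E, p$K_E) - p$d_mm * Mm
  dM   <- p$t_m * Mm - p$d_m * M
  dT1  <- p$k_timer * (M - T1)
  dT2  <- p$k_timer * (T1 - T2)
  dEm  <- p$v_e * hill2(T2, p$K_T) - p$d_em * Em
  dE   <- p$t_e * Em - p$d_e0 * (1 + p$k_e_light * ls) * E
  dCOm <- p$v_co * hill2(T2, p$K_T2) * rep2(M, p$K_M) * rep2(E, p$K_E3) -
    p$d_com * COm
  dCO  <- p$t_co * COm * lg - (p$g_co_light + p$g_co_dark * (1 - lg)) * CO
  dFT  <- p$v_ft * hill2(CO, p$K_ft) + p$v_ft0 - p$d_ft * FT
  dPIF <- p$v_pif * hill2(E, p$K_E2) - (p$d_pif + p$d_pif_light * la) * PIF
  dA2  <- p$v_a * hill2(PIF, p$K_a) + p$v_a0 - p$d_a * A2

  c(dP, dMm, dM, dT1, dT2, dEm, dE, dCOm, dCO, dFT, dPIF, dA2)
}

#' Compact light-coincidence clock model
#'
#' A package-authored 12-species reduction of the Arabidopsis circadian
#' clock with its flowering and hypocotyl-elongation output pathways.  It
#' reproduces the architecture of published clock + output models: a dark
#' accumulator gives acute dawn induction of a morning gene, whose protein
#' feeds a kinetic timer chain driving an evening complex (closing a
#' morning/evening negative feedback loop); CO mRNA is transcribed in a
#' late-day window and the CO protein is stabilised only in light, so FT
#' production requires coincidence of the window with the photoperiod
#' (external coincidence); a PIF-like factor accumulates in darkness and
#' drives ATHB2.  This is not a transcription of any published equation set;
#' it is the package's own reduced model, calibrated once to canonical
#' Arabidopsis photoperiod physiology (see the methods vignette).  The driver
#' accepts any [clock_model()], so a transcription of a full published
#' gene-network model can be substituted without touching the rest of the
#' pipeline.
#'
#' @param params optional named list overriding entries of the default
#'   kinetic parameter set.
#' @return A [clock_model()] with 12 species including `FT` and `ATHB2`.
#' @export
coincidence_model <- function(params = list()) {
  p <- coincidence_default_params()
  bad <- setdiff(names(params), names(p))
  if (length(bad)) stop("unknown coincidence model parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(params)] <- params
  init <- c(P = 0.5, Mm = 0.1, M = 0.2, T1 = 0.2, T2 = 0.2,
            Em = 0.1, E = 0.2, COm = 0.05, CO = 0.01,
            FT = 0.01, PIF = 0.1, ATHB2 = 0.05)
  clock_model(
    name = "coincidence",
    species = names(init),
    rhs = coincidence_rhs,
    init = init,
    params = p,
    description = "compact 12-ODE coincidence clock + FT/ATHB2 output pathways (package-authored)"
  )
}

#' Resolve a clock model by name
#'
#' @param model a [clock_model()] (returned unchanged) or one of the built-in
#'   names `"coincidence"` (default) and `"toy"`.
#' @return A [clock_model()].
#' @export
get_clock_model <- function(model = "coincidence") {
  if (inherits(model, "clock_model")) return(model)
  if (is.character(model) && length(model) == 1L) {
    return(switch(model,
                  coincidence = coincidence_model(),
                  toy = toy_clock_model(),
                  stop("unknown clock model '", model, "'")))
  }
  stop("model must be a clock_model object or a built-in model name")
}
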