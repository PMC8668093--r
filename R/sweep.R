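#' Recommendation criteria for light-schedule selection
#'
#' Thresholds and preferences used when ranking sweep rows.  A row is
#' feasible when neither phenotype exceeds its threshold (by default the
#' nominal baseline values, so "no worse than the standard schedule").
#' Preferences are soft: the natural 24 h period, and the absence of constant
#' background light, are each enforced only when a row satisfying them lies
#' within `comparable_days` of the unconstrained optimum — a distant-optimal
#' exotic schedule never vetoes a near-optimal practical one.
#'
#' @param max_days feasibility cap on days to flower; `NULL` = use the
#'   baseline row's value.
#' @param max_hypocotyl feasibility cap on hypocotyl length (mm); `NULL` =
#'   baseline value.
#' @param prefer_natural_period prefer `pr_hours == natural_period` rows.
#' @param prefer_no_offset prefer rows without background light
#'   (`offset == 0`).
#' @param natural_period the natural diurnal period (hours).
#' @param comparable_days margin (days) within which two schedules count as
#'   phenotypically comparable.
#' @param comparable_mm analogous margin for hypocotyl length.
#' @return An object of class `rec_criteria`.
#' @export
rec_criteria <- function(max_days = NULL, max_hypocotyl = NULL,
                         prefer_natural_period = TRUE,
                         prefer_no_offset = TRUE,
                         natural_period = 24,
                         comparable_days = 1.5, comparable_mm = 0.1) {
  if (!is.null(max_days) && max_days <= 0) stop("max_days must be positive")
  if (!is.null(max_hypocotyl) && max_hypocotyl <= 0)
    stop("max_hypocotyl must be positive")
  structure(list(max_days = max_days, max_hypocotyl = max_hypocotyl,
                 prefer_natural_period = prefer_natural_period,
                 prefer_no_offset = prefer_no_offset,
                 natural_period = natural_period,
                 comparable_days = comparable_days,
                 comparable_mm = comparable_mm),
            class = "rec_criteria")
}

#' Create a simulation cache
#'
#' Trajectory phenotypes are cached by light-profile key so overlapping grids
#' (e.g. a collective grid sharing cells with a single-property sweep) re-use
#' simulations.  Pass the same cache object to successive sweep calls.
#'
#' @return An environment used as a mutable cache.
#' @export
new_sim_cache <- function() new.env(parent = emptyenv())

profile_key <- function(profile, model_name, settings) {
  paste(model_name,
        paste(format(unlist(profile[c("pr_hours", "ph_hours", "dw_hours",
                                      "tw_hours", "amplitude", "offset")]),
                     digits = 15), collapse = "|"),
        format(settings$output_dt, digits = 15),
        format(settings$convergence_tol, digits = 15), sep = "|")
}

# Simulate one profile and convert to phenotypes, via the cache when given.
# Returns a one-row data frame; on simulation failure the phenotype columns
# are NA and status records the error message.
evaluate_profile_row <- function(profile, settings, model, phen, energy,
                                 cache = NULL) {
  model <- get_clock_model(model)
  key <- profile_key(profile, model$name, settings)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  row <- tryCatch({
    traj <- simulate_entrained(profile, settings, model)
    ph <- phenotypes(traj, phen, energy)
    cbind(as.data.frame(profile), as.data.frame(ph),
          cycles = traj$cycles, residual = traj$residual,
          status = "ok", stringsAsFactors = FALSE)
  }, error = function(e) {
    cbind(as.data.frame(profile),
          data.frame(days_to_flower = NA_real_, hypocotyl_mm = NA_real_,
                     ft_area = NA_real_, eldf_hours = NA_real_,
                     energy_mwh_per_year = NA_real_, flags = "",
                     cycles = NA_integer_, residual = NA_real_,
                     status = paste0("error: ", conditionMessage(e)),
                     stringsAsFactors = FALSE))
  })
  if (!is.null(cache)) cache[[key]] <- row
  row
}

sweep_property_field <- c(photoperiod = "ph_hours", offset = "offset",
                          amplitude = "amplitude", dawn = "dw_hours",
                          twilight = "tw_hours", period = "pr_hours",
                          period_with_half_photoperiod = "pr_hours")

#' Default grids for the single-property sweeps
#'
#' The standard value lists: photoperiod 0–24 h step 1; offset 0–5% step 1%;
#' amplitude 0.90–1.10 step 0.02; dawn -6 to 6 h step 2; twilight 0.01–3 h on
#' a log-then-linear ladder; period 16–32 h step 2 (with `ph = pr/2` when the
#' property is `period_with_half_photoperiod`).
#'
#' @param property sweep property name.
#' @return Numeric vector of values.
#' @export
default_sweep_values <- function(property) {
  switch(property,
         photoperiod = 0:24,
         offset = seq(0, 0.05, by = 0.01),
         amplitude = seq(0.90, 1.10, by = 0.02),
         dawn = seq(-6, 6, by = 2),
         twilight = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 1.5, 2, 2.5, 3),
         period = seq(16, 32, by = 2),
         period_with_half_photoperiod = seq(16, 32, by = 2),
         stop("unknown sweep property '", property, "'"))
}

#' Sweep one light property
#'
#' Varies a single property of the baseline profile over `values`, entrains
#' the clock model for each resulting profile and converts the trajectory to
#' phenotypes, effective light duration and energy.  A failed simulation is
#' recorded in its row's `status` and the sweep continues.
#'
#' @param property one of `"photoperiod"`, `"offset"`, `"amplitude"`,
#'   `"dawn"`, `"twilight"`, `"period"`, `"period_with_half_photoperiod"`
#'   (the last sets `ph = pr/2` for each period value).
#' @param values values to sweep; defaults to [default_sweep_values()].
#' @param baseline a [light_profile()] supplying the unswept properties.
#' @param settings a [sim_settings()].
#' @param model clock model or built-in name (see [get_clock_model()]).
#' @param phen a [phenotype_params()].
#' @param energy an [energy_params()].
#' @param cache optional [new_sim_cache()].
#' @return An object of class `light_sweep`: list with `property`, `rows`
#'   (one data-frame row per value, order preserved) and `baseline_row`.
#' @export
sweep_single <- function(property, values = NULL,
                         baseline = light_profile(),
                         settings = sim_settings(), model = "coincidence",
                         phen = phenotype_params(), energy = energy_params(),
                         cache = NULL) {
  if (!property %in% names(sweep_property_field))
    stop("unknown sweep property '", property, "'")
  if (is.null(values)) values <- default_sweep_values(property)
  if (!length(values)) stop("values must be non-empty")
  validate_light_profile(baseline)

  field <- sweep_property_field[[property]]
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    repl <- stats::setNames(list(values[[i]]), field)
    if (property == "period_with_half_photoperiod")
      repl$ph_hours <- values[[i]] / 2
    prof <- do.call(modify_profile, c(list(baseline), repl))
    rows[[i]] <- cbind(property = property, value = values[[i]],
                       evaluate_profile_row(prof, settings, model, phen,
                                            energy, cache),
                       stringsAsFactors = FALSE)
  }
  base_row <- evaluate_profile_row(baseline, settings, model, phen, energy, cache)
  structure(list(property = property,
                 rows = do.call(rbind, rows),
                 baseline_row = base_row,
                 settings = settings,
                 model_name = get_clock_model(model)$name),
            class = "light_sweep")
}

#' @export
print.light_sweep <- function(x, ...) {
  ok <- sum(x$rows$status == "ok")
  cat(sprintf("Light sweep over %s: %d rows (%d ok), model '%s'\n",
              x$property, nrow(x$rows), ok, x$model_name))
  if (!is.null(x$baseline_row) && is.finite(x$baseline_row$days_to_flower))
    cat(sprintf("  baseline: %.2f days, %.2f mm\n",
                x$baseline_row$days_to_flower, x$baseline_row$hypocotyl_mm))
  cols <- intersect(c("value", "days_to_flower", "hypocotyl_mm",
                      "eldf_hours", "energy_mwh_per_year", "flags", "status"),
                    names(x$rows))
  print(x$rows[, cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.light_sweep <- function(x, ...) {
  ok <- x$rows$status == "ok"
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)), add = TRUE)
  graphics::plot(x$rows$value[ok], x$rows$days_to_flower[ok], type = "b",
                 xlab = x$property, ylab = "days to flower", ...)
  graphics::abline(h = x$baseline_row$days_to_flower, lty = 3)
  graphics::plot(x$rows$value[ok], x$rows$hypocotyl_mm[ok], type = "b",
                 xlab = x$property, ylab = "hypocotyl (mm)", ...)
  graphics::abline(h = x$baseline_row$hypocotyl_mm, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.light_sweep <- function(x, ...) x$rows

# Resolve NULL criteria thresholds against the baseline row.
resolve_criteria <- function(criteria, baseline_row) {
  if (is.null(criteria$max_days))
    criteria$max_days <- baseline_row$days_to_flower
  if (is.null(criteria$max_hypocotyl))
    criteria$max_hypocotyl <- baseline_row$hypocotyl_mm
  criteria
}

feasible_rows <- function(rows, criteria) {
  ok <- rows$status == "ok" &
    is.finite(rows$days_to_flower) & is.finite(rows$hypocotyl_mm) &
    rows$days_to_flower >= 0 &
    rows$days_to_flower <= criteria$max_days &
    rows$hypocotyl_mm <= criteria$max_hypocotyl
  rows[ok, , drop = FALSE]
}

# The selection rule.  Soft preferences (natural period, then no background
# light) are applied only when a preferred row lies within comparable_days of
# the current optimum; then days are minimised with ties broken by lower
# energy, lower effective light duration, and zero offset.
select_recommended <- function(feas, criteria) {
  if (!nrow(feas)) return(NULL)
  pool <- feas
  for (pref in c("period", "offset")) {
    keep <- if (pref == "period" && criteria$prefer_natural_period)
      pool$pr_hours == criteria$natural_period
    else if (pref == "offset" && criteria$prefer_no_offset)
      pool$offset == 0
    else rep(TRUE, nrow(pool))
    if (any(keep) &&
        min(pool$days_to_flower[keep]) <=
          min(pool$days_to_flower) + criteria$comparable_days)
      pool <- pool[keep, , drop = FALSE]
  }
  ord <- order(pool$days_to_flower, pool$energy_mwh_per_year,
               pool$eldf_hours, pool$offset)
  pool[ord[1L], , drop = FALSE]
}

#' Stage 1 of the collective search: photoperiod x period grid
#'
#' Evaluates the Cartesian grid of periods and photoperiods (pairs with
#' `ph > pr` are skipped and counted), keeps the rows whose phenotypes do not
#' exceed the criteria thresholds, and reports (i) the phenotype-optimal
#' combination, (ii) alternates with shorter photoperiod and comparable
#' phenotypes ranked by effective light duration, and (iii) the schedule the
#' selection rule recommends.
#'
#' @param pr_values,ph_values grid values in hours.
#' @param baseline profile supplying the remaining properties.
#' @inheritParams sweep_single
#' @param criteria a [rec_criteria()].
#' @return An object of class `collective_result` with elements `rows`,
#'   `feasible`, `best`, `alternates`, `recommended`, `baseline_row`,
#'   `n_skipped`, `status`.
#' @export
collective_stage1 <- function(pr_values = seq(18, 32, by = 2),
                              ph_values = 12:28,
                              baseline = light_profile(),
                              settings = sim_settings(),
                              model = "coincidence",
                              phen = phenotype_params(),
                              energy = energy_params(),
                              criteria = rec_criteria(),
                              cache = NULL) {
  if (!length(pr_values) || !length(ph_values)) stop("grids must be non-empty")
  rows <- list(); skipped <- 0L
  for (pr in pr_values) for (ph in ph_values) {
    if (ph > pr) { skipped <- skipped + 1L; next }
    prof <- modify_profile(baseline, pr_hours = pr, ph_hours = ph)
    rows[[length(rows) + 1L]] <-
      evaluate_profile_row(prof, settings, model, phen, energy, cache)
  }
  base_row <- evaluate_profile_row(baseline, settings, model, phen, energy, cache)
  rows <- if (length(rows)) do.call(rbind, rows) else base_row[0L, , drop = FALSE]
  criteria <- resolve_criteria(criteria, base_row)
  feas <- feasible_rows(rows, criteria)
  finish_collective(rows, feas, base_row, criteria, skipped, stage = 1L)
}

#' Stage 2 of the collective search: amplitude x offset grid
#'
#' With period and photoperiod fixed at the Stage-1 choice, evaluates the
#' Cartesian grid over amplitude and offset.  Rows with `offset > 0` carry a
#' `BACKGROUND_LIGHT` flag (they require constant background light).  Rows
#' are ranked by days to flower then energy; the recommendation applies the
#' no-background-light preference of the selection rule.
#'
#' @param amplitudes,offsets grid values.
#' @param fixed profile carrying the Stage-1 period and photoperiod.
#' @inheritParams collective_stage1
#' @return A `collective_result` (see [collective_stage1()]).
#' @export
collective_stage2 <- function(amplitudes = seq(0.97, 1.03, by = 0.01),
                              offsets = seq(0, 0.05, by = 0.01),
                              fixed,
                              settings = sim_settings(),
                              model = "coincidence",
                              phen = phenotype_params(),
                              energy = energy_params(),
                              criteria = rec_criteria(),
                              cache = NULL) {
  if (!length(amplitudes) || !length(offsets)) stop("grids must be non-empty")
  validate_light_profile(fixed)
  rows <- list()
  for (a in amplitudes) for (dl in offsets) {
    prof <- modify_profile(fixed, amplitude = a, offset = dl)
    r <- evaluate_profile_row(prof, settings, model, phen, energy, cache)
    if (dl > 0)
      r$flags <- paste(c(Filter(nzchar, strsplit(r$flags, ";")[[1]]),
                         "BACKGROUND_LIGHT"), collapse = ";")
    rows[[length(rows) + 1L]] <- r
  }
  rows <- do.call(rbind, rows)
  base_row <- evaluate_profile_row(modify_profile(fixed, amplitude = 1, offset = 0),
                                   settings, model, phen, energy, cache)
  criteria <- resolve_criteria(criteria, base_row)
  feas <- feasible_rows(rows, criteria)
  ord <- order(rows$days_to_flower, rows$energy_mwh_per_year)
  rows <- rows[ord, , drop = FALSE]
  finish_collective(rows, feas, base_row, criteria, 0L, stage = 2L)
}

finish_collective <- function(rows, feas, base_row, criteria, skipped, stage) {
  if (!nrow(feas)) {
    return(structure(list(stage = stage, rows = rows, feasible = feas,
                          best = NULL, alternates = feas, recommended = NULL,
                          baseline_row = base_row, criteria = criteria,
                          n_skipped = skipped, status = "empty feasible set"),
                     class = "collective_result"))
  }
  best <- feas[which.min(feas$days_to_flower), , drop = FALSE]
  alt <- feas[feas$ph_hours < best$ph_hours &
                feas$days_to_flower <= best$days_to_flower + criteria$comparable_days &
                feas$hypocotyl_mm <= best$hypocotyl_mm + criteria$comparable_mm, ,
              drop = FALSE]
  alt <- alt[order(alt$eldf_hours), , drop = FALSE]
  structure(list(stage = stage, rows = rows, feasible = feas, best = best,
                 alternates = alt,
                 recommended = select_recommended(feas, criteria),
                 baseline_row = base_row, criteria = criteria,
                 n_skipped = skipped, status = "ok"),
            class = "collective_result")
}

#' @export
print.collective_result <- function(x, ...) {
  cat(sprintf("Collective manipulation stage %d: %d rows (%d feasible, %d skipped)\n",
              x$stage, nrow(x$rows), nrow(x$feasible), x$n_skipped))
  if (identical(x$status, "empty feasible set")) {
    cat("  no feasible combination under the criteria thresholds\n")
    return(invisible(x))
  }
  fmt <- function(r, what) cat(sprintf(
    "  %s: Pr=%g Ph=%g A=%g dl=%g -> %.2f days, %.2f mm, %.2f MWh/yr\n",
    what, r$pr_hours, r$ph_hours, r$amplitude, r$offset,
    r$days_to_flower, r$hypocotyl_mm, r$energy_mwh_per_year))
  fmt(x$best, "best (phenotype-optimal)")
  if (!is.null(x$recommended)) fmt(x$recommended, "recommended")
  if (nrow(x$alternates)) cat(sprintf("  %d alternate(s) with shorter photoperiod\n",
                                      nrow(x$alternates)))
  invisible(x)
}

#' @export
as.data.frame.collective_result <- function(x, ...) x$rows

#' Summarise the influence of each light property
#'
#' Builds the per-property summary table from the six single-property sweeps:
#' the best (lowest) days to flower with its percent improvement over
#' nominal, the hypocotyl range across the sweep, and a `"No change"` verdict
#' when neither phenotype deviates from nominal by 1% or more anywhere in the
#' sweep.
#'
#' @param sweep_results named list of `light_sweep` objects covering
#'   `photoperiod`, `offset`, `amplitude`, `dawn`, `twilight` and `period`
#'   (or `period_with_half_photoperiod`).
#' @return A data frame with one row per property.
#' @export
summarize_influence <- function(sweep_results) {
  need <- c("photoperiod", "offset", "amplitude", "dawn", "twilight")
  have <- vapply(sweep_results, function(s) s$property, character(1))
  missing <- setdiff(need, have)
  if (!("period" %in% have || "period_with_half_photoperiod" %in% have))
    missing <- c(missing, "period")
  if (length(missing))
    stop("missing sweep(s): ", paste(missing, collapse = ", "))
  out <- lapply(sweep_results, function(s) {
    ok <- s$rows[s$rows$status == "ok", , drop = FALSE]
    nom_d <- s$baseline_row$days_to_flower
    nom_h <- s$baseline_row$hypocotyl_mm
    pos <- ok[ok$days_to_flower >= 0, , drop = FALSE]   # flagged rows excluded from "best"
    best_d <- min(pos$days_to_flower)
    dev_d <- max(abs(pos$days_to_flower - nom_d)) / abs(nom_d)
    dev_h <- max(abs(ok$hypocotyl_mm - nom_h)) / abs(nom_h)
    data.frame(property = s$property,
               nominal_days = nom_d,
               best_days = best_d,
               days_improvement_pct = 100 * (nom_d - best_d) / nom_d,
               hypocotyl_min = min(ok$hypocotyl_mm),
               hypocotyl_max = max(ok$hypocotyl_mm),
               verdict = if (dev_d < 0.01 && dev_h < 0.01) "No change"
                         else if (best_d < nom_d) "Improvement possible"
                         else "No improvement",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
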