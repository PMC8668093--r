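#' Load a run configuration
#'
#' Reads a YAML configuration (or builds the defaults when `path` is `NULL`)
#' and validates every block.  With no file the configuration reproduces the
#' nominal setup: the standard 12 h / 24 h light schedule, default solver and
#' entrainment settings, the published phenotype constants, the default LED
#' driver, and the standard sweep grids.  Unknown keys anywhere in the file
#' are rejected by name, so typos never silently fall back to defaults.
#'
#' Recognised blocks: `light` (the six profile fields), `simulation`
#' (arguments of [sim_settings()] plus `model`), `phenotype`
#' ([phenotype_params()] arguments), `energy` ([energy_params()] arguments),
#' `criteria` ([rec_criteria()] arguments), `sweeps` (named value lists per
#' sweep property), `synthetic` ([make_trajectory()] arguments) and
#' `output_dir`.
#'
#' @param path YAML file path, or `NULL` for the built-in defaults.
#' @return An object of class `run_config`: a named list of validated
#'   component objects.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  }
  known <- c("light", "simulation", "phenotype", "energy", "criteria",
             "sweeps", "synthetic", "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))

  take <- function(block, fn, extra_ok = character(0)) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    ok <- c(names(formals(fn)), extra_ok)
    bad <- setdiff(names(args), ok)
    if (length(bad))
      stop("unknown key(s) in config block '", block, "': ",
           paste(bad, collapse = ", "))
    args
  }

  sim_args <- take("simulation", sim_settings, extra_ok = "model")
  model <- if (!is.null(sim_args$model)) sim_args$model else "coincidence"
  sim_args$model <- NULL

  sweeps <- raw$sweeps
  if (!is.null(sweeps)) {
    bad <- setdiff(names(sweeps), names(sweep_property_field))
    if (length(bad))
      stop("unknown key(s) in config block 'sweeps': ", paste(bad, collapse = ", "))
  }

  cfg <- list(
    light = do.call(light_profile, take("light", light_profile)),
    simulation = do.call(sim_settings, sim_args),
    model = model,
    phenotype = do.call(phenotype_params, take("phenotype", phenotype_params)),
    energy = do.call(energy_params, take("energy", energy_params)),
    criteria = do.call(rec_criteria, take("criteria", rec_criteria)),
    sweeps = sweeps,
    synthetic = take("synthetic", make_trajectory),
    output_dir = if (is.null(raw$output_dir)) "greenlight_results" else raw$output_dir
  )
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' Writes a `run_config` back to YAML such that [load_config()] on the result
#' reproduces it.
#'
#' @param config a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(light = unclass(config$light),
              simulation = unclass(config$simulation),
              phenotype = unclass(config$phenotype),
              energy = unclass(config$energy),
              criteria = config$criteria[!vapply(config$criteria, is.null, logical(1))],
              output_dir = config$output_dir)
  out$simulation$model <- config$model
  if (!is.null(config$sweeps)) out$sweeps <- config$sweeps
  if (length(config$synthetic)) out$synthetic <- config$synthetic
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("greenlight run configuration\n")
  cat(sprintf("  model: %s;  output_dir: %s\n", x$model, x$output_dir))
  print(x$light)
  invisible(x)
}

format_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) format(v, digits = 6, trim = TRUE),
                              character(1)))
}

write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  nrow(df)
}

#' Write sweep or phenotype results to disk
#'
#' Serialises a result object into the output directory: sweeps and
#' collective stages as CSV tables with a fixed column order and 6
#' significant digits, phenotype results and recommendations as JSON carrying
#' all six light properties plus the phenotypes, effective light duration and
#' energy.  Files contain no timestamps, so re-running an identical
#' configuration reproduces them byte for byte.
#'
#' @param result a `phenotype_result`, `light_sweep` or `collective_result`.
#' @param out_dir output directory (created if needed).
#' @return Data frame manifest (`file`, `rows`), invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(file, rows) manifest[[length(manifest) + 1L]] <<-
    data.frame(file = file, rows = rows, stringsAsFactors = FALSE)

  if (inherits(result, "phenotype_result")) {
    path <- file.path(out_dir, "phenotypes.json")
    payload <- c(as.list(as.data.frame(result$profile)),
                 list(days_to_flower = result$days_to_flower,
                      hypocotyl_mm = result$hypocotyl_mm,
                      ft_area = result$ft_area,
                      eldf_hours = result$eldf_hours,
                      energy_mwh_per_year = result$energy_mwh_per_year,
                      flags = as.list(result$flags)))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    add("phenotypes.json", 1L)
  } else if (inherits(result, "light_sweep")) {
    file <- paste0("sweep_", result$property, ".csv")
    add(file, write_table_csv(result$rows, file.path(out_dir, file)))
  } else if (inherits(result, "collective_result")) {
    file <- sprintf("stage%d.csv", result$stage)
    add(file, write_table_csv(result$rows, file.path(out_dir, file)))
    if (!is.null(result$recommended)) {
      rec <- as.list(result$recommended)
      jsonlite::write_json(rec, file.path(out_dir, "recommendation.json"),
                           auto_unbox = TRUE, digits = NA)
      add("recommendation.json", 1L)
    }
  } else if (is.data.frame(result)) {
    add("influence_table.csv",
        write_table_csv(result, file.path(out_dir, "influence_table.csv")))
  } else stop("unsupported result type: ", paste(class(result), collapse = "/"))

  invisible(do.call(rbind, manifest))
}
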