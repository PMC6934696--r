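#' Run configuration for scenario-driven analyses
#'
#' Bundles everything a run needs: a scenario name (or an inline parameter
#' set and energy model), the output directory, resolutions, tolerances,
#' seed and plot flag.  Configurations round-trip losslessly through YAML or
#' JSON via [write_config()] / [read_config()].
#'
#' @param scenario name of a built-in scenario (see [builtin_scenarios()]),
#'   or `NULL` to use `params`/`model` directly.
#' @param params inline [regulatory_params()] (ignored when `scenario` is
#'   given).
#' @param model inline [energy_model()].
#' @param out_dir output directory (created if missing).
#' @param step energy-sweep step.
#' @param landscape_res length-2 integer: axis1 x axis2 landscape nodes
#'   (overrides scenario axes when set).
#' @param basin_res basin-map resolution.
#' @param n_starts root-solver starts per axis.
#' @param a_star fixed energy level for basin runs.
#' @param seed integer seed recorded with the run.
#' @param plot also write PNG figures.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, params = regulatory_params(),
                       model = energy_model(), out_dir = ".",
                       step = 5e-3, landscape_res = NULL, basin_res = 61L,
                       n_starts = 15L, a_star = 1, seed = 1L, plot = FALSE) {
  structure(list(scenario = scenario, params = params, model = model,
                 out_dir = out_dir, step = step,
                 landscape_res = landscape_res, basin_res = basin_res,
                 n_starts = n_starts, a_star = a_star, seed = seed,
                 plot = plot),
            class = "run_config")
}

#' Read or write a run configuration
#'
#' @param config a [run_config()].
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- unclass(config)
  flat$params <- unclass(flat$params)
  flat$model <- unclass(flat$model)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(flat, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  flat <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  flat$params <- do.call(regulatory_params, flat$params)
  flat$model <- energy_model(flat$model$kind, s1 = flat$model$s1,
                             s2 = flat$model$s2, floor = flat$model$floor,
                             ceiling = flat$model$ceiling)
  do.call(run_config, flat)
}

resolve_scenario <- function(config, expected_type = NULL) {
  if (!is.null(config$scenario)) {
    sc <- get_scenario(config$scenario)
    if (!is.null(expected_type) && sc$type != expected_type) {
      stop("scenario '", sc$name, "' has type '", sc$type,
           "', expected '", expected_type, "'", call. = FALSE)
    }
    sc
  } else {
    structure(list(name = "inline", type = expected_type %||% "sweep",
                   params = config$params, model = config$model,
                   provenance = "inline configuration"),
              class = "scenario")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prep_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  config$out_dir
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run an energy bifurcation sweep and write its outputs
#'
#' Resolves the configured scenario, sweeps `A*`, and writes
#' `sweep_<name>.csv` (long format: `a_star`, `x1`, `x2`, `stability`,
#' `leading_re`, `residual`) plus `sweep_<name>_summary.json` containing the
#' run-length-encoded stable counts, the change points, and the re-entrance
#' flag.  Scenarios carrying a set of `a` values (the re-entrance scan)
#' write one file pair per `a`.
#'
#' @param config a [run_config()].
#' @return invisibly, a named list of written file paths.
#' @export
run_sweep <- function(config) {
  sc <- resolve_scenario(config, "sweep")
  out_dir <- prep_out_dir(config)
  sw_args <- sc$sweep %||% list(a_star_min = 0, a_star_max = 1,
                                step = config$step)
  a_values <- sc$a_values %||% NA
  paths <- list()
  for (a in a_values) {
    p <- if (is.na(a)) sc$params else set_param(sc$params, "a", a)
    tag <- if (is.na(a)) sc$name else sprintf("%s_a%g", sc$name, a)
    sw <- do.call(sweep_energy,
                  c(list(params = p, model = sc$model,
                         n_starts = config$n_starts), sw_args))
    csv <- file.path(out_dir, paste0("sweep_", tag, ".csv"))
    write_table(sw$states, csv)
    cs <- count_sequence(sw)
    smry <- list(scenario = sc$name, a = if (is.na(a)) NULL else a,
                 seed = config$seed,
                 stable_counts_rle = cs$runs, reentrant = cs$reentrant,
                 change_points = sw$change_points,
                 final_stable_count = utils::tail(sw$stable_counts, 1))
    js <- file.path(out_dir, paste0("sweep_", tag, "_summary.json"))
    jsonlite::write_json(smry, js, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    if (isTRUE(config$plot)) {
      png <- file.path(out_dir, paste0("sweep_", tag, ".png"))
      grDevices::png(png, 800, 600)
      plot(sw, main = tag)
      grDevices::dev.off()
      paths[[paste0(tag, "_png")]] <- png
    }
    paths[[paste0(tag, "_csv")]] <- csv
    paths[[paste0(tag, "_json")]] <- js
  }
  invisible(paths)
}

#' Run an attractor-count landscape and write its outputs
#'
#' Writes `landscape_<name>.csv` (`axis1`, `axis2`, `count`) and a JSON
#' summary with the set of distinct stable counts.  Scenarios with an
#' `a_values` panel series write one file pair per panel.
#'
#' @param config a [run_config()].
#' @return invisibly, a named list of written file paths.
#' @export
run_landscape <- function(config) {
  sc <- resolve_scenario(config, "landscape")
  out_dir <- prep_out_dir(config)
  ax1 <- sc$axis1
  ax2 <- sc$axis2
  if (!is.null(config$landscape_res)) {
    r <- config$landscape_res
    ax1$values <- seq(min(ax1$values), max(ax1$values), length.out = r[1])
    ax2$values <- seq(min(ax2$values), max(ax2$values), length.out = r[2])
  }
  a_values <- sc$a_values %||% NA
  paths <- list()
  for (a in a_values) {
    p <- if (is.na(a)) sc$params else set_param(sc$params, "a", a)
    tag <- if (is.na(a)) sc$name else sprintf("%s_a%g", sc$name, a)
    g <- attractor_count_grid(p, ax1, ax2, model = sc$model,
                              n_starts = config$n_starts)
    csv <- file.path(out_dir, paste0("landscape_", tag, ".csv"))
    write_table(as.data.frame(g), csv)
    smry <- list(scenario = sc$name, a = if (is.na(a)) NULL else a,
                 seed = config$seed,
                 distinct_counts = sort(unique(as.vector(g$counts))),
                 max_count = max(g$counts))
    js <- file.path(out_dir, paste0("landscape_", tag, "_summary.json"))
    jsonlite::write_json(smry, js, auto_unbox = TRUE, digits = NA)
    if (isTRUE(config$plot)) {
      png <- file.path(out_dir, paste0("landscape_", tag, ".png"))
      grDevices::png(png, 700, 700)
      plot(g, main = tag)
      grDevices::dev.off()
      paths[[paste0(tag, "_png")]] <- png
    }
    paths[[paste0(tag, "_csv")]] <- csv
    paths[[paste0(tag, "_json")]] <- js
  }
  invisible(paths)
}

#' Run a basin map and write it as CSV
#'
#' Writes `basins_<name>.csv` with columns `x1_0`, `x2_0`, `label` (empty
#' for separatrix/undetermined cells).
#'
#' @param config a [run_config()]; uses `config$a_star` and
#'   `config$basin_res`.
#' @return invisibly, the written file path.
#' @export
run_basins <- function(config) {
  sc <- resolve_scenario(config, NULL)
  out_dir <- prep_out_dir(config)
  bm <- basin_map(sc$params, config$a_star, sc$model,
                  resolution = config$basin_res)
  csv <- file.path(out_dir, paste0("basins_", sc$name, ".csv"))
  write_table(bm$cells, csv)
  invisible(csv)
}

#' Run a transition-difficulty grid and write it as CSV
#'
#' Writes `transitions_<name>.csv` with columns `axis1`, `axis2`,
#' `min_distance`, `route`; monostable cells have empty distance fields.
#' Scenario axes are re-gridded to `config$landscape_res` when set.
#'
#' @param config a [run_config()].
#' @return invisibly, the written file path.
#' @export
run_transitions <- function(config) {
  sc <- resolve_scenario(config, "transitions")
  out_dir <- prep_out_dir(config)
  ax1 <- sc$axis1
  ax2 <- sc$axis2
  if (!is.null(config$landscape_res)) {
    r <- config$landscape_res
    ax1$values <- seq(min(ax1$values), max(ax1$values), length.out = r[1])
    ax2$values <- seq(min(ax2$values), max(ax2$values), length.out = r[2])
  }
  tg <- transition_difficulty_grid(sc$params, ax1, ax2,
                                   model = sc$model,
                                   resolution = config$basin_res,
                                   n_starts = config$n_starts)
  csv <- file.path(out_dir, paste0("transitions_", sc$name, ".csv"))
  write_table(as.data.frame(tg), csv)
  invisible(csv)
}

#' List the built-in scenarios
#'
#' @return data.frame with columns `name`, `type`, `provenance`.
#' @export
list_scenarios <- function() {
  sc <- builtin_scenarios()
  data.frame(name = vapply(sc, `[[`, "", "name"),
             type = vapply(sc, `[[`, "", "type"),
             provenance = vapply(sc, `[[`, "", "provenance"),
             row.names = NULL)
}
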