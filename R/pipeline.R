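# Orchestration: config handling and the three pipeline commands.
# Each command is an ordinary R function over the module APIs; the thin
# Rscript wrapper in inst/scripts/carbonscape.R maps them onto a shell
# interface. Every run writes a manifest with all effective parameters so
# it can be re-run bit-identically.

#' Load a run configuration
#'
#' A config is a named list; when given a YAML path, relative input paths
#' are resolved against the file's directory. Recognised keys: `t0`, `t1`,
#' `drivers` (directory of `.asc` layers or named list of paths),
#' `density_table`, `area_table`, `indicator_table`, `out_dir`, `horizons`
#' (Markov steps), `sampling_rate`, `seed`, `ca` (fields of [ca_config()]).
#'
#' @param config list or YAML file path.
#' @return Normalised config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    rel <- function(p) if (!is.null(p) && !grepl("^/", p)) file.path(base, p)
                       else p
    for (k in c("t0", "t1", "density_table", "area_table",
                "indicator_table", "drivers", "out_dir"))
      if (!is.null(config[[k]]) && is.character(config[[k]]))
        config[[k]] <- vapply(config[[k]], rel, character(1))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$sampling_rate <- config$sampling_rate %||% 0.01
  config$out_dir <- config$out_dir %||% "."
  config
}

write_manifest <- function(out_dir, command, config, extra = list()) {
  manifest <- c(list(command = command), config, extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

read_config_drivers <- function(config) {
  drv <- config$drivers
  if (length(drv) == 1 && dir.exists(drv[[1]])) {
    paths <- list.files(drv[[1]], pattern = "\\.asc$", full.names = TRUE)
    read_driver_stack(stats::setNames(paths,
                                      tools::file_path_sans_ext(basename(paths))))
  } else read_driver_stack(unlist(drv))
}

#' Carbon bookkeeping command
#'
#' Computes per-class area/storage summaries from a class-map raster (and,
#' when a second epoch is given, the per-cell storage-change raster), or
#' from a tabular `area_table` CSV (columns `class_code` plus one or more
#' `area_*` columns, one summary per column). Summaries are written as CSV,
#' change maps as `.asc`.
#'
#' @param config see [load_run_config()].
#' @return List of summaries (and change-map path), invisibly.
#' @export
cmd_carbon <- function(config) {
  config <- load_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  density <- read_density_table(config$density_table)
  out <- list()
  if (!is.null(config$area_table)) {
    at <- utils::read.csv(config$area_table)
    acols <- grep("^area", names(at), value = TRUE)
    for (ac in acols) {
      areas <- stats::setNames(at[[ac]], names(CLASS_CODES)[at$class_code])
      s <- storage_from_area_table(areas, density)
      utils::write.csv(s, file.path(config$out_dir,
                                    paste0("storage_", ac, ".csv")),
                       row.names = FALSE)
      out[[ac]] <- s
    }
  }
  if (!is.null(config$t0)) {
    t0 <- read_class_map(config$t0)
    out$t0 <- carbon_storage(t0, density)
    utils::write.csv(out$t0, file.path(config$out_dir, "storage_t0.csv"),
                     row.names = FALSE)
    if (!is.null(config$t1)) {
      t1 <- read_class_map(config$t1)
      out$t1 <- carbon_storage(t1, density)
      utils::write.csv(out$t1, file.path(config$out_dir, "storage_t1.csv"),
                       row.names = FALSE)
      cm <- carbon_change_map(t0, t1, density)
      p <- file.path(config$out_dir, "carbon_change.asc")
      write_asc(cm, p, cellsize = t0$georef$cellsize %||% 1)
      utils::write.csv(as.data.frame(transition_matrix(t0, t1)),
                       file.path(config$out_dir, "transitions.csv"))
      out$change_map <- p
    }
  }
  if (length(out) == 0) stop("cmd_carbon needs t0 and/or area_table")
  write_manifest(config$out_dir, "carbon", config)
  invisible(out)
}

#' Simulation command
#'
#' Runs the full projection ([run_projection()]) on a raster bundle and
#' writes, per horizon: the simulated map, the demand table, the carbon
#' summary, the round log, and an agreement report against the observed t1
#' map; plus the suitability driver contributions and domain weights.
#'
#' @param config see [load_run_config()]; `horizons` holds Markov steps.
#' @return The [run_projection()] result, invisibly.
#' @export
cmd_simulate <- function(config) {
  config <- load_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- read_class_map(config$t0)
  t1 <- read_class_map(config$t1)
  drivers <- read_config_drivers(config)
  density <- read_density_table(config$density_table)
  ca <- config$ca %||% list()
  ca$rng_seed <- ca$rng_seed %||% config$seed
  cfg <- do.call(ca_config, ca)
  steps <- as.integer(unlist(config$horizons %||% list(1L)))
  proj <- run_projection(t0, t1, drivers, density, cfg = cfg, steps = steps,
                         sampling_rate = config$sampling_rate,
                         seed = config$seed)
  utils::write.csv(
    data.frame(class_name = names(proj$weights), weight = proj$weights),
    file.path(config$out_dir, "domain_weights.csv"), row.names = FALSE)
  contrib <- do.call(rbind, lapply(names(proj$suitability$contributions),
    function(nm) data.frame(class_name = nm, driver =
      names(proj$suitability$contributions[[nm]]),
      contribution = as.numeric(proj$suitability$contributions[[nm]]))))
  utils::write.csv(contrib, file.path(config$out_dir,
                                      "driver_contributions.csv"),
                   row.names = FALSE)
  for (h in names(proj$horizons)) {
    hz <- proj$horizons[[h]]
    write_class_map(hz$result$map,
                    file.path(config$out_dir, paste0("map_step", h, ".asc")))
    utils::write.csv(hz$demand,
                     file.path(config$out_dir, paste0("demand_step", h, ".csv")),
                     row.names = FALSE)
    utils::write.csv(hz$summary,
                     file.path(config$out_dir, paste0("storage_step", h, ".csv")),
                     row.names = FALSE)
    utils::write.csv(hz$result$log,
                     file.path(config$out_dir, paste0("log_step", h, ".csv")),
                     row.names = FALSE)
    ag <- agreement(t1, hz$result$map)
    utils::write.csv(
      data.frame(metric = c("overall_accuracy", "kappa"),
                 value = c(ag$overall_accuracy, ag$kappa)),
      file.path(config$out_dir, paste0("agreement_step", h, ".csv")),
      row.names = FALSE)
  }
  write_manifest(config$out_dir, "simulate", config)
  invisible(proj)
}

#' Sustainability assessment command
#'
#' Reads a region-by-indicator CSV with orientations, runs the entropy
#' weighting, and writes the weight and score tables (scores carry a
#' quantile band column when `bands` > 0).
#'
#' @param config see [load_run_config()]; optional keys `form`, `basis`,
#'   `bands` (default 4).
#' @return The [sustainability_index()] result, invisibly.
#' @export
cmd_assess <- function(config) {
  config <- load_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  it <- read_indicator_table(config$indicator_table,
                             config$orientation_table %||% NULL)
  res <- sustainability_index(it$values, it$orientations,
                              form = config$form %||% "conventional",
                              basis = config$basis %||% "standardized",
                              bands = config$bands %||% 4)
  utils::write.csv(
    data.frame(indicator = names(res$weights),
               entropy = res$entropy[names(res$weights)],
               weight = res$weights),
    file.path(config$out_dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(res$scores, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)
  write_manifest(config$out_dir, "assess", config)
  invisible(res)
}
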