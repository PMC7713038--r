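# Pipeline configuration and output writing.

#' Load (or default) the full pipeline configuration
#'
#' Reads a YAML or JSON configuration file with sections \code{geometry},
#' \code{muscle}, \code{contact}, \code{simulation}, plus
#' \code{sweep_angles} and \code{output_dir}, merges it over the package
#' defaults and validates every value through the corresponding
#' constructor. Unknown keys are rejected by name (typo safety). With no
#' file, the resolved defaults are returned.
#'
#' @param path Path to a .yaml/.yml/.json file, or NULL for defaults.
#' @return A \code{pipeline_config}: list with \code{geometry},
#'   \code{muscle}, \code{contact}, \code{simulation}, \code{sweep_angles},
#'   \code{output_dir} and \code{hash} (fingerprint of the resolved
#'   values).
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
            else if (ext == "json") jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
            else stop("config file must be .yaml/.yml or .json")
    if (is.null(user)) user <- list()
  }
  known_sections <- c("geometry", "muscle", "contact", "simulation",
                      "sweep_angles", "output_dir")
  unknown <- setdiff(names(user), known_sections)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))

  build_section <- function(section, constructor) {
    vals <- user[[section]] %||% list()
    allowed <- names(formals(constructor))
    bad <- setdiff(names(vals), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in config section '%s': %s",
                   section, paste(bad, collapse = ", ")))
    do.call(constructor, vals)
  }
  cfg <- list(
    geometry = build_section("geometry", geometry_params),
    muscle = build_section("muscle", hill_muscle_params),
    contact = build_section("contact", contact_params),
    simulation = build_section("simulation", simulation_config),
    sweep_angles = as.numeric(user$sweep_angles %||% default_sweep_angles()),
    output_dir = user$output_dir %||% "."
  )
  if (!length(cfg$sweep_angles) || any(!is.finite(cfg$sweep_angles)))
    stop("sweep_angles must be a non-empty numeric list")
  if (any(cfg$sweep_angles < 90 | cfg$sweep_angles > 120))
    stop("sweep_angles must lie within [90, 120] degrees")
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  core <- lapply(cfg[c("geometry", "muscle", "contact", "simulation",
                       "sweep_angles", "output_dir")],
                 function(x) if (is.list(x)) unclass(x) else x)
  fnv1a_hex(core)
}

#' Serialize a pipeline configuration to file
#'
#' Round-trips: reloading the written file reproduces identical resolved
#' values (and hash).
#'
#' @param config A \code{pipeline_config}.
#' @param path Output .yaml/.yml or .json path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(geometry = unclass(config$geometry),
              muscle = unclass(config$muscle),
              contact = unclass(config$contact),
              simulation = unclass(config$simulation),
              sweep_angles = config$sweep_angles,
              output_dir = config$output_dir)
  ## drop derived fields that the constructors recompute
  out$contact$penalty_stiffness <- NULL
  out$contact$contact_damping <- config$contact$contact_damping
  ext <- tolower(tools::file_ext(path))
  ## precision 17 makes the double round-trip exact
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(out, path, precision = 17)
  else if (ext == "json") jsonlite::write_json(out, path, auto_unbox = TRUE,
                                               digits = NA, null = "null")
  else stop("config file must be .yaml/.yml or .json")
  invisible(path)
}

## Recursively drop S3 classes so nested configuration objects serialize
## as plain JSON maps.
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' Write simulation outputs to a directory
#'
#' A single run produces one CSV of the sampled time series plus one JSON
#' metadata file (resolved configuration, its hash, package version). A
#' sweep produces one CSV per angle (\code{run_aldfa_<angle>.csv}) plus a
#' sweep JSON with the per-angle verdicts and the critical angle. Floats
#' are written with 9 significant digits; overwriting is idempotent.
#'
#' @param x A \code{simulation_result} or a \code{sweep_result} (the sweep
#'   must have been run with \code{keep_results = TRUE} to emit per-run
#'   CSVs).
#' @param output_dir Output directory, created if needed.
#' @return Character vector of the files written.
#' @export
write_outputs <- function(x, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) stop("cannot create directory: ", output_dir)
  ver <- as.character(utils::packageVersion("stiflesim"))
  if (inherits(x, "simulation_result")) {
    base <- sprintf("run_aldfa_%s", format_angle(x$aldfa_deg))
    csv <- file.path(output_dir, paste0(base, ".csv"))
    json <- file.path(output_dir, paste0(base, ".json"))
    write_samples_csv(x$samples, csv)
    meta <- list(aldfa_deg = x$aldfa_deg,
                 side = x$side,
                 displacement_origin_mm = x$displacement_origin,
                 engine = x$engine,
                 config = strip_classes(x$config),
                 config_hash = fnv1a_hex(strip_classes(x$config)),
                 package_version = ver)
    jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(c(csv, json))
  }
  if (inherits(x, "sweep_result")) {
    files <- character(0)
    for (key in names(x$results %||% list())) {
      files <- c(files, write_outputs(x$results[[key]], output_dir))
    }
    rep_list <- lapply(x$reports, function(r) {
      list(luxated = r$luxated,
           onset_time_s = r$onset_time,
           first_zero_time_s = r$first_zero_time,
           direction = r$direction,
           max_medial_displacement_mm = r$max_medial_displacement)
    })
    sweep_json <- file.path(output_dir, "sweep.json")
    jsonlite::write_json(list(angles = x$angles,
                              reports = rep_list,
                              critical_angle = x$critical_angle,
                              stable_max_angle = x$stable_max_angle,
                              errors = x$errors,
                              package_version = ver),
                         sweep_json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(c(files, sweep_json))
  }
  stop("write_outputs expects a simulation_result or sweep_result")
}

write_samples_csv <- function(samples, path) {
  out <- samples
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- fmt9(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
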