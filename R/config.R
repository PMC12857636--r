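#' Run configuration
#'
#' Validated, serializable description of a full pipeline run: the potential
#' (built-in name + parameters, no adapter reference resolvable from a
#' file), the chain-optimizer settings, profile options, grid-analysis
#' options, group annotations, output directory, seed and log level.
#' Unknown keys are rejected up front, before any computation, and the
#' object round-trips through YAML exactly.
#'
#' @param potential list: `name` (`"threading"` or a benchmark surface
#'   name) plus parameters forwarded to [threading_config()].
#' @param neb list of [neb_config()] arguments.
#' @param profile list: `align`, `eps_flat`.
#' @param nci list: `spacing`, `iso_s`, `rho_min`, `rho_max`, `padding`.
#' @param eda list: `max_points`, `coarsen`, `images` (index subset).
#' @param groups named list of index vectors (annotations for external
#'   structures).
#' @param output_dir output directory.
#' @param seed integer seed.
#' @param log_level `"info"` or `"quiet"`.
#' @export
run_config <- function(potential = list(name = "threading"), neb = list(),
                       profile = list(), nci = list(), eda = list(),
                       groups = list(), output_dir = "rotapath_out",
                       seed = 1L, log_level = "info") {
  allowed <- list(
    potential = c("name", "n_ring_beads", "ring_bond_length", "ring_stiffness",
                  "angle_stiffness", "axle_bead_count", "terminal_radius",
                  "lj_epsilon", "charge_state", "bead_charges", "dielectric",
                  "seed"),
    neb = c("n_images", "spring_k", "climbing", "string_method", "fmax_band",
            "fmax_endpoint", "max_steps", "history_size", "max_step", "seed"),
    profile = c("align", "eps_flat"),
    nci = c("spacing", "iso_s", "rho_min", "rho_max", "padding"),
    eda = c("max_points", "coarsen", "images")
  )
  for (sec in names(allowed)) {
    given <- get(sec)
    bad <- setdiff(names(given), allowed[[sec]])
    if (length(bad)) {
      stop("validation error: unknown key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  if (!log_level %in% c("info", "quiet")) {
    stop("validation error: log_level must be 'info' or 'quiet'")
  }
  # eager validation of the numeric sections
  do.call(neb_config, neb)
  if (identical(potential$name, "threading")) {
    do.call(threading_config, potential[setdiff(names(potential), "name")])
  } else if (!is.null(potential$name)) {
    benchmark_surface(potential$name)
  }
  cfg <- list(potential = potential, neb = neb, profile = profile, nci = nci,
              eda = eda, groups = groups, output_dir = output_dir,
              seed = as.integer(seed), log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

#' Read and validate a YAML run configuration
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("potential", "neb", "profile", "nci", "eda", "groups",
             "output_dir", "seed", "log_level")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("validation error: unknown top-level key(s): ",
         paste(bad, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()]. @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  write_atomic(path, function(tmp) yaml::write_yaml(unclass(cfg), tmp))
  invisible(path)
}

#' Write the run manifest of an output directory
#'
#' Records the configuration hash, seed and library versions; identical
#' manifests imply identical numerical outputs (all randomness is
#' seed-derived and all solvers are deterministic).
#'
#' @param dir output directory.
#' @param cfg the [run_config()] used.
#' @export
write_manifest <- function(dir, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("rotapath")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = "run manifest"
  )
  write_atomic(file.path(dir, "manifest.json"), function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(file.path(dir, "manifest.json"))
}

#' Build the potential and endpoints described by a run configuration
#' @param cfg a [run_config()].
#' @return For `"threading"`, the [build_threading_model()] list; for a
#'   benchmark surface, the [benchmark_surface()] list.
#' @export
resolve_potential <- function(cfg) {
  pot <- cfg$potential
  if (identical(pot$name, "threading")) {
    tc <- do.call(threading_config,
                  c(pot[setdiff(names(pot), "name")]))
    build_threading_model(tc)
  } else {
    benchmark_surface(pot$name)
  }
}
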