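#' Load a configuration file
#'
#' Reads a YAML or JSON configuration and returns the corresponding
#' fully-resolved parameter object with shipped defaults filled in for
#' omitted fields. The top-level key `kind` selects the object type:
#' `"neuron"`, `"girk"`, `"release"`, `"diffusion"`, `"geometry"` or
#' `"network"`. Unknown keys are rejected with the offending name.
#'
#' For `kind: network`, the remaining keys mirror the arguments of
#' [network_config()], with `neurons` a list of neuron-parameter
#' override lists, `protocols` a list of step tables and `edges` /
#' `gap_junctions` row lists.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return a parameter object (see above).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  if (is.null(raw$kind))
    stop("config must have a top-level 'kind' key", call. = FALSE)
  kind <- raw$kind
  body <- raw[setdiff(names(raw), "kind")]
  ctor <- switch(kind,
                 neuron = lc_neuron_params,
                 girk = girk_params,
                 release = release_params,
                 diffusion = diffusion_params,
                 geometry = lc_geometry_calibration,
                 network = NULL,
                 stop("unknown config kind: ", kind, call. = FALSE))
  if (kind == "network") return(network_config_from_list(body))
  if (kind != "neuron") {
    bad <- setdiff(names(body), names(formals(ctor)))
    if (length(bad))
      stop("unknown key(s) in ", kind, " config: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(ctor, body)
}

network_config_from_list <- function(body) {
  known <- c("neurons", "edges", "gap_junctions", "protocols", "girk",
             "release", "diffusion", "kernel", "duration_ms", "dt",
             "record_dt", "noise", "seed")
  bad <- setdiff(names(body), known)
  if (length(bad))
    stop("unknown key(s) in network config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  neurons <- lapply(body$neurons %||% list(list()),
                    function(ov) do.call(lc_neuron_params, as.list(ov)))
  args <- list(neurons = neurons)
  if (!is.null(body$edges))
    args$edges <- dplyr::bind_rows(lapply(body$edges, tibble::as_tibble))
  if (!is.null(body$gap_junctions))
    args$gap_junctions <- dplyr::bind_rows(lapply(body$gap_junctions,
                                                  tibble::as_tibble))
  if (!is.null(body$protocols))
    args$protocols <- lapply(body$protocols, function(p)
      do.call(stimulus_protocol, as.list(p)))
  if (!is.null(body$girk)) args$girk <- do.call(girk_params, body$girk)
  if (!is.null(body$release))
    args$release <- do.call(release_params, body$release)
  if (!is.null(body$diffusion))
    args$diffusion <- do.call(diffusion_params, body$diffusion)
  for (k in c("kernel", "duration_ms", "dt", "record_dt", "noise", "seed"))
    if (!is.null(body[[k]])) args[[k]] <- body[[k]]
  do.call(network_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a parameter object as a config file
#'
#' Inverse of [load_config()] for the simple parameter kinds; loading a
#' saved config reproduces the object (round-trip idempotence).
#'
#' @param object a parameter object created by one of the constructors.
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(object, path) {
  kind <- switch(class(object)[1],
                 lc_neuron_params = "neuron", girk_params = "girk",
                 release_params = "release", diffusion_params = "diffusion",
                 geometry_calibration = "geometry",
                 stop("cannot serialise objects of class ",
                      class(object)[1], call. = FALSE))
  fields <- unclass(object)
  # derived girk fields are recomputed on load
  if (kind == "girk") fields$t_peak <- fields$B <- NULL
  out <- c(list(kind = kind), fields)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else yaml::write_yaml(out, path)
  invisible(path)
}

#' Deterministic fixture bundle
#'
#' Small, seeded inputs exercising every module: network configurations
#' for the three interaction scenarios (shortened), a 289-cell synthetic
#' cloud, a template action-potential trace and a diffusion grid
#' specification. The same seed yields an identical bundle.
#'
#' @param seed integer seed.
#' @return a named list.
#' @export
make_fixtures <- function(seed = 1) {
  set.seed(seed)
  params <- lc_neuron_params()
  amp <- 10 # nominal high-activity step (uA/cm^2), fixed for determinism
  template_t <- seq(0, 200, by = 0.1)
  template <- -60 + 80 * exp(-((template_t - 100) / 0.8)^2) -
    8 * exp(-(pmax(template_t - 101, 0)) / 40) *
      (template_t > 100)
  list(
    dendro_somatic = scenario_dendro_somatic(params, step_amp = amp,
                                             duration_ms = 4000,
                                             seed = seed,
                                             kernel = "shipped"),
    autoinhibition = scenario_autoinhibition(params, step_amp = amp,
                                             duration_ms = 4000,
                                             seed = seed,
                                             kernel = "shipped"),
    volume = scenario_volume(params, step_amp = amp, n_steps = 1,
                             duration_ms = 5000, seed = seed,
                             kernel = "shipped"),
    cloud = generate_lc_cloud(289, seed = seed),
    template_ap = tibble::tibble(time_ms = template_t, mV = template),
    diffusion_grid = list(r_um = c(5, 10, 15, 20, 22.5, 25, 50),
                          t_ms = seq(50, 1000, by = 50)))
}

#' Run manifest
#'
#' Provenance record written beside simulation outputs: configuration
#' hash, seed, package version, file checksums and a timestamp.
#'
#' @param files character vector of output file paths.
#' @param config the configuration object used.
#' @param seed the seed used.
#' @param path optional JSON path to write.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(files = character(), config = NULL, seed = NULL,
                         path = NULL) {
  man <- list(
    package = "lcsim",
    version = as.character(utils::packageVersion("lcsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(config),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}

#' Export simulation outputs
#'
#' Writes the trace table as CSV, spike times and summary as JSON, the
#' release log as CSV, and a manifest JSON, into `dir`.
#'
#' @param sim an `lc_sim` object.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
export_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_trace <- file.path(dir, "trace.csv")
  f_spikes <- file.path(dir, "spikes.json")
  f_rel <- file.path(dir, "releases.csv")
  utils::write.csv(as.data.frame(sim$trace), f_trace, row.names = FALSE)
  jsonlite::write_json(
    list(spikes_ms = sim$spikes,
         rate_hz = vapply(sim$spikes, function(s)
           1000 * length(s) / sim$config$duration_ms, numeric(1))),
    f_spikes, auto_unbox = FALSE, digits = NA)
  utils::write.csv(as.data.frame(sim$releases), f_rel, row.names = FALSE)
  run_manifest(c(f_trace, f_spikes, f_rel), sim$config, sim$meta$seed,
               file.path(dir, "manifest.json"))
}
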