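#' Read and validate a pipeline run configuration
#'
#' Configurations are JSON objects with a global `seed`, an `out_dir`, and
#' optional per-stage blocks (`synthgen`, `preprocess`, `spotdetect`,
#' `spatialstats`, `nucgrad`, `sddsim`, `fitmodel`). Unknown top-level or
#' stage keys are rejected so that typos fail loudly.
#'
#' @param path path to a JSON file, or a list already parsed.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else path
  known_top <- c("seed", "out_dir", "verbosity", "synthgen", "preprocess",
                 "spotdetect", "spatialstats", "nucgrad", "sddsim",
                 "fitmodel")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  known_stage <- list(
    synthgen = c("stage", "geometry_mode", "n_particles", "dims",
                 "background_photons", "gain", "read_noise_sd"),
    preprocess = c("max_shift", "n_patches", "patch_size", "smooth"),
    spotdetect = c("threshold", "center_radius_px", "surround_radius_px",
                   "r_min", "r_max", "min_shadows", "xy_radius_px",
                   "z_window"),
    spatialstats = c("n_bins"),
    nucgrad = c("n_bins", "fit_window", "decay_length_el",
                "attenuation_length_um"),
    sddsim = c("D", "tau", "T_src_on", "T_src_off", "T_diff_off",
               "D_residual", "source_mode", "length_um", "width_um",
               "spacing_um"),
    fitmodel = c("D", "tau", "T_src_on", "T_src_off", "T_diff_off",
                 "noise_fraction"))
  for (st in intersect(names(cfg), names(known_stage))) {
    bad <- setdiff(names(cfg[[st]]), known_stage[[st]])
    if (length(bad))
      stop(sprintf("unknown keys in '%s': %s", st,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% tempfile("bcdgrad_run_")
  structure(cfg, class = "run_config")
}

#' Run a pipeline stage and write versioned outputs with a manifest
#'
#' Thin orchestration over the package functions: each subcommand generates
#' or loads its inputs, runs the corresponding stage, writes its artifacts
#' under `out_dir` and records a manifest (inputs, parameters, seed,
#' checksums) so any run is reproducible from the manifest alone.
#'
#' @param subcommand one of `"simulate-images"`, `"simulate-gradients"`,
#'   `"detect"`, `"spatial-stats"`, `"sdd"`, `"fit"`, `"full-demo"`.
#' @param config a `run_config` (or path to one).
#' @return Invisibly, a list with the paths written and the main result.
#' @export
run_pipeline <- function(subcommand = c("simulate-images",
                                        "simulate-gradients", "detect",
                                        "spatial-stats", "sdd", "fit",
                                        "full-demo"),
                         config = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  sg <- cfg$synthgen %||% list()
  dims <- sg$dims %||% c(200, 512, 16)
  # desk-scale embryo (1 px = 1 um) sized to the requested stack
  len <- min(500, dims[2] - 12)
  model <- embryo_model(length_um = len, width_um = min(0.36 * len,
                                                        dims[1] - 10),
                        pixel_size_nm = 1000, z_step_nm = 1000,
                        stage = sg$stage %||% 12,
                        geometry_mode = sg$geometry_mode %||%
                          (if ((sg$stage %||% 12) < 7) "wedge" else "cup"))
  artifacts <- list()
  result <- NULL

  if (subcommand %in% c("simulate-images", "detect", "spatial-stats",
                        "full-demo")) {
    particles <- sample_particles(model, n_particles = sg$n_particles %||% 2000,
                                  seed = seed)
    spec <- render_spec(background_photons = sg$background_photons %||% 100,
                        gain = sg$gain %||% seq(2.2, 2.8, length.out = dims[3]),
                        read_noise_sd = sg$read_noise_sd %||% 3,
                        seed = seed + 1)
    rendered <- render_stack(particles, model, spec, dims)
    artifacts$stack <- write_synthetic_embryo(rendered, cfg$out_dir,
                                              prefix = "embryo",
                                              config = unclass(cfg))
    result <- rendered
  }
  if (subcommand %in% c("detect", "spatial-stats", "full-demo")) {
    pp <- cfg$preprocess %||% list()
    stack <- realign_stack(result$stack, max_shift = pp$max_shift %||% 5L)
    gains <- estimate_gains(stack, n_patches = pp$n_patches %||% 2000,
                            seed = seed + 2)
    stack <- normalize_slices(stack, gains)
    sdcfg <- cfg$spotdetect %||% list()
    parts <- detect_particles(
      stack,
      dog_params(center_radius_px = sdcfg$center_radius_px %||% 1.5,
                 surround_radius_px = sdcfg$surround_radius_px %||% 2.5,
                 threshold = sdcfg$threshold %||% 150),
      filter_criteria(r_min = sdcfg$r_min %||% 0.7,
                      r_max = sdcfg$r_max %||% 2.5,
                      min_shadows = sdcfg$min_shadows %||% 1L))
    p_detect <- file.path(cfg$out_dir, "particles.csv")
    write.csv(parts, p_detect, row.names = FALSE)
    artifacts$particles <- p_detect
    result <- parts
  }
  if (subcommand %in% c("spatial-stats", "full-demo")) {
    reg <- known_registration(model, dims)
    proj <- project_particles(result, reg)
    dist <- ap_distribution(proj, n_bins = (cfg$spatialstats %||% list())$n_bins %||% 50)
    p_dist <- file.path(cfg$out_dir, "ap_distribution.csv")
    write.csv(as.data.frame(dist), p_dist, row.names = FALSE)
    artifacts$ap_distribution <- p_dist
    result <- list(particles = proj, distribution = dist,
                   anterior20 = intensity_fraction(proj, 0.2))
  }
  if (subcommand %in% c("simulate-gradients", "sdd", "fit")) {
    sp <- cfg$sddsim %||% list()
    geometry <- sdd_geometry(sp$length_um %||% 500, sp$width_um %||% 180,
                             sp$spacing_um %||% 10)
    params <- sdd_params(D = sp$D %||% 3.1, tau = sp$tau %||% 100,
                         T_src_on = sp$T_src_on %||% 7,
                         T_src_off = sp$T_src_off %||% 13,
                         T_diff_off = sp$T_diff_off %||% 12,
                         source_mode = sp$source_mode %||% "realistic")
    if (subcommand == "fit") {
      fm <- cfg$fitmodel %||% list()
      series <- simulate_gradient_series(params,
                                         noise_fraction = fm$noise_fraction %||% 0.1,
                                         seed = seed, geometry = geometry)
      fit <- sdd_grid_search(series, geometry,
                             default_sources(geometry, seed = 1),
                             default_grids(D = fm$D %||% c(1, 2, 3.1, 4, 6),
                                           tau = fm$tau %||% c(60, 100, 140, 200)))
      p_fit <- file.path(cfg$out_dir, "best_fit.json")
      jsonlite::write_json(fit$best, p_fit, auto_unbox = TRUE, digits = NA)
      artifacts$best_fit <- p_fit
      result <- fit
    } else {
      sol <- run_paper_scenario(params = params, geometry = geometry,
                                seed = seed)
      p_prof <- file.path(cfg$out_dir, "profiles.csv")
      write.csv(sol$snapshots, p_prof, row.names = FALSE)
      artifacts$profiles <- p_prof
      result <- sol
    }
  }
  manifest <- list(subcommand = subcommand, seed = seed,
                   config = unclass(cfg),
                   artifacts = lapply(artifacts, function(p) {
                     p <- unname(unlist(p))
                     data.frame(path = p, md5 = tools::md5sum(p),
                                row.names = NULL)
                   }),
                   package_version = as.character(utils::packageVersion("bcdgrad")))
  p_man <- file.path(cfg$out_dir, paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA)
  invisible(list(artifacts = artifacts, manifest = p_man, result = result))
}
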