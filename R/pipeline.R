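#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, by extension) configuration with a `params` block
#' holding the six rate constants plus `pool_total`, and optional `stages`,
#' `sweep`, `hypoxia`, `noise`, `fit` and `seed` blocks. Validation reports
#' each offending key by name; defaults are filled for everything optional.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` configuration file.
#' @return A list of class `run_config` with elements `params`
#'   ([kinetic_params()]), `stages` (character vector), `seed` (integer),
#'   `sweep` (list: `ippi_values`, `r0`, `n_r`), `hypoxia` (list:
#'   `kd2_factors`, `k4_values`), `noise` ([noise_model()]), `fit` (list:
#'   `n_restarts`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "warburgnfl_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$params)) {
    abort("config is missing the 'params' block",
          class = "warburgnfl_config_error")
  }
  p <- raw$params
  if (is.null(p$pool_total)) p$pool_total <- 1
  params <- as_kinetic_params(p)

  stages_known <- c("steady", "simulate", "sweep", "hypoxia", "generate",
                    "fit")
  stages <- raw$stages %||% stages_known
  bad <- setdiff(stages, stages_known)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "warburgnfl_usage_error")
  }

  sweep <- modifyList(list(ippi_values = c(1.05, 1.5, 2, 5, 10),
                           r0 = 1 / 100, n_r = 201),
                      raw$sweep %||% list())
  hypoxia <- modifyList(list(kd2_factors = seq(0.2, 1, by = 0.2),
                             k4_values = params$k4 * c(1, 2, 5)),
                        raw$hypoxia %||% list())
  noise_raw <- modifyList(list(sigma = 0.05, seed = raw$seed %||% 1L),
                          raw$noise %||% list())
  fit_cfg <- modifyList(list(n_restarts = 10), raw$fit %||% list())

  structure(list(params = params,
                 stages = stages,
                 seed = as.integer(raw$seed %||% 1L),
                 sweep = sweep, hypoxia = hypoxia,
                 noise = noise_model(noise_raw$sigma, noise_raw$seed),
                 fit = fit_cfg),
            class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config` object.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(params = unclass(config$params),
              stages = config$stages,
              seed = config$seed,
              sweep = config$sweep,
              hypoxia = config$hypoxia,
              noise = list(sigma = config$noise$sigma,
                           seed = config$noise$seed),
              fit = config$fit)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order -- steady-state
#' analysis, trajectory simulation, ratio sweep, hypoxia scenario,
#' synthetic-data generation, and parameter recovery -- writing each result
#' under `out_dir` and finishing with a JSON manifest listing every written
#' file with its MD5 content hash. Reruns with the same configuration and
#' seed are bit-identical at the manifest level.
#'
#' @param config A `run_config` from [load_config()], or a path to one.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return The manifest, invisibly: a list with `seed`, `stages`, and
#'   `files` (tibble of `file`, `md5`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ",
                        ...)
  }
  params <- config$params
  written <- character(0)
  add <- function(f) written <<- c(written, f)

  dataset <- NULL
  for (stage in intersect(c("steady", "simulate", "sweep", "hypoxia",
                            "generate", "fit"), config$stages)) {
    switch(stage,
      steady = {
        say("steady", "computing steady-state branches")
        ss <- steady_states(params)
        add(write_steady_states(ss, file.path(out_dir, "steady_states.tsv"),
                                file.path(out_dir, "steady_states.json")))
        add(file.path(out_dir, "steady_states.json"))
      },
      simulate = {
        say("simulate", "integrating trajectory to convergence")
        ini <- c(C_P = 0.1, N = 0.5 * quiescence_nadh(params))
        traj <- simulate_trajectory(params, ini)
        add(write_trajectory(traj, file.path(out_dir, "trajectory.csv")))
        add(file.path(out_dir, "trajectory.csv.json"))
      },
      sweep = {
        say("sweep", "ratio sweep over ",
            length(config$sweep$ippi_values), " IPPI values")
        r0 <- config$sweep$r0
        sw <- ratio_sweep(config$sweep$ippi_values, r0,
                          exp(seq(log(r0 / 10), log(10 * r0),
                                  length.out = config$sweep$n_r)))
        add(write_sweep(sw, file.path(out_dir, "ratio_sweep.tsv")))
      },
      hypoxia = {
        say("hypoxia", "scenario grid")
        hy <- hypoxia_scenario(params, config$hypoxia$kd2_factors,
                               config$hypoxia$k4_values)
        add(write_sweep(hy, file.path(out_dir, "hypoxia.tsv")))
      },
      generate = {
        say("generate", "synthetic dataset, sigma = ", config$noise$sigma)
        dataset <- generate_dataset(params, noise = config$noise)
        dsdir <- file.path(out_dir, "dataset")
        write_dataset(dataset, dsdir)
        add(file.path(dsdir, list.files(dsdir)))
      },
      fit = {
        say("fit", "parameter recovery (", config$fit$n_restarts,
            " restarts)")
        if (is.null(dataset)) dataset <- generate_dataset(params,
                                                          noise = config$noise)
        fit <- fit_parameters(dataset, init_guess = params,
                              n_restarts = config$fit$n_restarts,
                              restart_seed = config$seed)
        rep <- recovery_report(params, fit)
        f <- file.path(out_dir, "recovery.tsv")
        write.table(as.data.frame(rep), f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        add(f)
        jf <- file.path(out_dir, "fit.json")
        jsonlite::write_json(list(estimates = unclass(fit$estimates),
                                  loss = fit$loss,
                                  converged = fit$converged),
                             jf, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        add(jf)
      })
  }

  files <- tibble(file = basename(written),
                  md5 = unname(tools::md5sum(written))) |>
    dplyr::arrange(.data$file)
  manifest <- list(seed = config$seed, stages = config$stages,
                   files = files)
  jsonlite::write_json(list(seed = manifest$seed, stages = manifest$stages,
                            files = as.data.frame(files)),
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", length(written), " files written to ", out_dir)
  invisible(manifest)
}
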