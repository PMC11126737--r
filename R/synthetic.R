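#' Multiplicative log-normal observation noise
#'
#' Both observables are positive (a fold-change and a concentration), so
#' observation error is modelled as independent multiplicative log-normal
#' factors `exp(sigma * z)`, `z ~ N(0, 1)`, applied entrywise; `sigma = 0`
#' returns the noiseless truth.
#'
#' @param sigma Standard deviation on the log scale (>= 0). Default 0.05,
#'   i.e. roughly 5% relative error.
#' @param seed Master integer seed; per-series substreams are derived from
#'   it deterministically and recorded in the dataset provenance.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.05, seed = 1L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  structure(list(type = "lognormal", sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic noisy-observation dataset
#'
#' Integrates the model exactly on `t_grid` from each initial condition and
#' multiplies both observed columns by independent log-normal noise factors.
#' The default design uses three initial conditions straddling the steady
#' state, which keeps transients in the data and makes all six rate
#' constants identifiable (a constant trajectory pins only their
#' steady-state combinations).
#'
#' @param truth A [kinetic_params()] object: the generating parameters.
#' @param initials List of named vectors `c(C_P = ..., N = ...)`. `NULL`
#'   picks three spanning initial conditions around the proliferative (or
#'   quiescent) branch.
#' @param t_grid Increasing observation time grid.
#' @param noise A [noise_model()].
#' @return A list of class `nfl_dataset` with elements `series` (list of
#'   tibbles `time, C_P_obs, N_obs`), `truth`, `noise`, `initials`,
#'   `series_seeds`, and `t_grid`. Generation is bit-reproducible given
#'   (`seed`, `t_grid`, `truth`, `initials`).
#' @examples
#' ds <- generate_dataset(kinetic_params(2, 1, 1, 4, 2, 1),
#'                        t_grid = seq(0, 10, length.out = 20),
#'                        noise = noise_model(sigma = 0, seed = 7))
#' ds$series[[1]]
#' @export
generate_dataset <- function(truth, initials = NULL,
                             t_grid = seq(0, 25, length.out = 50),
                             noise = noise_model()) {
  truth <- as_kinetic_params(truth)
  stopifnot(inherits(noise, "noise_model"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0) || t_grid[1] < 0) {
    abort("t_grid must be increasing and non-negative",
          class = "warburgnfl_domain_error")
  }
  if (is.null(initials)) initials <- default_initials(truth)
  for (ini in initials) {
    if (any(!is.finite(c(ini[["C_P"]], ini[["N"]]))) ||
        any(c(ini[["C_P"]], ini[["N"]]) < 0)) {
      abort("initial states must be finite and non-negative",
            class = "warburgnfl_domain_error")
    }
  }

  # one master seed spawns one substream seed per series
  set.seed(noise$seed)
  seeds <- sample.int(.Machine$integer.max, length(initials))

  series <- purrr::map2(initials, seeds, function(ini, s) {
    traj <- simulate_trajectory(truth, ini, times = t_grid)
    set.seed(s)
    n <- nrow(traj)
    fac_cp <- exp(noise$sigma * stats::rnorm(n))
    fac_n <- exp(noise$sigma * stats::rnorm(n))
    tibble(time = traj$time,
           C_P_obs = traj$C_P * fac_cp,
           N_obs = traj$N * fac_n)
  })

  structure(list(series = series, truth = truth, noise = noise,
                 initials = initials, series_seeds = seeds, t_grid = t_grid),
            class = "nfl_dataset")
}

# initial conditions under and over the steady state, plus one far start
default_initials <- function(params) {
  target <- if (attr(params, "proliferative_feasible")) {
    ss <- steady_states(params)
    prolif <- ss[ss$branch == "proliferative", ]
    if (nrow(prolif) == 1) c(C_P = prolif$C_P_star, N = prolif$N_star)
    else c(C_P = 0, N = quiescence_nadh(params))
  } else {
    c(C_P = 0, N = quiescence_nadh(params))
  }
  cp <- max(target[["C_P"]], 0.5)
  nn <- target[["N"]]
  list(c(C_P = 0.25 * cp, N = 0.5 * nn),
       c(C_P = 2 * cp, N = 2 * nn),
       c(C_P = 0.1 * cp, N = 3 * nn))
}

#' @export
print.nfl_dataset <- function(x, ...) {
  cat(sprintf("<nfl_dataset> %d series x %d timepoints, sigma = %g, seed = %d\n",
              length(x$series), length(x$t_grid), x$noise$sigma,
              x$noise$seed))
  invisible(x)
}

#' Write / read a synthetic dataset (CSV series + JSON manifest)
#'
#' Each series becomes `series_<i>.csv` with header `time,C_P_obs,N_obs`;
#' the manifest records the generating parameters, noise model, seeds, and
#' initial conditions so a dataset round-trips through plain text (up to
#' textual float precision).
#'
#' @param dataset An `nfl_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly (writer); an `nfl_dataset` (reader).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "nfl_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(dataset$series)) {
    f <- file.path(dir, sprintf("series_%d.csv", i))
    write.csv(as.data.frame(dataset$series[[i]]), f, row.names = FALSE,
              quote = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(
    truth = unclass(dataset$truth),
    noise = unclass(dataset$noise),
    initials = lapply(dataset$initials, as.list),
    series_seeds = dataset$series_seeds,
    t_grid = dataset$t_grid,
    series_files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) {
    abort("manifest.json not found in dataset directory",
          class = "warburgnfl_config_error")
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (key in c("truth", "noise", "initials", "series_files", "t_grid")) {
    if (is.null(manifest[[key]])) {
      abort(paste0("dataset manifest is missing key '", key, "'"),
            class = "warburgnfl_config_error")
    }
  }
  for (key in rate_constant_names()) {
    if (is.null(manifest$truth[[key]])) {
      abort(paste0("dataset manifest truth block is missing key '", key, "'"),
            class = "warburgnfl_config_error")
    }
  }
  series <- purrr::map(manifest$series_files, function(f) {
    df <- read.csv(file.path(dir, f))
    tibble(time = df$time, C_P_obs = df$C_P_obs, N_obs = df$N_obs)
  })
  raw_ini <- manifest$initials
  initials <- if (is.data.frame(raw_ini)) {
    purrr::map(seq_len(nrow(raw_ini)),
               \(i) c(C_P = raw_ini$C_P[i], N = raw_ini$N[i]))
  } else {
    purrr::map(raw_ini, \(x) c(C_P = x$C_P, N = x$N))
  }
  structure(list(series = series,
                 truth = as_kinetic_params(manifest$truth),
                 noise = structure(as.list(manifest$noise),
                                   class = "noise_model"),
                 initials = initials,
                 series_seeds = manifest$series_seeds,
                 t_grid = manifest$t_grid),
            class = "nfl_dataset")
}
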