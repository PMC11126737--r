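#' Integration options for the trajectory simulator
#'
#' Conservative defaults for a cheap, low-dimensional, possibly stiff
#' system: the `lsoda` stiffness-switching integrator with tight tolerances
#' and a convergence test on the relative time derivatives.
#'
#' @param t_end Integration horizon. `NULL` (default) uses
#'   `50 / min(kd1, kd2)` -- fifty times the slowest relaxation time -- and
#'   allows automatic doubling (up to `max_extensions` times) until the
#'   convergence test passes.
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param n_steps Number of output points on the time grid.
#' @param convergence_tol Threshold on `max |dX/dt| / (|X| + atol)` below
#'   which the trajectory is declared converged to steady state.
#' @param max_extensions Maximum number of horizon doublings.
#' @return A list of class `integration_options`.
#' @export
integration_options <- function(t_end = NULL, rtol = 1e-8, atol = 1e-10,
                                n_steps = 200, convergence_tol = 1e-8,
                                max_extensions = 4) {
  stopifnot(rtol > 0, atol > 0, convergence_tol > 0, n_steps >= 2)
  if (!is.null(t_end)) stopifnot(t_end > 0)
  structure(list(t_end = t_end, rtol = rtol, atol = atol, n_steps = n_steps,
                 convergence_tol = convergence_tol,
                 max_extensions = max_extensions),
            class = "integration_options")
}

#' Numerically integrate the proliferation--NADH system
#'
#' Integrates the coupled ODEs from a non-negative initial state and reports
#' the trajectory as a tidy tibble. The equations preserve non-negativity
#' analytically, so any solver excursion below `-atol` raises an error;
#' smaller round-off undershoots are clamped to zero.
#'
#' @param params A [kinetic_params()] object.
#' @param initial Named vector/list with non-negative `C_P` and `N`.
#' @param options An [integration_options()] list.
#' @param times Optional explicit output time grid (overrides `t_end` /
#'   `n_steps` and disables automatic extension).
#' @return A tibble of class `nfl_trajectory` with columns `time`, `C_P`,
#'   `N`, and attributes `params`, `converged` (logical), `final_residual`
#'   (max relative derivative at the final state).
#' @examples
#' p <- kinetic_params(2, 1, 1, 4, 2, 1)
#' traj <- simulate_trajectory(p, c(C_P = 0.1, N = 0.5))
#' tail(traj)  # converges to the proliferative branch (C_P = 2, N = 1)
#' @export
simulate_trajectory <- function(params, initial,
                                options = integration_options(),
                                times = NULL) {
  params <- as_kinetic_params(params)
  C_P0 <- initial[["C_P"]]
  N0 <- initial[["N"]]
  if (!is.finite(C_P0) || !is.finite(N0) || C_P0 < 0 || N0 < 0) {
    abort("initial state must be finite and non-negative",
          class = "warburgnfl_domain_error")
  }

  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(c(parms$k1 * y[[1]] * y[[2]] / (parms$k2 + y[[2]]) -
             parms$kd1 * y[[1]],
           parms$k3 / (parms$k4 + y[[1]]) - parms$kd2 * y[[2]]))
  }

  run <- function(tt) {
    sol <- deSolve::ode(y = c(C_P = C_P0, N = N0), times = tt, func = rhs,
                        parms = params, method = "lsoda",
                        rtol = options$rtol, atol = options$atol)
    if (attr(sol, "istate")[1] < 0) {
      abort("ODE integration failed (step-size collapse or stiffness); see deSolve diagnostics",
            class = "warburgnfl_integration_error")
    }
    sol <- as.data.frame(sol)
    if (any(!is.finite(as.matrix(sol)))) {
      abort("ODE integration produced non-finite states",
            class = "warburgnfl_integration_error")
    }
    if (min(sol$C_P, sol$N) < -options$atol) {
      abort("integration violated non-negativity beyond solver tolerance",
            class = "warburgnfl_integration_error")
    }
    sol$C_P <- pmax(sol$C_P, 0)
    sol$N <- pmax(sol$N, 0)
    sol
  }

  residual_at <- function(sol) {
    last <- sol[nrow(sol), ]
    d <- ode_rhs(c(C_P = last$C_P, N = last$N), params)
    max(abs(d) / (abs(c(last$C_P, last$N)) + options$atol))
  }

  if (!is.null(times)) {
    stopifnot(length(times) >= 2, all(diff(times) > 0), times[1] >= 0)
    sol <- run(times)
    converged <- residual_at(sol) < options$convergence_tol
  } else {
    t_end <- options$t_end %||% (50 / min(params$kd1, params$kd2))
    extensions <- 0
    repeat {
      sol <- run(seq(0, t_end, length.out = options$n_steps))
      converged <- residual_at(sol) < options$convergence_tol
      if (converged || extensions >= options$max_extensions) break
      t_end <- t_end * 2
      extensions <- extensions + 1
    }
  }

  out <- tibble(time = sol$time, C_P = sol$C_P, N = sol$N)
  structure(out,
            class = c("nfl_trajectory", class(out)),
            params = params,
            converged = converged,
            final_residual = residual_at(sol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Promote a converged trajectory to a steady-state record
#'
#' If the final relative derivatives of a trajectory are below `threshold`,
#' returns the final state as a one-row steady-state tibble (branch inferred
#' from whether `C_P` is numerically zero); otherwise returns a typed
#' not-converged condition via `converged = FALSE` -- never a silent
#' default.
#'
#' @param traj An `nfl_trajectory` from [simulate_trajectory()].
#' @param threshold Convergence threshold on the final relative derivative;
#'   defaults to the trajectory's own integration threshold.
#' @return A one-row tibble with `branch`, `N_star`, `C_P_star`, `ippi`,
#'   `converged`, `final_residual`. `branch` is `NA` when not converged.
#' @export
converged_state <- function(traj, threshold = 1e-8) {
  if (!inherits(traj, "nfl_trajectory") || nrow(traj) == 0) {
    abort("'traj' must be a non-empty nfl_trajectory",
          class = "warburgnfl_domain_error")
  }
  params <- attr(traj, "params")
  last <- traj[nrow(traj), ]
  resid <- attr(traj, "final_residual")
  ok <- resid < threshold
  cp_zero <- last$C_P <= 1e-6 * max(1, last$N)
  tibble(
    branch = if (!ok) NA_character_ else if (cp_zero) "quiescent" else "proliferative",
    N_star = last$N,
    C_P_star = last$C_P,
    ippi = compute_ippi(params, last$N),
    converged = ok,
    final_residual = resid
  )
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV has header `time,C_P,N`; the sidecar records the kinetic
#' parameters and convergence metadata so a trajectory round-trips through
#' text.
#'
#' @param traj An `nfl_trajectory`.
#' @param path CSV output path; the sidecar is written at `<path>.json`.
#' @return `path` invisibly (writer); an `nfl_trajectory` (reader).
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj)[, c("time", "C_P", "N")], path,
            row.names = FALSE, quote = FALSE)
  params <- attr(traj, "params")
  jsonlite::write_json(
    list(params = unclass(params),
         converged = attr(traj, "converged"),
         final_residual = attr(traj, "final_residual")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- tibble(time = df$time, C_P = df$C_P, N = df$N)
  structure(out,
            class = c("nfl_trajectory", class(out)),
            params = as_kinetic_params(meta$params),
            converged = meta$converged,
            final_residual = meta$final_residual)
}
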