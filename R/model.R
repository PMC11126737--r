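#' Time derivatives of the proliferation--NADH feedback system
#'
#' The model couples cell proliferation `C_P` (fold increase in cell number
#' from a single cell) to cytoplasmic NADH concentration `N` through a
#' negative feedback loop:
#' \deqn{dC_P/dt = k_1 C_P N / (k_2 + N) - k_{d1} C_P}
#' \deqn{dN/dt   = k_3 / (k_4 + C_P) - k_{d2} N}
#' NADH drives cell-cycle progression (saturating positive arm, via CtBP),
#' while proliferation dilutes and consumes NADH (negative arm); the
#' remaining NADH-equivalent flux drains to mitochondria at rate `kd2 * N`.
#'
#' @param state Named numeric vector or list with components `C_P` and `N`,
#'   both non-negative.
#' @param params A [kinetic_params()] object.
#'
#' @return Named numeric vector `c(dC_P, dN)`.
#' @examples
#' p <- kinetic_params(2, 1, 1, 4, 2, 1)
#' ode_rhs(c(C_P = 0, N = 2), p)   # quiescent fixed point: both zero
#' @export
ode_rhs <- function(state, params) {
  params <- as_kinetic_params(params)
  C_P <- state[["C_P"]]
  N <- state[["N"]]
  if (!is.finite(C_P) || !is.finite(N) || C_P < 0 || N < 0) {
    abort("state components C_P and N must be finite and non-negative",
          class = "warburgnfl_domain_error")
  }
  c(dC_P = params$k1 * C_P * N / (params$k2 + N) - params$kd1 * C_P,
    dN = params$k3 / (params$k4 + C_P) - params$kd2 * N)
}

# Jacobian of the right-hand side at (C_P, N); used for the stability
# diagnostic on steady-state branches (an extension beyond the closed-form
# analysis, reported as stable/unstable/unknown).
model_jacobian <- function(state, params) {
  C_P <- state[["C_P"]]
  N <- state[["N"]]
  with(params, matrix(c(
    k1 * N / (k2 + N) - kd1, k1 * C_P * k2 / (k2 + N)^2,
    -k3 / (k4 + C_P)^2, -kd2
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("C_P", "N"), c("C_P", "N"))))
}

#' The IPPI dimensionless number
#'
#' IPPI ("inverse of potential-to-proliferation-increase") is the ratio of
#' the incoming glycolytic NADH flux to the lactate-amplified mitochondrial
#' NADH outflow at a baseline NADH level `N0`:
#' \deqn{IPPI = k_3 / (k_4 \, k_{d2} \, N_0)}
#' At a self-consistent baseline steady state with non-negative
#' proliferation, IPPI \eqn{\ge} 1; IPPI = 1 is the quiescence condition,
#' IPPI > 1 implies positive baseline proliferation, and lower IPPI gives a
#' larger relative proliferation gain when the NADH/NAD+ ratio falls.
#'
#' @param params A [kinetic_params()] object.
#' @param N0 Baseline cytoplasmic NADH concentration (> 0).
#' @return The IPPI value (dimensionless scalar).
#' @examples
#' compute_ippi(kinetic_params(2, 1, 1, 4, 2, 1), N0 = 2)  # 1: quiescent
#' @export
compute_ippi <- function(params, N0) {
  params <- as_kinetic_params(params)
  if (!is.numeric(N0) || any(!is.finite(N0)) || any(N0 <= 0)) {
    abort("N0 must be strictly positive and finite",
          class = "warburgnfl_domain_error")
  }
  params$k3 / (params$k4 * params$kd2 * N0)
}

#' Map between NADH/NAD+ ratio and NADH concentration
#'
#' Assumes a conserved total redox pool `T = NADH + NAD+`, so that
#' `N = T * r / (1 + r)`. This mapping turns the steady-state proliferation
#' expression in terms of `N` into the relative-proliferation formula in
#' terms of the redox ratio `r` (see [relative_proliferation()]).
#'
#' The physiological cytoplasmic ratio lies between roughly 1/700 and 1/60;
#' a warning (never an error) is raised for `r >= 1/60`, where the model's
#' small-ratio conclusions no longer apply even though the algebra remains
#' evaluable.
#'
#' @param r NADH/NAD+ ratio (> 0); vectorised.
#' @param pool_total Total NADH + NAD+ pool (> 0).
#' @param warn_unphysiological Emit a warning when `r >= 1/60`?
#' @return NADH concentration(s), in the units of `pool_total`.
#' @seealso [concentration_to_ratio()] for the inverse map.
#' @examples
#' ratio_to_concentration(1, pool_total = 2)  # equal split: N = 1
#' @export
ratio_to_concentration <- function(r, pool_total = 1,
                                   warn_unphysiological = TRUE) {
  check_positive(r, "r")
  check_positive(pool_total, "pool_total")
  if (warn_unphysiological && any(r >= physiological_ratio_max())) {
    warn(paste0("NADH/NAD+ ratio >= 1/60: outside the physiological range ",
                "(1/700 to 1/60); small-ratio conclusions do not apply"),
         class = "warburgnfl_ratio_warning")
  }
  pool_total * r / (1 + r)
}

#' @rdname ratio_to_concentration
#' @param N NADH concentration (> 0 and < `pool_total`).
#' @export
concentration_to_ratio <- function(N, pool_total = 1) {
  check_positive(N, "N")
  check_positive(pool_total, "pool_total")
  if (any(N >= pool_total)) {
    abort("N must be smaller than pool_total (NAD+ must be positive)",
          class = "warburgnfl_domain_error")
  }
  N / (pool_total - N)
}

# upper end of the cited physiological NADH/NAD+ window (1/700 .. 1/60)
physiological_ratio_max <- function() 1 / 60

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("'", name, "' must be strictly positive and finite"),
          class = "warburgnfl_domain_error")
  }
  invisible(x)
}
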