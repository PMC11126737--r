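#' Steady-state NADH level on the proliferative branch
#'
#' When proliferating cells are at steady state, the NADH level is pinned by
#' the cell-cycle and apoptosis constants alone:
#' \deqn{N^* = k_{d1} k_2 / (k_1 - k_{d1})}
#' It exists (positively) only when `k1 > kd1`; as `k1` approaches `kd1`
#' from above the required NADH level diverges.
#'
#' @param params A [kinetic_params()] object with `k1 > kd1`.
#' @return The steady NADH concentration (positive scalar).
#' @export
steady_state_n <- function(params) {
  params <- as_kinetic_params(params)
  if (params$k1 <= params$kd1) {
    abort(paste0("proliferative branch infeasible: k1 <= kd1 gives no ",
                 "positive steady NADH level"),
          class = "warburgnfl_branch_error")
  }
  params$kd1 * params$k2 / (params$k1 - params$kd1)
}

#' Steady-state proliferation at a given NADH level
#'
#' The negative feedback loop makes steady proliferation an inverse function
#' of NADH:
#' \deqn{C_P = k_3 / (k_{d2} N) - k_4}
#' The value may be negative (when the lactate-amplified mitochondrial
#' outflow exceeds the glycolytic inflow at that NADH level); it is returned
#' as-is, never clamped -- the dynamic system cannot reach negative states,
#' but the algebraic branch is informative (see the methods vignette).
#'
#' @param params A [kinetic_params()] object.
#' @param N NADH concentration (> 0); vectorised.
#' @return Steady-state proliferation (dimensionless; may be negative).
#' @export
steady_state_cp <- function(params, N) {
  params <- as_kinetic_params(params)
  check_positive(N, "N")
  params$k3 / (params$kd2 * N) - params$k4
}

#' Baseline NADH level required for quiescence
#'
#' Setting proliferation to zero at steady state gives the quiescent NADH
#' level \eqn{N_0 = k_3 / (k_{d2} k_4)}: quiescence at a moderate NADH level
#' needs either high oxidative phosphorylation (`kd2`) or high lactate
#' production (`k4`); as either vanishes the required NADH level diverges,
#' so without oxygen or pyruvate-to-lactate conversion quiescence is
#' unattainable.
#'
#' @inheritParams steady_state_n
#' @return The quiescent-baseline NADH concentration. [compute_ippi()] at
#'   this level is exactly 1.
#' @export
quiescence_nadh <- function(params) {
  params <- as_kinetic_params(params)
  params$k3 / (params$kd2 * params$k4)
}

#' All steady-state branches of the coupled system
#'
#' Returns the quiescent branch (`C_P = 0`, `N = k3/(k4*kd2)`), which always
#' exists, and -- when `k1 > kd1` -- the proliferative branch
#' (`N = kd1*k2/(k1-kd1)`, `C_P = k3/(kd2*N) - k4`). A proliferative branch
#' whose algebraic `C_P` is negative is labelled `"negative-algebraic"`: it
#' solves the steady-state equations but is unreachable from non-negative
#' initial conditions.
#'
#' Stability is a numerical diagnostic beyond the closed-form analysis: the
#' eigenvalues of the 2x2 Jacobian are computed at each branch and the branch
#' is labelled `"stable"` (all real parts < 0), `"unstable"`, or `"unknown"`
#' (a real part within tolerance of 0).
#'
#' @inheritParams steady_state_n
#' @return A tibble of class `nfl_steady`, one row per branch, with columns
#'   `branch`, `N_star`, `C_P_star`, `ippi`, `stable`, `residual` (the
#'   max-norm of the time derivatives at the branch point, using `C_P = 0`
#'   for the negative-algebraic label check).
#' @examples
#' steady_states(kinetic_params(2, 1, 1, 4, 2, 1))
#' @export
steady_states <- function(params) {
  params <- as_kinetic_params(params)

  branch_row <- function(branch, N_star, C_P_star) {
    state <- c(C_P = max(C_P_star, 0), N = N_star)
    resid <- if (C_P_star >= 0) {
      max(abs(ode_rhs(state, params)))
    } else {
      # algebraic residual for the unreachable branch, evaluated directly
      max(abs(c(params$k1 * C_P_star * N_star / (params$k2 + N_star) -
                  params$kd1 * C_P_star,
                params$k3 / (params$k4 + C_P_star) - params$kd2 * N_star)))
    }
    tibble(branch = branch,
           N_star = N_star,
           C_P_star = C_P_star,
           ippi = compute_ippi(params, N_star),
           stable = branch_stability(c(C_P = C_P_star, N = N_star), params),
           residual = resid)
  }

  out <- branch_row("quiescent", quiescence_nadh(params), 0)
  if (attr(params, "proliferative_feasible")) {
    N_star <- steady_state_n(params)
    C_P_star <- steady_state_cp(params, N_star)
    label <- if (C_P_star < 0) "negative-algebraic" else "proliferative"
    out <- dplyr::bind_rows(out, branch_row(label, N_star, C_P_star))
  }
  structure(out, class = c("nfl_steady", class(out)))
}

branch_stability <- function(state, params, tol = 1e-9) {
  ev <- eigen(model_jacobian(state, params), only.values = TRUE)$values
  re <- Re(ev)
  scale <- max(abs(re), 1)
  if (all(re < -tol * scale)) "stable"
  else if (any(re > tol * scale)) "unstable"
  else "unknown"
}

#' Classify the proliferation regime from IPPI
#'
#' IPPI < 1 corresponds to negative algebraic baseline proliferation,
#' IPPI = 1 (within tolerance) to quiescence, and IPPI > 1 to positive
#' proliferation. The quiescence condition is exact algebra, so only
#' floating-point slack is granted by default.
#'
#' @param ippi IPPI value(s) (> 0); vectorised.
#' @param tol Relative tolerance around 1 counted as quiescent.
#' @return Character vector in `c("negative", "quiescent", "proliferative")`.
#' @export
classify_regime <- function(ippi, tol = 1e-9) {
  check_positive(ippi, "ippi")
  dplyr::case_when(
    abs(ippi - 1) <= tol ~ "quiescent",
    ippi > 1 ~ "proliferative",
    TRUE ~ "negative"
  )
}

#' Relative proliferation as a function of the NADH/NAD+ ratio
#'
#' The closed-form ratio of steady proliferation at redox ratio `r` to that
#' at the baseline ratio `r0`:
#' \deqn{\frac{C_P}{C_{P0}} =
#'   \frac{IPPI \cdot \frac{r+1}{r_0+1} \cdot \frac{r_0}{r} - 1}{IPPI - 1}}
#' It equals 1 at `r = r0`, rises above 1 as `r` falls below `r0` (lower
#' redox ratio, faster proliferation), decreases in `r`, and for fixed
#' `r < r0` is larger for IPPI closer to 1; as IPPI grows the curves
#' collapse onto \eqn{\frac{r+1}{r_0+1}\frac{r_0}{r}}, independent of IPPI.
#' For `r` and `r0` both much greater than 1 the value tends to 1
#' (proliferation becomes invariant), though that regime is unphysiological.
#'
#' @param ippi IPPI value, strictly > 1 (at IPPI = 1 the baseline is
#'   quiescent and the ratio is undefined; see [quiescence_nadh()]).
#' @param r NADH/NAD+ ratio(s) (> 0); vectorised.
#' @param r0 Baseline NADH/NAD+ ratio (> 0).
#' @param warn_unphysiological Warn when `r` or `r0` is >= 1/60.
#' @return Relative proliferation `C_P / C_P0` (may be negative for large
#'   `r`: proliferation turns negative beyond the quiescence ratio).
#' @examples
#' relative_proliferation(2, r = 1 / 200, r0 = 1 / 100)  # about 2.98
#' @export
relative_proliferation <- function(ippi, r, r0, warn_unphysiological = TRUE) {
  check_positive(r, "r")
  check_positive(r0, "r0")
  if (!is.numeric(ippi) || length(ippi) != 1 || !is.finite(ippi)) {
    abort("'ippi' must be a single finite number",
          class = "warburgnfl_domain_error")
  }
  if (ippi <= 1) {
    abort(paste0("relative proliferation requires ippi > 1 (quiescent ",
                 "baseline has C_P0 = 0; analyse it via quiescence_nadh())"),
          class = "warburgnfl_domain_error")
  }
  if (warn_unphysiological && any(c(r, r0) >= physiological_ratio_max())) {
    warn("r or r0 >= 1/60: outside the physiological redox-ratio range",
         class = "warburgnfl_ratio_warning")
  }
  (ippi * ((r + 1) / (r0 + 1)) * (r0 / r) - 1) / (ippi - 1)
}

#' Redox ratio at which proliferating cells reach quiescence
#'
#' Setting the relative proliferation to zero and solving for `r` gives the
#' redox ratio a proliferating population must reach to become quiescent.
#' The zero condition is linear in `r`, with exact root
#' \deqn{r = \frac{IPPI \cdot r_0}{1 + r_0 - IPPI \cdot r_0}}
#' and, in the physiological small-ratio regime where
#' \eqn{(r+1)/(r_0+1) \approx 1}, the approximation \eqn{r \approx IPPI
#' \cdot r_0}: cells must *raise* their NADH/NAD+ ratio by the factor IPPI
#' (> 1) to exit the cycle. When `1 + r0 - ippi*r0 <= 0` no positive
#' quiescence ratio exists and `r_exact` is `NA` with `attainable = FALSE`.
#'
#' @param ippi IPPI value (>= 1).
#' @param r0 Baseline NADH/NAD+ ratio (> 0).
#' @return A tibble with columns `ippi`, `r0`, `r_exact`, `r_approx`
#'   (`= ippi * r0`), and `attainable`.
#' @export
quiescence_ratio <- function(ippi, r0) {
  check_positive(r0, "r0")
  if (!is.numeric(ippi) || any(!is.finite(ippi)) || any(ippi < 1)) {
    abort("'ippi' must be >= 1 (IPPI < 1 has no quiescence target)",
          class = "warburgnfl_domain_error")
  }
  denom <- 1 + r0 - ippi * r0
  exact <- ifelse(denom > 0, ippi * r0 / denom, NA_real_)
  tibble(ippi = ippi, r0 = r0,
         r_exact = exact,
         r_approx = ippi * r0,
         attainable = denom > 0)
}

#' Steady-state NADH flux decomposition
#'
#' Splits the NADH bookkeeping at a state into the incoming glycolytic flux
#' `k3`, the lactate-amplified mitochondrial outflow `k4 * kd2 * N`, and the
#' proliferation-coupled outflow `C_P * kd2 * N`. At any steady state these
#' balance: \eqn{k_3 = k_4 k_{d2} N + C_P k_{d2} N}; at a quiescent steady
#' state the glycolytic inflow is carried entirely by the lactate-amplified
#' outflow, which is why pyruvate-to-lactate conversion acts as an amplifier
#' of oxidative phosphorylation.
#'
#' @param params A [kinetic_params()] object.
#' @param state Named vector/list with `C_P` and `N`, at (or near) steady
#'   state.
#' @param tol Relative tolerance on the balance residual (fraction of `k3`)
#'   above which a warning flags that the state is not at steady state.
#' @return A one-row tibble with columns `incoming_glycolysis`,
#'   `outgoing_oxphos` (`kd2 * N`), `lactate_amplified_outflow`,
#'   `proliferation_flux`, `residual`, and `balanced`.
#' @examples
#' p <- kinetic_params(2, 1, 1, 4, 2, 1)
#' flux_decomposition(p, c(C_P = 2, N = 1))  # 4 = 2 + 2
#' @export
flux_decomposition <- function(params, state, tol = 1e-8) {
  params <- as_kinetic_params(params)
  C_P <- state[["C_P"]]
  N <- state[["N"]]
  base_out <- params$kd2 * N
  out <- tibble(
    incoming_glycolysis = params$k3,
    outgoing_oxphos = base_out,
    lactate_amplified_outflow = params$k4 * base_out,
    proliferation_flux = C_P * base_out
  )
  out$residual <- out$incoming_glycolysis - out$lactate_amplified_outflow -
    out$proliferation_flux
  out$balanced <- abs(out$residual) <= tol * params$k3
  if (!out$balanced) {
    warn(sprintf(paste0("flux balance residual %.3g exceeds %.1g * k3: ",
                        "state is not at steady state"),
                 out$residual, tol),
         class = "warburgnfl_flux_warning")
  }
  out
}

#' Write steady-state branches to disk
#'
#' Emits the branch table as tidy TSV (one row per branch) and, optionally,
#' as JSON for machine consumption.
#'
#' @param ss An `nfl_steady` tibble from [steady_states()].
#' @param path Output TSV path.
#' @param json_path Optional JSON path.
#' @return `path`, invisibly.
#' @export
write_steady_states <- function(ss, path, json_path = NULL) {
  write.table(as.data.frame(ss), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(ss), json_path, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
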