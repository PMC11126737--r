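#' Kinetic parameters of the proliferation--NADH feedback model
#'
#' Bundles the six rate constants of the coupled proliferation/NADH system
#' together with the total cytoplasmic redox pool. All quantities are in
#' arbitrary but mutually consistent units (the model is scale-free; see the
#' methods vignette).
#'
#' @param k1 Maximal NADH-dependent proliferation rate (1/time). Lumps the
#'   NADH--CtBP drive of the cell cycle.
#' @param k2 NADH concentration scale of the saturating proliferation /
#'   apoptosis term (concentration).
#' @param kd1 Cell-cycle-dependent apoptosis rate (1/time).
#' @param k3 Incoming NADH flux from the upstream steps of glycolysis
#'   (concentration/time).
#' @param k4 Fold decrease in the glycolytic NADH flux due to the
#'   pyruvate-to-lactate conversion reaction (dimensionless).
#' @param kd2 First-order rate constant of the NADH / NADH-equivalent flux to
#'   mitochondrial oxidative phosphorylation and the TCA cycle (1/time).
#' @param pool_total Total cytoplasmic NADH + NAD+ pool (concentration).
#'   Used only by the redox-ratio mapping; defaults to 1.
#'
#' @return An object of class `kinetic_params`: a named list of the seven
#'   values with a `proliferative_feasible` attribute, `TRUE` iff `k1 > kd1`
#'   (the proliferative steady-state branch has a positive NADH level only
#'   then).
#'
#' @examples
#' p <- kinetic_params(k1 = 2, k2 = 1, kd1 = 1, k3 = 4, k4 = 2, kd2 = 1)
#' p
#' steady_states(p)
#' @export
kinetic_params <- function(k1, k2, kd1, k3, k4, kd2, pool_total = 1) {
  vals <- list(k1 = k1, k2 = k2, kd1 = kd1, k3 = k3, k4 = k4, kd2 = kd2,
               pool_total = pool_total)
  validate_params(vals)
  structure(vals,
            proliferative_feasible = k1 > kd1,
            class = "kinetic_params")
}

validate_params <- function(p) {
  keys <- c("k1", "k2", "kd1", "k3", "k4", "kd2", "pool_total")
  missing <- setdiff(keys, names(p))
  if (length(missing) > 0) {
    abort(paste0("missing kinetic parameter(s): ",
                 paste(missing, collapse = ", ")),
          class = "warburgnfl_config_error")
  }
  for (key in keys) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("kinetic parameter '", key,
                   "' must be a single strictly positive finite number"),
            class = "warburgnfl_parameter_error")
    }
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  k1 = %g  k2 = %g  kd1 = %g  (proliferation / apoptosis)\n",
              x$k1, x$k2, x$kd1))
  cat(sprintf("  k3 = %g  k4 = %g  kd2 = %g  (glycolysis / lactate / oxphos)\n",
              x$k3, x$k4, x$kd2))
  cat(sprintf("  pool_total = %g (NADH + NAD+)\n", x$pool_total))
  cat(sprintf("  proliferative branch feasible (k1 > kd1): %s\n",
              attr(x, "proliferative_feasible")))
  invisible(x)
}

#' @export
as_tibble.kinetic_params <- function(x, ...) {
  tibble(parameter = c("k1", "k2", "kd1", "k3", "k4", "kd2", "pool_total"),
         value = c(x$k1, x$k2, x$kd1, x$k3, x$k4, x$kd2, x$pool_total))
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  x <- as.list(x)
  if (is.null(x$pool_total)) x$pool_total <- 1
  kinetic_params(x$k1, x$k2, x$kd1, x$k3, x$k4, x$kd2, x$pool_total)
}

# shared helper: the six fitted rate constants, in canonical order
rate_constant_names <- function() c("k1", "k2", "kd1", "k3", "k4", "kd2")
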