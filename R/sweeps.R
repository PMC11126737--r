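#' Relative-proliferation curves over a redox-ratio grid
#'
#' Evaluates the closed-form relative proliferation over the product grid of
#' IPPI values and NADH/NAD+ ratios, producing the tidy table behind the
#' model's curve families: proliferation rises as `r` falls below the
#' baseline `r0`, falls (eventually below zero) as `r` rises above it, and
#' the gain at fixed `r < r0` is larger for IPPI closer to 1, with all
#' curves collapsing once IPPI is much greater than 1.
#'
#' Default grids place `r0 = 1/100` inside the physiological window
#' (1/700 to 1/60) with `r` log-spaced over two decades around it, and an
#' IPPI family spanning near-quiescent (1.05) to amplifier-saturated (10);
#' exact published grids are not available, so these are representative
#' families, not pixel reproductions.
#'
#' @param ippi_values IPPI values, all > 1.
#' @param r0 Baseline NADH/NAD+ ratio.
#' @param r_grid Redox-ratio grid (positive, need not include `r0`).
#' @return A tibble of class `nfl_sweep` with columns `ippi`, `r`, `r0`,
#'   `relative_proliferation`, `regime` (sign-based:
#'   increased/baseline/decreased/negative), and `physiological` (is
#'   `r < 1/60`?).
#' @examples
#' sw <- ratio_sweep(ippi_values = c(1.5, 2), r0 = 1 / 100,
#'                   r_grid = c(1 / 200, 1 / 100, 1 / 50))
#' sw
#' @export
ratio_sweep <- function(ippi_values = c(1.05, 1.5, 2, 5, 10),
                        r0 = 1 / 100,
                        r_grid = exp(seq(log(r0 / 10), log(10 * r0),
                                         length.out = 201))) {
  if (any(ippi_values <= 1)) {
    abort("all ippi_values must be > 1 (quiescent baselines have no relative curve)",
          class = "warburgnfl_domain_error")
  }
  check_positive(r_grid, "r_grid")
  check_positive(r0, "r0")

  r0_base <- r0
  grid <- tidyr::expand_grid(ippi = ippi_values, r = r_grid)
  out <- grid |>
    dplyr::mutate(
      r0 = r0_base,
      relative_proliferation = purrr::map2_dbl(
        .data$ippi, .data$r,
        \(i, rr) relative_proliferation(i, rr, r0_base,
                                        warn_unphysiological = FALSE)),
      regime = dplyr::case_when(
        .data$relative_proliferation < 0 ~ "negative",
        .data$r == r0_base ~ "baseline",
        .data$relative_proliferation > 1 ~ "increased",
        TRUE ~ "decreased"
      ),
      physiological = .data$r < physiological_ratio_max()
    )
  structure(out, class = c("nfl_sweep", class(out)), r0 = r0_base)
}

#' Hypoxia scenario: competition between proliferation and quiescence
#'
#' Hypoxia lowers oxidative phosphorylation (scales `kd2` down) while
#' lactate production (`k4`) rises. Over a grid of `kd2` scalings and `k4`
#' values this sweep recomputes, per cell, the baseline NADH level set by
#' the cell-cycle constants, the IPPI number, the quiescence target ratio
#' `r/r0 = IPPI`, and the regime label. Because IPPI is proportional to
#' `1/(k4 * kd2)`, raising `k4` in proportion to the drop in `kd2` holds
#' IPPI constant: the iso-IPPI contour along which lactate production
#' compensates hypoxia and cells stay simultaneously proliferative and
#' close to quiescence.
#'
#' @param base A [kinetic_params()] object (its `k1, k2, kd1` fix the
#'   baseline NADH level; its `k3` is kept).
#' @param kd2_factors Multiplicative hypoxia-severity factors in (0, 1]
#'   applied to `base$kd2` (1 = normoxia, smaller = more severe hypoxia).
#' @param k4_values Absolute `k4` values to cross with the factors.
#' @return A tibble of class `nfl_hypoxia` with columns `kd2_factor`, `kd2`,
#'   `k4`, `N0`, `ippi`, `quiescence_ratio` (`r/r0` needed for quiescence),
#'   `regime`, and `feasible` (baseline NADH level exists, i.e.
#'   `k1 > kd1`).
#' @export
hypoxia_scenario <- function(base, kd2_factors, k4_values) {
  base <- as_kinetic_params(base)
  if (any(kd2_factors <= 0) || any(kd2_factors > 1)) {
    abort("kd2_factors must lie in (0, 1]",
          class = "warburgnfl_domain_error")
  }
  check_positive(k4_values, "k4_values")

  is_feasible <- attr(base, "proliferative_feasible")
  N0_base <- if (is_feasible) steady_state_n(base) else NA_real_

  out <- tidyr::expand_grid(kd2_factor = kd2_factors, k4 = k4_values) |>
    dplyr::mutate(
      kd2 = .data$kd2_factor * base$kd2,
      N0 = N0_base,
      feasible = is_feasible,
      ippi = if (is_feasible) base$k3 / (.data$k4 * .data$kd2 * N0_base)
             else NA_real_,
      quiescence_ratio = .data$ippi,
      regime = if (is_feasible) classify_regime(.data$ippi)
               else NA_character_
    ) |>
    dplyr::relocate("kd2_factor", "kd2", "k4", "N0", "ippi",
                    "quiescence_ratio", "regime", "feasible")
  structure(out, class = c("nfl_hypoxia", class(out)))
}

#' Write a sweep table as tidy TSV
#'
#' @param x An `nfl_sweep` or `nfl_hypoxia` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
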