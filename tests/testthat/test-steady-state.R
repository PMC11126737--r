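test_that("proliferative-branch NADH level: worked value, linearity, infeasibility", {
  expect_identical(steady_state_n(worked_params()), 1)
  p2 <- kinetic_params(2, 2, 1, 4, 2, 1)
  expect_identical(steady_state_n(p2), 2)  # doubling k2 doubles N*
  expect_error(steady_state_n(kinetic_params(1, 1, 1, 4, 2, 1)),
               class = "warburgnfl_branch_error")
  # k1 -> kd1+ divergence
  expect_gt(steady_state_n(kinetic_params(1 + 1e-12, 1, 1, 4, 2, 1)), 1e10)
})

test_that("steady proliferation: worked value, sign set by IPPI, monotonicity", {
  p <- worked_params()
  expect_identical(steady_state_cp(p, N = 1), 2)
  # at the quiescent NADH level (IPPI = 1) proliferation is exactly zero
  expect_identical(steady_state_cp(p, quiescence_nadh(p)), 0)
  # IPPI > 1 at a level below N0 -> positive; IPPI < 1 above N0 -> negative
  expect_gt(steady_state_cp(p, 1.5), 0)
  expect_lt(steady_state_cp(p, 3), 0)
  # strictly decreasing in N
  Ns <- c(0.5, 1, 2, 4)
  expect_true(all(diff(steady_state_cp(p, Ns)) < 0))
  expect_error(steady_state_cp(p, 0), class = "warburgnfl_domain_error")
})

test_that("coupled steady states: worked set has both branches with zero residual", {
  ss <- steady_states(worked_params())
  expect_s3_class(ss, "nfl_steady")
  q <- ss[ss$branch == "quiescent", ]
  pr <- ss[ss$branch == "proliferative", ]
  expect_equal(q$N_star, 2)
  expect_identical(q$C_P_star, 0)
  expect_identical(q$ippi, 1)
  expect_equal(pr$N_star, 1)
  expect_equal(pr$C_P_star, 2)
  expect_equal(pr$ippi, 2)
  expect_lt(max(ss$residual), 1e-12)
  expect_equal(pr$stable, "stable")
  expect_equal(q$stable, "unstable")  # with IPPI > 1 quiescence repels
})

test_that("infeasible proliferative branch: only the quiescent row is returned", {
  ss <- steady_states(kinetic_params(1, 1, 2, 4, 2, 1))
  expect_identical(ss$branch, "quiescent")
})

test_that("negative algebraic proliferation is labelled, not clamped", {
  # N* = 1 but k3/(kd2 N*) = 1 < k4 = 2 -> C_P* = -1
  p <- kinetic_params(2, 1, 1, 1, 2, 1)
  ss <- steady_states(p)
  neg <- ss[ss$branch == "negative-algebraic", ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$C_P_star, -1)
  expect_lt(neg$residual, 1e-12)
})

test_that("quiescent-baseline NADH: worked value, scaling, IPPI exactly 1", {
  p <- worked_params()
  expect_identical(quiescence_nadh(p), 2)
  half_kd2 <- kinetic_params(p$k1, p$k2, p$kd1, p$k3, p$k4, p$kd2 / 2)
  expect_identical(quiescence_nadh(half_kd2), 4)
  for (q in random_params(25, seed = 7)) {
    expect_equal(compute_ippi(q, quiescence_nadh(q)), 1, tolerance = 1e-14)
  }
})

test_that("regime classification around IPPI = 1", {
  expect_identical(classify_regime(1), "quiescent")
  expect_identical(classify_regime(1 + 1e-12), "quiescent")
  expect_identical(classify_regime(2), "proliferative")
  expect_identical(classify_regime(0.5), "negative")
  expect_identical(classify_regime(c(0.5, 1, 2)),
                   c("negative", "quiescent", "proliferative"))
})

test_that("relative proliferation: fixed points and frozen worked value", {
  # identity at r = r0 for any ippi > 1
  for (ippi in c(1.01, 2, 50)) {
    expect_equal(relative_proliferation(ippi, 1 / 100, 1 / 100), 1,
                 tolerance = 1e-14)
  }
  # frozen value computed independently: (2*(1.005/1.01)*2 - 1) / 1
  expect_equal(relative_proliferation(2, 1 / 200, 1 / 100),
               2.98019801980198, tolerance = 1e-12)
  expect_error(relative_proliferation(1, 1 / 200, 1 / 100),
               class = "warburgnfl_domain_error")
  expect_warning(relative_proliferation(2, 0.5, 0.4),
                 class = "warburgnfl_ratio_warning")
})

test_that("closed-form curve equals the ratio of steady proliferations under the pool map", {
  # Eq-consistency: C_P/C_P0 from the ratio formula must equal two direct
  # steady-state evaluations at pool-mapped NADH levels
  r0 <- 1 / 100
  pool <- 50
  for (ippi in c(1.2, 2, 10)) {
    N0 <- ratio_to_concentration(r0, pool, warn_unphysiological = FALSE)
    p <- params_with_ippi(ippi, N0 = N0, pool_total = pool)
    cp0 <- steady_state_cp(p, N0)
    for (r in c(1 / 400, 1 / 150, 1 / 80)) {
      N <- ratio_to_concentration(r, pool, warn_unphysiological = FALSE)
      direct <- steady_state_cp(p, N) / cp0
      formula <- relative_proliferation(ippi, r, r0)
      expect_equal(formula, direct, tolerance = 1e-10)
    }
  }
})

test_that("relative proliferation is monotone in r and in IPPI as expected", {
  r0 <- 1 / 100
  r_grid <- exp(seq(log(r0 / 10), log(10 * r0), length.out = 51))
  vals2 <- relative_proliferation(2, r_grid, r0, warn_unphysiological = FALSE)
  expect_true(all(diff(vals2) < 0))  # decreasing in r
  # for r < r0, curves with smaller IPPI dominate
  r_small <- r_grid[r_grid < r0]
  v_low <- relative_proliferation(1.5, r_small, r0,
                                  warn_unphysiological = FALSE)
  v_high <- relative_proliferation(5, r_small, r0,
                                   warn_unphysiological = FALSE)
  expect_true(all(v_low > v_high))
  # large-IPPI limit: ((r+1)/(r0+1)) * r0/r, independent of IPPI
  lim <- ((r_small + 1) / (r0 + 1)) * r0 / r_small
  v_huge <- relative_proliferation(1e6, r_small, r0,
                                   warn_unphysiological = FALSE)
  expect_equal(v_huge, lim, tolerance = 1e-4)
})

test_that("quiescence target ratio: exact root matches root-finding oracle", {
  # ippi = 1: already quiescent at r = r0
  qr <- quiescence_ratio(1, 1 / 100)
  expect_equal(qr$r_exact, 1 / 100, tolerance = 1e-12)
  expect_equal(qr$r_approx, 1 / 100)

  for (case in list(c(2, 1 / 700), c(1.3, 1 / 100), c(5, 1 / 300))) {
    ippi <- case[1]; r0 <- case[2]
    qr <- quiescence_ratio(ippi, r0)
    # oracle: 1-D root of the un-approximated quiescence condition
    f <- function(r) ippi * ((r + 1) / (r0 + 1)) * (r0 / r) - 1
    root <- uniroot(f, c(r0 / 10, 1), tol = 1e-14)$root
    expect_equal(qr$r_exact, root, tolerance = 1e-8)
    # approximate and exact agree to first order in r0
    expect_equal(qr$r_approx / qr$r_exact, 1, tolerance = 2 * ippi * r0)
    # proliferating cells must raise their redox ratio to go quiescent
    expect_gt(qr$r_exact / r0, 1)
  }
  # no positive root once ippi * r0 >= 1 + r0
  qr <- quiescence_ratio(300, 1 / 100)
  expect_false(qr$attainable)
  expect_true(is.na(qr$r_exact))
  expect_error(quiescence_ratio(0.5, 1 / 100),
               class = "warburgnfl_domain_error")
})

test_that("flux decomposition balances at both worked branches", {
  p <- worked_params()
  fq <- flux_decomposition(p, c(C_P = 0, N = 2))
  expect_identical(fq$incoming_glycolysis, 4)
  expect_identical(fq$lactate_amplified_outflow, 4)
  expect_identical(fq$proliferation_flux, 0)
  expect_true(fq$balanced)

  fp <- flux_decomposition(p, c(C_P = 2, N = 1))
  expect_identical(fp$lactate_amplified_outflow, 2)
  expect_identical(fp$proliferation_flux, 2)
  expect_true(fp$balanced)

  expect_warning(flux_decomposition(p, c(C_P = 1, N = 1)),
                 class = "warburgnfl_flux_warning")
})

test_that("proliferative steady states keep glycolytic inflow above the lactate outflow", {
  for (p in random_params(30, seed = 42, require_proliferative = TRUE)) {
    ss <- steady_states(p)
    pr <- ss[ss$branch == "proliferative", ]
    if (nrow(pr) == 0 || pr$C_P_star <= 0) next
    f <- flux_decomposition(p, c(C_P = pr$C_P_star, N = pr$N_star))
    expect_gt(f$incoming_glycolysis, f$lactate_amplified_outflow)
    expect_lt(abs(f$residual), 1e-8 * p$k3)
  }
})
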