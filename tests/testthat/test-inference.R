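test_that("the truth is a fixed point of the exact-data objective", {
  truth <- worked_params()
  ds <- generate_dataset(truth, t_grid = seq(0, 10, length.out = 25),
                         noise = noise_model(sigma = 0, seed = 2))
  fit <- fit_parameters(ds, init_guess = truth, n_restarts = 0)
  expect_lt(fit$loss, 1e-12)
  expect_true(fit$converged)
  expect_lt(max(fit$relative_error), 1e-6)
})

test_that("all six constants recover from perturbed starts on exact data", {
  truth <- worked_params()
  ds <- generate_dataset(truth, t_grid = seq(0, 10, length.out = 25),
                         noise = noise_model(sigma = 0, seed = 2))
  guess <- kinetic_params(truth$k1 * 1.2, truth$k2 * 0.8, truth$kd1 * 1.2,
                          truth$k3 * 0.8, truth$k4 * 1.2, truth$kd2 * 0.8)
  fit <- fit_parameters(ds, init_guess = guess, n_restarts = 2)
  expect_lt(max(fit$relative_error), 1e-4)
  expect_false(any(fit$flat_profile))
})

test_that("single-start and restart schedules are deterministic", {
  truth <- worked_params()
  ds <- generate_dataset(truth, t_grid = seq(0, 8, length.out = 20),
                         noise = noise_model(sigma = 0.05, seed = 6))
  f1 <- fit_parameters(ds, init_guess = truth, n_restarts = 3,
                       restart_seed = 9)
  f2 <- fit_parameters(ds, init_guess = truth, n_restarts = 3,
                       restart_seed = 9)
  expect_identical(unclass(f1$estimates), unclass(f2$estimates))
  expect_identical(f1$start_losses, f2$start_losses)
})

test_that("a dataset with fewer than two series is refused", {
  truth <- worked_params()
  ds <- generate_dataset(truth, initials = list(c(C_P = 0.5, N = 0.5)),
                         t_grid = seq(0, 5, length.out = 10),
                         noise = noise_model(0, 1))
  expect_error(fit_parameters(ds, init_guess = truth),
               class = "warburgnfl_domain_error")
})

test_that("recovery report: zero error at truth, IPPI error within propagated bound", {
  truth <- worked_params()
  ds <- generate_dataset(truth, t_grid = seq(0, 10, length.out = 25),
                         noise = noise_model(sigma = 0, seed = 4))
  fit <- fit_parameters(ds, init_guess = truth, n_restarts = 0)
  rep0 <- recovery_report(truth, fit)
  expect_true(all(rep0$relative_error < 1e-6))
  expect_setequal(rep0$quantity,
                  c(rate_names_for_tests(), "ippi", "N_star", "C_P_star"))

  # noisy fit: to first order the IPPI error is bounded by the sum of its
  # constituent errors (k3, k4, kd2 and the N* built from k1, k2, kd1)
  dsn <- generate_dataset(truth, t_grid = seq(0, 25, length.out = 50),
                          noise = noise_model(sigma = 0.05, seed = 13))
  fitn <- fit_parameters(dsn, init_guess = truth, n_restarts = 3)
  repn <- recovery_report(truth, fitn)
  err <- setNames(repn$relative_error, repn$quantity)
  bound <- err[["k3"]] + err[["k4"]] + err[["kd2"]] + err[["N_star"]]
  expect_lt(err[["ippi"]], bound * 1.2 + 1e-12)
})

test_that("constant quiescent data leaves the cell-cycle constants unidentified", {
  truth <- worked_params()
  N0 <- quiescence_nadh(truth)
  # two series pinned at the quiescent steady state: nothing moves, so the
  # proliferation-arm constants never enter the likelihood
  ds <- generate_dataset(truth,
                         initials = list(c(C_P = 0, N = N0),
                                         c(C_P = 0, N = N0)),
                         t_grid = seq(0, 10, length.out = 20),
                         noise = noise_model(0, 3))
  fit <- suppressWarnings(fit_parameters(ds, init_guess = truth,
                                         n_restarts = 0))
  flat <- fit$flat_profile
  expect_true(all(flat[c("k1", "k2", "kd1")]))
  # the redox-arm constants still move the NADH trajectory off its level
  expect_false(any(flat[c("k3", "kd2")]))
})

test_that("tidy and glance expose the fit in broom shape", {
  truth <- worked_params()
  ds <- generate_dataset(truth, t_grid = seq(0, 6, length.out = 12),
                         noise = noise_model(0, 5))
  fit <- fit_parameters(ds, init_guess = truth, n_restarts = 0)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$parameter, rate_names_for_tests())
  expect_true(all(c("estimate", "flat_profile", "relative_error") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
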