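# Two-phase packed-bed mass-balance model.

test_that("global coefficient matches its closed form and limits", {
  p <- pde_params(kf_a = 1, ks_a = 0.5, F = 1, tc1 = 10, tc2 = 20, H = 0.01,
                  switch_scale = 1)
  expect_equal(global_coefficient(15, p),
               1 * (1 + exp(-5)) / (1 + exp(-5)) + 0.5 / (1 + exp(-5)))
  expect_equal(global_coefficient(15, p), 1.496654, tolerance = 1e-6)

  # with the first switch far in the past, t = tc2 is the logistic half-point
  p2 <- pde_params(kf_a = 1, ks_a = 0.5, F = 1, tc1 = -1e6, tc2 = 20, H = 0.01,
                   switch_scale = 1)
  expect_equal(global_coefficient(20, p2), (1 * 1 + 0.5) / 2)
  # both switches exhausted: coefficient vanishes
  expect_lt(global_coefficient(1e4, p2), 1e-12)
  # stable far below tc1 (no overflow)
  p3 <- pde_params(kf_a = 0.05, ks_a = 0.02, tc1 = 200, tc2 = 500, H = 0.01,
                   switch_scale = 1)
  expect_true(is.finite(global_coefficient(0, p3)))
})

test_that("degenerate transfer gives zero yield", {
  bed <- ref_bed(); chg <- ref_charge()
  t <- c(10, 30, 60)
  pH0 <- ref_pde_params(H = 0)
  # H = 0: the equilibrium concentration is zero, nothing dissolves
  sol <- pde_solution(bed, chg, pH0, 0.4, 881.3, t, n_cells = 8)
  expect_lt(max(sol$yield_pct), 1e-10)
  pK0 <- ref_pde_params(kf_a = 0, ks_a = 0)
  sol2 <- pde_solution(bed, chg, pK0, 0.4, 881.3, t, n_cells = 8)
  expect_lt(max(sol2$yield_pct), 1e-10)
})

test_that("mass balance closes at every output time", {
  bed <- ref_bed(); chg <- ref_charge(0.84)
  crv <- simulate_extraction(bed, chg, ref_pde_params(), 0.4, 881.30,
                             study_times, n_cells = 50)
  expect_true(all(abs(attr(crv, "balance")) < 0.005))
  expect_true(all(diff(crv$yields) > 0))
  expect_lt(max(crv$yields), 100 * chg$oil_mass / bed$charge_mass)
})

test_that("single well-mixed cell matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  bed <- ref_bed(); chg <- ref_charge()
  # constant coefficient: switches pushed out of the horizon
  p <- pde_params(kf_a = 0.04, ks_a = 0.02, tc1 = -1e6, tc2 = 1e6, H = 0.005,
                  switch_scale = 1)
  sol <- pde_solution(bed, chg, p, flow_kg_h = 1e-9, rho_co2 = 881.3,
                      times = c(5, 20, 60, 150), n_cells = 1)
  Ka <- 0.06; eps <- bed$porosity; H <- 0.005
  M <- matrix(c(-Ka / eps, Ka * H / eps,
                Ka / (1 - eps), -Ka * H / (1 - eps)), 2, 2, byrow = TRUE)
  x0 <- c(0, sol$Cs0)
  for (i in seq_along(sol$times)) {
    exact <- as.numeric(Matrix::expm(M * sol$times[i]) %*% x0)
    expect_equal(unname(sol$C_f[i, 1]), exact[1], tolerance = 1e-6)
    expect_equal(unname(sol$C_s[i, 1]), exact[2], tolerance = 1e-6)
  }
})

test_that("early extraction is linear during the constant-rate period", {
  bed <- ref_bed(); chg <- ref_charge()
  # strong transfer: the outlet rides the Henry equilibrium
  p <- ref_pde_params(kf_a = 0.5, ks_a = 0.1)
  t <- seq(1, 240, by = 1)
  sol <- pde_solution(bed, chg, p, 0.4, 881.3, t, n_cells = 40, rtol = 1e-8)
  y <- sol$yield_pct
  sel <- y > 0 & y <= 0.1 * y[length(y)]
  fit <- stats::lm(y[sel] ~ t[sel])
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("grid refinement converges at first order", {
  bed <- ref_bed(); chg <- ref_charge()
  rep <- grid_convergence(bed, chg, ref_pde_params(), 0.4, 881.3,
                          c(60, 120, 240), c(10, 20, 40, 80))
  expect_true(all(diff(abs(diff(rep$yields$final_yield))) < 0))
  expect_true(all(rep$order > 0.8 & rep$order < 1.2))
  one <- grid_convergence(bed, chg, ref_pde_params(), 0.4, 881.3,
                          c(60, 240), c(12))
  expect_null(one$order)
  expect_equal(nrow(one$yields), 1)
})

test_that("invalid grids and parameters are refused", {
  bed <- ref_bed(); chg <- ref_charge()
  expect_error(simulate_extraction(bed, chg, ref_pde_params(), 0.4, 881.3,
                                   c(30, 15), n_cells = 10),
               class = "sfe_invalid_argument")
  expect_error(simulate_extraction(bed, chg, ref_pde_params(), 0.4, 881.3,
                                   study_times, n_cells = 2),
               class = "sfe_invalid_argument")
  expect_error(pde_params(kf_a = -1, ks_a = 0, tc1 = 1, tc2 = 2, H = 0.1),
               class = "sfe_invalid_argument")
  expect_error(pde_params(kf_a = 1, ks_a = 0, F = 2, tc1 = 1, tc2 = 2, H = 0.1),
               class = "sfe_invalid_argument")
})
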