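# Goodness of fit, multi-start estimation, initial slopes and OFAT.

test_that("goodness-of-fit statistics match hand arithmetic", {
  g <- gof_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(g$sse, g$r2, g$aard), c(0, 1, 0))

  g2 <- gof_stats(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g2$sse, 1)
  expect_equal(g2$r2, 0.5)
  expect_equal(g2$aard, 1 / 9)

  # zero observation carries no AARD term
  g3 <- gof_stats(c(0, 1, 2), c(0.1, 1, 2))
  expect_equal(g3$n_aard, 2)
  expect_equal(g3$aard, 0)

  expect_error(gof_stats(c(2, 2, 2), c(1, 2, 3)),
               class = "sfe_undefined_statistic")
  expect_error(gof_stats(c(0, 0), c(1, 1)), class = "sfe_undefined_statistic")

  # invariant to jointly permuting the pairs
  with_seed_local(9, {
    y <- runif(8); yh <- runif(8); o <- sample(8)
    a <- gof_stats(y, yh); b <- gof_stats(y[o], yh[o])
    expect_equal(c(a$sse, a$r2, a$aard), c(b$sse, b$r2, b$aard))
  })
})

test_that("kinetic curves enforce their invariants", {
  expect_error(kinetic_curve("x", c(0, 10, 5), c(0, 1, 2)),
               class = "sfe_invalid_argument")
  expect_error(kinetic_curve("x", c(0, 10), c(0, 1, 2)),
               class = "sfe_invalid_argument")
  expect_error(kinetic_curve("x", c(0, 10, 20), c(0, 2, 1)),
               class = "sfe_invalid_argument")
  # small decreases within the 2% noise allowance pass
  crv <- kinetic_curve("x", c(0, 10, 20), c(0, 2, 1.97))
  expect_s3_class(crv, "kinetic_curve")
})

test_that("noiseless single-exponential parameters are recovered exactly", {
  fit <- fit_model(ref_curve_I(5, 0.01), "I", n_starts = 8, seed = 2021)
  expect_equal(unname(fit$par[["Yinf"]]), 5, tolerance = 1e-6)
  expect_equal(unname(fit$par[["k"]]), 0.01, tolerance = 1e-6)
  expect_true(fit$converged)
  # the winner never exceeds the best initial point
  expect_lte(fit$gof$sse, min(fit$starts$sse_initial))
})

test_that("noiseless three-period parameters are recovered within 1%", {
  chg <- charge_composition(118.82, 0.84)
  truth <- list(r = 0.271, theta_e = 0.019, theta_i = 233.86, beta = 1.922)
  ctx <- list(ys = 0.0976, charge = chg, Qdot = 0.2 / 60, m_in = 130,
              gamma = 0.437)
  p8 <- analytic8_params(ys = ctx$ys, xu = chg$xu, r = truth$r,
                         theta_e = truth$theta_e, theta_i = truth$theta_i,
                         beta = truth$beta, gamma = ctx$gamma)
  q <- q_from_time(study_times, ctx$Qdot, chg$Nmg / 1000)
  crv <- kinetic_curve("r8", study_times,
                       e_to_yield_pct(model8_yield(q, p8), chg$Nmg, 130))
  fit <- fit_model(crv, "VIII", context = ctx, n_starts = 24, seed = 7)
  for (nm in names(truth)) {
    expect_lt(abs(fit$par[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)
  }
})

test_that("estimator bias on noisy replicates stays below 10%", {
  k_true <- 0.008
  center <- sfe_design_table()[11, , drop = FALSE]
  khat <- vapply(1:20, function(i) {
    crv <- generate_curve(ground_truth("I", seed = i), center)
    fit_model(crv, "I", n_starts = 6, seed = 1)$par[["k"]]
  }, numeric(1))
  expect_lt(abs(mean(khat) - k_true) / k_true, 0.10)
})

test_that("underdetermined fits and missing context are refused", {
  crv <- kinetic_curve("tiny", c(15, 30), c(0.5, 1.0))
  expect_error(fit_model(crv, "IV"), class = "sfe_underdetermined")
  expect_error(fit_model(ref_curve_I(), "VI"), "needs context")
  expect_error(fit_model(ref_curve_I(), "IX"), class = "sfe_unsupported_model")
})

test_that("initial slope uses the origin-constrained window estimator", {
  crv <- kinetic_curve("lin", c(15, 30, 45), 0.02 * c(15, 30, 45))
  expect_equal(initial_slope(crv), 0.02)
  # frozen closed-form sum for the reference exponential curve
  crv2 <- ref_curve_I(5.13, 0.002, times = c(15, 30, 45))
  t <- c(15, 30, 45); y <- 5.13 * (1 - exp(-0.002 * t))
  expect_equal(initial_slope(crv2), sum(t * y) / sum(t^2))
  expect_equal(initial_slope(crv2), 0.00987481, tolerance = 1e-6)
  crv3 <- kinetic_curve("zero", c(15, 30, 45), c(0, 0, 0))
  expect_equal(initial_slope(crv3), 0)
  expect_error(initial_slope(crv, window = 10), class = "sfe_invalid_argument")
  # points beyond the window are ignored
  crv4 <- kinetic_curve("win", c(15, 30, 45, 240), c(0.3, 0.6, 0.9, 20))
  expect_equal(initial_slope(crv4, window = 45), 0.02)
})

test_that("OFAT grouping isolates the varied factor", {
  mk <- function(id, P, T, F, y_scale) {
    kinetic_curve(id, study_times, y_scale * (1 - exp(-0.01 * study_times)),
                  pressure = P, temperature = T, flow = F, particle_size = 741)
  }
  curves <- list(mk("a", 200, 70, 0.4, 4), mk("b", 275, 70, 0.4, 5),
                 mk("c", 350, 70, 0.4, 6), mk("d", 350, 40, 0.2, 3))
  tab <- ofat_effect(curves, "pressure")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$level, c(200, 275, 350))
  # generated with a positive pressure effect: final yields increase
  expect_true(all(diff(tab$final_yield) > 0))
  expect_warning(t2 <- ofat_effect(curves[4], "temperature"), "no group")
  expect_equal(nrow(t2), 0)
})

test_that("simulated bed-model curves are refit best by the bed model", {
  bed <- ref_bed(); chg <- ref_charge(0.84)
  p <- ref_pde_params()
  ctx <- list(bed = bed, charge = chg, flow_kg_h = 0.4, rho_co2 = 881.30,
              H = 0.005, n_cells = 30)
  crv <- simulate_extraction(bed, chg, p, 0.4, 881.30, study_times,
                             n_cells = 30)
  near <- matrix(c(0.05, 0.028, 100, 480), 1,
                 dimnames = list(NULL, c("kf_a", "ks_a", "tc1", "tc2")))
  f6 <- fit_model(crv, "VI", context = ctx, n_starts = 2, seed = 1,
                  starts = near)
  for (m in c("I", "III", "V")) {
    fm <- fit_model(crv, m, n_starts = 8, seed = 1)
    expect_lte(f6$gof$sse, fm$gof$sse)
  }
})
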