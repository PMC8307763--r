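# Piecewise analytical broken-and-intact-cells solutions.

test_that("the period boundary qc is the first positive crossing", {
  # frozen from a dense grid scan + bisection on 0.02 q = 0.1 (1 - e^{-0.5 q})
  qc <- solve_qc(ys = 0.02, xu = 0.1, C1 = 1, C2 = 0.5)
  expect_equal(qc, 4.463224, tolerance = 1e-6)
  expect_lt(abs(qc * 0.02 - 0.1 * (1 - exp(-0.5 * qc))), 1e-10)

  # q = 0 solves the equation when C1 = 1 but is excluded
  expect_gt(solve_qc(0.01, 0.1, 1, 0.5), 1)

  # homogeneity: scaling ys and xu together leaves qc unchanged
  expect_equal(solve_qc(0.04, 0.2, 1, 0.5), qc, tolerance = 1e-9)

  # solubility line above the depletion branch everywhere: no crossing
  expect_error(solve_qc(ys = 1, xu = 0.1, C1 = 1, C2 = 0.5),
               class = "sfe_no_crossing")
})

test_that("two-period yield is continuous, saturating and slope-ys early", {
  p <- analytic7_params(ys = 0.02, xu = 0.1, C1 = 1, C2 = 0.5)
  expect_equal(model7_yield(0, p), 0)
  eps <- 1e-10
  expect_equal(model7_yield(p$qc - eps, p), model7_yield(p$qc + eps, p),
               tolerance = 1e-8)
  expect_equal(model7_yield(1e6, p), p$xu, tolerance = 1e-9)
  # CER slope in q is exactly the solubility
  q <- seq(0, p$qc * 0.999, length.out = 50)
  expect_equal(model7_yield(q, p), q * 0.02)
})

test_that("initializers for grinding efficiency and internal coefficient", {
  expect_equal(grinding_efficiency(1, 0.5, 0), 0)
  expect_equal(grinding_efficiency(0, 0.5, 3), 1)
  expect_equal(grinding_efficiency(0.5, 0.1, 10), 1 - 0.5 * exp(-1))
  expect_warning(grinding_efficiency(2, 0.001, 1), "outside")

  expect_equal(ksas_estimate(1, 0.5, 0.006, 2, 0.0238), 0)
  expect_equal(ksas_estimate(0.8, 0.5, 0.006, 2, 0.0238),
               0.2 * 0.5 * 0.006 * 2 / 0.0238)
  expect_equal(ksas_estimate(0.8, 0.5, 0.012, 2, 0.0238),
               2 * ksas_estimate(0.8, 0.5, 0.006, 2, 0.0238))
  expect_error(ksas_estimate(0.8, 0.5, 0.006, 2, 0), class = "sfe_invalid_argument")
})

test_that("three-period boundaries follow their closed forms", {
  p <- list(ys = 0.02, xu = 5.25, r = 0.25, theta_e = 0.019,
            theta_i = 233.86, beta = 1.922, gamma = 0.437)
  b <- model8_boundaries(p)
  expect_equal(b[["qm"]], 0.25 * 5.25 * 0.019 / 0.02)
  expect_equal(b[["qm"]], 1.246875)
  expect_equal(b[["qn"]] - b[["qm"]],
               0.437 * 233.86 * log(1 - 0.25 + 0.25 * exp(1 / 1.922)))

  # no falling-rate period as beta -> infinity
  p$beta <- 1e9
  b2 <- model8_boundaries(p)
  expect_equal(b2[["qn"]], b2[["qm"]], tolerance = 1e-6)
})

test_that("recomputed FER/DC boundary matches the published column", {
  tab <- model8_param_table()
  qn2 <- tab$qm + tab$gamma * tab$tau_i *
    log(1 - tab$r + tab$r * exp(1 / tab$beta))
  ard <- abs(qn2 - tab$qn) / tab$qn
  expect_lt(mean(ard), 0.005)
  expect_lt(max(ard), 0.01)
})

test_that("three-period yield is continuous, monotone and bounded", {
  draws <- draw_params8(50, seed = 42)
  lo <- 1 - 1e-12; hi <- 1 + 1e-12
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
  for (p in draws) {
    q <- seq(0, 100, length.out = 2001)
    e <- model8_yield(q, p)
    expect_true(all(diff(e) >= -1e-10))
    expect_true(all(e <= p$xu * (1 + 1e-9)))
    expect_lt(rel(model8_yield(p$qm * lo, p), model8_yield(p$qm * hi, p)), 1e-8)
    expect_lt(rel(model8_yield(p$qn * lo, p), model8_yield(p$qn * hi, p)), 1e-8)
  }
})

test_that("three-period limits: damped solubility line and full depletion", {
  # theta_e -> 0: the CER bracket approaches 1, slope -> ys
  p <- analytic8_params(ys = 0.02, xu = 5, r = 0.3, theta_e = 1e-4,
                        theta_i = 300, beta = 1, gamma = 0.4)
  q <- seq(0, p$qm * 0.99, length.out = 20)
  expect_equal(model8_yield(q, p), q * 0.02, tolerance = 1e-9)

  # large r, large theta_i: pure damped solubility line up to qm
  p2 <- analytic8_params(ys = 0.02, xu = 5, r = 0.95, theta_e = 0.02,
                         theta_i = 1e5, beta = 1, gamma = 0.4)
  q2 <- seq(0, p2$qm, length.out = 20)
  expect_equal(model8_yield(q2, p2), q2 * 0.02 * (1 - exp(-1 / 0.02)),
               tolerance = 1e-9)

  # deep DC tail approaches xu from below
  p3 <- analytic8_params(ys = 0.05, xu = 4, r = 0.3, theta_e = 0.02,
                         theta_i = 100, beta = 1, gamma = 0.4)
  expect_equal(model8_yield(p3$qn + 50 * p3$gamma * p3$theta_i, p3), 4,
               tolerance = 1e-6)
})

test_that("time/consumption conversion and yield scaling", {
  expect_equal(q_from_time(60, 0.2 / 60, 0.019011), 0.2 / 0.019011,
               tolerance = 1e-12)
  expect_equal(e_to_yield_pct(0.1, 19.011, 130), 100 * 0.1 * 19.011 / 130)
  p <- analytic8_params(ys = 0.02, xu = 5, r = 0.3, theta_e = 0.02,
                        theta_i = 300, beta = 1, gamma = 0.4)
  js <- analytic_params_json(p)
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$tau_i, 300)
  expect_equal(rec$beta_m, 1)
  expect_equal(rec$qm, unname(p$qm))
})
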