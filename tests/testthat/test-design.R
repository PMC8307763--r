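# Experimental-design builder, density grid and synthetic curve generator.

test_that("Box-Behnken builder reproduces the published coded matrix", {
  bb <- box_behnken()
  expect_equal(nrow(bb), 15)
  coded <- bb[c("pressure_coded", "temperature_coded", "flow_coded")]
  expect_equal(sum(rowSums(abs(coded)) == 0), 3) # three center replicates

  des <- sfe_design_table()[1:15, c("P_coded", "T_coded", "F_coded")]
  key <- function(d) sort(do.call(paste, as.list(d)))
  expect_equal(key(coded), key(des))

  # balance: each factor sits at 0 in 4 edge rows and at +-1 in 4 rows each
  edge <- coded[rowSums(abs(coded)) > 0, ]
  for (j in 1:3) {
    expect_equal(unname(table(factor(edge[[j]], levels = -1:1))), c(4, 4, 4),
                 ignore_attr = TRUE)
  }

  expect_error(box_behnken(list(a = 1:3, b = 1:3)),
               class = "sfe_unsupported_design")
})

test_that("additional runs carry the published operating points", {
  extra <- additional_runs()
  expect_equal(nrow(extra), 6)
  expect_equal(extra$run, 16:21)
  r16 <- extra[extra$run == 16, ]
  r19 <- extra[extra$run == 19, ]
  expect_equal(unlist(r16[c("pressure", "temperature", "flow", "particle_um")]),
               unlist(r19[c("pressure", "temperature", "flow", "particle_um")]))
  expect_equal(unlist(extra[extra$run == 17, c("pressure", "temperature", "flow")]),
               c(pressure = 350, temperature = 40, flow = 0.4))
  expect_equal(extra$particle_label[extra$run %in% 20:21], c("<800", ">800"))
})

test_that("density interpolation is exact at knots, bilinear, monotone", {
  expect_equal(co2_density(350, 40), 934.90)
  expect_equal(co2_density(200, 70), 658.95)
  expect_equal(co2_density(275, 55), 830.45)
  expect_equal(co2_density(237.5, 40), (839.90 + 894.80) / 2)
  expect_equal(co2_density(237.5, 40), 867.35)

  P <- seq(200, 350, by = 15); T <- seq(40, 70, by = 3)
  for (tt in T) expect_true(all(diff(co2_density(P, tt)) > 0))
  for (pp in P) expect_true(all(diff(co2_density(pp, T)) < 0))

  expect_error(co2_density(150, 50), class = "sfe_extrapolation_refused")
  expect_error(co2_density(300, 80), class = "sfe_extrapolation_refused")

  # the design table densities all sit on the grid
  des <- sfe_design_table()
  expect_equal(co2_density(des$pressure, des$temperature), des$density)
})

test_that("synthetic curves are deterministic and unbiased around the truth", {
  truth <- ground_truth("I", seed = 3)
  row <- sfe_design_table()[6, , drop = FALSE]

  exact <- generate_curve(ground_truth("I", noise_sigma = 0, seed = 3), row)
  pars <- attr(exact, "true_params")
  mu <- eval_empirical(do.call(empirical_params, c(list(model = "I"), pars)),
                       exact$times)
  expect_equal(exact$yields, mu)

  expect_identical(generate_curve(truth, row)$yields,
                   generate_curve(truth, row)$yields)

  # CLT: mean of 200 noisy replicates within 3 SE of the noiseless curve
  reps <- vapply(1:200, function(i) {
    generate_curve(ground_truth("I", seed = 3000 + i), row)$yields
  }, numeric(8))
  se <- 0.05 / sqrt(200)
  expect_true(all(abs(rowMeans(reps) - mu) < 3 * se + 1e-12))
})

test_that("factor effects carry the study's signs into the generated data", {
  truth <- ground_truth("I", noise_sigma = 0, seed = 1)
  des <- sfe_design_table()
  y_at <- function(run) {
    crv <- generate_curve(truth, des[run, , drop = FALSE])
    crv$yields[length(crv$yields)]
  }
  # runs 8 -> 2 raise pressure at fixed (55 degC, 0.2 kg/h)
  expect_gt(y_at(2), y_at(8))
  # runs 17 -> 16 raise temperature at fixed (350 bar, 0.4 kg/h)
  expect_lt(y_at(16), y_at(17))
  # runs 4 -> 10 raise flow at fixed (275 bar, 70 degC)
  expect_gt(y_at(10), y_at(4))
  # coarser particles (run 21) extract less than finer (run 20)
  expect_lt(y_at(21), y_at(20))

  # asymptotic yields span roughly the fitted 3-6.4% range
  Yinf <- vapply(1:19, function(i) {
    attr(generate_curve(truth, des[i, , drop = FALSE]), "true_params")$Yinf
  }, numeric(1))
  expect_gt(min(Yinf), 2.9)
  expect_lt(max(Yinf), 6.5)

  # invalid factor combinations are named in the failure
  bad <- ground_truth("I", base = list(Yinf = 0.5, k = 0.008),
                      effects = list(Yinf = c(P = 1, T = 0, F = 0, S = 0)),
                      seed = 1)
  expect_error(generate_curve(bad, des[12, , drop = FALSE]),
               class = "sfe_generation_failure")
})

test_that("generator supports the two-phase bed model as ground truth", {
  truth <- ground_truth("VI", noise_sigma = 0, seed = 2,
                        pde = list(n_cells = 12))
  crv <- generate_curve(truth, sfe_design_table()[15, , drop = FALSE],
                        t_grid = c(30, 60, 120, 240))
  expect_true(all(diff(crv$yields) > 0))
  expect_gt(crv$yields[4], 0.5)
})
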