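# Experimental-design builder, CO2 density grid and synthetic kinetic
# curve generator. The generator stands in for unpublished raw extraction
# curves: it produces monotone saturating yield trajectories sampled on
# the study's schedule, with known ground-truth parameters and additive
# gravimetric noise, so every downstream stage (fitting, slope
# extraction, surrogate training) is testable end to end.

.default_levels <- list(pressure = c(200, 275, 350),
                        temperature = c(40, 55, 70),
                        flow = c(0.2, 0.3, 0.4))

#' Three-factor Box-Behnken design
#'
#' Builds the 12 edge-midpoint rows (all (+-1, +-1, 0) permutations over
#' factor pairs) plus `n_center` center replicates, mapping coded levels
#' to natural values through the level lists.
#'
#' @param levels Named list of exactly three factors, each with the three
#'   natural values for coded levels -1, 0, +1.
#' @param n_center Number of center-point replicates (default 3).
#' @return A data.frame with coded (`*_coded`) and natural columns, 12 +
#'   `n_center` rows.
#' @export
box_behnken <- function(levels = .default_levels, n_center = 3) {
  if (length(levels) != 3 || any(lengths(levels) != 3)) {
    stop(structure(class = c("sfe_unsupported_design", "error", "condition"),
                   list(message = "exactly 3 factors with 3 levels each required",
                        call = NULL)))
  }
  pairs <- utils::combn(3, 2)
  coded <- NULL
  for (p in seq_len(ncol(pairs))) {
    for (a in c(-1, 1)) for (b in c(-1, 1)) {
      row <- c(0, 0, 0)
      row[pairs[1, p]] <- a
      row[pairs[2, p]] <- b
      coded <- rbind(coded, row)
    }
  }
  coded <- rbind(coded, matrix(0, n_center, 3))
  nm <- names(levels)
  out <- data.frame(run = seq_len(nrow(coded)))
  for (j in 1:3) {
    out[[paste0(nm[j], "_coded")]] <- coded[, j]
    out[[nm[j]]] <- levels[[j]][coded[, j] + 2]
  }
  rownames(out) <- NULL
  out
}

#' Additional runs of the cherry-seed study
#'
#' The six extra operating points appended to the Box-Behnken block,
#' including the two particle-size variants of the
#' (350 bar, 70 degC, 0.4 kg/h) point.
#'
#' @return A data.frame of 6 rows (runs 16-21) from [sfe_design_table()].
#' @export
additional_runs <- function() {
  df <- sfe_design_table()
  df[df$block == "additional", , drop = FALSE]
}

# 3x3 density grid (kg/m^3) at the design pressures x temperatures.
.density_grid <- local({
  g <- matrix(c(839.90, 754.10, 658.95,
                894.80, 830.45, 762.35,
                934.90, 881.30, 826.30),
              nrow = 3, byrow = TRUE,
              dimnames = list(P = c(200, 275, 350), T = c(40, 55, 70)))
  g
})

#' CO2 density at an operating point
#'
#' Bilinear interpolation on the study's 3x3 density grid over
#' 200-350 bar and 40-70 degC (kg/m^3; exact at the nine knots). Queries
#' outside the grid are refused rather than extrapolated.
#'
#' @param pressure Pressure (bar), in [200, 350].
#' @param temperature Temperature (degC), in [40, 70].
#' @return Density in kg/m^3 (vectorized over the inputs).
#' @examples
#' co2_density(350, 40) # 934.90
#' @export
co2_density <- function(pressure, temperature) {
  n <- max(length(pressure), length(temperature))
  pressure <- rep_len(pressure, n); temperature <- rep_len(temperature, n)
  if (any(pressure < 200 | pressure > 350 | temperature < 40 | temperature > 70)) {
    stop(structure(class = c("sfe_extrapolation_refused", "error", "condition"),
                   list(message = "operating point outside the 200-350 bar x 40-70 degC grid",
                        call = NULL)))
  }
  Ps <- c(200, 275, 350); Ts <- c(40, 55, 70)
  vapply(seq_len(n), function(k) {
    i <- findInterval(pressure[k], Ps, rightmost.closed = TRUE)
    j <- findInterval(temperature[k], Ts, rightmost.closed = TRUE)
    wp <- (pressure[k] - Ps[i]) / (Ps[i + 1] - Ps[i])
    wt <- (temperature[k] - Ts[j]) / (Ts[j + 1] - Ts[j])
    (1 - wp) * (1 - wt) * .density_grid[i, j] +
      wp * (1 - wt) * .density_grid[i + 1, j] +
      (1 - wp) * wt * .density_grid[i, j + 1] +
      wp * wt * .density_grid[i + 1, j + 1]
  }, numeric(1))
}

#' Ground truth for synthetic kinetic curves
#'
#' Defines the generating model and how the operating factors shift its
#' parameters (linearly in coded units), plus the measurement-noise level
#' and the base seed. The defaults encode the study's observed effect
#' directions - pressure and flow raise both the asymptotic yield and the
#' rate, temperature and coarser particles lower them - with magnitudes
#' chosen so the asymptotic yield spans roughly 3-6.4% of charge over the
#' factor space, matching the fitted range of the single-exponential
#' model, and gravimetric noise of 0.05% yield.
#'
#' @param model Generating model: `"I"` (default, single exponential) or
#'   `"VI"` (two-phase bed model).
#' @param base Named list of base parameter values at the center point.
#' @param effects Named list: per parameter, a named vector of per-coded-
#'   unit shifts for `P`, `T`, `F`, `S` (particle size).
#' @param noise_sigma Gaussian noise standard deviation (% yield).
#' @param seed Base seed; each run's curve derives its stream from it.
#' @param pde Extra constants for `model = "VI"`: a list with `bed`,
#'   `cu`, `H`, `F`, `switch_scale`, `n_cells`.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(model = c("I", "VI"), base = NULL, effects = NULL,
                         noise_sigma = 0.05, seed = 1, pde = NULL) {
  model <- match.arg(model)
  if (model == "I") {
    base <- base %||% list(Yinf = 4.7, k = 0.008)
    effects <- effects %||% list(
      Yinf = c(P = 0.9, T = -0.35, F = 0.4, S = -0.5),
      k = c(P = 0.003, T = -0.001, F = 0.0015, S = -0.001))
  } else {
    base <- base %||% list(kf_a = 0.035, ks_a = 0.02, tc1 = 150, tc2 = 350)
    effects <- effects %||% list(
      kf_a = c(P = 0.01, T = -0.004, F = 0.006, S = -0.004),
      tc1 = c(P = 20, T = -10, F = 10, S = 0))
    pde <- pde %||% list()
    pde$bed <- pde$bed %||% cherry_bed()
    pde$cu <- pde$cu %||% 0.8
    pde$H <- pde$H %||% 0.005
    pde$F <- pde$F %||% 1
    pde$switch_scale <- pde$switch_scale %||% 20
    pde$n_cells <- pde$n_cells %||% 30
  }
  if (noise_sigma < 0) stop_invalid("noise_sigma must be >= 0")
  structure(list(model = model, base = base, effects = effects,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 pde = pde),
            class = "ground_truth")
}

# Coded levels of a design row, including particle size as
# (particle_um - 741)/160 so the coarse (>800 um) fraction sits near +1.
.coded_levels <- function(design_row) {
  pc <- design_row$P_coded %||% ((design_row$pressure - 275) / 75)
  tc <- design_row$T_coded %||% ((design_row$temperature - 55) / 15)
  fc <- design_row$F_coded %||% ((design_row$flow - 0.3) / 0.1)
  sc <- ((design_row$particle_um %||% 741) - 741) / 160
  c(P = as.numeric(pc), T = as.numeric(tc), F = as.numeric(fc),
    S = as.numeric(sc))
}

#' True (noise-free) parameters for one design row
#'
#' Applies the ground truth's linear factor-effect map to the base
#' parameters at the row's coded levels.
#'
#' @param truth A [ground_truth()].
#' @param design_row One row of [sfe_design_table()] or [box_behnken()].
#' @return Named list of generating parameters.
#' @export
true_params <- function(truth, design_row) {
  stopifnot(inherits(truth, "ground_truth"))
  lev <- .coded_levels(design_row)
  pars <- truth$base
  for (nm in names(truth$effects)) {
    eff <- truth$effects[[nm]]
    pars[[nm]] <- pars[[nm]] + sum(eff * lev[names(eff)])
  }
  pars
}

#' Generate one synthetic kinetic curve
#'
#' Evaluates the generating model with the row's factor-shifted
#' parameters on the sampling schedule and adds i.i.d. Gaussian noise
#' (sd `noise_sigma`), truncated at zero so yields stay non-negative.
#' Each run draws from a deterministic stream derived from the base seed
#' and the run id, so the same truth reproduces the same curves.
#'
#' @param truth A [ground_truth()].
#' @param design_row One design row (needs `run`, coded or natural factor
#'   columns and `particle_um`).
#' @param t_grid Sampling times (min); default is the study schedule
#'   15-240 min.
#' @return A [kinetic_curve()] with the true parameters attached as
#'   attribute `"true_params"`.
#' @export
generate_curve <- function(truth, design_row,
                           t_grid = c(15, 30, 45, 60, 90, 120, 180, 240)) {
  stopifnot(inherits(truth, "ground_truth"))
  pars <- true_params(truth, design_row)
  bad <- names(pars)[vapply(pars, function(v) !is.finite(v) || v <= 0, logical(1))]
  if (length(bad)) {
    stop(structure(class = c("sfe_generation_failure", "error", "condition"),
                   list(message = sprintf(
                     "factor combination (%s bar, %s degC, %s kg/h, %s um) gives non-positive %s",
                     design_row$pressure, design_row$temperature,
                     design_row$flow, design_row$particle_um %||% 741,
                     paste(bad, collapse = ", ")), call = NULL)))
  }
  run <- design_row$run %||% 0
  if (truth$model == "I") {
    mu <- eval_empirical(do.call(empirical_params, c(list(model = "I"), pars)),
                         t_grid)
  } else {
    bed <- truth$pde$bed
    chg <- charge_composition(bed$dried_mass, truth$pde$cu)
    p <- pde_params(kf_a = pars$kf_a, ks_a = pars$ks_a %||% truth$base$ks_a,
                    F = truth$pde$F, tc1 = pars$tc1, tc2 = pars$tc2 %||% truth$base$tc2,
                    H = truth$pde$H, switch_scale = truth$pde$switch_scale)
    rho <- co2_density(design_row$pressure, design_row$temperature)
    sol <- pde_solution(bed, chg, p, design_row$flow, rho, t_grid,
                        n_cells = truth$pde$n_cells, rtol = 1e-8)
    mu <- sol$yield_pct
  }
  curve_seed <- as.integer((abs(truth$seed) %% 2e6) * 1000 + as.integer(run) %% 1000)
  y <- with_seed(curve_seed, {
    pmax(0, mu + stats::rnorm(length(mu), sd = truth$noise_sigma))
  })
  # keep the sample inside the curve invariant: decreases are floored at
  # 2% of the running maximum (rare; expected ~1e-4 of pairs at the
  # default noise level, so the noise stays effectively unbiased)
  for (i in seq_along(y)[-1]) {
    y[i] <- max(y[i], y[i - 1] - 0.02 * max(y[seq_len(i - 1)]))
  }
  crv <- kinetic_curve(run_id = paste0("run", run), times = t_grid, yields = y,
                       pressure = design_row$pressure %||% NA_real_,
                       temperature = design_row$temperature %||% NA_real_,
                       flow = design_row$flow %||% NA_real_,
                       particle_size = design_row$particle_um %||% 741)
  attr(crv, "true_params") <- pars
  crv
}

#' Generate a full synthetic dataset
#'
#' @param truth A [ground_truth()].
#' @param design Data.frame of design rows; defaults to kinetic runs 1-19
#'   of [sfe_design_table()].
#' @param t_grid Sampling times (min).
#' @return Named list of [kinetic_curve()] objects, one per design row.
#' @export
generate_dataset <- function(truth, design = NULL,
                             t_grid = c(15, 30, 45, 60, 90, 120, 180, 240)) {
  design <- design %||% utils::head(sfe_design_table(), 19)
  out <- lapply(seq_len(nrow(design)), function(i) {
    generate_curve(truth, design[i, , drop = FALSE], t_grid)
  })
  names(out) <- vapply(out, `[[`, character(1), "run_id")
  out
}
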