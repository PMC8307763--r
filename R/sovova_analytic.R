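# Piecewise analytical solutions of the broken-and-intact-cells model in
# the solvent-consumption coordinate q (kg CO2 passed per kg insoluble
# solid). Yields e are expressed per kg insoluble solid; e -> xu at full
# depletion.
#
# The two-period solution ("Model VII") is a solubility line followed by
# an exponential depletion tail; the switch point qc makes the two
# branches meet. The three-period solution ("Model VIII") has a
# constant-rate (CER) line damped by the external resistance theta_e, a
# falling-rate (FER) branch, and a logarithmic diffusion-controlled tail
# whose integration constant is fixed by continuity at the FER/DC
# boundary qn. When the coefficient beta equals ys*gamma*theta_i/xu (the
# consistency the fitted parameter sets obey), that tail coincides with
# the closed-form solution of the underlying model.

#' Solve the period boundary of the two-period solution
#'
#' Finds the smallest strictly positive root `qc` of
#' `q * ys = xu * (1 - C1 * exp(-C2 * q))`, the solvent consumption at
#' which the solubility line meets the depletion branch.
#'
#' @param ys Oil solubility in the solvent (kg oil / kg CO2).
#' @param xu Oil load of the untreated solid (kg/kg).
#' @param C1,C2 Adjustable coefficients of the depletion branch (> 0).
#' @return The boundary `qc` (kg CO2 / kg insoluble solid), with root
#'   residual below 1e-10.
#' @export
solve_qc <- function(ys, xu, C1, C2) {
  check_positive(ys, "ys"); check_positive(xu, "xu")
  check_positive(C1, "C1"); check_positive(C2, "C2")
  f <- function(q) q * ys - xu * (1 - C1 * exp(-C2 * q))
  # beyond q_max the line is above the bounded branch for good
  q_max <- xu * (1 + C1) / ys + 10 / C2
  q_lo <- 1e-9 * q_max
  grid <- seq(q_lo, q_max, length.out = 4096)
  fg <- f(grid)
  idx <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (!length(idx)) {
    stop(structure(class = c("sfe_no_crossing", "error", "condition"),
                   list(message = "branches do not cross at any q > 0",
                        call = NULL)))
  }
  i <- idx[1]
  root <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  if (abs(f(root)) > 1e-10 * max(1, xu)) {
    stop(structure(class = c("sfe_no_crossing", "error", "condition"),
                   list(message = "root residual above tolerance", call = NULL)))
  }
  root
}

#' Two-period analytical model parameters
#'
#' Solves the boundary `qc` and derives the grinding efficiency `r` and,
#' when flow and solid mass are supplied, the internal coefficient
#' `ks_as`.
#'
#' @inheritParams solve_qc
#' @param Qdot Solvent mass flow (kg/min), optional.
#' @param Nm Insoluble solid mass (kg), optional.
#' @param eps Bed porosity, used for `ks_as`.
#' @return Object of class `analytic7_params` with fields `ys`, `xu`,
#'   `C1`, `C2`, `qc`, `r` and (when derivable) `ks_as`, `Qdot`, `Nm`.
#' @export
analytic7_params <- function(ys, xu, C1, C2, Qdot = NULL, Nm = NULL, eps = 0.5) {
  qc <- solve_qc(ys, xu, C1, C2)
  r <- grinding_efficiency(C1, C2, qc)
  ks_as <- if (!is.null(Qdot) && !is.null(Nm)) {
    ksas_estimate(r, eps, Qdot, C2, Nm)
  }
  structure(list(ys = ys, xu = xu, C1 = C1, C2 = C2, qc = qc, r = r,
                 ks_as = ks_as, Qdot = Qdot, Nm = Nm, eps = eps),
            class = "analytic7_params")
}

#' Two-period analytical yield
#'
#' `e = q * ys` on the solubility-controlled branch (`q <= qc`), then
#' `e = xu * (1 - C1 * exp(-C2 * q))`; continuous at `qc` by
#' construction of the boundary.
#'
#' @param q Solvent consumption (kg CO2 / kg insoluble solid), vectorized.
#' @param p An [analytic7_params()] record.
#' @return Yield e in kg extract / kg insoluble solid.
#' @export
model7_yield <- function(q, p) {
  if (!inherits(p, "analytic7_params")) stop_invalid("p must be analytic7_params")
  if (is.null(p$qc)) {
    stop(structure(class = c("sfe_state_error", "error", "condition"),
                   list(message = "qc has not been solved", call = NULL)))
  }
  if (any(q < 0)) stop_invalid("q must be non-negative")
  ifelse(q <= p$qc, q * p$ys, p$xu * (1 - p$C1 * exp(-p$C2 * q)))
}

#' Grinding efficiency from the depletion-branch coefficients
#'
#' `r = 1 - C1 * exp(-C2 * qc)`: the fraction of oil in cells broken by
#' milling, i.e. the depletion branch evaluated at the period boundary
#' expressed as a recovered fraction.
#'
#' @param C1,C2 Depletion-branch coefficients.
#' @param qc Period boundary (>= 0).
#' @return Fraction in `[0, 1]`; values outside are returned with a
#'   warning.
#' @export
grinding_efficiency <- function(C1, C2, qc) {
  if (qc < 0) stop_invalid("qc must be >= 0")
  r <- 1 - C1 * exp(-C2 * qc)
  if (r < 0 || r > 1) {
    warning(sprintf("grinding efficiency %.4f outside [0, 1]", r), call. = FALSE)
  }
  r
}

#' Internal mass-transfer coefficient estimate
#'
#' `ks_as = (1 - r) * (1 - eps) * Qdot * C2 / Nm`, the starting value of
#' the solid-phase volumetric coefficient implied by the two-period fit.
#'
#' @param r Grinding efficiency, in `[0, 1]`.
#' @param eps Bed porosity.
#' @param Qdot Solvent mass flow (kg/min).
#' @param C2 Depletion-branch coefficient.
#' @param Nm Insoluble solid mass (kg).
#' @return Coefficient in 1/min.
#' @export
ksas_estimate <- function(r, eps, Qdot, C2, Nm) {
  if (r < 0 || r > 1) stop_invalid("r must lie in [0, 1]")
  check_fraction(eps, "eps")
  check_positive(Qdot, "Qdot")
  check_positive(C2, "C2")
  check_positive(Nm, "Nm")
  (1 - r) * (1 - eps) * Qdot * C2 / Nm
}

#' Three-period analytical model parameters
#'
#' @param ys Oil solubility (kg/kg).
#' @param xu Oil load of the untreated solid (kg/kg).
#' @param r Grinding efficiency, in (0, 1).
#' @param theta_e External transport resistance (dimensionless group).
#' @param theta_i Internal transport resistance (dimensionless group).
#' @param beta Depletion coefficient of the diffusion tail.
#' @param gamma Solvent-to-solid mass ratio held in the bed.
#' @return Object of class `analytic8_params` with the inputs plus the
#'   period boundaries `qm` (CER/FER) and `qn` (FER/DC).
#' @export
analytic8_params <- function(ys, xu, r, theta_e, theta_i, beta, gamma) {
  check_positive(ys, "ys"); check_positive(xu, "xu")
  check_fraction(r, "r")
  check_positive(theta_e, "theta_e"); check_positive(theta_i, "theta_i")
  check_positive(beta, "beta"); check_positive(gamma, "gamma")
  p <- list(ys = ys, xu = xu, r = r, theta_e = theta_e, theta_i = theta_i,
            beta = beta, gamma = gamma)
  b <- model8_boundaries(p)
  p$qm <- b[["qm"]]; p$qn <- b[["qn"]]
  structure(p, class = "analytic8_params")
}

#' Period boundaries of the three-period solution
#'
#' `qm = r * xu * theta_e / ys` ends the constant-rate period;
#' `qn = qm + gamma * theta_i * log(1 - r + r * exp(1/beta))` ends the
#' falling-rate period.
#'
#' @param p A list or [analytic8_params()] with fields `ys`, `xu`, `r`,
#'   `theta_e`, `theta_i`, `beta`, `gamma`.
#' @return Named numeric vector `c(qm, qn)`.
#' @export
model8_boundaries <- function(p) {
  arg <- 1 - p$r + p$r * exp(1 / p$beta)
  if (!is.finite(arg) || arg <= 0) stop_invalid("log argument must be positive")
  qm <- p$r * p$xu * p$theta_e / p$ys
  c(qm = qm, qn = qm + p$gamma * p$theta_i * log(arg))
}

# FER branch value; also used to anchor the DC tail.
.model8_fer <- function(q, p) {
  u <- log1p((1 / p$r) * expm1((q - p$qm) / (p$gamma * p$theta_i)))
  q * p$ys - p$r * p$xu * p$theta_e *
    exp((p$beta / p$theta_e) * u - 1 / p$theta_e)
}

#' Three-period analytical yield
#'
#' Piecewise curve in the solvent-consumption coordinate:
#' * CER, `q <= qm`: `e = q * ys * (1 - exp(-1/theta_e))` (solubility
#'   line damped by the external resistance);
#' * FER, `qm < q <= qn`:
#'   `e = q*ys - r*xu*theta_e * exp( (beta/theta_e) *
#'    log(1 + (1/r)*(exp((q-qm)/(gamma*theta_i)) - 1)) - 1/theta_e )`;
#' * DC, `q > qn`:
#'   `e = xu * (1 - beta * log(1 + A * exp(-(q-qn)/(gamma*theta_i))))`
#'   with `A = exp((xu - e(qn))/(xu*beta)) - 1` fixed by continuity, so
#'   the tail rises monotonically to `xu`.
#'
#' The three branches are continuous at `qm` and `qn` by construction;
#' an internal audit signals if the evaluated mismatch ever exceeds
#' `1e-6 * xu`.
#'
#' @param q Solvent consumption, vectorized, `q >= 0`.
#' @param p An [analytic8_params()] record.
#' @return Yield e in kg extract / kg insoluble solid.
#' @export
model8_yield <- function(q, p) {
  if (!inherits(p, "analytic8_params")) stop_invalid("p must be analytic8_params")
  if (any(q < 0)) stop_invalid("q must be non-negative")
  cer <- function(q) q * p$ys * (1 - exp(-1 / p$theta_e))
  fail <- function(mism) {
    stop(structure(class = c("sfe_internal_consistency", "error", "condition"),
                   list(message = sprintf(
                     "piecewise branches disagree at a boundary (%.3g)", mism),
                     call = NULL)))
  }
  out <- numeric(length(q))
  i1 <- q <= p$qm
  i2 <- q > p$qm & q <= p$qn
  i3 <- q > p$qn
  out[i1] <- cer(q[i1])
  if (any(i2) || any(i3)) {
    mism <- abs(cer(p$qm) - .model8_fer(p$qm, p))
    if (!is.finite(mism) || mism > 1e-6 * p$xu) fail(mism)
    out[i2] <- .model8_fer(q[i2], p)
  }
  if (any(i3)) {
    # diffusion tail anchored by continuity at qn
    e_n <- .model8_fer(p$qn, p)
    A <- expm1((p$xu - e_n) / (p$xu * p$beta))
    dc <- function(q) {
      p$xu * (1 - p$beta * log1p(A * exp(-(q - p$qn) / (p$gamma * p$theta_i))))
    }
    mism <- abs(e_n - dc(p$qn))
    if (!is.finite(mism) || mism > 1e-6 * p$xu) fail(mism)
    out[i3] <- dc(q[i3])
  }
  out
}

#' Solvent-consumption coordinate from time
#'
#' At constant solvent flow, `q(t) = Qdot * t / Nm`.
#'
#' @param t Time (min).
#' @param Qdot Solvent mass flow (kg/min).
#' @param Nm Insoluble solid mass (kg).
#' @return q in kg CO2 / kg insoluble solid.
#' @export
q_from_time <- function(t, Qdot, Nm) {
  check_positive(Qdot, "Qdot"); check_positive(Nm, "Nm")
  if (any(t < 0)) stop_invalid("t must be non-negative")
  Qdot * t / Nm
}

#' Convert per-solid yield to percent of charge
#'
#' `Y = 100 * e * Nmg / m_in`: extract mass per insoluble solid, scaled
#' by the solid mass and expressed as percent of the loaded charge.
#'
#' @param e Yield per kg insoluble solid.
#' @param Nmg Insoluble solid mass (g).
#' @param m_in Charge mass (g).
#' @return Yield in % of charge.
#' @export
e_to_yield_pct <- function(e, Nmg, m_in) {
  check_positive(Nmg, "Nmg"); check_positive(m_in, "m_in")
  100 * e * Nmg / m_in
}

#' Serialize analytical parameter records to JSON
#'
#' Round-trips [analytic7_params()] / [analytic8_params()] records using
#' the published column names (`cu`, `Nmg`, `xu`, `gamma`, `tau_e`, `r`,
#' `ks_as`, `qm`, `tau_i`, `beta_m`, `qn`, ...).
#'
#' @param p An analytic parameter record.
#' @param path Optional file path.
#' @return JSON string, or `path` invisibly.
#' @export
analytic_params_json <- function(p, path = NULL) {
  if (inherits(p, "analytic8_params")) {
    rec <- list(model = "VIII", ys = p$ys, xu = p$xu, r = p$r,
                tau_e = p$theta_e, tau_i = p$theta_i, beta_m = p$beta,
                gamma = p$gamma, qm = p$qm, qn = p$qn)
  } else if (inherits(p, "analytic7_params")) {
    rec <- list(model = "VII", ys = p$ys, xu = p$xu, C1 = p$C1, C2 = p$C2,
                qc = p$qc, r = p$r, ks_as = p$ks_as)
  } else {
    stop_invalid("p must be an analytic parameter record")
  }
  if (is.null(path)) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
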