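# Kinetic curves, goodness-of-fit statistics and multi-start nonlinear
# least-squares estimation of all model families.

#' Kinetic extraction curve
#'
#' One run's sampled cumulative-yield trajectory plus its operating
#' conditions. Times must be strictly increasing and non-negative,
#' yields non-negative and of equal length; yields must be non-decreasing
#' within a measurement-noise allowance of 2% of the running maximum
#' yield (a point-relative allowance would spuriously reject ordinary
#' gravimetric noise on the near-zero early samples).
#'
#' @param run_id Run label.
#' @param times Sampling times (min).
#' @param yields Cumulative yields (% of charge).
#' @param pressure,temperature,flow,particle_size Operating metadata
#'   (bar, degC, kg CO2/h, um).
#' @return An object of class `kinetic_curve` (a list).
#' @export
kinetic_curve <- function(run_id, times, yields, pressure = NA_real_,
                          temperature = NA_real_, flow = NA_real_,
                          particle_size = NA_real_) {
  if (length(times) != length(yields)) {
    stop_invalid("times and yields must have equal length")
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop_invalid("times must be strictly increasing and non-negative")
  }
  if (any(!is.finite(yields)) || any(yields < 0)) {
    stop_invalid("yields must be finite and non-negative")
  }
  if (length(yields) > 1) {
    allow <- 0.02 * cummax(yields)[-length(yields)]
    if (any(diff(yields) < -allow - 1e-12)) {
      stop_invalid("yields decrease by more than the 2% noise allowance")
    }
  }
  structure(list(run_id = as.character(run_id), times = as.numeric(times),
                 yields = as.numeric(yields), pressure = pressure,
                 temperature = temperature, flow = flow,
                 particle_size = particle_size),
            class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("Kinetic curve '%s': %d points, %g-%g min, final yield %.3f%%\n",
              x$run_id, length(x$times), min(x$times), max(x$times),
              x$yields[length(x$yields)]))
  if (is.finite(x$pressure)) {
    cat(sprintf("  conditions: %g bar, %g degC, %g kg/h, %g um\n",
                x$pressure, x$temperature, x$flow, x$particle_size))
  }
  invisible(x)
}

#' @export
as.data.frame.kinetic_curve <- function(x, ...) {
  data.frame(run_id = x$run_id, time_min = x$times, yield_pct = x$yields,
             stringsAsFactors = FALSE)
}

#' Goodness-of-fit statistics
#'
#' Sum of squared errors, coefficient of determination (about the mean of
#' the observations) and average absolute relative deviation. AARD
#' averages `|y - yhat| / y` over the observations with `y > 0` only
#' (a zero observation, e.g. at t = 0, contributes no term).
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 points).
#' @return Object of class `gof_stats`: list with `sse`, `r2`, `aard`
#'   and `n` (points), `n_aard` (points entering AARD).
#' @examples
#' gof_stats(c(1, 2, 3), c(1, 2, 4)) # SSE 1, R2 0.5, AARD 1/9
#' @export
gof_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop_invalid("observed and predicted must have equal length >= 2")
  }
  res <- observed - predicted
  sse <- sum(res^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop(structure(class = c("sfe_undefined_statistic", "error", "condition"),
                   list(message = "R2 undefined: observations have zero variance",
                        call = NULL)))
  }
  pos <- observed > 0
  if (!any(pos)) {
    stop(structure(class = c("sfe_undefined_statistic", "error", "condition"),
                   list(message = "AARD undefined: no positive observations",
                        call = NULL)))
  }
  aard <- mean(abs(res[pos]) / observed[pos])
  structure(list(sse = sse, r2 = 1 - sse / sst, aard = aard,
                 n = length(observed), n_aard = sum(pos)),
            class = "gof_stats")
}

#' @export
print.gof_stats <- function(x, ...) {
  cat(sprintf("SSE = %.4g, R2 = %.4f, AARD = %.4f (n = %d)\n",
              x$sse, x$r2, x$aard, x$n))
  invisible(x)
}

# ---- model registry for fitting ------------------------------------------
# Each entry: free parameter names, default box bounds, and a predictor
# pred(par, t, context) returning yield in % of charge.

.fit_registry <- function(model, context) {
  emp <- function(id) {
    list(
      par = .empirical_fields[[id]],
      pred = function(par, t, ctx) {
        eval_empirical(do.call(empirical_params, c(list(model = id), as.list(par))), t)
      }
    )
  }
  def <- switch(model,
    I = c(emp("I"), list(lower = c(Yinf = 1e-6, k = 1e-6),
                         upper = c(Yinf = 20, k = 10))),
    II = c(emp("II"), list(lower = c(Yinf = 1e-6, a = -0.1, b = -0.5),
                           upper = c(Yinf = 20, a = -1e-6, b = 0.5))),
    III = c(emp("III"), list(lower = c(Yinf = 1e-6, k = 1e-3),
                             upper = c(Yinf = 20, k = 1000))),
    IV = c(emp("IV"), list(lower = c(Yinf = 1e-6, f1 = 0, k1 = 1e-6, f2 = 0, k2 = 1e-6),
                           upper = c(Yinf = 20, f1 = 1, k1 = 10, f2 = 1, k2 = 10))),
    V = c(emp("V"), list(lower = c(Yinf = 1e-6, G = 1e-3, t1 = 1, ti = 0.1),
                         upper = c(Yinf = 20, G = 1, t1 = 2000, ti = 1000))),
    VI = list(
      par = c("kf_a", "ks_a", "tc1", "tc2"),
      lower = c(kf_a = 1e-5, ks_a = 1e-5, tc1 = 1, tc2 = 1),
      upper = c(kf_a = 1, ks_a = 1, tc1 = 400, tc2 = 600),
      pred = function(par, t, ctx) {
        p <- pde_params(kf_a = par[["kf_a"]], ks_a = par[["ks_a"]],
                        F = ctx$F %||% 1, tc1 = par[["tc1"]], tc2 = par[["tc2"]],
                        H = ctx$H, switch_scale = ctx$switch_scale %||% 20)
        sol <- pde_solution(ctx$bed, ctx$charge, p, ctx$flow_kg_h, ctx$rho_co2,
                            t, n_cells = ctx$n_cells %||% 30,
                            rtol = ctx$rtol %||% 1e-6, atol = 1e-10)
        sol$yield_pct
      }
    ),
    VII = list(
      par = c("C1", "C2"),
      lower = c(C1 = 1e-4, C2 = 1e-4),
      upper = c(C1 = 5, C2 = 10),
      pred = function(par, t, ctx) {
        p <- analytic7_params(ys = ctx$ys, xu = ctx$charge$xu,
                              C1 = par[["C1"]], C2 = par[["C2"]])
        q <- q_from_time(t, ctx$Qdot, ctx$charge$Nmg / 1000)
        e_to_yield_pct(model7_yield(q, p), ctx$charge$Nmg, ctx$m_in)
      }
    ),
    VIII = list(
      par = c("r", "theta_e", "theta_i", "beta"),
      lower = c(r = 1e-3, theta_e = 1e-3, theta_i = 1, beta = 0.05),
      upper = c(r = 0.999, theta_e = 2, theta_i = 5000, beta = 5),
      pred = function(par, t, ctx) {
        p <- analytic8_params(ys = ctx$ys, xu = ctx$charge$xu, r = par[["r"]],
                              theta_e = par[["theta_e"]],
                              theta_i = par[["theta_i"]], beta = par[["beta"]],
                              gamma = ctx$gamma)
        q <- q_from_time(t, ctx$Qdot, ctx$charge$Nmg / 1000)
        e_to_yield_pct(model8_yield(q, p), ctx$charge$Nmg, ctx$m_in)
      }
    ),
    stop(structure(class = c("sfe_unsupported_model", "error", "condition"),
                   list(message = paste("unknown model", model), call = NULL)))
  )
  def
}

#' Fit a kinetic model to a curve
#'
#' Minimizes the sum of squared yield errors over the model's free
#' parameters by bounded Levenberg-Marquardt, started from a seeded
#' Latin-hypercube sample of the parameter box (plus any user-supplied
#' starts). The best start by final SSE wins; exact ties go to the start
#' with the smallest parameter norm.
#'
#' @param curve A [kinetic_curve()].
#' @param model Model id: `"I"`..`"V"` (empirical), `"VI"` (two-phase
#'   bed model), `"VII"`/`"VIII"` (analytical broken-and-intact-cells).
#' @param context Named list of fixed constants the model needs: the bed
#'   models use `bed`, `charge`, `flow_kg_h`, `rho_co2`, `H` (and
#'   optionally `F`, `switch_scale`, `n_cells`, `rtol`); the analytical
#'   models use `ys`, `charge`, `Qdot` (kg/min), `m_in` (g) and, for
#'   `"VIII"`, `gamma`.
#' @param n_starts Number of Latin-hypercube starts (default 16).
#' @param seed RNG seed for the start sample (default 2021).
#' @param starts Optional matrix/list of explicit starting vectors, used
#'   in addition to the Latin-hypercube sample.
#' @param lower,upper Optional named overrides of the default bounds.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return Object of class `fit_result`: `model`, `par` (named vector),
#'   `gof` ([gof_stats()]), `fitted`, `n_starts_used`, `converged`, and
#'   `starts` (per-start diagnostic table).
#' @examples
#' crv <- kinetic_curve("r1", c(15, 30, 45, 60, 90, 120, 180, 240),
#'                      eval_empirical(empirical_params("I", Yinf = 5, k = 0.01),
#'                                     c(15, 30, 45, 60, 90, 120, 180, 240)))
#' fit <- fit_model(crv, "I", n_starts = 8)
#' @export
fit_model <- function(curve, model, context = list(), n_starts = 16,
                      seed = 2021, starts = NULL, lower = NULL, upper = NULL,
                      maxiter = 200) {
  stopifnot(inherits(curve, "kinetic_curve"))
  spec <- .fit_registry(model, context)
  need <- switch(model, VI = c("bed", "charge", "flow_kg_h", "rho_co2", "H"),
                 VII = c("ys", "charge", "Qdot", "m_in"),
                 VIII = c("ys", "charge", "Qdot", "m_in", "gamma"),
                 character(0))
  missing_ctx <- setdiff(need, names(context))
  if (length(missing_ctx)) {
    stop_invalid("model ", model, " needs context entries: ",
                 paste(missing_ctx, collapse = ", "))
  }
  npar <- length(spec$par)
  if (length(curve$times) <= npar) {
    stop(structure(class = c("sfe_underdetermined", "error", "condition"),
                   list(message = sprintf(
                     "%d points cannot determine %d free parameters",
                     length(curve$times), npar), call = NULL)))
  }
  lo <- spec$lower; hi <- spec$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  start_mat <- with_seed(seed, lhs::randomLHS(n_starts, npar))
  # rate-like parameters (positive boxes spanning >= 2 decades) are
  # sampled log-uniformly: uniform draws would leave the small-rate
  # basin of exponential models unexplored
  log_scale <- lo > 0 & hi / lo >= 100
  for (j in seq_len(npar)) {
    start_mat[, j] <- if (log_scale[j]) {
      10^(log10(lo[j]) + start_mat[, j] * (log10(hi[j]) - log10(lo[j])))
    } else {
      lo[j] + start_mat[, j] * (hi[j] - lo[j])
    }
  }
  colnames(start_mat) <- spec$par
  if (!is.null(starts)) {
    extra <- if (is.list(starts)) do.call(rbind, lapply(starts, function(s) s[spec$par]))
             else starts[, spec$par, drop = FALSE]
    start_mat <- rbind(extra, start_mat)
  }

  resid_fn <- function(par) {
    par <- stats::setNames(as.numeric(par), spec$par)
    pred <- tryCatch(suppressWarnings(spec$pred(par, curve$times, context)),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      return(rep(1e4, length(curve$times)))
    }
    curve$yields - pred
  }

  runs <- vector("list", nrow(start_mat))
  for (i in seq_len(nrow(start_mat))) {
    st <- pmin(pmax(start_mat[i, ], lo), hi)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-15, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(ans)) {
      runs[[i]] <- list(par = stats::setNames(as.numeric(ans$par), spec$par),
                        sse = sum(resid_fn(ans$par)^2),
                        sse0 = sum(resid_fn(st)^2),
                        info = ans$info)
    }
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    stop(structure(class = c("sfe_fit_failure", "error", "condition"),
                   list(message = "no start converged", call = NULL)))
  }
  runs <- runs[ok]
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  norms <- vapply(runs, function(r) sqrt(sum(r$par^2)), numeric(1))
  best <- order(sses, norms)[1]
  par <- runs[[best]]$par
  fitted <- spec$pred(par, curve$times, context)
  gof <- gof_stats(curve$yields, fitted)
  diag_tab <- data.frame(
    start = seq_along(runs),
    sse_initial = vapply(runs, `[[`, numeric(1), "sse0"),
    sse_final = sses,
    info = vapply(runs, `[[`, numeric(1), "info"))
  structure(list(model = model, par = par, gof = gof, fitted = fitted,
                 n_starts_used = nrow(start_mat),
                 converged = all(is.finite(par)) && is.finite(gof$sse),
                 starts = diag_tab, run_id = curve$run_id),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model %s fit to '%s' (%d starts)\n", x$model, x$run_id,
              x$n_starts_used))
  cat("  ", paste(names(x$par), signif(x$par, 5), sep = " = ", collapse = ", "),
      "\n", sep = "")
  print(x$gof)
  invisible(x)
}

#' Initial slope of a kinetic curve
#'
#' Least-squares slope of yield versus time constrained through the
#' origin, over the sample points with `0 < t <= window`:
#' `b = sum(t * Y) / sum(t^2)` (% of charge per min). This is the
#' constant-rate-period extraction rate used as the response of the
#' network surrogate.
#'
#' @param curve A [kinetic_curve()].
#' @param window Upper time limit of the fitting window (min, default 45).
#' @return Slope in %/min.
#' @export
initial_slope <- function(curve, window = 45) {
  stopifnot(inherits(curve, "kinetic_curve"))
  sel <- curve$times > 0 & curve$times <= window
  if (!any(sel)) stop_invalid("no sample points inside the window")
  t <- curve$times[sel]; y <- curve$yields[sel]
  sum(t * y) / sum(t^2)
}

#' One-factor-at-a-time effect summary
#'
#' Groups curves that share all operating factors except `factor` and
#' tabulates the final yield and initial slope per level of the varied
#' factor.
#'
#' @param curves List of [kinetic_curve()] objects.
#' @param factor One of `"pressure"`, `"temperature"`, `"flow"`,
#'   `"particle_size"`.
#' @param window Initial-slope window passed to [initial_slope()].
#' @return A data.frame with one row per (group, level): the common
#'   values of the held factors, the varied level, `final_yield` and
#'   `initial_slope`. Empty (with a warning) when no group varies the
#'   factor.
#' @export
ofat_effect <- function(curves, factor = c("pressure", "temperature", "flow",
                                           "particle_size"), window = 45) {
  factor <- match.arg(factor)
  others <- setdiff(c("pressure", "temperature", "flow", "particle_size"), factor)
  meta <- data.frame(
    idx = seq_along(curves),
    run_id = vapply(curves, `[[`, character(1), "run_id"),
    pressure = vapply(curves, `[[`, numeric(1), "pressure"),
    temperature = vapply(curves, `[[`, numeric(1), "temperature"),
    flow = vapply(curves, `[[`, numeric(1), "flow"),
    particle_size = vapply(curves, `[[`, numeric(1), "particle_size"),
    stringsAsFactors = FALSE)
  key <- do.call(paste, c(meta[others], sep = "|"))
  out <- list()
  for (k in unique(key)) {
    rows <- meta[key == k, , drop = FALSE]
    if (length(unique(rows[[factor]])) < 2) next
    rows <- rows[order(rows[[factor]]), , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      crv <- curves[[rows$idx[j]]]
      rec <- rows[j, c("run_id", others, factor)]
      names(rec)[ncol(rec)] <- "level"
      rec$varied <- factor
      rec$final_yield <- crv$yields[length(crv$yields)]
      rec$initial_slope <- initial_slope(crv, window)
      out[[length(out) + 1]] <- rec
    }
  }
  if (!length(out)) {
    warning("no group of curves varies '", factor,
            "' with the other factors held fixed", call. = FALSE)
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
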