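# Forward evaluation of the five empirical extraction-yield models.
# All express cumulative yield Y (% of charge) versus extraction time t
# (min); Yinf is the asymptotic yield.

.empirical_fields <- list(
  I   = c("Yinf", "k"),
  II  = c("Yinf", "a", "b"),
  III = c("Yinf", "k"),
  IV  = c("Yinf", "f1", "k1", "f2", "k2"),
  V   = c("Yinf", "G", "t1", "ti")
)

#' Empirical model parameter record
#'
#' Builds a validated parameter record for one of the five empirical
#' models:
#' * `I`   single exponential `Yinf * (1 - exp(-k * t))`
#' * `II`  corrected exponential `Yinf * (1 - exp(a * t + b))`
#' * `III` hyperbolic `Yinf * t / (k + t)` (`k` is the half-saturation
#'   time in min)
#' * `IV`  two-pool exponential
#'   `Yinf * (1 - f1 * exp(-k1 * t) - f2 * exp(-k2 * t))`
#' * `V`   piecewise constant-rate: linear `Yinf * G * t / t1` up to
#'   `t1`, then `Yinf * (1 - (1 - G) * exp(-(t - t1) / ti))`
#'
#' For model V the second branch uses a decaying exponential so the curve
#' is continuous at `t1` and approaches `Yinf`; `f1 + f2` is not forced to
#' one for model IV (fitted values may deviate slightly).
#'
#' @param model One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param ... Named parameters as listed above.
#' @return An object of class `empirical_params`.
#' @examples
#' p <- empirical_params("I", Yinf = 5.13, k = 0.002)
#' eval_empirical(p, c(0, 60, 240))
#' @export
empirical_params <- function(model, ...) {
  model <- match.arg(model, names(.empirical_fields))
  pars <- list(...)
  need <- .empirical_fields[[model]]
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    stop_invalid("model ", model, " requires parameters: ",
                 paste(missing, collapse = ", "))
  }
  pars <- pars[need]
  if (!all(vapply(pars, function(p) is.numeric(p) && length(p) == 1 && is.finite(p),
                  logical(1)))) {
    stop_invalid("all parameters must be finite scalars")
  }
  if (pars$Yinf <= 0) stop_invalid("Yinf must be positive")
  if (model == "V") {
    if (pars$G <= 0 || pars$G > 1) stop_invalid("G must lie in (0, 1]")
    if (pars$t1 <= 0 || pars$ti <= 0) stop_invalid("t1 and ti must be positive")
  }
  structure(c(list(model = model), pars), class = "empirical_params")
}

#' @export
print.empirical_params <- function(x, ...) {
  vals <- unlist(x[.empirical_fields[[x$model]]])
  cat(sprintf("Empirical model %s: %s\n", x$model,
              paste(names(vals), signif(vals, 4), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Evaluate an empirical extraction model
#'
#' @param params An [empirical_params()] record.
#' @param t Extraction times (min), vectorized, `t >= 0`.
#' @return Cumulative yield in % of charge at each `t`.
#' @export
eval_empirical <- function(params, t) {
  if (!inherits(params, "empirical_params")) {
    stop_invalid("params must be an empirical_params record")
  }
  if (any(t < 0)) stop_invalid("t must be non-negative")
  p <- params
  switch(p$model,
    I   = p$Yinf * (1 - exp(-p$k * t)),
    II  = p$Yinf * (1 - exp(p$a * t + p$b)),
    III = p$Yinf * t / (p$k + t),
    IV  = p$Yinf * (1 - (p$f1 * exp(-p$k1 * t) + p$f2 * exp(-p$k2 * t))),
    V   = ifelse(t <= p$t1,
                 p$Yinf * p$G * t / p$t1,
                 p$Yinf * (1 - (1 - p$G) * exp(-(t - p$t1) / p$ti))),
    stop(structure(class = c("sfe_unsupported_model", "error", "condition"),
                   list(message = paste("unknown model", p$model), call = NULL)))
  )
}

#' End of the constant-rate period for the piecewise model
#'
#' `t1 = G / (Km * qdot)`, the duration of the linear (constant
#' extraction rate) branch given the mass-related coefficient `Km` and
#' the solvent flow `qdot`.
#'
#' @param G Fraction of readily extractable solute, in (0, 1].
#' @param Km Mass-related coefficient.
#' @param qdot Solvent mass flow.
#' @return Duration of the linear branch (min when `Km * qdot` is 1/min).
#' @export
model5_t1 <- function(G, Km, qdot) {
  check_positive(G, "G")
  check_positive(Km, "Km")
  check_positive(qdot, "qdot")
  G / (Km * qdot)
}

# Parameter records round-trip to JSON keyed by model id.

#' Serialize empirical parameters to JSON
#'
#' @param params An [empirical_params()] record.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly when written to file.
#' @export
empirical_params_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "empirical_params"))
  rec <- unclass(params)
  if (is.null(path)) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname empirical_params_json
#' @param json JSON string or file path produced by [empirical_params_json()].
#' @export
empirical_params_from_json <- function(json) {
  rec <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
         else jsonlite::fromJSON(json)
  do.call(empirical_params, rec)
}
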