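# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_invalid <- function(...) {
  stop(structure(
    class = c("sfe_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(name, " must be finite and strictly positive")
  }
  invisible(x)
}

#' @noRd
check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop_invalid(name, " must lie strictly inside (0, 1)")
  }
  invisible(x)
}

# Numerically stable log(1 + exp(x)).
#' @noRd
log1pexp <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
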