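# Feed-forward surrogate of the initial extraction slope over the
# operating factors (pressure, temperature, flow), with quasi-Newton
# (BFGS) weight training, Yoon weight-product sensitivity and grid
# optimization of the predicted slope.
#
# Architecture: inputs -> n_hidden tanh units -> one linear output, with
# min-max scaling of inputs and output to [-1, 1]. For 3 inputs and 6
# hidden units the parameter count is 3*6 + 6 + 6 + 1 = 31.

#' Split rows into training / test / validation sets
#'
#' Seeded random partition in 60/20/20 proportions. The test set takes
#' `ceiling(0.2 n)` rows and the validation set `floor(0.2 n)`; the
#' remainder (at least 60%) trains.
#'
#' @param n Number of rows (>= 5).
#' @param seed RNG seed for the shuffle.
#' @return List of disjoint index vectors `train`, `test`, `validation`.
#' @examples
#' lengths(split_data(19, seed = 1)) # 12, 4, 3
#' @export
split_data <- function(n, seed = 1) {
  if (!is.numeric(n) || n < 5) stop_invalid("need at least 5 rows to split")
  n <- as.integer(n)
  n_test <- ceiling(0.2 * n)
  n_val <- floor(0.2 * n)
  idx <- with_seed(seed, sample.int(n))
  list(train = sort(idx[seq_len(n - n_test - n_val)]),
       test = sort(idx[n - n_test - n_val + seq_len(n_test)]),
       validation = sort(idx[n - n_val + seq_len(n_val)]))
}

# -- forward pass and gradients (vector of 31 packed weights) --------------

.ann_unpack <- function(w, n_in, n_hid) {
  i1 <- n_in * n_hid
  list(W1 = matrix(w[seq_len(i1)], n_in, n_hid),
       B1 = w[i1 + seq_len(n_hid)],
       W2 = w[i1 + n_hid + seq_len(n_hid)],
       B2 = w[i1 + 2 * n_hid + 1])
}

.ann_pack <- function(W1, B1, W2, B2) c(as.numeric(W1), B1, W2, B2)

.ann_forward <- function(w, X, n_hid) {
  p <- .ann_unpack(w, ncol(X), n_hid)
  H <- tanh(sweep(X %*% p$W1, 2, p$B1, "+"))
  list(yhat = as.numeric(H %*% p$W2 + p$B2), H = H, p = p)
}

.ann_loss <- function(w, X, y, n_hid) {
  sum((.ann_forward(w, X, n_hid)$yhat - y)^2)
}

.ann_grad <- function(w, X, y, n_hid) {
  fw <- .ann_forward(w, X, n_hid)
  r <- 2 * (fw$yhat - y)                  # n
  dH <- (1 - fw$H^2) * (r %o% fw$p$W2)    # n x h
  gW1 <- t(X) %*% dH
  gB1 <- colSums(dH)
  gW2 <- as.numeric(t(fw$H) %*% r)
  gB2 <- sum(r)
  .ann_pack(gW1, gB1, gW2, gB2)
}

.minmax_scale <- function(x, rng) {
  if (any(rng[2, ] - rng[1, ] <= 0)) stop_invalid("degenerate scaling range")
  sweep(sweep(x, 2, rng[1, ]), 2, (rng[2, ] - rng[1, ]) / 2, "/") - 1
}

.minmax_unscale <- function(z, rng) {
  (z + 1) * (rng[2] - rng[1]) / 2 + rng[1]
}

#' Train the slope surrogate network
#'
#' Fits the feed-forward network by BFGS quasi-Newton minimisation of the
#' training-set squared error, from several seeded random weight
#' initialisations; among the restarts, the model with the lowest
#' test-set SSE is kept (lowest training SSE when no test rows are
#' given).
#'
#' @param X Numeric matrix of factor rows (columns = inputs, e.g.
#'   pressure, temperature, flow), unscaled.
#' @param y Response vector (initial slopes, %/min).
#' @param split A [split_data()]-style list of index vectors; `NULL`
#'   trains on all rows.
#' @param n_hidden Hidden-layer width (default 6).
#' @param n_restarts Random restarts (default 20).
#' @param seed RNG seed for initial weights.
#' @param maxit BFGS iteration cap per restart.
#' @return Object of class `ann_model`: weight matrices `W1` (inputs x
#'   hidden), `B1`, `W2`, `B2`, the input/output min-max `scaling`,
#'   `n_params`, the training `r2`, per-set SSEs and the `seed`.
#' @export
train_mlp <- function(X, y, split = NULL, n_hidden = 6, n_restarts = 20,
                      seed = 2021, maxit = 500) {
  X <- as.matrix(X)
  if (n_hidden < 1) stop_invalid("n_hidden must be >= 1")
  if (nrow(X) != length(y)) stop_invalid("X rows and y length differ")
  if (diff(range(y)) == 0) {
    stop(structure(class = c("sfe_undefined_statistic", "error", "condition"),
                   list(message = "zero-variance response: R2 undefined",
                        call = NULL)))
  }
  in_rng <- apply(X, 2, range)
  out_rng <- range(y)
  Xs <- .minmax_scale(X, in_rng)
  ys <- (y - out_rng[1]) / diff(out_rng) * 2 - 1

  tr <- split$train %||% seq_len(nrow(X))
  te <- split$test %||% integer(0)
  n_in <- ncol(X)
  n_par <- n_in * n_hidden + n_hidden + n_hidden + 1

  cand <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      w0 <- stats::rnorm(n_par, sd = 0.5)
      ans <- tryCatch(
        stats::optim(w0, fn = .ann_loss, gr = .ann_grad, X = Xs[tr, , drop = FALSE],
                     y = ys[tr], n_hid = n_hidden, method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-12)),
        error = function(e) NULL)
      ans
    })
  })
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) {
    stop(structure(class = c("sfe_training_failure", "error", "condition"),
                   list(message = "all restarts diverged", call = NULL)))
  }
  score <- vapply(cand, function(a) {
    if (length(te)) .ann_loss(a$par, Xs[te, , drop = FALSE], ys[te], n_hidden)
    else a$value
  }, numeric(1))
  best <- cand[[which.min(score)]]
  p <- .ann_unpack(best$par, n_in, n_hidden)

  yhat_tr <- .ann_forward(best$par, Xs[tr, , drop = FALSE], n_hidden)$yhat
  r2_tr <- 1 - sum((ys[tr] - yhat_tr)^2) / sum((ys[tr] - mean(ys[tr]))^2)
  structure(list(W1 = p$W1, B1 = p$B1, W2 = p$W2, B2 = p$B2,
                 scaling = list(input = in_rng, output = out_rng),
                 n_hidden = n_hidden, n_params = n_par,
                 input_names = colnames(X) %||% paste0("x", seq_len(n_in)),
                 r2 = r2_tr, sse_train = best$value,
                 sse_test = if (length(te)) min(score) else NA_real_,
                 split = split, seed = seed),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("Feed-forward surrogate %d-%d-1 (%d weights and biases)\n",
              nrow(x$W1), x$n_hidden, x$n_params))
  cat(sprintf("  training R2 = %.4f, training SSE = %.3g (scaled units)\n",
              x$r2, x$sse_train))
  invisible(x)
}

#' Predict from a trained surrogate
#'
#' @param object An [train_mlp()] model.
#' @param newdata Matrix or data.frame of factor rows on the original
#'   scale.
#' @param ... Unused.
#' @return Predicted response on the original scale.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- .minmax_scale(X, object$scaling$input)
  w <- .ann_pack(object$W1, object$B1, object$W2, object$B2)
  z <- .ann_forward(w, Xs, object$n_hidden)$yhat
  .minmax_unscale(z, object$scaling$output)
}

#' Yoon relative importance of the inputs
#'
#' Signed weight-product decomposition of a trained network:
#' `RI_i = 100 * sum_k(W1[i,k] * W2[k]) / sum_j |sum_k(W1[j,k] * W2[k])|`.
#' The absolute importances always sum to 100.
#'
#' @param model A trained [train_mlp()] model.
#' @return Object of class `sensitivity_result`: named vector
#'   `relative_importance` (signed %).
#' @export
yoon_importance <- function(model) {
  stopifnot(inherits(model, "ann_model"))
  s <- as.numeric(model$W1 %*% model$W2)
  denom <- sum(abs(s))
  if (denom == 0) {
    stop(structure(class = c("sfe_undefined_statistic", "error", "condition"),
                   list(message = "all weight products are zero", call = NULL)))
  }
  ri <- 100 * s / denom
  names(ri) <- model$input_names
  structure(list(relative_importance = ri), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  ri <- x$relative_importance
  cat("Yoon relative importance (signed %):\n")
  for (i in seq_along(ri)) cat(sprintf("  %-12s %+7.2f%%\n", names(ri)[i], ri[i]))
  invisible(x)
}

#' Grid optimization of the predicted slope
#'
#' Evaluates the surrogate on a full factorial grid over the given factor
#' ranges and returns the maximizing operating point. Ties are broken
#' towards the lowest pressure, then the lowest flow, then the lowest
#' temperature (the energy-economical corner).
#'
#' @param model A trained [train_mlp()] model (inputs in the order
#'   pressure, temperature, flow).
#' @param ranges Named list of `c(lo, hi)` per factor; defaults to the
#'   training domain stored in the model.
#' @param grid_density Points per factor (default 31; 2 evaluates only
#'   the corners).
#' @return List with `factors` (named vector of the maximizing point)
#'   and `predicted` (slope there).
#' @export
optimize_slope <- function(model, ranges = NULL, grid_density = 31) {
  stopifnot(inherits(model, "ann_model"))
  if (grid_density < 2) stop_invalid("grid_density must be >= 2")
  rng <- model$scaling$input
  nm <- model$input_names
  if (is.null(ranges)) {
    ranges <- stats::setNames(lapply(seq_along(nm), function(j) rng[, j]), nm)
  }
  if (!all(nm %in% names(ranges))) {
    stop_invalid("ranges must cover all inputs: ", paste(nm, collapse = ", "))
  }
  for (j in seq_along(nm)) {
    r <- ranges[[nm[j]]]
    if (r[1] < rng[1, j] - 1e-9 || r[2] > rng[2, j] + 1e-9) {
      stop_invalid("range for ", nm[j], " lies outside the training domain")
    }
  }
  axes <- lapply(nm, function(f) seq(ranges[[f]][1], ranges[[f]][2],
                                     length.out = grid_density))
  names(axes) <- nm
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  # tie-break ordering: pressure, then flow, then temperature, ascending
  tie_cols <- intersect(c("pressure", "flow", "temperature"), nm)
  if (length(tie_cols)) grid <- grid[do.call(order, grid[tie_cols]), , drop = FALSE]
  pred <- predict(model, as.matrix(grid[nm]))
  i <- which.max(pred)
  list(factors = unlist(grid[i, nm]), predicted = pred[i])
}

#' Serialize a trained surrogate to JSON
#'
#' Weights are written row-major with the scaling blocks and seed, so a
#' model round-trips exactly.
#'
#' @param model An `ann_model`.
#' @param path Optional file path.
#' @return JSON string or `path` invisibly.
#' @export
ann_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "ann_model"))
  rec <- list(W1 = as.numeric(t(model$W1)), B1 = model$B1, W2 = model$W2,
              B2 = model$B2, n_inputs = nrow(model$W1),
              n_hidden = model$n_hidden,
              input_names = model$input_names,
              input_scaling = list(min = model$scaling$input[1, ],
                                   max = model$scaling$input[2, ]),
              output_scaling = list(min = model$scaling$output[1],
                                    max = model$scaling$output[2]),
              seed = model$seed)
  if (is.null(path)) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname ann_model_json
#' @param json JSON string or file path.
#' @export
ann_model_from_json <- function(json) {
  rec <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
         else jsonlite::fromJSON(json)
  n_in <- rec$n_inputs; n_hid <- rec$n_hidden
  structure(list(
    W1 = matrix(rec$W1, n_in, n_hid, byrow = TRUE),
    B1 = rec$B1, W2 = rec$W2, B2 = rec$B2,
    scaling = list(
      input = rbind(rec$input_scaling$min, rec$input_scaling$max),
      output = c(rec$output_scaling$min, rec$output_scaling$max)),
    n_hidden = n_hid, n_params = n_in * n_hid + 2 * n_hid + 1,
    input_names = rec$input_names, r2 = NA_real_, sse_train = NA_real_,
    sse_test = NA_real_, split = NULL, seed = rec$seed),
    class = "ann_model")
}
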