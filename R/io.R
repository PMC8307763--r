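# File formats and the end-to-end pipeline. Curves travel as CSV with
# header run_id,time_min,yield_pct (dot decimal, UTF-8, yields in % of
# charge) plus an optional JSON sidecar of per-run operating metadata.

#' Read kinetic curves from CSV
#'
#' Parses a curve table with header `run_id,time_min,yield_pct`
#' (additional columns are preserved as a per-curve `extras` attribute)
#' and validates every run against the [kinetic_curve()] invariants,
#' reporting offending file lines.
#'
#' @param path CSV file path.
#' @param metadata Optional path to a JSON sidecar: an object keyed by
#'   run id with fields `pressure`, `temperature`, `flow`,
#'   `particle_size`.
#' @return Named list of [kinetic_curve()] objects.
#' @export
read_curves <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "time_min", "yield_pct")
  if (!all(need %in% names(df))) {
    stop(structure(class = c("sfe_format_error", "error", "condition"),
                   list(message = paste0(
                     "malformed header: need columns ",
                     paste(need, collapse = ", ")), call = NULL)))
  }
  dup <- duplicated(df[c("run_id", "time_min")])
  if (any(dup)) {
    stop(structure(class = c("sfe_validation_error", "error", "condition"),
                   list(message = paste0(
                     "duplicated (run_id, time) at file line(s) ",
                     paste(which(dup) + 1, collapse = ", ")), call = NULL)))
  }
  meta <- if (!is.null(metadata)) jsonlite::read_json(metadata, simplifyVector = TRUE)
  extras_cols <- setdiff(names(df), need)
  out <- list()
  for (id in unique(df$run_id)) {
    rows <- df[df$run_id == id, , drop = FALSE]
    m <- meta[[as.character(id)]]
    crv <- tryCatch(
      kinetic_curve(run_id = id, times = rows$time_min, yields = rows$yield_pct,
                    pressure = m$pressure %||% NA_real_,
                    temperature = m$temperature %||% NA_real_,
                    flow = m$flow %||% NA_real_,
                    particle_size = m$particle_size %||% NA_real_),
      error = function(e) {
        stop(structure(class = c("sfe_validation_error", "error", "condition"),
                       list(message = paste0(
                         "run '", id, "' (file lines ",
                         paste(range(which(df$run_id == id) + 1), collapse = "-"),
                         "): ", conditionMessage(e)), call = NULL)))
      })
    if (length(extras_cols)) attr(crv, "extras") <- rows[extras_cols]
    out[[as.character(id)]] <- crv
  }
  out
}

#' Write kinetic curves to CSV
#'
#' Inverse of [read_curves()]: long-format CSV (yields to 4 decimals)
#' plus an optional JSON metadata sidecar.
#'
#' @param curves List of [kinetic_curve()] objects.
#' @param path Output CSV path.
#' @param metadata Optional sidecar JSON path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, metadata = NULL) {
  tabs <- lapply(curves, function(crv) {
    df <- as.data.frame(crv)
    df$yield_pct <- round(df$yield_pct, 4)
    ex <- attr(crv, "extras")
    if (!is.null(ex)) df <- cbind(df, ex)
    df
  })
  all_cols <- Reduce(union, lapply(tabs, names))
  tabs <- lapply(tabs, function(df) {
    df[setdiff(all_cols, names(df))] <- NA
    df[all_cols]
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata)) {
    meta <- lapply(curves, function(crv) {
      list(pressure = crv$pressure, temperature = crv$temperature,
           flow = crv$flow, particle_size = crv$particle_size)
    })
    names(meta) <- vapply(curves, `[[`, character(1), "run_id")
    jsonlite::write_json(meta, metadata, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles (or reads from JSON/YAML) the configuration of a full
#' analysis: input curves, models to fit, fitting and surrogate options
#' and the output directory.
#'
#' @param curves Path to a curves CSV, or a list of [kinetic_curve()]s.
#' @param metadata Optional metadata sidecar path.
#' @param models Character vector of model ids to fit (may be empty).
#' @param out_dir Output directory.
#' @param fit Named list of fitting options (`n_starts`, `seed`, ...).
#' @param ann Named list of surrogate options (`n_hidden`, `n_restarts`,
#'   `split_seed`, `seed`, `window`).
#' @param context Shared fitting context (see [fit_model()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(curves, metadata = NULL, models = c("I"),
                       out_dir = tempfile("sfe_report_"),
                       fit = list(), ann = list(), context = list()) {
  fit <- utils::modifyList(list(n_starts = 16, seed = 2021), fit)
  ann <- utils::modifyList(list(n_hidden = 6, n_restarts = 20,
                                split_seed = 1, seed = 2021, window = 45,
                                enabled = TRUE), ann)
  structure(list(curves = curves, metadata = metadata, models = models,
                 out_dir = out_dir, fit = fit, ann = ann, context = context),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON or YAML file with the fields of `run_config`.
#' @export
read_run_config <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, rec)
}

#' Run the full analysis pipeline
#'
#' Fits the requested models to every curve, tabulates per-run model
#' comparisons (SSE, R2, AARD) and parameter estimates, extracts initial
#' slopes, trains the slope surrogate with Yoon sensitivity and grid
#' optimization (when at least 5 curves carry complete operating
#' metadata), and writes everything to `out_dir` together with a log of
#' seeds and versions. Deterministic for fixed seeds. Stage failures are
#' collected into `errors.json` rather than aborting the whole run.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fits`, `comparison`, `slopes`,
#'   `ann`, `sensitivity`, `optimum`, `errors` and `out_dir`.
#' @export
pipeline_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  errors <- list()
  note <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  curves <- if (is.character(config$curves)) {
    read_curves(config$curves, config$metadata)
  } else config$curves

  fits <- list(); comp <- list()
  for (m in config$models) {
    for (crv in curves) {
      key <- paste0(crv$run_id, ".", m)
      f <- tryCatch(
        fit_model(crv, m, context = config$context,
                  n_starts = config$fit$n_starts, seed = config$fit$seed),
        error = function(e) note(paste0("fit:", key), e))
      if (is.null(f)) next
      fits[[key]] <- f
      comp[[key]] <- data.frame(run_id = crv$run_id, model = m,
                                SSE = f$gof$sse, R2 = f$gof$r2,
                                AARD = f$gof$aard,
                                t(f$par), check.names = FALSE)
    }
  }
  comparison <- if (length(comp)) {
    tab <- do.call(rbind, lapply(comp, function(d) d[c("run_id", "model", "SSE", "R2", "AARD")]))
    rownames(tab) <- NULL
    utils::write.csv(tab, file.path(config$out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    for (m in unique(tab$model)) {
      sub <- do.call(rbind, comp[vapply(comp, function(d) d$model == m, logical(1))])
      utils::write.csv(sub, file.path(config$out_dir, paste0("params_model_", m, ".csv")),
                       row.names = FALSE)
    }
    tab
  }

  slopes <- data.frame(
    run_id = vapply(curves, `[[`, character(1), "run_id"),
    pressure = vapply(curves, `[[`, numeric(1), "pressure"),
    temperature = vapply(curves, `[[`, numeric(1), "temperature"),
    flow = vapply(curves, `[[`, numeric(1), "flow"),
    initial_slope = vapply(curves, initial_slope, numeric(1),
                           window = config$ann$window))
  rownames(slopes) <- NULL
  utils::write.csv(slopes, file.path(config$out_dir, "initial_slopes.csv"),
                   row.names = FALSE)

  ann <- sens <- opt <- NULL
  complete <- stats::complete.cases(slopes[c("pressure", "temperature", "flow")])
  if (isTRUE(config$ann$enabled) && sum(complete) >= 5) {
    res <- tryCatch({
      X <- as.matrix(slopes[complete, c("pressure", "temperature", "flow")])
      y <- slopes$initial_slope[complete]
      sp <- split_data(nrow(X), seed = config$ann$split_seed)
      model <- train_mlp(X, y, split = sp, n_hidden = config$ann$n_hidden,
                         n_restarts = config$ann$n_restarts,
                         seed = config$ann$seed)
      list(model = model, sens = yoon_importance(model),
           opt = optimize_slope(model))
    }, error = function(e) note("ann", e))
    if (!is.null(res)) {
      ann <- res$model; sens <- res$sens; opt <- res$opt
      ann_model_json(ann, file.path(config$out_dir, "ann_model.json"))
      jsonlite::write_json(
        list(relative_importance = as.list(sens$relative_importance),
             optimum = as.list(opt$factors),
             predicted_slope = opt$predicted),
        file.path(config$out_dir, "sensitivity.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }

  log_lines <- c(
    paste0("sfekinetics ", as.character(utils::packageVersion("sfekinetics"))),
    paste0("R ", R.version.string),
    paste0("fit seed: ", config$fit$seed, "; starts: ", config$fit$n_starts),
    paste0("ann seed: ", config$ann$seed, "; split seed: ", config$ann$split_seed,
           "; restarts: ", config$ann$n_restarts),
    paste0("models: ", paste(config$models, collapse = ", ")))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  if (length(errors)) {
    jsonlite::write_json(errors, file.path(config$out_dir, "errors.json"),
                         auto_unbox = TRUE)
  }
  invisible(list(fits = fits, comparison = comparison, slopes = slopes,
                 ann = ann, sensitivity = sens, optimum = opt,
                 errors = errors, out_dir = config$out_dir))
}
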