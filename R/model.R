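# The user-facing QSPR model: fragment descriptors + PLS1 + LOO latent
# variable selection + coefficient-threshold pruning, per target metal.

#' Fit a fragment-based QSPR sensitivity model
#'
#' End-to-end training for one target ion: SMILES are parsed to
#' hydrogen-suppressed Kekule graphs, shortest-path fragment descriptors of
#' `min_atoms`-`max_atoms` atoms are counted into a molecule x fragment
#' matrix, a PLS1 model is fit with the latent-variable count chosen by
#' leave-one-out cross-validation, descriptors with weighted coefficients in
#' `(-threshold, threshold)` are pruned, and the model is refit on the
#' reduced vocabulary (LV count re-selected by LOO). Records lacking the
#' target metal's sensitivity are excluded from training. The whole procedure
#' is deterministic.
#'
#' @param data data frame with columns `id`, `smiles` and a sensitivity
#'   column for the target metal (in mV/decade), e.g. from
#'   [read_sensitivity_data()].
#' @param metal target ion label; the response column is `metal` itself if
#'   present, otherwise `sens_<metal>` (so `metal = "Cd"` reads `sens_Cd`).
#'   Any label works — nothing is specific to Cu/Cd/Pb.
#' @param min_atoms,max_atoms fragment length bounds in atoms.
#' @param max_lv largest latent-variable count tried in cross-validation.
#' @param prune apply coefficient-threshold pruning (default `TRUE`).
#' @param threshold weighted-coefficient pruning threshold (default 0.05).
#' @param min_support importance-report support filter (default 5 molecules).
#' @param collapse_nested,nested_tol see [important_fragments()].
#' @param bonds_in_string write bond symbols inside fragment strings
#'   (default `TRUE`; `FALSE` gives atom-sequence-only fragments).
#' @param graphs optional named list of pre-parsed `molecular_graph` objects
#'   matching `data$id`, e.g. from [generate_molecules()]; skips SMILES
#'   parsing in simulation studies. Ignored for rows excluded by missing
#'   sensitivities.
#' @return object of class `smf_pls`; see [predict.smf_pls()],
#'   [summary.smf_pls()], [write_smf_pls()].
#' @examples
#' \donttest{
#' spec <- synthetic_spec(n_molecules = 30, seed = 1)
#' ds <- synthetic_dataset(spec)
#' m <- smf_pls(ds$data, metal = "synthetic", max_lv = 5)
#' summary(m)
#' }
#' @export
smf_pls <- function(data, metal, min_atoms = 2L, max_atoms = 9L, max_lv = 10L,
                    prune = TRUE, threshold = 0.05, min_support = 5L,
                    collapse_nested = FALSE, nested_tol = 0.2,
                    bonds_in_string = TRUE, graphs = NULL) {
  cl <- match.call()
  if (!is.data.frame(data)) stop("smf_pls: data must be a data frame")
  if (!all(c("id", "smiles") %in% names(data))) {
    stop("smf_pls: data needs 'id' and 'smiles' columns")
  }
  ycol <- if (metal %in% names(data)) metal else paste0("sens_", metal)
  if (!ycol %in% names(data)) {
    stop(sprintf("smf_pls: no sensitivity column '%s' or '%s' in data",
                 metal, paste0("sens_", metal)))
  }
  keep <- !is.na(data[[ycol]])
  if (sum(keep) < 5L) {
    stop(sprintf("smf_pls: need >= 5 records with %s sensitivity, have %d",
                 metal, sum(keep)))
  }
  dat <- data[keep, , drop = FALSE]
  y <- as.numeric(dat[[ycol]])
  if (stats::sd(y) == 0) stop("smf_pls: all sensitivities are identical")

  if (is.null(graphs)) {
    graphs <- parse_smiles(dat$smiles, ids = dat$id)
    if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  } else {
    if (!all(dat$id %in% names(graphs))) {
      stop("smf_pls: supplied graphs do not cover every training id")
    }
    graphs <- graphs[dat$id]
  }
  X_full <- descriptor_matrix(graphs, min_atoms = min_atoms,
                              max_atoms = max_atoms,
                              bonds_in_string = bonds_in_string)
  cv_full <- loo_cv(X_full, y, max_lv = max_lv)
  fit_full <- fit_pls(X_full, y, n_lv = cv_full$selected_lv)
  metrics_full <- list(
    calibration = regression_metrics(y, fit_full$fitted, "calibration"),
    validation = regression_metrics(
      y, cv_full$predictions[, cv_full$selected_lv], "loo_validation"))

  if (prune) {
    pr <- prune_descriptors(fit_full, X_full, y, threshold = threshold,
                            max_lv = max_lv)
    fit_final <- pr$fit
    X_final <- pr$X
    cv_final <- pr$cv
    metrics_final <- list(calibration = pr$calibration,
                          validation = pr$validation)
  } else {
    fit_final <- fit_full; X_final <- X_full; cv_final <- cv_full
    metrics_final <- metrics_full
  }
  importance <- important_fragments(fit_final, X_final,
                                    min_support = min_support,
                                    collapse_nested = collapse_nested,
                                    nested_tol = nested_tol)
  config <- list(min_atoms = as.integer(min_atoms),
                 max_atoms = as.integer(max_atoms),
                 max_lv = as.integer(max_lv), prune = prune,
                 threshold = threshold, min_support = as.integer(min_support),
                 collapse_nested = collapse_nested, nested_tol = nested_tol,
                 bonds_in_string = bonds_in_string)
  digest <- .data_digest(dat[, c("id", "smiles", ycol)], config)

  structure(list(
    call = cl, metal = metal, response_column = ycol, config = config,
    ids = dat$id, smiles = dat$smiles, y = y,
    vocabulary_full = colnames(X_full),
    vocabulary = fit_final$kept_columns,
    fit = fit_final, X = X_final, cv = cv_final, cv_full = cv_full,
    metrics_full = metrics_full, metrics = metrics_final,
    importance = importance, input_digest = digest
  ), class = "smf_pls")
}

# md5 of a canonical text rendering of the training table + config
.data_digest <- function(df, config) {
  txt <- c(vapply(seq_len(nrow(df)),
                  function(r) paste(format(unlist(df[r, ]), digits = 17),
                                    collapse = ","), ""),
           paste(names(config), vapply(config, format, ""), sep = "="))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' @export
print.smf_pls <- function(x, ...) {
  cat(sprintf("QSPR sensitivity model for %s (PLS1, %d latent variables)\n",
              x$metal, x$fit$n_lv))
  cat(sprintf("  training molecules : %d\n", length(x$y)))
  cat(sprintf("  fragment vocabulary: %d full -> %d after pruning (|b_w| >= %g)\n",
              length(x$vocabulary_full), length(x$vocabulary),
              x$config$threshold))
  print(x$metrics$calibration)
  print(x$metrics$validation)
  invisible(x)
}

#' Summarise a QSPR sensitivity model
#'
#' Collects the model-quality table (slope / RMSE / R-squared for calibration
#' and leave-one-out validation, before and after pruning), vocabulary sizes,
#' the chosen latent-variable count and the top of the fragment-importance
#' ranking.
#'
#' @param object an `smf_pls` model.
#' @param ... unused.
#' @return a `summary.smf_pls` list; its print method renders the report.
#' @export
summary.smf_pls <- function(object, ...) {
  row <- function(m) c(slope = m$slope, RMSE = m$rmse, R2 = m$r2)
  tab <- rbind(full_calibration = row(object$metrics_full$calibration),
               full_validation = row(object$metrics_full$validation),
               calibration = row(object$metrics$calibration),
               validation = row(object$metrics$validation))
  vf <- if (is.null(object$vocabulary_full)) {
    object$vocabulary_full_size          # restored from JSON
  } else {
    length(object$vocabulary_full)
  }
  structure(list(metal = object$metal, n = length(object$y),
                 n_lv = object$fit$n_lv,
                 n_lv_full = object$cv_full$selected_lv,
                 vocabulary_full = vf,
                 vocabulary = length(object$vocabulary),
                 metrics = tab, importance = object$importance,
                 threshold = object$config$threshold,
                 digest = object$input_digest),
            class = "summary.smf_pls")
}

#' @export
print.summary.smf_pls <- function(x, ...) {
  cat(sprintf("QSPR sensitivity model: %s\n", x$metal))
  cat(sprintf("  %d training molecules; vocabulary %d -> %d (threshold %g); %d LVs\n",
              x$n, x$vocabulary_full, x$vocabulary, x$threshold, x$n_lv))
  print(round(x$metrics, 3))
  cat("\nTop fragments:\n")
  print(x$importance, n = 10L)
  invisible(x)
}

#' @export
coef.smf_pls <- function(object, weighted = FALSE, ...) {
  coef(object$fit, weighted = weighted)
}

#' @export
fitted.smf_pls <- function(object, ...) {
  stats::setNames(object$fit$fitted, object$ids)
}

#' @export
residuals.smf_pls <- function(object, ...) {
  stats::setNames(object$y - object$fit$fitted, object$ids)
}

#' Predict sensitivities for new ionophores
#'
#' Parses the new SMILES, counts their fragments against the model's pruned
#' vocabulary (fragments unknown to the model are ignored; vocabulary
#' fragments absent from a molecule count zero) and applies the PLS
#' coefficients. Each prediction carries an applicability `coverage`: the
#' fraction of the molecule's distinct fragments that appear in the model
#' vocabulary. Low coverage (< 0.5) signals extrapolation and triggers a
#' warning, but never changes the prediction. Molecules that fail to parse
#' yield `NA` with a warning instead of aborting the batch.
#'
#' @param object an `smf_pls` model.
#' @param newdata character vector of SMILES, or a data frame with `smiles`
#'   and optionally `id`.
#' @param coverage_warn warn below this coverage (default 0.5).
#' @param ... unused.
#' @return data frame with columns `id`, `smiles`, `predicted` (mV/decade)
#'   and `coverage`.
#' @export
predict.smf_pls <- function(object, newdata, coverage_warn = 0.5, ...) {
  if (is.character(newdata)) {
    newdata <- data.frame(id = paste0("new", seq_along(newdata)),
                          smiles = newdata, stringsAsFactors = FALSE)
  }
  if (!"smiles" %in% names(newdata)) stop("predict: newdata needs a 'smiles' column")
  if (!"id" %in% names(newdata)) newdata$id <- paste0("new", seq_len(nrow(newdata)))

  cfg <- object$config
  out <- data.frame(id = newdata$id, smiles = newdata$smiles,
                    predicted = NA_real_, coverage = NA_real_,
                    stringsAsFactors = FALSE)
  failed <- character(0)
  # batch parse; on failure fall back to one-by-one so a bad SMILES only
  # voids its own row
  gs <- tryCatch({
    g <- parse_smiles(newdata$smiles, ids = newdata$id)
    if (inherits(g, "molecular_graph")) stats::setNames(list(g), newdata$id) else g
  }, error = function(e) NULL)
  if (is.null(gs)) {
    gs <- lapply(seq_len(nrow(newdata)), function(r) {
      tryCatch(parse_smiles(newdata$smiles[r], ids = newdata$id[r]),
               error = function(e) NULL)
    })
    names(gs) <- newdata$id
  }
  for (r in seq_len(nrow(newdata))) {
    g <- gs[[r]]
    if (is.null(g)) { failed <- c(failed, newdata$id[r]); next }
    cc <- count_fragments(g, cfg$min_atoms, cfg$max_atoms,
                          bonds_in_string = cfg$bonds_in_string)
    x <- stats::setNames(numeric(length(object$vocabulary)), object$vocabulary)
    hit <- intersect(names(cc), object$vocabulary)
    x[hit] <- cc[hit]
    out$predicted[r] <- sum(x * object$fit$b_raw[object$vocabulary]) +
      object$fit$intercept
    out$coverage[r] <- if (length(cc) == 0L) 0 else
      length(hit) / length(cc)
  }
  if (length(failed)) {
    warning("predict: unparseable SMILES for: ", paste(failed, collapse = ", "))
  }
  low <- !is.na(out$coverage) & out$coverage < coverage_warn
  if (any(low)) {
    warning(sprintf(
      "predict: low fragment coverage (< %g) for %s; predictions are extrapolations",
      coverage_warn, paste(out$id[low], collapse = ", ")))
  }
  out
}

#' Diagnostic plots for a QSPR sensitivity model
#'
#' Two base-graphics panels: measured vs leave-one-out-predicted sensitivity
#' with the identity line, and the weighted regression coefficient profile
#' with the pruning threshold band.
#'
#' @param x an `smf_pls` model.
#' @param which `1` (measured vs predicted), `2` (coefficients), or both.
#' @param ... passed to [graphics::plot()].
#' @exportS3Method graphics::plot
plot.smf_pls <- function(x, which = 1:2, ...) {
  if (length(which) > 1L) {
    old <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(old))
  }
  if (1L %in% which) {
    pred <- x$cv$predictions[, x$cv$selected_lv]
    graphics::plot(x$y, pred,
                   xlab = sprintf("measured %s sensitivity (mV/dec)", x$metal),
                   ylab = "LOO-predicted (mV/dec)",
                   main = sprintf("%s: %d LVs", x$metal, x$fit$n_lv), ...)
    graphics::abline(0, 1, lty = 2)
  }
  if (2L %in% which) {
    b <- x$fit$b_weighted
    graphics::plot(seq_along(b), b, type = "h",
                   xlab = "descriptor index", ylab = "weighted coefficient",
                   main = "coefficient profile", ...)
    graphics::abline(h = c(-1, 1) * x$config$threshold, col = 2, lty = 3)
  }
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' `write_smf_pls` stores everything prediction and reporting need —
#' vocabulary, centring/scaling vectors, coefficients, intercept, LV count,
#' metrics, importance table, configuration and the training-input digest —
#' as a JSON document with 17 significant digits, so doubles survive the
#' round trip bit-exactly and identical models serialize to identical bytes.
#' `read_smf_pls` restores a model usable with `predict`, `summary`, `coef`.
#'
#' @param object an `smf_pls` model.
#' @param path JSON file path.
#' @return `write_smf_pls`: `path` invisibly. `read_smf_pls`: an `smf_pls`
#'   object (without training scores; refit to recover them).
#' @export
write_smf_pls <- function(object, path) {
  stopifnot(inherits(object, "smf_pls"))
  met <- function(m) m[c("slope", "rmse", "r2", "r2_ss", "n", "context")]
  doc <- list(
    format = "smfpls-model", format_version = 1L,
    metal = object$metal, response_column = object$response_column,
    config = object$config, input_digest = object$input_digest,
    training_ids = object$ids, training_smiles = object$smiles,
    y = object$y,
    vocabulary_full_size = length(object$vocabulary_full),
    vocabulary = object$vocabulary,
    x_center = unname(object$fit$x_center),
    x_scale = unname(object$fit$x_scale),
    y_center = object$fit$y_center,
    b_weighted = unname(object$fit$b_weighted),
    b_raw = unname(object$fit$b_raw),
    intercept = object$fit$intercept,
    n_lv = object$fit$n_lv,
    rmsecv = unname(object$cv$rmsecv),
    metrics_full = lapply(object$metrics_full, met),
    metrics = lapply(object$metrics, met),
    importance = as.data.frame(object$importance))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_smf_pls
#' @export
read_smf_pls <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "smfpls-model")) {
    stop("read_smf_pls: not an smfpls model file")
  }
  vocab <- doc$vocabulary
  fit <- structure(list(
    kept_columns = vocab, dropped_columns = character(0),
    x_center = stats::setNames(doc$x_center, vocab),
    x_scale = stats::setNames(doc$x_scale, vocab),
    y_center = doc$y_center,
    b_weighted = stats::setNames(doc$b_weighted, vocab),
    b_raw = stats::setNames(doc$b_raw, vocab),
    intercept = doc$intercept, n_lv = doc$n_lv
  ), class = "smf_plsfit")
  met <- function(m) structure(m, class = "model_metrics")
  imp <- doc$importance
  structure(list(
    call = NULL, metal = doc$metal, response_column = doc$response_column,
    config = doc$config, ids = doc$training_ids, smiles = doc$training_smiles,
    y = doc$y,
    vocabulary_full = NULL,
    vocabulary_full_size = doc$vocabulary_full_size,
    vocabulary = vocab, fit = fit, X = NULL,
    cv = list(rmsecv = doc$rmsecv, selected_lv = doc$n_lv),
    metrics_full = lapply(doc$metrics_full, met),
    metrics = lapply(doc$metrics, met),
    importance = imp, input_digest = doc$input_digest
  ), class = "smf_pls")
}
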