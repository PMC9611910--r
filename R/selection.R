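# Coefficient-threshold descriptor pruning and signed fragment-importance
# reporting.

#' Prune descriptors by weighted-coefficient threshold and refit
#'
#' Removes every descriptor column whose weighted (autoscaled-space)
#' regression coefficient lies strictly inside `(-threshold, +threshold)`,
#' then refits on the reduced matrix with the latent-variable count
#' re-selected by leave-one-out cross-validation. A single elimination pass is
#' performed by default; `iterate = TRUE` repeats the prune/refit cycle until
#' the kept set is stable.
#'
#' @param fit an `smf_plsfit` fitted on `X`.
#' @param X the descriptor matrix the model was fit on.
#' @param y the response used for the fit.
#' @param threshold coefficient magnitude below which a descriptor is dropped
#'   (default 0.05, on the weighted-coefficient scale).
#' @param max_lv largest latent-variable count for the refit CV.
#' @param iterate repeat pruning until stable (off by default).
#' @return list with `X` (reduced matrix), `fit` (refitted model),
#'   `calibration` and `validation` metrics, `cv` (the [loo_cv()] result),
#'   `kept` and `removed` fragment vectors, and `threshold`.
#' @export
prune_descriptors <- function(fit, X, y, threshold = 0.05, max_lv = 10L,
                              iterate = FALSE) {
  stopifnot(inherits(fit, "smf_plsfit"))
  X <- as.matrix(X)
  if (threshold < 0) stop("prune_descriptors: threshold must be >= 0")
  repeat {
    keep <- names(fit$b_weighted)[abs(fit$b_weighted) >= threshold]
    if (length(keep) == 0L) {
      stop("prune_descriptors: no descriptor passes the threshold; ",
           "use a smaller threshold")
    }
    Xr <- X[, keep, drop = FALSE]
    cv <- loo_cv(Xr, y, max_lv = max_lv)
    refit <- fit_pls(Xr, y, n_lv = cv$selected_lv)
    if (!iterate || identical(sort(refit$kept_columns), sort(fit$kept_columns))) {
      cal <- regression_metrics(y, refit$fitted, "calibration")
      val <- regression_metrics(y, cv$predictions[, cv$selected_lv],
                                "loo_validation")
      removed <- setdiff(colnames(X), keep)
      return(list(X = Xr, fit = refit, calibration = cal, validation = val,
                  cv = cv, kept = keep, removed = removed,
                  threshold = threshold))
    }
    fit <- refit; X <- Xr
  }
}

# Does fragment `long` extend fragment `short` only by terminal carbon
# atoms/bonds?  Checked on token sequences, in both orientations of `short`.
.extends_by_terminal_carbons <- function(long, short) {
  lt <- fragment_tokens(long); st <- fragment_tokens(short)
  nl <- length(lt$elements); ns <- length(st$elements)
  if (nl <= ns) return(FALSE)
  cand <- list(st, list(elements = rev(st$elements), orders = rev(st$orders)))
  for (s in cand) {
    for (off in 0:(nl - ns)) {
      idx <- seq_len(ns) + off
      if (all(lt$elements[idx] == s$elements) &&
          (ns < 2L || all(lt$orders[idx[-ns]] == s$orders))) {
        extra <- lt$elements[-idx]
        if (all(extra == "C")) return(TRUE)
      }
    }
  }
  FALSE
}

#' Signed fragment-importance report
#'
#' Ranks the fragments of a fitted model by the absolute value of their
#' weighted regression coefficient — the larger the magnitude, the more the
#' fragment contributes to the modelled sensitivity — keeping only fragments
#' present in at least `min_support` training molecules (guards against
#' chance correlations from rare fragments). With `collapse_nested = TRUE`, a
#' fragment that extends a shorter reported fragment only by terminal carbon
#' atoms is suppressed when the two coefficients are similar (relative
#' difference below `nested_tol`), so e.g. of a near-duplicate pair
#' `C-C-P-C=C-C` / `C-C-P-C=C` only the shorter is listed.
#'
#' @param fit an `smf_plsfit`.
#' @param X the descriptor matrix the model was fit on (for supports).
#' @param min_support minimum number of molecules containing the fragment
#'   (default 5).
#' @param collapse_nested suppress terminal-carbon extensions with similar
#'   coefficients (default `FALSE`).
#' @param nested_tol relative coefficient tolerance for collapsing
#'   (default 0.2).
#' @return object of class `importance_report`: data frame with columns
#'   `fragment`, `coefficient` (weighted), `support`, `sign`, sorted by
#'   decreasing `|coefficient|`; attributes `min_support`, `collapse_nested`,
#'   `nested_tol`.
#' @export
important_fragments <- function(fit, X, min_support = 5L,
                                collapse_nested = FALSE, nested_tol = 0.2) {
  stopifnot(inherits(fit, "smf_plsfit"))
  X <- as.matrix(X)
  frags <- fit$kept_columns
  supp <- fragment_support(X, frags)
  coefs <- fit$b_weighted
  keep <- supp >= min_support
  df <- data.frame(fragment = frags[keep],
                   coefficient = unname(coefs[keep]),
                   support = unname(supp[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(-abs(df$coefficient), df$fragment, method = "radix"), ,
           drop = FALSE]
  if (collapse_nested && nrow(df) > 1L) {
    drop <- logical(nrow(df))
    for (a in seq_len(nrow(df))) {
      for (b in seq_len(nrow(df))) {
        if (a == b || drop[b]) next
        if (.extends_by_terminal_carbons(df$fragment[a], df$fragment[b])) {
          ca <- df$coefficient[a]; cb <- df$coefficient[b]
          denom <- max(abs(ca), abs(cb))
          if (denom > 0 && abs(ca - cb) / denom < nested_tol) {
            drop[a] <- TRUE
            break
          }
        }
      }
    }
    df <- df[!drop, , drop = FALSE]
  }
  df$sign <- ifelse(df$coefficient >= 0, "positive", "negative")
  rownames(df) <- NULL
  structure(df, class = c("importance_report", "data.frame"),
            min_support = min_support, collapse_nested = collapse_nested,
            nested_tol = nested_tol)
}

#' @export
print.importance_report <- function(x, n = 20L, ...) {
  cat(sprintf("Fragment importance (min support %d%s): %d fragments\n",
              attr(x, "min_support"),
              if (isTRUE(attr(x, "collapse_nested"))) ", nested collapsed" else "",
              nrow(x)))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Write an importance report to TSV
#'
#' Columns `fragment`, `coefficient`, `support`, `sign`, tab-separated.
#'
#' @param report an `importance_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_importance <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
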