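# NIPALS PLS1 with autoscaled descriptors, leave-one-out cross-validation
# for choosing the number of latent variables, and regression metrics.

# Core NIPALS PLS1 on a centred/scaled X and centred y.
# Returns weights W, loadings P, scores Tm, y-loadings q, and the
# coefficient path Bpath (scaled-space coefficients for 1..A components).
# With strict = FALSE, rank exhaustion truncates the decomposition at the
# attainable number of components instead of erroring.
.nipals_pls1 <- function(Xs, yc, A, tol = 1e-12, strict = TRUE) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  # X is never deflated: with orthogonal scores, E_a' f_a = X' f_a and
  # E_a' t_a = X' t_a, and t_a = X w_a - sum_b t_b (p_b' w_a); only the
  # response residual f needs updating.  Identical to textbook NIPALS.
  f <- yc
  attained <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xs, f)
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      if (strict) stop(sprintf(
        "fit_pls: %d latent variables exceed the rank of the training matrix", A))
      break
    }
    w <- w / nw
    t_a <- as.numeric(Xs %*% w)
    if (a > 1L) {
      bb <- seq_len(a - 1L)
      t_a <- t_a - as.numeric(Tm[, bb, drop = FALSE] %*%
                                crossprod(P[, bb, drop = FALSE], w))
    }
    tt <- sum(t_a^2)
    if (tt < tol) {
      if (strict) stop(sprintf(
        "fit_pls: %d latent variables exceed the rank of the training matrix", A))
      break
    }
    p_a <- as.numeric(crossprod(Xs, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    attained <- a
  }
  A <- attained
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
  Bpath <- matrix(0, p, A)
  for (a in seq_len(A)) {
    PtW <- crossprod(P[, seq_len(a), drop = FALSE], W[, seq_len(a), drop = FALSE])
    Bpath[, a] <- W[, seq_len(a), drop = FALSE] %*% solve(PtW, q[seq_len(a)])
  }
  list(W = W, P = P, Tm = Tm, q = q, Bpath = Bpath, n_lv = A)
}

# fast per-column standard deviations (denominator n - 1)
.col_sds <- function(X) {
  n <- nrow(X)
  cm <- colMeans(X)
  v <- (colSums(X * X) - n * cm^2) / (n - 1)
  sqrt(pmax(v, 0))
}

# numerical rank; via the n x n Gram matrix when p > n
.mat_rank <- function(X, tol = 1e-9) {
  if (ncol(X) > nrow(X)) {
    ev <- eigen(tcrossprod(X), symmetric = TRUE, only.values = TRUE)$values
    sum(ev > tol * max(ev, 0) & ev > 0)
  } else {
    qr(X)$rank
  }
}

#' Fit a PLS1 regression of sensitivity on fragment counts
#'
#' Columns constant across the training rows are dropped, the remaining
#' descriptor columns are autoscaled (centred, unit variance) and the response
#' is centred; NIPALS PLS1 then extracts `n_lv` latent variables. The model is
#' deterministic — no randomness is involved. Coefficients are returned both
#' in the autoscaled descriptor space (`b_weighted`, the "weighted regression
#' coefficients" used for the pruning threshold) and in the original count
#' space (`b_raw` plus `intercept`), which give identical predictions.
#'
#' @param X numeric matrix of descriptor counts (rows = molecules, named
#'   columns = fragments), e.g. from [descriptor_matrix()].
#' @param y numeric response vector (mV/decade), no missing values.
#' @param n_lv number of latent variables (>= 1, at most the rank of the
#'   centred/scaled matrix).
#' @return an object of class `smf_plsfit`: list with `kept_columns`,
#'   `dropped_columns`, `x_center`, `x_scale`, `y_center`, `b_weighted`,
#'   `b_raw`, `intercept`, `n_lv`, `scores`, `loadings`, `weights`,
#'   `y_loadings`, `fitted`.
#' @examples
#' X <- cbind(a = c(1, 2, 3, 4), b = c(0, 1, 0, 2))
#' fit <- fit_pls(X, c(2, 4.1, 5.9, 8), n_lv = 2)
#' fit$b_raw
#' @export
fit_pls <- function(X, y, n_lv = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("fit_pls: rows of X must match length of y")
  if (anyNA(X) || anyNA(y)) stop("fit_pls: missing values are not allowed")
  n <- nrow(X)
  if (n < 3L) stop("fit_pls: at least 3 training rows are required")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L) stop("fit_pls: n_lv must be >= 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  sds <- .col_sds(X)
  keep <- sds > 1e-12
  if (!any(keep)) stop("fit_pls: all descriptor columns are constant")
  Xk <- X[, keep, drop = FALSE]
  mu <- colMeans(Xk); sdk <- sds[keep]
  Xs <- scale(Xk, center = mu, scale = sdk)
  y_center <- mean(y)
  yc <- y - y_center

  r <- .mat_rank(Xs)
  if (n_lv > r) stop(sprintf(
    "fit_pls: n_lv = %d exceeds the rank (%d) of the centred/scaled matrix",
    n_lv, r))
  nip <- .nipals_pls1(Xs, yc, n_lv)
  b_w <- nip$Bpath[, n_lv]
  b_raw <- b_w / sdk
  intercept <- y_center - sum(b_raw * mu)
  fitted <- as.numeric(Xk %*% b_raw) + intercept

  structure(list(
    kept_columns = colnames(Xk),
    dropped_columns = colnames(X)[!keep],
    x_center = stats::setNames(as.numeric(mu), colnames(Xk)),
    x_scale = stats::setNames(as.numeric(sdk), colnames(Xk)),
    y_center = y_center,
    b_weighted = stats::setNames(as.numeric(b_w), colnames(Xk)),
    b_raw = stats::setNames(as.numeric(b_raw), colnames(Xk)),
    intercept = intercept,
    n_lv = n_lv,
    rank = r,
    weights = nip$W, loadings = nip$P, scores = nip$Tm, y_loadings = nip$q,
    fitted = fitted
  ), class = "smf_plsfit")
}

#' @export
print.smf_plsfit <- function(x, ...) {
  cat(sprintf("<smf_plsfit: %d latent variables, %d descriptors (%d constant dropped)>\n",
              x$n_lv, length(x$kept_columns), length(x$dropped_columns)))
  invisible(x)
}

#' @export
coef.smf_plsfit <- function(object, weighted = FALSE, ...) {
  if (weighted) object$b_weighted else c(`(Intercept)` = object$intercept, object$b_raw)
}

#' Predict sensitivities from a fitted PLS model
#'
#' Applies `yhat = X b_raw + intercept` row by row. `newdata` must contain
#' every column the model was fit on (`kept_columns`); extra columns are
#' ignored. Build conforming matrices with
#' `descriptor_matrix(graphs, vocabulary = fit$kept_columns)`.
#'
#' @param object an `smf_plsfit` from [fit_pls()].
#' @param newdata descriptor matrix with named columns.
#' @param ... unused.
#' @return numeric vector of predictions, named by row.
#' @export
predict.smf_plsfit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  missing <- setdiff(object$kept_columns, colnames(X))
  if (length(missing)) {
    stop("predict: descriptor matrix lacks model columns: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" ... (%d total)", length(missing)))
  }
  X <- X[, object$kept_columns, drop = FALSE]
  stats::setNames(as.numeric(X %*% object$b_raw) + object$intercept, rownames(X))
}

#' Leave-one-out cross-validation over the number of latent variables
#'
#' For each candidate latent-variable count `A` in `1..max_lv`, every sample
#' is predicted by a model trained on the remaining `n - 1` samples; column
#' dropping, centring and scaling are recomputed inside every fold so no
#' information leaks from the held-out row. In folds whose reduced matrix
#' supports fewer than `A` components, the largest attainable count is used.
#' The selected count minimises the cross-validated RMSE; ties go to the
#' smallest count (parsimony).
#'
#' @param X descriptor count matrix.
#' @param y numeric response.
#' @param max_lv largest latent-variable count to try (capped at `n - 2` and
#'   at the matrix rank).
#' @return list with `rmsecv` (per-A vector), `selected_lv`, `predictions`
#'   (n x A matrix of held-out predictions) and `n_folds`.
#' @export
loo_cv <- function(X, y, max_lv = 10L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("loo_cv: rows of X must match length of y")
  if (n < 4L) stop("loo_cv: at least 4 samples are required")
  max_lv <- min(as.integer(max_lv), n - 2L)
  if (max_lv < 1L) stop("loo_cv: max_lv must be >= 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  preds <- matrix(NA_real_, n, max_lv,
                  dimnames = list(rownames(X), paste0("A", seq_len(max_lv))))
  p <- ncol(X)
  S <- colSums(X); Q <- colSums(X * X); ytot <- sum(y)
  tol <- 1e-12
  # Each fold runs NIPALS on the implicitly centred/scaled matrix
  # D = (X[-i,] - mu) diag(1/sd): residual vectors carry a structural zero in
  # position i, so every product with D reduces to a product with the full X
  # (all centring terms vanish because scores and residuals sum to zero).
  for (i in seq_len(n)) {
    xi <- X[i, ]
    mu <- (S - xi) / (n - 1)
    v <- (Q - xi^2 - (n - 1) * mu^2) / (n - 2)
    sdv <- sqrt(pmax(v, 0))
    keep <- sdv > tol
    ybar <- (ytot - y[i]) / (n - 1)
    if (!any(keep)) { preds[i, ] <- ybar; next }
    invsd <- ifelse(keep, 1 / sdv, 0)
    A_i <- min(max_lv, n - 2L, sum(keep))
    W <- matrix(0, p, A_i); P <- matrix(0, p, A_i)
    Tm <- matrix(0, n, A_i); q <- numeric(A_i)
    f <- y - ybar; f[i] <- 0
    attained <- 0L
    for (a in seq_len(A_i)) {
      w <- invsd * as.numeric(crossprod(X, f))
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      t_a <- as.numeric(X %*% (invsd * w)) - sum(mu * invsd * w)
      t_a[i] <- 0
      if (a > 1L) {
        bb <- seq_len(a - 1L)
        t_a <- t_a - as.numeric(Tm[, bb, drop = FALSE] %*%
                                  crossprod(P[, bb, drop = FALSE], w))
      }
      tt <- sum(t_a^2)
      if (tt < tol) break
      p_a <- invsd * as.numeric(crossprod(X, t_a)) / tt
      q_a <- sum(f * t_a) / tt
      f <- f - t_a * q_a
      W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
      attained <- a
    }
    if (attained == 0L) { preds[i, ] <- ybar; next }
    xh <- (xi - mu) * invsd
    ph <- numeric(attained)
    for (a in seq_len(attained)) {
      aa <- seq_len(a)
      B_a <- W[, aa, drop = FALSE] %*%
        solve(crossprod(P[, aa, drop = FALSE], W[, aa, drop = FALSE]), q[aa])
      ph[a] <- sum(xh * B_a) + ybar
    }
    preds[i, ] <- ph[pmin(seq_len(max_lv), attained)]
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  list(rmsecv = rmsecv,
       selected_lv = unname(which.min(rmsecv)),  # ties resolve to the smallest A
       predictions = preds,
       n_folds = n)
}

#' Calibration / validation metrics for a sensitivity model
#'
#' Computes the three headline statistics reported for each metal model:
#' `rmse = sqrt(mean((y - yhat)^2))` in mV/decade, `r2` the squared Pearson
#' correlation between measured and predicted, and `slope` of the
#' least-squares line of predicted on measured (the measured-vs-predicted
#' plot convention). `r2_ss`, the 1 - SS_res/SS_tot variant, is included for
#' completeness.
#'
#' @param y measured values.
#' @param y_hat predicted values (same length, >= 2).
#' @param context `"calibration"` or `"loo_validation"` tag carried in the
#'   result.
#' @return object of class `model_metrics`: list with `slope`, `rmse`, `r2`,
#'   `r2_ss`, `n`, `context`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 3))
#' @export
regression_metrics <- function(y, y_hat,
                               context = c("calibration", "loo_validation")) {
  context <- match.arg(context)
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat) || length(y) < 2L) {
    stop("regression_metrics: y and y_hat must have equal length >= 2")
  }
  if (anyNA(y) || anyNA(y_hat)) stop("regression_metrics: missing values")
  if (stats::sd(y) == 0) {
    stop("regression_metrics: zero variance in y; r2 and slope are undefined")
  }
  res <- y - y_hat
  rmse <- sqrt(mean(res^2))
  r2 <- if (stats::sd(y_hat) == 0) 0 else stats::cor(y, y_hat)^2
  slope <- stats::cov(y, y_hat) / stats::var(y)
  structure(list(slope = slope, rmse = rmse, r2 = r2,
                 r2_ss = 1 - sum(res^2) / sum((y - mean(y))^2),
                 n = length(y), context = context),
            class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("%-15s n=%d  slope=%.3f  RMSE=%.3f mV/dec  R2=%.3f\n",
              x$context, x$n, x$slope, x$rmse, x$r2))
  invisible(x)
}
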