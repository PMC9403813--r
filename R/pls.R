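# Partial least squares regression (single response).
#
# NIPALS-style sequential extraction of latent components from the
# mean-centred predictor matrix and response; no variance scaling, since
# hologram bins all carry the same (count) scale.  Components are nested,
# so one fit at A components yields predictions at every k <= A.

#' Fit a PLS regression model
#'
#' @param x numeric predictor matrix (rows = samples).
#' @param y numeric response vector, `length(y) == nrow(x)`.
#' @param ncomp number of latent components requested.  If the centred
#'   predictor matrix runs out of rank (or of covariance with the residual
#'   response) earlier, the count is clamped with a warning.
#' @return an object of class `hq_pls`: centring offsets, per-component
#'   weights/loadings, and the cumulative regression coefficient matrix
#'   `coefs` (one column per component count 1..ncomp) with intercepts.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' y <- x %*% c(1, 2, 0, 0) + 5
#' fit <- pls_fit(x, y, 2)
#' @export
pls_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop_config("length(y) must equal nrow(x)")
  if (n < 3L) stop_config("need at least 3 training samples")
  ncomp <- as.integer(ncomp)
  if (is.na(ncomp) || ncomp < 1L) stop_config("'ncomp' must be >= 1")
  if (sd(y) == 0) stop_data("response is constant; nothing to fit")

  xbar <- colMeans(x)
  ybar <- mean(y)
  e <- sweep(x, 2, xbar)   # X residual
  f <- y - ybar            # y residual
  max_a <- min(ncomp, n - 1L, p)
  w_mat <- matrix(0, p, max_a)
  p_mat <- matrix(0, p, max_a)
  q_vec <- numeric(max_a)
  tol <- 1e-12 * max(1, sum(e^2))
  a <- 0L
  while (a < max_a) {
    w <- crossprod(e, f)                 # p x 1
    wn <- sqrt(sum(w^2))
    if (wn^2 <= tol * max(1, sum(f^2))) break
    w <- w / wn
    t_scr <- e %*% w
    tt <- sum(t_scr^2)
    if (tt <= tol) break
    p_load <- crossprod(e, t_scr) / tt
    q_load <- sum(f * t_scr) / tt
    e <- e - t_scr %*% t(p_load)
    f <- f - t_scr * q_load
    a <- a + 1L
    w_mat[, a] <- w
    p_mat[, a] <- p_load
    q_vec[a] <- q_load
  }
  if (a == 0L) stop_data("predictor matrix has no covariance with response")
  if (a < ncomp) {
    warning("ncomp clamped from ", ncomp, " to ", a,
            " (rank/covariance exhausted)", call. = FALSE)
  }
  w_mat <- w_mat[, seq_len(a), drop = FALSE]
  p_mat <- p_mat[, seq_len(a), drop = FALSE]
  q_vec <- q_vec[seq_len(a)]

  # R = W (P'W)^-1 built incrementally; B_k = R_(1:k) q_(1:k), cumulative
  r_mat <- matrix(0, p, a)
  coefs <- matrix(0, p, a)
  b <- numeric(p)
  for (k in seq_len(a)) {
    r <- w_mat[, k]
    if (k > 1L) {
      r <- r - r_mat[, seq_len(k - 1L), drop = FALSE] %*%
        crossprod(p_mat[, seq_len(k - 1L), drop = FALSE], w_mat[, k])
    }
    r_mat[, k] <- r
    b <- b + r * q_vec[k]
    coefs[, k] <- b
  }
  intercepts <- ybar - as.numeric(crossprod(coefs, xbar))
  structure(list(ncomp = a, xbar = xbar, ybar = ybar, weights = w_mat,
                 loadings = p_mat, yloadings = q_vec, coefs = coefs,
                 intercepts = intercepts, fitted = pls_apply(
                   list(coefs = coefs, intercepts = intercepts), x, a)),
            class = "hq_pls")
}

# prediction core shared by the model object and serialized models
pls_apply <- function(state, x, ncomp) {
  as.numeric(x %*% state$coefs[, ncomp] + state$intercepts[ncomp])
}

#' Predict from a PLS model
#'
#' @param object an `hq_pls` fit.
#' @param x new predictor matrix with the training column count.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.hq_pls <- function(object, x, ncomp = object$ncomp, ...) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(object$coefs)) {
    stop_config("new data has ", ncol(x), " columns; model expects ",
                nrow(object$coefs))
  }
  ncomp <- min(as.integer(ncomp), object$ncomp)
  if (ncomp < 1L) stop_config("'ncomp' must be >= 1")
  pls_apply(object, x, ncomp)
}

#' @export
print.hq_pls <- function(x, ...) {
  cat("<hq_pls> ", x$ncomp, " components, ", nrow(x$coefs),
      " predictors\n", sep = "")
  invisible(x)
}

# Leave-one-out predictions for component counts 1..max_ncomp: one refit per
# held-out row, reusing the nesting of PLS components.  Returns an
# n x max_ncomp matrix; folds whose fit supports fewer components carry the
# deepest available prediction in the remaining columns.
loo_predictions <- function(x, y, max_ncomp) {
  x <- as.matrix(x)
  n <- nrow(x)
  out <- matrix(NA_real_, n, max_ncomp)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(pls_fit(x[-i, , drop = FALSE], y[-i], max_ncomp))
    for (k in seq_len(max_ncomp)) {
      out[i, k] <- pls_apply(fit, x[i, , drop = FALSE], min(k, fit$ncomp))
    }
  }
  out
}

#' Leave-one-out cross-validated q2
#'
#' For each sample, the model is refit on the remaining samples with the
#' same component count and the held-out sample predicted; the statistic is
#' `1 - PRESS / TSS` with `TSS` taken about the full-set response mean.
#'
#' @inheritParams pls_fit
#' @param ncomp number of components used in every fold.
#' @return a single number (at most 1; negative when prediction is worse
#'   than the mean).
#' @export
loo_q2 <- function(x, y, ncomp) {
  y <- as.numeric(y)
  pred <- loo_predictions(x, y, as.integer(ncomp))[, as.integer(ncomp)]
  q2(y, pred, mean(y))
}

#' Select the PLS component count by leave-one-out q2
#'
#' Scans component counts `1..max_ncomp` (capped at `n - 2` and at the
#' predictor rank), picks the count maximizing the leave-one-out q2 (ties
#' resolved toward fewer components), and refits on the full data.
#'
#' @inheritParams pls_fit
#' @param max_ncomp largest component count scanned (default 8).
#' @return a list with elements `pcs` (selected count), `fit` (the full-data
#'   `hq_pls`), and `report`: `r2`, `see` (standard error of estimate,
#'   denominator `n - pcs - 1`), `q2cv`, `pcs`, and the per-count q2 curve.
#' @export
select_components <- function(x, y, max_ncomp = 8L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  max_ncomp <- as.integer(max_ncomp)
  if (max_ncomp < 1L) stop_config("'max_ncomp' must be >= 1")
  max_ncomp <- max(1L, min(max_ncomp, n - 2L))
  full <- suppressWarnings(pls_fit(x, y, max_ncomp))
  max_ncomp <- min(max_ncomp, full$ncomp)
  loo <- loo_predictions(x, y, max_ncomp)
  q2s <- vapply(seq_len(max_ncomp),
                function(k) q2(y, loo[, k], mean(y)), numeric(1))
  pcs <- which.max(q2s)  # first maximum = fewest components on ties
  fit <- if (full$ncomp == pcs) full else
    suppressWarnings(pls_fit(x, y, pcs))
  res <- y - fit$fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  list(pcs = pcs, fit = fit,
       report = list(r2 = 1 - ss_res / ss_tot,
                     see = sqrt(ss_res / max(1L, n - pcs - 1L)),
                     q2cv = q2s[pcs], pcs = pcs, q2_curve = q2s))
}
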