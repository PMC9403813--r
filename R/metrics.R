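# Validation statistics.
#
# The suite comprises the cross-validated / external predictive squared
# correlations q2 (referenced to the training-set mean), Lin's concordance
# correlation coefficient CCC, the external predictive statistics QF2
# (referenced to the external set's own mean) and QF3 (external mean squared
# error normalized by training variance, both per-sample), and RMSE / MAPE.
# Conventional adequacy thresholds are CCC > 0.85, QF2 and QF3 > 0.60,
# q2 > 0.50; they are reported as flags, never enforced.

#' Predictive squared correlation q2
#'
#' `1 - sum((yhat - y)^2) / sum((y - y_ref_mean)^2)`.  With leave-one-out
#' predictions of the training set and the training mean this is the
#' cross-validated q2; with external predictions and the training mean it
#' is the external q2.
#'
#' @param y experimental values.
#' @param yhat predictions, same length.
#' @param y_ref_mean reference mean, normally the training-set mean of the
#'   experimental values.
#' @return a single number (at most 1).
#' @examples
#' q2(c(1, 2, 3), c(1, 2, 4), 2)
#' @export
q2 <- function(y, yhat, y_ref_mean) {
  .check_pair(y, yhat)
  den <- sum((y - y_ref_mean)^2)
  if (den == 0) stop_data("zero denominator: y has no spread about the reference mean")
  1 - sum((yhat - y)^2) / den
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of predictions with observations about the identity line:
#' `2 * S_xy / (S_xx + S_yy + n * (mean(y) - mean(yhat))^2)` with the
#' cross/within sums of squares taken about the respective means.
#'
#' @inheritParams q2
#' @return a number in `[-1, 1]`.
#' @export
ccc <- function(y, yhat) {
  .check_pair(y, yhat)
  n <- length(y)
  if (n < 2L) stop_config("need at least 2 observations")
  dy <- y - mean(y)
  dp <- yhat - mean(yhat)
  den <- sum(dy^2) + sum(dp^2) + n * (mean(y) - mean(yhat))^2
  if (den == 0) stop_data("zero denominator in concordance correlation")
  2 * sum(dy * dp) / den
}

#' Predictive squared correlation QF2
#'
#' `1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`: like the external q2 but
#' referenced to the evaluated set's own mean.
#'
#' @inheritParams q2
#' @return a single number (at most 1).
#' @export
qf2 <- function(y, yhat) {
  .check_pair(y, yhat)
  q2(y, yhat, mean(y))
}

#' Predictive squared correlation QF3
#'
#' `1 - (PRESS / n_ext) / (TSS / n_tr)` where `PRESS` is the squared
#' prediction error summed over the external set and `TSS` the squared
#' deviation of the training responses about the training mean.
#'
#' @param y_ext,yhat_ext external experimental values and predictions.
#' @param y_train training-set experimental values.
#' @return a single number (at most 1).
#' @export
qf3 <- function(y_ext, yhat_ext, y_train) {
  .check_pair(y_ext, yhat_ext)
  if (!length(y_train)) stop_config("'y_train' must be non-empty")
  tss <- sum((y_train - mean(y_train))^2)
  if (tss == 0) stop_data("zero training sum of squares")
  press <- sum((yhat_ext - y_ext)^2)
  1 - (press / length(y_ext)) / (tss / length(y_train))
}

#' Root mean square error
#' @inheritParams q2
#' @return a non-negative number.
#' @export
rmse <- function(y, yhat) {
  .check_pair(y, yhat)
  sqrt(mean((yhat - y)^2))
}

#' Mean absolute percentage error
#' @inheritParams q2
#' @return a non-negative number, in percent.
#' @export
mape <- function(y, yhat) {
  .check_pair(y, yhat)
  if (any(y == 0)) stop_data("MAPE undefined: experimental value of 0")
  100 * mean(abs(yhat - y) / abs(y))
}

.check_pair <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop_config("'y' and 'yhat' differ in length")
  }
  if (!length(y)) stop_config("empty input")
  if (anyNA(y) || anyNA(yhat)) stop_data("missing values in input")
  invisible(TRUE)
}

#' Full evaluation report for one phase and one model column
#'
#' Computes the seven validation statistics from a prediction table:
#' the cross-validated q2 over group I (whose predictions are expected to be
#' leave-one-out), the external q2 / CCC / QF2 / QF3 over group II (training
#' statistics from group I), and RMSE / MAPE pooled over all compounds.
#'
#' @param dataset an `hq_dataset`.
#' @param phase phase identifier, e.g. `"DB-210"`.
#' @param model `"individual"` or `"ensemble"`.
#' @param predictions data frame with columns `name`, `phase`, `model`,
#'   `predicted`; defaults to the predictions attached to the dataset.
#' @return an object of class `hq_report`: a list with `stats` (named
#'   vector: `rmse`, `mape`, `ccc`, `q2_ext`, `qf2`, `qf3`, `q2_cv`),
#'   `passes` (threshold flags), `phase`, `model`, `n_train`, `n_ext`.
#' @examples
#' evaluate_predictions(load_bundled_dataset(), "DB-210", "ensemble")
#' @export
evaluate_predictions <- function(dataset, phase, model,
                                 predictions = dataset$predictions) {
  if (is.null(predictions)) stop_config("no predictions supplied")
  sel <- predictions$phase == phase & predictions$model == model
  pred <- predictions[sel, ]
  y_all <- .phase_values(dataset, phase)
  missing <- setdiff(names(y_all), pred$name)
  if (length(missing)) {
    stop_data("predictions missing for: ", paste(missing, collapse = ", "))
  }
  yhat <- setNames(pred$predicted, pred$name)[names(y_all)]
  gi <- dataset$compounds$group == "I"
  gii <- dataset$compounds$group == "II"
  y_tr <- y_all[gi]
  stats <- c(
    rmse = rmse(y_all, yhat),
    mape = mape(y_all, yhat),
    ccc = if (sum(gii) >= 2) ccc(y_all[gii], yhat[gii]) else NA_real_,
    q2_ext = if (any(gii)) q2(y_all[gii], yhat[gii], mean(y_tr)) else NA_real_,
    qf2 = if (sum(gii) >= 2) qf2(y_all[gii], yhat[gii]) else NA_real_,
    qf3 = if (any(gii)) qf3(y_all[gii], yhat[gii], y_tr) else NA_real_,
    q2_cv = if (any(gi)) q2(y_tr, yhat[gi], mean(y_tr)) else NA_real_)
  passes <- c(ccc = unname(stats["ccc"] > 0.85),
              qf2 = unname(stats["qf2"] > 0.60),
              qf3 = unname(stats["qf3"] > 0.60),
              q2_ext = unname(stats["q2_ext"] > 0.50),
              q2_cv = unname(stats["q2_cv"] > 0.50))
  structure(list(stats = stats, passes = passes, phase = phase,
                 model = model, n_train = sum(gi), n_ext = sum(gii)),
            class = "hq_report")
}

#' @export
print.hq_report <- function(x, digits = 3, ...) {
  cat("<hq_report> phase ", x$phase, ", ", x$model, " model (n_train = ",
      x$n_train, ", n_ext = ", x$n_ext, ")\n", sep = "")
  s <- x$stats
  lab <- c(rmse = "RMSE", mape = "MAPE/%", ccc = "CCC", q2_ext = "q2_ext",
           qf2 = "QF2", qf3 = "QF3", q2_cv = "q2_cv")
  for (k in names(lab)) {
    flag <- if (k %in% names(x$passes) && !is.na(x$passes[k])) {
      if (x$passes[k]) "  [ok]" else "  [below threshold]"
    } else ""
    cat(sprintf("  %-7s %8.3f%s\n", lab[k], s[k], flag))
  }
  invisible(x)
}

#' One-row data frame form of an evaluation report
#' @param x an `hq_report`.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @export
as.data.frame.hq_report <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  cbind(data.frame(phase = x$phase, model = x$model),
        as.data.frame(as.list(x$stats)))
}
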