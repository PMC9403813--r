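# Individual HQSAR models: a model specification fitted on the group-I
# training rows of a dataset, predicting through fragments -> hologram ->
# PLS.

#' Fit an individual model on the training group
#'
#' Fits the PLS regression of the chosen phase's property on the hologram
#' matrix of the group-I compounds, under the hyperparameters of `spec`.
#' When `spec$pcs` is `NULL`, the component count is selected by
#' leave-one-out q2 first and frozen into the returned model.
#'
#' @param dataset an `hq_dataset`.
#' @param phase phase identifier.
#' @param spec an [model_spec()].
#' @return an object of class `hq_model`.
#' @export
fit_model <- function(dataset, phase, spec) {
  stopifnot(inherits(spec, "hq_spec"))
  gi <- dataset$compounds$group == "I"
  if (sum(gi) < 3L) stop_data("need at least 3 group-I training compounds")
  y_tr <- .phase_values(dataset, phase)[gi]
  smiles <- setNames(dataset$compounds$smiles, dataset$compounds$name)[gi]
  x_tr <- build_matrix(smiles, spec$params, spec$hl)
  .fit_model_x(x_tr, y_tr, phase, spec)
}

# fit from a precomputed training hologram matrix (reused by the search and
# ensemble leave-one-out loops)
.fit_model_x <- function(x_tr, y_tr, phase, spec) {
  report <- NULL
  if (is.null(spec$pcs)) {
    sel <- select_components(x_tr, y_tr)
    spec$pcs <- sel$pcs
    fit <- sel$fit
    report <- sel$report
  } else {
    fit <- suppressWarnings(pls_fit(x_tr, y_tr, spec$pcs))
    spec$pcs <- fit$ncomp
  }
  structure(list(spec = spec, phase = phase, pls = fit,
                 train_names = rownames(x_tr), report = report),
            class = "hq_model")
}

#' @export
print.hq_model <- function(x, ...) {
  cat("<hq_model> phase ", x$phase, ", ", format(x$spec), ", trained on ",
      length(x$train_names), " compounds\n", sep = "")
  invisible(x)
}

#' Predict retention indices with an individual model
#'
#' @param object an `hq_model`.
#' @param newdata an `hq_dataset` or a character vector of SMILES.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.hq_model <- function(object, newdata, ...) {
  x <- build_matrix(newdata, object$spec$params, object$spec$hl)
  setNames(predict(object$pls, x, object$spec$pcs), rownames(x))
}

#' Validate an individual model by leave-one-out and external prediction
#'
#' Reproduces the reference validation protocol for one specification:
#' every group-I compound is predicted by a model refit on the remaining
#' group-I compounds (component count held at the specification's value),
#' and every group-II compound by the model fit on all of group I.  The
#' hologram matrix is computed once and reused across folds (descriptor
#' generation involves no fitting, so no information leaks).
#'
#' @inheritParams fit_model
#' @return a list with `predictions` (data frame: `name`, `phase`, `model`,
#'   `predicted`), `report` (an `hq_report`), and `model` (the full-data
#'   fit).
#' @export
validate_model <- function(dataset, phase, spec) {
  out <- .validate_specs(dataset, phase, list(spec), model_label = "individual")
  out
}

# Shared validation engine: leave-one-out + external prediction for a list
# of specifications; the per-compound submodel predictions are averaged
# when more than one specification is given.
.validate_specs <- function(dataset, phase, specs, model_label) {
  gi <- which(dataset$compounds$group == "I")
  gii <- which(dataset$compounds$group == "II")
  if (length(gi) < 4L) stop_data("need at least 4 group-I training compounds")
  y <- .phase_values(dataset, phase)
  smiles <- setNames(dataset$compounds$smiles, dataset$compounds$name)
  mols <- parse_smiles_all(smiles)
  n <- length(smiles)

  pred_mat <- matrix(NA_real_, n, length(specs))
  models <- vector("list", length(specs))
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    frags <- lapply(mols, enumerate_fragments, params = spec$params)
    x_all <- fold_rows(frags, spec$hl)
    x_tr <- x_all[gi, , drop = FALSE]
    y_tr <- y[gi]
    full <- tryCatch(
      .fit_model_x(x_tr, y_tr, phase, spec),
      error = function(e) stop_data("submodel fit failed for ", format(spec),
                                    ": ", conditionMessage(e)))
    models[[si]] <- full
    pcs <- full$spec$pcs
    if (length(gii)) {
      pred_mat[gii, si] <- predict(full$pls, x_all[gii, , drop = FALSE], pcs)
    }
    for (k in seq_along(gi)) {
      fit_k <- suppressWarnings(pls_fit(x_tr[-k, , drop = FALSE], y_tr[-k],
                                        pcs))
      pred_mat[gi[k], si] <- pls_apply(fit_k, x_tr[k, , drop = FALSE],
                                       min(pcs, fit_k$ncomp))
    }
  }
  predicted <- rowMeans(pred_mat)
  predictions <- data.frame(name = names(smiles), phase = phase,
                            model = model_label, predicted = predicted)
  report <- evaluate_predictions(dataset, phase, model_label,
                                 predictions = predictions)
  list(predictions = predictions, report = report,
       model = if (length(specs) == 1L) models[[1]] else models,
       submodel_predictions = pred_mat)
}
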