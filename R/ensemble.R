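# Consensus (ensemble) models.
#
# An ensemble model averages the predictions of T individual submodels with
# equal weights: H(x) = (1/T) * sum_i h_i(x).  Submodels are the top-ranked
# individual models of the fragment-size scan (T = 4 by default), all
# trained on the same group-I set of the same phase.  Averaging lets the
# error of one submodel be compensated by the others, so the ensemble's
# pooled squared error never exceeds the mean pooled squared error of its
# submodels.

#' Build a consensus model from submodel specifications
#'
#' @param dataset an `hq_dataset`.
#' @param phase phase identifier.
#' @param specs list of at least two [model_spec()] objects (e.g.
#'   [top_specs()] of a fragment-size scan).
#' @return an object of class `hq_ensemble`.
#' @export
build_ensemble <- function(dataset, phase, specs) {
  if (!is.list(specs) || length(specs) < 2L) {
    stop_config("an ensemble needs at least 2 submodel specifications")
  }
  submodels <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    submodels[[i]] <- tryCatch(
      fit_model(dataset, phase, specs[[i]]),
      error = function(e) stop_data("submodel fit failed for ",
                                    format(specs[[i]]), ": ",
                                    conditionMessage(e)))
  }
  structure(list(submodels = submodels, phase = phase,
                 t_size = length(specs)),
            class = "hq_ensemble")
}

#' @export
print.hq_ensemble <- function(x, ...) {
  cat("<hq_ensemble> phase ", x$phase, ", T = ", x$t_size,
      " submodels:\n", sep = "")
  for (m in x$submodels) cat("  ", format(m$spec), "\n", sep = "")
  invisible(x)
}

#' Predict retention indices with a consensus model
#'
#' @param object an `hq_ensemble`.
#' @param newdata an `hq_dataset` or a character vector of SMILES.
#' @param ... unused.
#' @return named numeric vector of ensemble predictions (the per-submodel
#'   predictions are attached as attribute `"submodels"`).
#' @export
predict.hq_ensemble <- function(object, newdata, ...) {
  per <- vapply(object$submodels, function(m) predict(m, newdata),
                numeric(if (inherits(newdata, "hq_dataset"))
                  nrow(newdata$compounds) else length(newdata)))
  per <- matrix(per, ncol = object$t_size)
  out <- rowMeans(per)
  names(out) <- if (inherits(newdata, "hq_dataset"))
    newdata$compounds$name else names(newdata)
  attr(out, "submodels") <- per
  out
}

#' Validate a consensus model by leave-one-out and external prediction
#'
#' For every held-out group-I compound each submodel is refit on the
#' remaining group-I compounds (component counts held at the
#' specifications' values) and the held-out prediction is the mean of the
#' submodel predictions; group-II compounds are predicted by the submodels
#' fit on all of group I and averaged.
#'
#' @inheritParams build_ensemble
#' @return a list with `predictions`, `report` (an `hq_report`), `model`
#'   (list of full-data submodel fits) and `submodel_predictions`
#'   (compounds x T matrix).
#' @export
validate_ensemble <- function(dataset, phase, specs) {
  if (!is.list(specs) || length(specs) < 2L) {
    stop_config("an ensemble needs at least 2 submodel specifications")
  }
  .validate_specs(dataset, phase, specs, model_label = "ensemble")
}
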