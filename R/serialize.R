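# Model serialization.
#
# Models are written as versioned JSON text files carrying the
# hyperparameters and the state sufficient for prediction (centring
# offsets, cumulative coefficient columns, intercepts).  Ensembles store
# their submodels inline.

.SERIAL_VERSION <- 1L

#' Write a fitted model to a JSON text file
#'
#' @param model an `hq_model` or `hq_ensemble`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- .serialize_model(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.serialize_model <- function(model) {
  if (inherits(model, "hq_ensemble")) {
    return(list(format = "hqsar-model", version = .SERIAL_VERSION,
                type = "ensemble",
                submodels = lapply(model$submodels, .serialize_model)))
  }
  stopifnot(inherits(model, "hq_model"))
  spec <- model$spec
  fit <- model$pls
  list(format = "hqsar-model", version = .SERIAL_VERSION,
       type = "individual", phase = model$phase,
       spec = list(flags = spec$params$flags,
                   fs = c(spec$params$min_size, spec$params$max_size),
                   hl = spec$hl, pcs = spec$pcs),
       pls = list(ncomp = fit$ncomp, xbar = fit$xbar, ybar = fit$ybar,
                  coefs = fit$coefs, intercepts = fit$intercepts),
       train_names = model$train_names)
}

#' Read a model written by [write_model()]
#'
#' @param path path to a model JSON file.
#' @return an `hq_model` or `hq_ensemble`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_config("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  .deserialize_model(obj)
}

.deserialize_model <- function(obj) {
  if (!identical(obj$format, "hqsar-model")) {
    stop_data("not an hqsar model file")
  }
  if (obj$version > .SERIAL_VERSION) {
    stop_data("model file version ", obj$version, " is newer than supported")
  }
  if (identical(obj$type, "ensemble")) {
    submodels <- lapply(obj$submodels, .deserialize_model)
    return(structure(list(submodels = submodels,
                          phase = submodels[[1]]$phase,
                          t_size = length(submodels)),
                     class = "hq_ensemble"))
  }
  spec <- model_spec(unlist(obj$spec$flags), obj$spec$fs[[1]],
                     obj$spec$fs[[2]], obj$spec$hl, obj$spec$pcs)
  ncomp <- as.integer(obj$pls$ncomp)
  # coefs was written column-wise as a list of rows by write_json; rebuild
  coefs <- do.call(rbind, lapply(obj$pls$coefs, unlist))
  coefs <- matrix(as.numeric(coefs), ncol = ncomp)
  fit <- structure(list(ncomp = as.integer(obj$pls$ncomp),
                        xbar = as.numeric(obj$pls$xbar),
                        ybar = as.numeric(obj$pls$ybar),
                        coefs = coefs,
                        intercepts = as.numeric(obj$pls$intercepts)),
                   class = "hq_pls")
  structure(list(spec = spec, phase = obj$phase, pls = fit,
                 train_names = as.character(obj$train_names),
                 report = NULL),
            class = "hq_model")
}
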