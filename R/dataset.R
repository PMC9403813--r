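# Compound-property datasets.
#
# A dataset couples an ordered compound table (name, SMILES, group label)
# with a matrix of measured property values, one column per stationary
# phase, and optionally a table of model predictions.  Group "I" is the
# training set (validated by leave-one-out), group "II" the external test
# set.

#' Construct a compound-property dataset
#'
#' @param compounds data frame with columns `name`, `smiles`, `group`
#'   (each `"I"` or `"II"`).
#' @param ri numeric matrix of property values, one row per compound, one
#'   named column per stationary phase.
#' @param predictions optional data frame with columns `name`, `phase`,
#'   `model` (`"individual"` or `"ensemble"`) and `predicted`.
#' @param check_smiles parse every SMILES and fail, naming the offending
#'   rows, if any is invalid or disconnected (default `TRUE`).
#' @return an object of class `hq_dataset`.
#' @export
hq_dataset <- function(compounds, ri, predictions = NULL,
                       check_smiles = TRUE) {
  need <- c("name", "smiles", "group")
  miss <- setdiff(need, names(compounds))
  if (length(miss)) {
    stop_config("compound table lacks column(s): ", paste(miss, collapse = ", "))
  }
  compounds <- as.data.frame(compounds)[need]
  if (anyDuplicated(compounds$name)) {
    stop_data("duplicate compound names: ",
              paste(unique(compounds$name[duplicated(compounds$name)]),
                    collapse = ", "))
  }
  if (!all(compounds$group %in% c("I", "II"))) {
    stop_data("group labels must be \"I\" or \"II\"")
  }
  ri <- as.matrix(ri)
  if (nrow(ri) != nrow(compounds) || is.null(colnames(ri))) {
    stop_config("'ri' must have one row per compound and named phase columns")
  }
  rownames(ri) <- compounds$name
  if (!is.null(predictions)) {
    predictions <- as.data.frame(predictions)
    pneed <- c("name", "phase", "model", "predicted")
    pmiss <- setdiff(pneed, names(predictions))
    if (length(pmiss)) {
      stop_config("prediction table lacks column(s): ",
                  paste(pmiss, collapse = ", "))
    }
    unknown <- setdiff(predictions$name, compounds$name)
    if (length(unknown)) {
      stop_data("predictions refer to unknown compound(s): ",
                paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(predictions[c("name", "phase", "model")])) {
      stop_data("duplicate (name, phase, model) prediction records")
    }
  }
  if (check_smiles) {
    invisible(parse_smiles_all(setNames(compounds$smiles, compounds$name)))
  }
  structure(list(compounds = compounds, ri = ri, predictions = predictions),
            class = "hq_dataset")
}

#' @export
print.hq_dataset <- function(x, ...) {
  cat("<hq_dataset> ", nrow(x$compounds), " compounds (",
      sum(x$compounds$group == "I"), " training / ",
      sum(x$compounds$group == "II"), " external), phases: ",
      paste(colnames(x$ri), collapse = ", "), sep = "")
  if (!is.null(x$predictions)) {
    cat(", ", nrow(x$predictions), " prediction records", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Phases of a dataset
#' @param dataset an `hq_dataset`.
#' @return character vector of phase identifiers.
#' @export
phases <- function(dataset) colnames(dataset$ri)

#' The bundled 34-compound aldehyde/ketone retention-index dataset
#'
#' Thirty-four aldehydes and ketones with experimental gas-chromatography
#' retention indices (Kovats-style, dimensionless) on the stationary phases
#' DB-210 and HP-Innowax, split into 26 training compounds (group I) and 8
#' external-test compounds (group II).  The attached prediction table holds
#' the reported individual-model and ensemble-model predictions for both
#' phases: leave-one-out predictions for group I, external predictions for
#' group II.  SMILES were assigned from the compound names; 2-butenal is
#' encoded without an E/Z descriptor since none is reported.
#'
#' @return an `hq_dataset` with 34 compounds and 136 prediction records.
#' @examples
#' ds <- load_bundled_dataset()
#' ds$ri["acetone", "DB-210"]
#' @export
load_bundled_dataset <- function() {
  comp <- read.csv(system.file("extdata", "aldehyde_ketone_ri.csv",
                               package = "hqsar"), check.names = FALSE)
  pred <- read.csv(system.file("extdata", "aldehyde_ketone_predictions.csv",
                               package = "hqsar"), check.names = FALSE)
  ri <- as.matrix(comp[c("ri_db210", "ri_innowax")])
  colnames(ri) <- c("DB-210", "HP-Innowax")
  hq_dataset(comp[c("name", "smiles", "group")], ri, pred,
             check_smiles = FALSE)
}

#' Read a dataset from a CSV file
#'
#' @param path path to a comma-separated file with a header row.
#' @param schema named list mapping roles to column names: `name`, `smiles`,
#'   `group`, and `properties`, a named character vector mapping phase
#'   identifiers to numeric property columns.  The default matches the
#'   bundled dataset layout.
#' @return an `hq_dataset`.
#' @export
read_dataset <- function(path,
                         schema = list(name = "name", smiles = "smiles",
                                       group = "group",
                                       properties = c("DB-210" = "ri_db210",
                                                      "HP-Innowax" = "ri_innowax"))) {
  if (!file.exists(path)) stop_config("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  cols <- c(schema$name, schema$smiles, schema$group,
            unname(schema$properties))
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_config("dataset file lacks column(s): ", paste(miss, collapse = ", "))
  }
  comp <- data.frame(name = df[[schema$name]],
                     smiles = df[[schema$smiles]],
                     group = df[[schema$group]])
  if (nrow(comp) == 0L) {
    ri <- matrix(numeric(0), nrow = 0, ncol = length(schema$properties),
                 dimnames = list(NULL, names(schema$properties)))
    return(structure(list(compounds = comp, ri = ri, predictions = NULL),
                     class = "hq_dataset"))
  }
  ri <- as.matrix(df[unname(schema$properties)])
  colnames(ri) <- names(schema$properties)
  hq_dataset(comp, ri)
}

#' Write a dataset to a CSV file
#'
#' Inverse of [read_dataset()] under the default schema; property values are
#' written at full precision so a write/read round trip is exact.
#'
#' @param dataset an `hq_dataset`.
#' @param path output path.
#' @param schema as in [read_dataset()].
#' @return the path, invisibly.
#' @export
write_dataset <- function(dataset, path,
                          schema = list(name = "name", smiles = "smiles",
                                        group = "group",
                                        properties = setNames(
                                          paste0("prop_", seq_len(ncol(dataset$ri))),
                                          colnames(dataset$ri)))) {
  df <- dataset$compounds
  names(df) <- c(schema$name, schema$smiles, schema$group)
  for (ph in names(schema$properties)) {
    df[[schema$properties[[ph]]]] <- dataset$ri[, ph]
  }
  write.csv(df, path, row.names = FALSE, quote = 1)
  invisible(path)
}

#' Write predictions with relative errors
#'
#' Writes a CSV with columns `name`, `phase`, `model`, `experimental`,
#' `predicted` and `relative_error` (in percent,
#' `100 * (predicted - experimental) / experimental`).
#'
#' @param dataset an `hq_dataset` supplying the experimental values.
#' @param predictions data frame with columns `name`, `phase`, `model`,
#'   `predicted`; defaults to the predictions attached to the dataset.
#' @param path output path.
#' @return the written data frame, invisibly.
#' @export
write_predictions <- function(dataset, predictions = dataset$predictions,
                              path) {
  if (is.null(predictions)) stop_config("no predictions to write")
  unknown <- setdiff(predictions$name, dataset$compounds$name)
  if (length(unknown)) {
    stop_data("predictions refer to unknown compound(s): ",
              paste(unknown, collapse = ", "))
  }
  exp_val <- dataset$ri[cbind(match(predictions$name, rownames(dataset$ri)),
                              match(predictions$phase, colnames(dataset$ri)))]
  out <- data.frame(name = predictions$name, phase = predictions$phase,
                    model = predictions$model, experimental = exp_val,
                    predicted = predictions$predicted,
                    relative_error = 100 * (predictions$predicted - exp_val) /
                      exp_val)
  write.csv(out, path, row.names = FALSE, quote = 1)
  invisible(out)
}

# experimental values of one phase, as a named vector
.phase_values <- function(dataset, phase) {
  if (!phase %in% colnames(dataset$ri)) {
    stop_config("unknown phase \"", phase, "\"; available: ",
                paste(colnames(dataset$ri), collapse = ", "))
  }
  setNames(dataset$ri[, phase], rownames(dataset$ri))
}
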