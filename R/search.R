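# Hyperparameter search.
#
# The protocol is two-stage: first scan fragment-distinction flag sets at
# the default fragment-size window 4-7, each candidate taking its best
# hologram length and component count by leave-one-out q2; then, at the
# winning flag set, scan fragment-size windows the same way.  The top
# entries of the second stage supply the ensemble submodels.

#' Model specification
#'
#' Hyperparameters of one individual model: fragment-distinction flags,
#' fragment-size window, hologram length and (optionally, once selected)
#' the PLS component count.
#'
#' @param flags fragment-distinction flags (see [fragment_params()]).
#' @param fs_min,fs_max fragment-size window.
#' @param hl hologram length.
#' @param pcs PLS component count, or `NULL` to select by leave-one-out q2
#'   at fit time.
#' @return an object of class `hq_spec`.
#' @examples
#' model_spec("DA", 1, 9, hl = 151, pcs = 5)
#' @export
model_spec <- function(flags, fs_min, fs_max, hl, pcs = NULL) {
  params <- fragment_params(flags, fs_min, fs_max)
  hl <- as.integer(hl)
  if (is.na(hl) || hl <= 0L) stop_config("'hl' must be a positive integer")
  if (!is.null(pcs)) {
    pcs <- as.integer(pcs)
    if (is.na(pcs) || pcs < 1L) stop_config("'pcs' must be >= 1")
  }
  structure(list(params = params, hl = hl, pcs = pcs), class = "hq_spec")
}

#' @export
print.hq_spec <- function(x, ...) {
  cat("<hq_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.hq_spec <- function(x, ...) {
  paste0("FD=", paste(x$params$flags, collapse = "+"),
         " FS=", x$params$min_size, "-", x$params$max_size,
         " HL=", x$hl,
         if (!is.null(x$pcs)) paste0(" PCs=", x$pcs) else "")
}

#' Default fragment-distinction candidates
#'
#' The six flag combinations scanned in the first search stage.
#' @return a list of character vectors.
#' @export
default_fd_candidates <- function() {
  list("B", "DA", c("A", "DA"), c("B", "DA"), c("A", "C", "DA"),
       c("A", "B", "H", "DA"))
}

#' Default fragment-size candidates
#'
#' The fragment-size windows scanned in the second search stage.
#' @return a list of integer pairs `c(min, max)`.
#' @export
default_fs_candidates <- function() {
  list(c(1L, 9L), c(3L, 10L), c(4L, 7L), c(2L, 5L), c(3L, 6L))
}

# shared scan core: one row per candidate, each candidate optimized over
# hl_set and component count on the group-I training rows
.scan <- function(dataset, phase, candidates, cand_kind, hl_set, max_pcs) {
  gi <- dataset$compounds$group == "I"
  if (!any(gi)) stop_data("dataset has no group-I training compounds")
  y_tr <- .phase_values(dataset, phase)[gi]
  smiles <- setNames(dataset$compounds$smiles, dataset$compounds$name)[gi]
  mols <- parse_smiles_all(smiles)
  hl_set <- as.integer(hl_set)

  rows <- list()
  specs <- list()
  for (ci in seq_along(candidates)) {
    params <- candidates[[ci]]
    frags <- lapply(mols, enumerate_fragments, params = params)
    best <- NULL
    for (hl in hl_set) {
      x <- fold_rows(frags, hl)
      sel <- select_components(x, y_tr, max_pcs)
      cand <- list(hl = hl, pcs = sel$pcs, report = sel$report)
      if (is.null(best) ||
          cand$report$q2cv > best$report$q2cv + 1e-12 ||
          (abs(cand$report$q2cv - best$report$q2cv) <= 1e-12 &&
           (cand$pcs < best$pcs ||
            (cand$pcs == best$pcs && cand$hl < best$hl)))) {
        best <- cand
      }
    }
    spec <- model_spec(params$flags, params$min_size, params$max_size,
                       best$hl, best$pcs)
    specs[[ci]] <- spec
    rows[[ci]] <- data.frame(
      fd = paste(params$flags, collapse = "+"),
      fs_min = params$min_size, fs_max = params$max_size,
      hl = best$hl, pcs = best$pcs,
      q2cv = best$report$q2cv, r2 = best$report$r2, see = best$report$see)
  }
  res <- do.call(rbind, rows)
  res$spec <- specs
  rank_models(structure(res, class = c("hq_search", "data.frame"),
                        phase = phase, stage = cand_kind))
}

#' Scan fragment-distinction candidates (search stage 1)
#'
#' For every flag-set candidate, builds models at the fixed fragment-size
#' window over all hologram lengths, selects components by leave-one-out
#' q2 on the group-I training set, retains the candidate's best (HL, PCs),
#' and ranks the candidates.
#'
#' @param dataset an `hq_dataset`.
#' @param phase phase identifier.
#' @param fd_candidates list of flag vectors (default
#'   [default_fd_candidates()]).
#' @param fs fragment-size window used throughout the stage (default
#'   `c(4, 7)`).
#' @param hl_set hologram lengths scanned (default `HL_DEFAULT`).
#' @param max_pcs largest component count scanned (default 8).
#' @return an `hq_search`: a ranked data frame with columns `fd`, `fs_min`,
#'   `fs_max`, `hl`, `pcs`, `q2cv`, `r2`, `see` and a `spec` list column.
#' @export
scan_fd <- function(dataset, phase, fd_candidates = default_fd_candidates(),
                    fs = c(4L, 7L), hl_set = HL_DEFAULT, max_pcs = 8L) {
  if (!length(fd_candidates)) stop_config("empty fragment-distinction candidate list")
  cands <- lapply(fd_candidates, function(fl) fragment_params(fl, fs[1], fs[2]))
  .scan(dataset, phase, cands, "fd", hl_set, max_pcs)
}

#' Scan fragment-size candidates (search stage 2)
#'
#' Like [scan_fd()] but with the flag set fixed and the fragment-size
#' window varying.  Windows with `max < min` are rejected with a warning;
#' duplicated windows are deduplicated with a warning.
#'
#' @inheritParams scan_fd
#' @param fd the fixed flag set (default `"DA"`).
#' @param fs_candidates list of `c(min, max)` windows (default
#'   [default_fs_candidates()]).
#' @export
scan_fs <- function(dataset, phase, fd = "DA",
                    fs_candidates = default_fs_candidates(),
                    hl_set = HL_DEFAULT, max_pcs = 8L) {
  if (!length(fs_candidates)) stop_config("empty fragment-size candidate list")
  key <- vapply(fs_candidates, function(w) paste(w, collapse = "-"),
                character(1))
  if (anyDuplicated(key)) {
    warning("duplicate fragment-size window(s) dropped: ",
            paste(unique(key[duplicated(key)]), collapse = ", "),
            call. = FALSE)
    fs_candidates <- fs_candidates[!duplicated(key)]
    key <- key[!duplicated(key)]
  }
  ok <- vapply(fs_candidates, function(w) w[2] >= w[1] && w[1] >= 1,
               logical(1))
  if (any(!ok)) {
    warning("rejected window(s) with max < min: ",
            paste(key[!ok], collapse = ", "), call. = FALSE)
    fs_candidates <- fs_candidates[ok]
  }
  if (!length(fs_candidates)) stop_config("no valid fragment-size windows")
  cands <- lapply(fs_candidates, function(w) fragment_params(fd, w[1], w[2]))
  .scan(dataset, phase, cands, "fs", hl_set, max_pcs)
}

#' Rank search results
#'
#' Orders models by descending leave-one-out q2; ties are broken toward
#' fewer components, then smaller hologram length, then lexicographic flag
#' string, so the ordering is fully deterministic.
#'
#' @param result an `hq_search` data frame.
#' @return the reordered `hq_search`.
#' @export
rank_models <- function(result) {
  ord <- order(-result$q2cv, result$pcs, result$hl, result$fd)
  out <- result[ord, ]
  rownames(out) <- NULL
  attr(out, "phase") <- attr(result, "phase")
  attr(out, "stage") <- attr(result, "stage")
  class(out) <- c("hq_search", "data.frame")
  out
}

#' Top model specifications of a search result
#'
#' @param result an `hq_search`.
#' @param n how many specifications to return (default 4, the ensemble
#'   size used throughout).
#' @return a list of `hq_spec`.
#' @export
top_specs <- function(result, n = 4L) {
  n <- min(n, nrow(result))
  result$spec[seq_len(n)]
}

#' @export
print.hq_search <- function(x, ...) {
  cat("<hq_search> stage ", attr(x, "stage"), ", phase ", attr(x, "phase"),
      ", ", nrow(x), " candidates (ranked by q2cv)\n", sep = "")
  print.data.frame(x[setdiff(names(x), "spec")], row.names = FALSE,
                   digits = 4)
  invisible(x)
}
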