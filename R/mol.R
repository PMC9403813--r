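# Molecular graph construction from SMILES.
#
# Structures are parsed with Open Babel (through ChemmineOB/ChemmineR) and
# reduced to the heavy-atom graph used by the fragment enumerator: element
# symbols, a bond table with integer orders, and per-atom annotations
# (attached-hydrogen count, hybridization class, hydrogen-bond donor/acceptor
# class).  Hydrogens are never graph vertices; each heavy atom carries its
# implicit hydrogen count instead.

# Default valences used to infer implicit hydrogen counts for neutral atoms.
.VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
              S = 2, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' The molecule is converted to a connection table by Open Babel and stored
#' as a lightweight graph over heavy atoms.  Bond orders are 1, 2, 3, or 4
#' (aromatic, as written by the converter).  Implicit hydrogen counts are
#' derived from default valences assuming neutral atoms; hybridization is
#' classed as `"sp"`, `"sp2"` or `"sp3"` from the incident bond orders; the
#' donor/acceptor class is `"donor"`, `"acceptor"`, `"both"` or `"none"`
#' (N and O are acceptors, N-H and O-H additionally donors).
#'
#' @param smiles a single SMILES string.
#' @return an object of class `hq_mol`: a list with elements `smiles`,
#'   `element` (character vector over heavy atoms), `bonds` (integer matrix
#'   with columns `i`, `j`, `order`), `nbrs` (adjacency list), `n_h`
#'   (attached hydrogens), `hyb`, `da` and `stereo` (per-atom character
#'   vectors).
#' @examples
#' mol <- parse_smiles("CC(C)=O")
#' mol$element
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop_data("'smiles' must be a single non-empty string")
  }
  sdf_text <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    error = function(e) "")
  if (!nzchar(trimws(sdf_text))) {
    stop_data("cannot parse SMILES: ", smiles)
  }
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop_data("cannot parse SMILES: ", smiles)
  }

  if (n_atoms >= 2L && n_bonds >= 1L) {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))[[1]]
    element <- sub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  } else {
    # Degenerate connection tables (single atom, or no bonds) are rejected by
    # the SDF container class, so read the V2000 atom lines directly.
    atom_lines <- lines[5:(4 + n_atoms)]
    element <- trimws(substr(atom_lines, 32, 34))
    bonds <- cbind(i = integer(0), j = integer(0), order = integer(0))
  }
  hq_mol(element, bonds, smiles = smiles)
}

# Assemble an hq_mol from an element vector and a bond table, deriving the
# per-atom annotations.  Exposed internally so tests and the synthetic
# generator can build graphs without round-tripping through SMILES.
hq_mol <- function(element, bonds, smiles = NA_character_) {
  n <- length(element)
  storage.mode(bonds) <- "integer"
  nbrs <- rep(list(integer(0)), n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  if (n > 1L && !all(.reachable(nbrs, 1L))) {
    stop_data("molecule is not a single connected structure: ", smiles)
  }

  # bond-order sum per atom; aromatic (order 4) counts 1.5
  ord_num <- ifelse(bonds[, "order"] == 4L, 1.5, as.numeric(bonds[, "order"]))
  bosum <- numeric(n)
  n_double <- integer(n)
  has_pi <- logical(n)
  has_sp <- logical(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      for (v in bonds[k, 1:2]) {
        bosum[v] <- bosum[v] + ord_num[k]
        if (bonds[k, "order"] == 2L) n_double[v] <- n_double[v] + 1L
        if (bonds[k, "order"] %in% c(2L, 4L)) has_pi[v] <- TRUE
        if (bonds[k, "order"] == 3L) has_sp[v] <- TRUE
      }
    }
  }
  val <- .VALENCE[element]
  n_h <- as.integer(pmax(0, ifelse(is.na(val), 0, val) - floor(bosum)))
  hyb <- ifelse(has_sp | n_double >= 2L, "sp",
                ifelse(has_pi, "sp2", "sp3"))
  is_don <- element %in% c("N", "O") & n_h >= 1L
  is_acc <- element %in% c("N", "O")
  da <- ifelse(is_don & is_acc, "both",
               ifelse(is_don, "donor", ifelse(is_acc, "acceptor", "none")))
  structure(list(smiles = smiles, element = element, bonds = bonds,
                 nbrs = nbrs, n_h = n_h, hyb = hyb, da = da,
                 stereo = rep("unspec", n)),
            class = "hq_mol")
}

# breadth-first reachability from `start` over an adjacency list
.reachable <- function(nbrs, start) {
  n <- length(nbrs)
  seen <- logical(n)
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    new <- nbrs[[v]][!seen[nbrs[[v]]]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen
}

#' @export
print.hq_mol <- function(x, ...) {
  cat("<hq_mol> ", x$smiles, ": ", length(x$element), " heavy atoms (",
      paste0(x$element, collapse = ""), "), ", nrow(x$bonds), " bonds\n",
      sep = "")
  invisible(x)
}

# Renumber the atoms of a molecule by a permutation; used by the
# renumbering-invariance tests.
permute_mol <- function(mol, perm) {
  inv <- order(perm)
  bonds <- mol$bonds
  bonds[, 1] <- inv[bonds[, 1]]
  bonds[, 2] <- inv[bonds[, 2]]
  hq_mol(mol$element[perm], bonds, smiles = mol$smiles)
}
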