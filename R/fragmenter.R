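# Fragment enumeration.
#
# A fragment is a connected induced subgraph of the heavy-atom graph whose
# atom count lies in the fragment-size window [M, N].  Every such atom
# subset contributes exactly one occurrence, so linear, branched, cyclic and
# mutually overlapping fragments are all generated.  Enumeration uses the
# ESU connected-subgraph extension scheme (each subset is visited exactly
# once); the molecules targeted here have at most a dozen heavy atoms, so no
# pruning beyond the size cap is needed.

.FD_FLAGS <- c("A", "B", "C", "H", "Ch", "DA")

#' Fragment-generation parameters
#'
#' Bundles the fragment-distinction flags and the fragment-size window.
#' Flags: `"A"` atoms (element identity), `"B"` bonds (bond-order classes),
#' `"C"` connections (hybridization state), `"H"` attached-hydrogen counts,
#' `"Ch"` chirality descriptors, `"DA"` hydrogen-bond donor/acceptor class.
#'
#' @param flags non-empty character vector, a subset of
#'   `c("A","B","C","H","Ch","DA")`.
#' @param min_size,max_size the fragment-size window `[M, N]` in heavy
#'   atoms; `min_size >= 1`, `max_size >= min_size`.
#' @param max_atoms upper cap on `max_size` (default 12).
#' @return an object of class `hq_params`.
#' @examples
#' fragment_params("DA", 4, 7)
#' @export
fragment_params <- function(flags, min_size, max_size, max_atoms = 12L) {
  flags <- as.character(flags)
  if (length(flags) == 0L) stop_config("'flags' must be non-empty")
  bad <- setdiff(flags, .FD_FLAGS)
  if (length(bad)) {
    stop_config("unknown fragment-distinction flag(s): ",
                paste(bad, collapse = ", "))
  }
  flags <- .FD_FLAGS[.FD_FLAGS %in% flags]  # fixed canonical order
  min_size <- as.integer(min_size)
  max_size <- as.integer(max_size)
  if (is.na(min_size) || min_size < 1L) stop_config("'min_size' must be >= 1")
  if (is.na(max_size) || max_size < min_size) {
    stop_config("'max_size' must be >= 'min_size'")
  }
  if (max_size > max_atoms) {
    stop_config("'max_size' exceeds the atom cap (", max_atoms, ")")
  }
  structure(list(flags = flags, min_size = min_size, max_size = max_size),
            class = "hq_params")
}

#' @export
print.hq_params <- function(x, ...) {
  cat("<hq_params> FD = ", paste(x$flags, collapse = "+"),
      ", FS = ", x$min_size, "-", x$max_size, "\n", sep = "")
  invisible(x)
}

#' Atom labels under a set of fragment-distinction flags
#'
#' Each heavy atom receives the concatenation of the label components
#' activated by the flags, in the fixed order A, C, H, Ch, DA: element
#' symbol, hybridization class, attached-hydrogen count, stereo descriptor,
#' and donor/acceptor class.  With none of the atom-level flags active
#' (e.g. `flags = "B"`) every atom is labelled `"*"`.  The bond flag `"B"`
#' acts on bond labels, not atom labels.
#'
#' @param mol an `hq_mol`.
#' @param flags character vector of fragment-distinction flags.
#' @return character vector of per-atom labels.
#' @examples
#' atom_labels(parse_smiles("CC(C)=O"), "DA")
#' @export
atom_labels <- function(mol, flags) {
  flags <- fragment_params(flags, 1L, 1L)$flags
  parts <- list()
  if ("A" %in% flags) parts <- c(parts, list(mol$element))
  if ("C" %in% flags) parts <- c(parts, list(mol$hyb))
  if ("H" %in% flags) parts <- c(parts, list(paste0("H", mol$n_h)))
  if ("Ch" %in% flags) parts <- c(parts, list(mol$stereo))
  if ("DA" %in% flags) parts <- c(parts, list(mol$da))
  if (!length(parts)) return(rep("*", length(mol$element)))
  do.call(paste, c(parts, sep = "."))
}

# Bond labels: order classes when the bond flag is active, otherwise bonds
# contribute connectivity only.
.bond_labels <- function(mol, flags) {
  if ("B" %in% flags) {
    c("-", "=", "#", ":")[mol$bonds[, "order"]]
  } else {
    rep("~", nrow(mol$bonds))
  }
}

#' Enumerate all fragments of a molecule
#'
#' Enumerates every connected induced subgraph with `min_size` to `max_size`
#' heavy atoms and tallies occurrences by canonical fragment key.
#'
#' @param mol an `hq_mol` (or a SMILES string, which is parsed first).
#' @param params an [fragment_params()] object.
#' @return an object of class `hq_fragments`: a named integer vector of
#'   occurrence counts keyed by canonical fragment key, with attribute
#'   `total` (the number of enumerated fragments) and `params`.
#' @examples
#' enumerate_fragments(parse_smiles("CCCCC"), fragment_params("A", 1, 5))
#' @export
enumerate_fragments <- function(mol, params) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "hq_mol"), inherits(params, "hq_params"))
  n <- length(mol$element)
  if (n < 1L) stop_data("molecule has no heavy atoms")

  subsets <- .connected_subsets(mol$nbrs, params$min_size, params$max_size)
  labels <- atom_labels(mol, params$flags)
  elabs <- .bond_labels(mol, params$flags)
  keys <- vapply(subsets, function(s) .fragment_key(mol, s, labels, elabs),
                 character(1))
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(counts, total = length(subsets), params = params,
            class = "hq_fragments")
}

#' @export
print.hq_fragments <- function(x, ...) {
  cat("<hq_fragments> ", attr(x, "total"), " occurrences, ",
      length(x), " distinct keys\n", sep = "")
  df <- data.frame(key = names(x), count = as.integer(x))
  print(head(df[order(-df$count, df$key), ], 20), row.names = FALSE)
  if (length(x) > 20) cat("...\n")
  invisible(x)
}

# ESU (extension) enumeration of connected induced subgraphs with size in
# [m, n_max].  Each subset is emitted exactly once: subsets are anchored at
# their minimum vertex and grown only through vertices with larger indices
# that are not yet adjacent to the growing set.
.connected_subsets <- function(nbrs, m, n_max) {
  n <- length(nbrs)
  out <- vector("list", 256)
  n_out <- 0L
  emit <- function(s) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- s
  }
  rec <- function(S, ext, seen) {
    if (length(S) >= m) emit(S)
    if (length(S) == n_max) return()
    while (length(ext)) {
      w <- ext[[1]]
      ext <- ext[-1]
      new <- nbrs[[w]]
      new <- new[new > S[[1]] & !seen[new]]
      seen2 <- seen
      seen2[new] <- TRUE
      rec(c(S, w), c(ext, new), seen2)
    }
  }
  for (s in seq_len(n)) {
    ext0 <- nbrs[[s]][nbrs[[s]] > s]
    seen <- logical(n)
    seen[c(s, ext0)] <- TRUE
    rec(s, ext0, seen)
  }
  out[seq_len(n_out)]
}

#' Canonical key of one fragment
#'
#' Computes the canonical string identity of the induced subgraph on a set
#' of atoms, under a set of fragment-distinction flags.  Keys are invariant
#' to atom numbering: two graph-isomorphic fragments with matching atom and
#' bond labels receive identical keys.
#'
#' @param mol an `hq_mol`.
#' @param atoms integer vector of atom indices (must induce a connected
#'   subgraph).
#' @param flags fragment-distinction flags.
#' @return a single string.
#' @examples
#' m <- parse_smiles("CC=O")
#' fragment_key(m, c(2, 3), c("A", "B"))
#' @export
fragment_key <- function(mol, atoms, flags) {
  stopifnot(inherits(mol, "hq_mol"))
  params <- fragment_params(flags, 1L, max(1L, length(atoms)),
                            max_atoms = length(mol$element))
  atoms <- as.integer(atoms)
  labels <- atom_labels(mol, params$flags)
  elabs <- .bond_labels(mol, params$flags)
  sub_n <- .induced_nbrs(mol, atoms)
  if (length(atoms) > 1L && !all(.reachable(sub_n$nbrs, 1L))) {
    stop_data("atom subset does not induce a connected fragment")
  }
  .fragment_key(mol, atoms, labels, elabs)
}

# local adjacency of the induced subgraph: neighbor lists and matching
# bond-row indices, in local 1..k numbering
.induced_nbrs <- function(mol, atoms) {
  k <- length(atoms)
  loc <- integer(length(mol$element))
  loc[atoms] <- seq_len(k)
  nbrs <- rep(list(integer(0)), k)
  erow <- rep(list(integer(0)), k)
  b <- mol$bonds
  if (nrow(b)) {
    inside <- loc[b[, 1]] > 0L & loc[b[, 2]] > 0L
    for (r in which(inside)) {
      i <- loc[b[r, 1]]; j <- loc[b[r, 2]]
      nbrs[[i]] <- c(nbrs[[i]], j); erow[[i]] <- c(erow[[i]], r)
      nbrs[[j]] <- c(nbrs[[j]], i); erow[[j]] <- c(erow[[j]], r)
    }
  }
  list(nbrs = nbrs, erow = erow)
}

# Dispatch: trees (the overwhelmingly common case for acyclic molecules) use
# the linear-time rooted-tree canonical form; fragments containing a ring
# fall back to a BLISS canonical labelling through igraph.
.fragment_key <- function(mol, atoms, labels, elabs) {
  k <- length(atoms)
  if (k == 1L) return(paste0("(", labels[atoms], ")"))
  sub <- .induced_nbrs(mol, atoms)
  n_edges <- sum(lengths(sub$nbrs)) / 2L
  llab <- labels[atoms]
  if (n_edges == k - 1L) {
    .tree_key(sub, llab, elabs)
  } else {
    .cyclic_key(sub, llab, elabs, k)
  }
}

# Canonical form of a labelled free tree: root at the tree centre (or the
# centre edge) and take the sorted recursive encoding of the rooted tree.
.tree_key <- function(sub, llab, elabs) {
  nbrs <- sub$nbrs
  erow <- sub$erow
  k <- length(nbrs)
  enc <- function(v, parent) {
    ns <- nbrs[[v]]
    rows <- erow[[v]]
    keep <- ns != parent
    kids <- ns[keep]
    if (!length(kids)) return(paste0("(", llab[v], ")"))
    parts <- character(length(kids))
    rows <- rows[keep]
    for (idx in seq_along(kids)) {
      parts[idx] <- paste0(elabs[rows[idx]], enc(kids[idx], v))
    }
    paste0("(", llab[v], paste0(sort(parts), collapse = ""), ")")
  }
  if (k == 1L) return(enc(1L, 0L))
  # peel leaves to find the 1- or 2-vertex centre
  deg <- lengths(nbrs)
  alive <- rep(TRUE, k)
  remaining <- k
  layer <- which(deg <= 1L)
  while (remaining > 2L) {
    alive[layer] <- FALSE
    remaining <- remaining - length(layer)
    nxt <- integer(0)
    for (v in layer) {
      for (u in nbrs[[v]]) {
        if (alive[u]) {
          deg[u] <- deg[u] - 1L
          if (deg[u] == 1L) nxt <- c(nxt, u)
        }
      }
    }
    layer <- nxt
  }
  centres <- which(alive)
  if (length(centres) == 1L) {
    enc(centres[1], 0L)
  } else {
    c1 <- centres[1]; c2 <- centres[2]
    r <- erow[[c1]][match(c2, nbrs[[c1]])]
    parts <- sort(c(enc(c1, c2), enc(c2, c1)))
    paste0("[", elabs[r], parts[1], parts[2], "]")
  }
}

# Canonical form of a labelled graph with cycles: subdivide every bond into
# a labelled vertex, colour vertices by label, and take the BLISS canonical
# permutation of the coloured graph.
.cyclic_key <- function(sub, llab, elabs, k) {
  nbrs <- sub$nbrs
  erow <- sub$erow
  # unique edges in local numbering
  ei <- integer(0); ej <- integer(0); er <- integer(0)
  for (v in seq_len(k)) {
    sel <- nbrs[[v]] > v
    ei <- c(ei, rep(v, sum(sel)))
    ej <- c(ej, nbrs[[v]][sel])
    er <- c(er, erow[[v]][sel])
  }
  n_e <- length(ei)
  bond_v <- k + seq_len(n_e)
  edges <- rbind(cbind(ei, bond_v), cbind(ej, bond_v))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  vlab <- c(paste0("a:", llab), paste0("b:", elabs[er]))
  colours <- match(vlab, sort(unique(vlab)))
  lab <- igraph::canonical_permutation(g, colors = colours)$labeling
  # canonical order of the atom vertices
  atom_rank <- rank(lab[seq_len(k)])
  ord <- order(atom_rank)
  ce_i <- pmin(atom_rank[ei], atom_rank[ej])
  ce_j <- pmax(atom_rank[ei], atom_rank[ej])
  eord <- order(ce_i, ce_j)
  paste0("{", paste0(llab[ord], collapse = ","), ";",
         paste0(ce_i[eord], "-", ce_j[eord], ":", elabs[er][eord],
                collapse = ","), "}")
}
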