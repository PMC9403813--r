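# Independent oracles used across the suite.

# Brute-force enumeration over all 2^n atom subsets: returns the sizes of
# every subset that induces a connected subgraph.  Deliberately naive and
# independent of the package's extension enumerator.
brute_force_connected_sizes <- function(mol) {
  n <- length(mol$element)
  stopifnot(n <= 12)
  sizes <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    atoms <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    if (bf_connected(atoms, mol$nbrs)) sizes <- c(sizes, length(atoms))
  }
  sizes
}

# plain breadth-first connectivity check on an atom subset
bf_connected <- function(atoms, nbrs) {
  if (length(atoms) == 1L) return(TRUE)
  seen <- atoms[1]
  repeat {
    new <- setdiff(intersect(unlist(nbrs[seen]), atoms), seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  length(seen) == length(atoms)
}

bf_total_in_window <- function(sizes, m, n) sum(sizes >= m & sizes <= n)

# fragment multisets as comparable objects
frag_signature <- function(fr) sort(paste(names(fr), as.integer(fr)))

# random carbonyl molecules with at most `max_heavy` heavy atoms
random_small_molecules <- function(n, seed, max_heavy = 10L) {
  ds <- generate_synthetic(synthetic_config(
    n_compounds = 3L * n, max_chain_length = 7L, branch_probability = 0.4,
    noise_sd = 0, seed = seed))
  keep <- ds$truth$heavy <= max_heavy
  smiles <- ds$compounds$smiles[keep]
  stopifnot(length(smiles) >= n)
  smiles[seq_len(n)]
}

# permutation helper from the package internals
permute_mol <- hqsar:::permute_mol

# the six fragment-distinction candidate sets of the first search stage
fd_candidate_sets <- function() {
  list("B", "DA", c("A", "DA"), c("B", "DA"), c("A", "C", "DA"),
       c("A", "B", "H", "DA"))
}
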