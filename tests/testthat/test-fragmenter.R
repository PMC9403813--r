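test_that("path and star molecules give the known fragment counts", {
  # contiguous segments of a 5-carbon path: 5+4+3+2+1
  p5 <- enumerate_fragments(parse_smiles("CCCCC"), fragment_params("A", 1, 5))
  expect_equal(attr(p5, "total"), 15L)
  # acetone, sizes 1-2: 4 singletons + 3 edges; keys C, O, C-C, C-O under {A}
  ac <- enumerate_fragments(parse_smiles("CC(C)=O"), fragment_params("A", 1, 2))
  expect_equal(attr(ac, "total"), 7L)
  expect_equal(length(ac), 4L)
  # single heavy atom
  m1 <- enumerate_fragments(parse_smiles("C"), fragment_params("A", 1, 1))
  expect_equal(attr(m1, "total"), 1L)
})

test_that("enumeration totals match the brute-force subset oracle", {
  mols <- c("CCCCC", "CC(C)=O", "CCC(C)C=O", "C1CCCCC1=O", "c1ccccc1C=O",
            "CC1CC1C=O")
  windows <- list(c(1, 9), c(2, 5), c(3, 6), c(4, 7))
  for (smi in mols) {
    mol <- parse_smiles(smi)
    sizes <- brute_force_connected_sizes(mol)
    for (w in windows) {
      fr <- enumerate_fragments(mol, fragment_params(c("A", "B"), w[1], w[2]))
      expect_equal(attr(fr, "total"), bf_total_in_window(sizes, w[1], w[2]),
                   info = paste(smi, w[1], w[2]))
    }
  }
})

test_that("fragment multisets are invariant to atom renumbering", {
  set.seed(101)
  for (smi in c("CCC(=O)CC", "CC(C)CC=O", "C1CCCCC1=O", "c1ccccc1C(C)=O")) {
    mol <- parse_smiles(smi)
    for (fl in list("A", c("A", "B"), c("A", "C", "DA"),
                    c("A", "B", "H", "DA"))) {
      ref <- frag_signature(enumerate_fragments(mol, fragment_params(fl, 1, 7)))
      for (r in 1:3) {
        mp <- permute_mol(mol, sample(length(mol$element)))
        expect_equal(frag_signature(enumerate_fragments(
          mp, fragment_params(fl, 1, 7))), ref, info = paste(smi, r))
      }
    }
  }
})

test_that("widening the size window never loses occurrences", {
  mol <- parse_smiles("CCC(C)CC(C)=O")
  totals <- vapply(1:8, function(n_max) {
    attr(enumerate_fragments(mol, fragment_params("A", 1, n_max)), "total")
  }, integer(1))
  expect_true(all(diff(totals) >= 0))
  # shrinking from below likewise
  t14 <- attr(enumerate_fragments(mol, fragment_params("A", 1, 4)), "total")
  t24 <- attr(enumerate_fragments(mol, fragment_params("A", 2, 4)), "total")
  expect_true(t24 <= t14)
})

test_that("fragment keys canonicalize and honour the bond flag", {
  m <- parse_smiles("CC=O")  # atoms: C1-C2=O3
  k1 <- fragment_key(m, c(1, 2, 3), c("A", "B"))
  k2 <- fragment_key(m, c(3, 2, 1), c("A", "B"))
  expect_identical(k1, k2)
  # C-C=O vs C-C-O: distinct under {A,B} (bond order) ...
  m_ol <- parse_smiles("CCO")
  expect_false(identical(fragment_key(m, 1:3, c("A", "B")),
                         fragment_key(m_ol, 1:3, c("A", "B"))))
  # ... and identical under {A} alone (same atoms, same topology)
  expect_identical(fragment_key(m, 1:3, "A"),
                   fragment_key(m_ol, 1:3, "A"))
  expect_error(fragment_key(m, c(1, 3), "A"), class = "hq_data_error")
})

test_that("atom labels expose exactly the flagged distinctions", {
  m <- parse_smiles("CC(C)=O")
  da <- atom_labels(m, "DA")
  expect_equal(da[m$element == "O"], "acceptor")
  expect_true(all(da[m$element == "C"] == "none"))
  ach <- atom_labels(m, c("A", "C", "H"))
  o <- which(m$element == "O")
  expect_equal(ach[o], "O.sp2.H0")
  expect_error(atom_labels(m, character(0)), class = "hq_config_error")
  # bond-only distinction leaves atoms indistinct
  expect_true(all(atom_labels(m, "B") == "*"))
})

test_that("parameter validation rejects bad windows and flags", {
  expect_error(fragment_params("A", 3, 2), class = "hq_config_error")
  expect_error(fragment_params("A", 0, 2), class = "hq_config_error")
  expect_error(fragment_params("X", 1, 2), class = "hq_config_error")
  expect_error(fragment_params("A", 1, 99), class = "hq_config_error")
  expect_silent(fragment_params("A", 1, 20, max_atoms = 20))
})
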