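---
title: "Hologram QSAR with ensemble modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hologram QSAR with ensemble modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hqsar)
```

## The problem

Gas-chromatography retention indices (RI) locate a compound's elution
between consecutive n-alkane references; they are dimensionless, depend on
the stationary phase, and are costly to measure for every compound of a
family.  Hologram QSAR (HQSAR) predicts such properties from 2D structure
alone: every connected molecular fragment of a molecule, within a size
window, is counted; the counts are folded into a fixed-length integer
vector (the *molecular hologram*); and the property is regressed on the
hologram by partial least squares (PLS).  This package implements that
pipeline end to end, together with a consensus ("ensemble") layer that
averages several individual HQSAR models, and ships a 34-compound
aldehyde/ketone RI dataset measured on the DB-210 and HP-Innowax phases
(26 training compounds, group I; 8 external-test compounds, group II).

## Fragments and their labels

A fragment is a **connected induced subgraph** of the heavy-atom graph with
between `M` and `N` atoms (the fragment-size window, FS).  Every qualifying
atom subset contributes exactly one occurrence, so branched, cyclic and
mutually overlapping fragments are all counted, and hydrogens are never
enumeration vertices.  Enumeration uses an extension scheme that visits
each connected subset exactly once; for the molecules this package targets
(a dozen heavy atoms or fewer) no pruning is needed, and the enumerator is
tested for exact agreement with a brute-force pass over all $2^n$ subsets.

What makes two fragments "the same" is controlled by the
fragment-distinction flags (FD):

* `A` — element identity;
* `B` — bond-order classes (single/double/triple/aromatic); without `B`,
  bonds contribute connectivity only;
* `C` — hybridization class (`sp`, `sp2`, `sp3`), inferred from incident
  bond orders;
* `H` — attached-hydrogen count, derived from default valences for neutral
  atoms;
* `Ch` — stereo descriptor.  Atom parity and E/Z labels are not carried
  through the current structure input path, so every atom is labelled
  "unspecified"; the flag exists for interface completeness and the bundled
  compounds declare no stereochemistry (2-butenal is deliberately encoded
  without E/Z);
* `DA` — hydrogen-bond donor/acceptor class.  The rule is: N and O are
  acceptors; N–H and O–H are additionally donors; everything else is
  "none".  A carbonyl oxygen is therefore an acceptor, and `DA` alone
  separates the carbonyl environment from the hydrocarbon skeleton — which
  is why it performs so well on carbonyl homologues.

Each fragment is reduced to a canonical key, invariant to atom numbering.
Acyclic fragments (the only kind arising from acyclic molecules) use a
rooted-tree canonical form: the tree is rooted at its centre (or centre
edge) and encoded by sorted recursive traversal, which is a complete
isomorphism invariant for labelled trees.  Fragments containing rings fall
back to a BLISS canonical permutation of a vertex-coloured graph in which
every bond is subdivided into a labelled vertex, so bond labels participate
in the canonical form.  The two encodings use disjoint string prefixes and
cannot collide.

## Holograms

A canonical key is mapped to a pseudo-random integer in $[0, 2^{31})$ by a
CRC-32 hash of its UTF-8 bytes masked to 31 bits, and its occurrence count
accumulates in bin `hash mod L`.  The hologram length `L` defaults to one
of the six primes 97, 151, 199, 257, 307, 353; prime lengths break up
systematic collision patterns, and `L` is treated as a tunable
hyperparameter.  Bin sums always equal the enumeration total — a
conservation law the test suite asserts for every molecule and length.
The original commercial implementation uses a proprietary fragment
canonicalization and hash; this package's choices are fixed, documented and
reproducible, but bin-level agreement with that software is not a goal, and
hash-dependent statistics (which fragments collide, hence exact
cross-validation values) legitimately differ.

## Regression

The hologram matrix is regressed on the property by single-response
NIPALS PLS: predictors and response are mean-centred, never
variance-scaled (all bins share the count scale), and latent components
are extracted sequentially, so one fit yields predictions at every
component count up to the requested one.  At the full rank of the centred
predictor matrix the fit coincides with ordinary least squares, which the
tests exploit as an independent oracle (tolerance 1e-8 on 20 random
12-by-6 systems).  The component count (PCs) is selected by leave-one-out
(LOO) cross-validation: for each left-out training compound the model is
refit on the rest and the held-out value predicted; the selected count
maximizes

$$q^2_{\mathrm{cv}} = 1 - \frac{\sum_i (\hat y_i - y_i)^2}
                              {\sum_i (y_i - \bar y_{\mathrm{TR}})^2},$$

with ties resolved toward fewer components.  The standard error of
estimate uses the denominator $n - \mathrm{PCs} - 1$, a reporting
convention.  Holograms are recomputed once, not per fold: descriptor
generation involves no fitting, so reusing them leaks no information.

## Validation statistics

For an external set (group II) predicted by a model trained on group I,
the package reports, alongside $q^2_{\mathrm{cv}}$:

* $q^2_{\mathrm{ext}}$ — same ratio form with external residuals and the
  **training** mean in the denominator;
* $Q^2_{F2}$ — referenced to the external set's own mean;
* $Q^2_{F3}$ — $1 - (\mathrm{PRESS}/n_{\mathrm{EXT}})
  / (\mathrm{TSS}/n_{\mathrm{TR}})$, external mean squared error normalized
  by per-sample training variance;
* CCC — Lin's concordance correlation coefficient, agreement about the
  identity line;
* RMSE and MAPE, pooled over all compounds (group I LOO predictions
  together with group II external predictions — the pooling convention was
  established by recomputing the published MAPE from the published
  predictions, and is fixed).

Customary adequacy levels (CCC > 0.85, $Q^2_{F2}, Q^2_{F3}$ > 0.60,
$q^2$ > 0.50) are attached to reports as flags, never enforced as errors.

## Hyperparameter search and the ensemble

The search reproduces a two-stage protocol.  Stage 1 scans
fragment-distinction candidates (`B`, `DA`, `A+DA`, `B+DA`, `A+C+DA`,
`A+B+H+DA`) at the default window FS 4–7; each candidate is optimized over
all six hologram lengths and component counts by LOO $q^2_{\mathrm{cv}}$.
Stage 2 fixes the winning flags and scans fragment-size windows
(1–9, 3–10, 4–7, 2–5, 3–6 by default).  Ranking is fully deterministic:
descending $q^2_{\mathrm{cv}}$, then fewer components, then smaller
hologram length, then the flag string.  Retrained from scratch on the
bundled data this protocol selects `DA` in stage 1 on both phases and the
windows 1–9 (DB-210) and 4–7 (HP-Innowax) in stage 2, with
$q^2_{\mathrm{cv}}$ of about 0.91 and 0.92 — the same qualitative optimum
as the reference software, with the expected hash-dependent numerical
differences.

The ensemble model is the unweighted arithmetic mean of T individual
submodels, $H(x) = \tfrac1T \sum_i h_i(x)$, with T = 4 top-ranked
stage-2 models by default.  Its LOO validation refits **every** submodel in
every fold, with each submodel's component count held at its selected
value.  Averaging guarantees (by convexity) that the ensemble's pooled
squared error never exceeds the mean pooled squared error of its
submodels; the corresponding RMSE comparison is not an identity but holds
in practice, and the suite checks it across seeds.  Only equal weights are
supported — the consensus definition is an unweighted mean.

## The synthetic generator

`generate_synthetic()` draws acyclic molecules with one carbonyl: a
backbone of 3 to `max_chain_length` (default 9) carbons, a carbonyl
position drawn uniformly (terminal = aldehyde), and methyl branches on
eligible interior carbons with probability 0.3.  The property is
`350 + 100*heavy_atoms - 25*branches + 12*carbonyl_position` plus Gaussian
noise, which mimics the magnitude (roughly 700–1400) and the dominant
size dependence of retention indices on an apolar-to-mid-polar phase;
the default noise level used in the noisy-recovery checks is 15 index
units, comparable to the standard errors of the bundled models.  The
generator emulates homologue-series structure with known ground truth; it
does **not** emulate polar-phase specific interactions, polyfunctional or
cyclic chemistry, or measurement error structure, so passing recovery
tests demonstrates correctness of the pipeline, not chemical realism.
Datasets are split 3:1 into groups I/II, are deterministic under the seed,
and leave the caller's RNG state untouched.

## Numerical and design choices

* **Problem sizes.**  The test suite enumerates fragments for the 34
  bundled plus 50 generated molecules under 30 flag/window combinations
  against the brute-force oracle, and runs the noisy ensemble comparison
  over 10 seeds at n = 24 — sizes chosen to exercise every code path on
  the same scale as the study itself.
* **Degenerate inputs.**  Empty flag sets, inverted windows, non-positive
  lengths and constant responses are configuration/data errors with
  dedicated condition classes (`hq_config_error`, `hq_data_error`), which
  the command-line driver maps to exit codes 2 and 3.  Component counts
  exceeding the achievable rank are clamped with a warning, including
  inside LOO folds.
* **Determinism.**  There is no randomness anywhere in the pipeline
  proper; holograms, searches and ensembles are bit-identical across runs.
  Randomness enters only through the synthetic generator's seed.
* **Single-atom molecules** are parsed through a direct read of the
  connection-table atom lines, since the SDF container class rejects
  bond-less records.
* **Known limitations.**  Implicit-hydrogen counts assume neutral atoms
  with default valences; stereo descriptors are not propagated to labels
  (see the `Ch` flag above); aromatic perception follows the Kekulé forms
  written by the structure converter; and hologram bin assignments are not
  interchangeable with those of other HQSAR implementations.
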