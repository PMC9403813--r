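# hqsar

Hologram QSAR (HQSAR) with consensus (ensemble) modelling, in R, for
predicting gas-chromatography retention indices — and, more generally, any
single numeric property — from SMILES structures.

HQSAR describes a molecule by its *molecular hologram*: every connected
fragment with `M`–`N` heavy atoms is enumerated (linear, branched, cyclic,
overlapping), labelled under a set of fragment-distinction flags (atoms
`A`, bonds `B`, connections `C`, hydrogens `H`, chirality `Ch`,
donor/acceptor `DA`), reduced to a canonical key, hashed by CRC-32 to an
integer in [0, 2³¹), and folded into one of `L` bins (`L` ∈ {97, 151, 199,
257, 307, 353} by default).  The property *y* is regressed on the hologram
by mean-centred NIPALS PLS, with the component count chosen by
leave-one-out cross-validation:

    q²cv = 1 − Σᵢ (ŷᵢ − yᵢ)² / Σᵢ (yᵢ − ȳ_TR)²

Model selection follows a two-stage protocol (scan flag sets at window
4–7, then scan windows at the best flags), and a consensus model averages
the top *T* = 4 individual models with equal weights:
`H(x) = (1/T) Σ hᵢ(x)`.  External validation reports RMSE, MAPE, Lin's
concordance correlation (CCC), q²ext, Q²F2 and Q²F3.

The package bundles a 34-compound aldehyde/ketone dataset with
experimental retention indices on the DB-210 and HP-Innowax stationary
phases (26 training / 8 external-test compounds) together with the
reported individual-model and ensemble predictions, and includes a
synthetic carbonyl-compound generator with a known linear
structure–property relationship for controlled end-to-end testing.

## Worked example

Evaluate the bundled ensemble predictions on DB-210 — this reproduces one
column of the study's statistics table:

```r
library(hqsar)
ds <- load_bundled_dataset()
evaluate_predictions(ds, "DB-210", "ensemble")
#> <hq_report> phase DB-210, ensemble model (n_train = 26, n_ext = 8)
#>   RMSE      40.417
#>   MAPE/%     2.686
#>   CCC        0.956  [ok]
#>   q2_ext     0.929  [ok]
#>   QF2        0.927  [ok]
#>   QF3        0.935  [ok]
#>   q2_cv      0.927  [ok]
```

RMSE and MAPE are pooled over all 34 compounds (group I leave-one-out +
group II external); CCC/q2_ext/QF2/QF3 are external statistics over the 8
group II compounds; q2_cv is the leave-one-out statistic over the 26
group I compounds.  `[ok]` marks the customary adequacy levels
(CCC > 0.85, QF2/QF3 > 0.60, q² > 0.50).

Retrain from scratch — stage-2 search at the donor/acceptor distinction,
then ensemble validation of the top four models:

```r
fs <- scan_fs(ds, "DB-210", fd = "DA")
fs
#> <hq_search> stage fs, phase DB-210, 5 candidates (ranked by q2cv)
#>  fd fs_min fs_max  hl pcs   q2cv     r2   see
#>  DA      1      9 199   8 0.9080 0.9824 24.96
#>  DA      3     10 199   8 0.8982 0.9825 24.83
#>  DA      3      6 353   8 0.8872 0.9787 27.44
#>  DA      4      7 199   8 0.8848 0.9824 24.91
#>  DA      2      5 257   5 0.8475 0.9518 38.05

val <- validate_ensemble(ds, "DB-210", top_specs(fs, 4))
val$report
#> <hq_report> phase DB-210, ensemble model (n_train = 26, n_ext = 8)
#>   RMSE      43.341
#>   MAPE/%     2.737
#>   CCC        0.966  [ok]
#>   q2_ext     0.938  [ok]
#>   QF2        0.936  [ok]
#>   QF3        0.943  [ok]
#>   q2_cv      0.911  [ok]
```

The search selects the same winning window (fragment size 1–9 on DB-210)
as the original study; the exact q²cv values differ because fragment
canonicalization and hashing are implementation-defined (see the methods
vignette).  `write_predictions()` exports predictions with signed relative
errors; `write_model()`/`read_model()` serialize individual and ensemble
models to versioned JSON.

A command-line driver wrapping these functions ships in
`inst/cli/hqsar.R` (subcommands `fragments`, `hologram`, `search`,
`train`, `ensemble`, `predict`, `validate`, `synth`; exit codes 0/2/3 for
success/configuration error/data error):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hqsar.R",package="hqsar"))')" \
    fragments --smiles 'CC(C)=O' --flags A --min 1 --max 2
```

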