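make_small_synth <- function(seed = 41, n = 16, noise = 10) {
  generate_synthetic(synthetic_config(n_compounds = n, noise_sd = noise,
                                      seed = seed))
}

two_specs <- list(model_spec("A", 1, 3, 97, pcs = 2),
                  model_spec("A", 1, 4, 151, pcs = 2))

test_that("ensembles require at least two submodels and name failures", {
  syn <- make_small_synth()
  expect_error(build_ensemble(syn, "synthetic", two_specs[1]),
               class = "hq_config_error")
  ens <- build_ensemble(syn, "synthetic", two_specs)
  expect_equal(ens$t_size, 2L)
  # a submodel that cannot fit aborts with its spec in the message
  small <- generate_synthetic(synthetic_config(n_compounds = 12,
                                               max_chain_length = 5,
                                               seed = 48))  # <= 9 heavy atoms
  bad <- list(model_spec("A", 1, 3, 97, pcs = 2),
              model_spec("A", 12, 12, 97, pcs = 2))  # no size-12 fragments
  expect_error(build_ensemble(small, "synthetic", bad),
               regexp = "FS=12-12", class = "hq_data_error")
})

test_that("ensemble prediction is the unweighted submodel mean", {
  syn <- make_small_synth()
  ens <- build_ensemble(syn, "synthetic", two_specs)
  pred <- predict(ens, syn)
  per <- attr(pred, "submodels")
  expect_equal(as.numeric(pred), rowMeans(per))
  expect_true(all(pred >= apply(per, 1, min) - 1e-9 &
                    pred <= apply(per, 1, max) + 1e-9))
  # T identical submodels reproduce the single model exactly
  ens_same <- build_ensemble(syn, "synthetic",
                             list(two_specs[[1]], two_specs[[1]]))
  single <- fit_model(syn, "synthetic", two_specs[[1]])
  expect_equal(as.numeric(predict(ens_same, syn)),
               as.numeric(predict(single, syn)))
  # permuting submodel order leaves the mean unchanged
  ens_rev <- build_ensemble(syn, "synthetic", rev(two_specs))
  expect_equal(as.numeric(predict(ens_rev, syn)), as.numeric(pred))
})

test_that("ensemble leave-one-out equals a hand-rolled fold loop", {
  # tiny system checked fold by fold against direct pls_fit calls
  syn <- generate_synthetic(synthetic_config(n_compounds = 8, noise_sd = 5,
                                             seed = 43))
  val <- validate_ensemble(syn, "synthetic", two_specs)
  gi <- which(syn$compounds$group == "I")
  y <- syn$ri[, "synthetic"]
  for (spec_i in 1:2) {
    spec <- two_specs[[spec_i]]
    x <- build_matrix(syn, spec$params, spec$hl)
    for (k in seq_along(gi)) {
      tr <- gi[-k]
      fit <- suppressWarnings(pls_fit(x[tr, ], y[tr], spec$pcs))
      expect_equal(
        val$submodel_predictions[gi[k], spec_i],
        as.numeric(predict(fit, x[gi[k], , drop = FALSE],
                           min(spec$pcs, fit$ncomp))),
        tolerance = 1e-10)
    }
  }
  expect_equal(val$predictions$predicted[gi],
               rowMeans(val$submodel_predictions)[gi])
})

test_that("averaging never increases the pooled squared error", {
  for (s in c(44, 45)) {
    syn <- make_small_synth(seed = s)
    val <- validate_ensemble(syn, "synthetic", two_specs)
    y <- syn$ri[, "synthetic"]
    ens_sse <- sum((val$predictions$predicted - y)^2)
    sub_sse <- mean(colSums((val$submodel_predictions - y)^2))
    expect_lte(ens_sse, sub_sse + 1e-9)
  }
})

test_that("a noiseless linear dataset is learned almost perfectly", {
  syn <- generate_synthetic(synthetic_config(n_compounds = 16, noise_sd = 0,
                                             seed = 46))
  val <- validate_ensemble(syn, "synthetic",
                           list(model_spec("A", 1, 3, 97),
                                model_spec("A", 1, 4, 151)))
  expect_gt(val$report$stats[["q2_cv"]], 0.95)
})
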