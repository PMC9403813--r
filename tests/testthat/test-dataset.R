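test_that("bundled dataset has the documented shape and values", {
  ds <- load_bundled_dataset()
  expect_equal(nrow(ds$compounds), 34L)
  expect_equal(sum(ds$compounds$group == "I"), 26L)
  expect_equal(sum(ds$compounds$group == "II"), 8L)
  expect_equal(phases(ds), c("DB-210", "HP-Innowax"))
  expect_equal(ds$ri["acetone", "DB-210"], 792.9)
  expect_equal(ds$ri["2-ethylhexanal", "HP-Innowax"], 1197.8)
  # all four prediction columns attached: 34 x 2 phases x 2 models
  expect_equal(nrow(ds$predictions), 136L)
  p <- ds$predictions
  expect_equal(p$predicted[p$name == "2-pentanone" & p$phase == "DB-210" &
                             p$model == "ensemble"], 978.7)
  # every SMILES parses to a connected molecule with exactly one carbonyl
  for (i in seq_len(34)) {
    m <- parse_smiles(ds$compounds$smiles[i])
    expect_equal(sum(m$element == "O"), 1L)
    expect_equal(sum(m$bonds[, "order"] == 2L &
                       (m$element[m$bonds[, "i"]] == "O" |
                          m$element[m$bonds[, "j"]] == "O")), 1L)
  }
})

test_that("bundled relative errors are recomputable from Exp and Pred", {
  ds <- load_bundled_dataset()
  p <- ds$predictions
  exp_val <- ds$ri[cbind(match(p$name, rownames(ds$ri)),
                         match(p$phase, colnames(ds$ri)))]
  re <- 100 * (p$predicted - exp_val) / exp_val
  expect_lt(max(abs(re - p$re_percent)), 0.01)
})

test_that("dataset CSV round trip preserves all numeric fields", {
  ds <- load_bundled_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path, schema = list(
    name = "name", smiles = "smiles", group = "group",
    properties = c("DB-210" = "ri_db210", "HP-Innowax" = "ri_innowax")))
  back <- read_dataset(path)
  expect_equal(back$compounds, ds$compounds)
  expect_equal(back$ri, ds$ri)
})

test_that("read_dataset validates schema and reports bad SMILES by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,smiles,group,ri_db210,ri_innowax",
               "a,CCO,I,1,2", "b,CCC,II,3,4"), path)
  ds <- read_dataset(path)
  expect_equal(nrow(ds$compounds), 2L)

  writeLines(c("name,smiles,group,ri_db210,ri_innowax",
               "a,CCO,I,1,2", "badrow,C(Q,II,3,4"), path)
  expect_error(read_dataset(path), regexp = "badrow",
               class = "hq_data_error")

  writeLines("name,smiles,group,ri_db210,ri_innowax", path)
  empty <- read_dataset(path)
  expect_equal(nrow(empty$compounds), 0L)

  writeLines(c("name,group", "a,I"), path)
  expect_error(read_dataset(path), class = "hq_config_error")
})

test_that("write_predictions computes signed relative errors in percent", {
  ds <- load_bundled_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  preds <- data.frame(name = c("acetone", "acetone", "butanal"),
                      phase = c("DB-210", "DB-210", "DB-210"),
                      model = c("individual", "ensemble", "individual"),
                      predicted = c(764.8, 792.9, 927.41))
  out <- write_predictions(ds, preds, path)
  expect_equal(round(out$relative_error[1], 2), -3.54)  # reported RE
  expect_equal(out$relative_error[2], 0)
  expect_equal(out$relative_error[3], 100 * (927.41 - 843.1) / 843.1)
  back <- read.csv(path)
  expect_equal(back$predicted, preds$predicted)
  expect_error(write_predictions(ds, data.frame(
    name = "nonesuch", phase = "DB-210", model = "individual",
    predicted = 1), path), regexp = "nonesuch", class = "hq_data_error")
})
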