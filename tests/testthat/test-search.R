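# The scans are exercised on small synthetic datasets; the bundled-data
# protocol runs live in the acceptance suite.

test_that("stage-1 scan returns one ranked row per flag-set candidate", {
  syn <- generate_synthetic(synthetic_config(n_compounds = 16, seed = 21))
  res <- scan_fd(syn, "synthetic",
                 fd_candidates = list("A", "DA", c("A", "B")),
                 fs = c(2, 4), hl_set = c(97, 151), max_pcs = 4)
  expect_s3_class(res, "hq_search")
  expect_equal(nrow(res), 3L)
  expect_true(all(diff(res$q2cv) <= 1e-12))  # descending
  expect_true(all(res$hl %in% c(97, 151)))
  single <- scan_fd(syn, "synthetic", fd_candidates = list("A"),
                    fs = c(2, 4), hl_set = 97, max_pcs = 3)
  expect_equal(nrow(single), 1L)
  expect_error(scan_fd(syn, "synthetic", fd_candidates = list()),
               class = "hq_config_error")
})

test_that("stage-2 scan validates, deduplicates and ranks windows", {
  syn <- generate_synthetic(synthetic_config(n_compounds = 16, seed = 22))
  expect_warning(
    res <- scan_fs(syn, "synthetic", fd = "A",
                   fs_candidates = list(c(1, 3), c(2, 4), c(1, 3)),
                   hl_set = 97, max_pcs = 3),
    regexp = "duplicate")
  expect_equal(nrow(res), 2L)
  expect_warning(
    res2 <- scan_fs(syn, "synthetic", fd = "A",
                    fs_candidates = list(c(1, 3), c(5, 2)),
                    hl_set = 97, max_pcs = 3),
    regexp = "max < min")
  expect_equal(nrow(res2), 1L)
  expect_error(
    suppressWarnings(scan_fs(syn, "synthetic",
                             fs_candidates = list(c(5, 2)))),
    class = "hq_config_error")
})

test_that("ranking is deterministic with the documented tie-breaks", {
  df <- data.frame(fd = c("DA", "A", "DA", "B"),
                   fs_min = 1, fs_max = 4,
                   hl = c(151L, 97L, 97L, 97L),
                   pcs = c(5L, 4L, 4L, 2L),
                   q2cv = c(0.92, 0.92, 0.92, 0.95),
                   r2 = 0.99, see = 10)
  df$spec <- as.list(1:4)
  ranked <- rank_models(structure(df, class = c("hq_search", "data.frame")))
  # highest q2 first; then fewer pcs; then smaller hl; then fd string
  expect_equal(ranked$fd, c("B", "A", "DA", "DA"))
  expect_equal(ranked$hl, c(97L, 97L, 97L, 151L))
  empty <- rank_models(structure(df[0, ], class = c("hq_search", "data.frame")))
  expect_equal(nrow(empty), 0L)
})

test_that("identical inputs give identical search results across runs", {
  syn <- generate_synthetic(synthetic_config(n_compounds = 14, seed = 23))
  r1 <- scan_fd(syn, "synthetic", fd_candidates = list("A", "DA"),
                fs = c(1, 3), hl_set = c(97, 151), max_pcs = 3)
  r2 <- scan_fd(syn, "synthetic", fd_candidates = list("A", "DA"),
                fs = c(1, 3), hl_set = c(97, 151), max_pcs = 3)
  expect_identical(r1$q2cv, r2$q2cv)
  expect_identical(r1$hl, r2$hl)
})

test_that("windows containing the informative fragment size win", {
  # the property is driven by heavy-atom count, i.e. by size-1 fragments:
  # windows that include size 1 should usually outrank those that do not
  wins <- 0L
  for (s in 1:10) {
    syn <- generate_synthetic(synthetic_config(
      n_compounds = 16, noise_sd = 10, seed = 300 + s))
    res <- scan_fs(syn, "synthetic", fd = "A",
                   fs_candidates = list(c(1, 3), c(4, 7)),
                   hl_set = 97, max_pcs = 3)
    if (res$fs_min[1] == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("flag sets that see the informative label rank at the top", {
  # skeleton pairs identical up to an O-for-C swap, all bonds single: with
  # bond labels only the pair members are indistinguishable, with element
  # labels the oxygen-dependent property is exactly recoverable
  skel <- c("CCCC", "CCCCC", "CC(C)CC", "CCCCCC", "CC(C)CCC", "CCCCCCC")
  smiles <- c(skel, sub("C$", "O", skel))
  n_o <- c(rep(0, 6), rep(1, 6))
  n_heavy <- nchar(gsub("[^CO]", "", smiles))
  prop <- 300 + 100 * n_heavy + 250 * n_o
  ds <- hq_dataset(
    data.frame(name = sprintf("m%02d", seq_along(smiles)), smiles = smiles,
               group = rep(c("I", "I", "II"), 4)),
    matrix(prop, ncol = 1, dimnames = list(NULL, "synthetic")))
  res <- scan_fd(ds, "synthetic", fd_candidates = list("B", "A"),
                 fs = c(1, 3), hl_set = c(97, 151), max_pcs = 3)
  expect_equal(res$fd[1], "A")
  expect_gt(res$q2cv[1], res$q2cv[2] + 0.05)
})
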