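# Shared small trained components for ensemble tests; built once per run.
ens_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tr <- generate_fragments(120, 120, 15, default_motif(2), seed = 61)
    te <- generate_fragments(80, 80, 15, default_motif(2), seed = 62)
    cfg <- cnn_config(epochs = 6L)
    comps <- list(
      ONEHOT = fit_component(tr$fragment, tr$label, "ONEHOT", "CNN",
                             stack_folds = 3L, seed = 7L, config = cfg),
      AAINDEX = fit_component(tr$fragment, tr$label, "AAINDEX", "CNN",
                              stack_folds = 3L, seed = 7L, config = cfg,
                              k_properties = 20L),
      PSSM = fit_component(tr$fragment, tr$label, "PSSM", "CNN",
                           stack_folds = 3L, seed = 7L, config = cfg),
      AAC = fit_component(tr$fragment, tr$label, "AAC", "RF",
                          stack_folds = 3L, seed = 7L, n_trees = 150L),
      PAAC = fit_component(tr$fragment, tr$label, "PAAC", "RF",
                           stack_folds = 3L, seed = 7L, n_trees = 150L))
    cache <<- list(tr = tr, te = te, comps = comps)
    cache
  }
})

test_that("the mammalian NN stack has the documented meta-input width", {
  fx <- ens_fixture()
  ens <- build_mammal_ensemble(
    fx$comps$ONEHOT, fx$comps$AAINDEX, fx$comps$PSSM,
    encode_fragments(fx$tr$fragment, "AAC"),
    encode_fragments(fx$tr$fragment, "PAAC"),
    fx$tr$label, aac_window = 15L, paac_window = 15L, seed = 7L)
  expect_equal(ens$cutoff, 0.046)  # published mammalian cutoff
  # meta width = sum of penultimate widths + 21 (AAC) + 34 (PAAC)
  expect_equal(ens$meta$n[1], 3 * 64 + 21 + 34)
  pr <- predict(ens, fx$te$fragment)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_identical(pr$call, as.integer(pr$score >= 0.046))
  expect_identical(colnames(pr$component_scores),
                   c("onehot", "aaindex", "pssm"))
  # stacking tracks the strongest component
  best <- max(vapply(fx$comps[1:3], function(cmp)
    roc_auc(fx$te$label, predict(cmp, fx$te$fragment)), numeric(1)))
  expect_gte(roc_auc(fx$te$label, pr$score), best - 0.05)
  # leakage sanity: shuffled held-out labels give a null AUC
  set.seed(1)
  expect_lt(abs(roc_auc(sample(fx$te$label), pr$score) - 0.5), 0.1)
  expect_error(build_mammal_ensemble(fx$comps$AAC, fx$comps$AAINDEX,
                                     fx$comps$PSSM, NULL, NULL, fx$tr$label,
                                     15L, 15L), "CNN")
})

test_that("the plant SVM stack aggregates five component probabilities", {
  fx <- ens_fixture()
  ens <- build_plant_ensemble(fx$comps, fx$tr$label, seed = 7L)
  expect_equal(ens$cutoff, 0.195)  # published plant cutoff
  expect_equal(ncol(ens$meta$SV), 5L)  # 5-dim meta input
  pr <- predict(ens, fx$te$fragment)
  best <- max(vapply(fx$comps, function(cmp)
    roc_auc(fx$te$label, predict(cmp, fx$te$fragment)), numeric(1)))
  expect_gte(roc_auc(fx$te$label, pr$score), best - 0.05)
  expect_error(build_plant_ensemble(fx$comps[1:4], fx$tr$label),
               "exactly 5")
})

test_that("majority voting follows the strict-majority rule", {
  expect_equal(majority_vote(c(1, 1, 0)), 1L)
  expect_equal(majority_vote(c(0, 0, 1, 1)), 0L)  # even tie is negative
  expect_equal(majority_vote(c(1, 1, 1)), 1L)
  expect_equal(majority_vote(c(0, 0, 0)), 0L)
  m <- rbind(c(1, 1, 0), c(0, 0, 1), c(1, 1, 1))
  expect_equal(majority_vote(m), c(1L, 0L, 1L))
  # identical components vote exactly like the single component
  fx <- ens_fixture()
  trio <- build_majority_ensemble(fx$comps[c("AAC", "AAC", "AAC")])
  pr <- predict(trio, fx$te$fragment)
  single <- as.integer(predict(fx$comps$AAC, fx$te$fragment) >= 0.5)
  expect_identical(pr$call, single)
})

test_that("whole-protein prediction scores every lysine at each window", {
  fx <- ens_fixture()
  ens <- build_plant_ensemble(fx$comps, fx$tr$label, seed = 7L)
  seq3 <- paste0(paste(rep("A", 10), collapse = ""), "K",
                 paste(rep("E", 10), collapse = ""), "K",
                 paste(rep("G", 10), collapse = ""), "K",
                 paste(rep("S", 10), collapse = ""))
  pr <- predict_protein(ens, seq3, "prot1")
  expect_equal(nrow(pr), 3L)
  expect_identical(pr$position, enumerate_lysines(seq3))
  expect_true(all(grepl("^score_", names(pr)[5:9])))
  expect_identical(pr$call, as.integer(pr$score >= 0.195))
  # deterministic for a fixed fitted ensemble
  expect_identical(pr, predict_protein(ens, seq3, "prot1"))
  expect_warning(none <- predict_protein(ens, "AAAA", "p0"), "no lysine")
  expect_equal(nrow(none), 0L)
  # threshold semantics: score at the cutoff is a positive call
  expect_equal(confusion(1, 0.05, 0.046)$TP, 1)
})

test_that("ensemble bundles survive a save/load round trip", {
  fx <- ens_fixture()
  ens <- build_plant_ensemble(fx$comps, fx$tr$label, seed = 7L)
  dir <- file.path(tempdir(), "bundle-test")
  save_ensemble(ens, dir, data_hash = "abc123")
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$aggregator, "SVM_STACK")
  expect_equal(mf$cutoff, 0.195)
  expect_equal(length(mf$components), 5L)
  ens2 <- load_ensemble(dir)
  p1 <- predict(ens, fx$te$fragment)$score
  p2 <- predict(ens2, fx$te$fragment)$score
  expect_identical(p1, p2)
  expect_error(load_ensemble(tempdir()), "not an ensemble bundle")
})
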