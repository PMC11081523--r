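# Counterfactual generation: validity, locality, ranking and fragment
# overlap accounting.

test_that("perturbation produces valid, distinct, seed-stable variants", {
  base <- "Cc1ccc2[nH]c(C(=O)NCC)cc2c1"
  v1 <- perturb_molecule(base, n_samples = 150, seed = 11)
  v2 <- perturb_molecule(base, n_samples = 150, seed = 11)
  expect_identical(v1, v2)
  expect_gt(length(v1), 20)
  expect_false(canonical_smiles(base) %in% v1)
  expect_false(anyDuplicated(v1) > 0)
  expect_false(anyNA(canonical_smiles(v1)))  # every variant parses
  expect_identical(perturb_molecule(base, n_samples = 0), character(0))
  expect_error(perturb_molecule("junk"), "invalid")
})

test_that("variants stay local: closer to the base than random library molecules", {
  base <- "Cc1ccc2[nH]c(C(=O)NCC)cc2c1"
  v <- perturb_molecule(base, n_samples = 100, seed = 3)
  sb <- small_bench()
  cfg <- featurizer_config()
  fb <- ecfp(base, cfg)
  sim_v <- mean(fragfocus:::tanimoto_matrix(ecfp(v, cfg), fb))
  sim_r <- mean(fragfocus:::tanimoto_matrix(ecfp(sb$ds$smiles[1:60], cfg), fb))
  expect_gt(sim_v, sim_r)
})

test_that("counterfactual search matches the exhaustive oracle and ranks by similarity", {
  sb <- small_bench()
  lib <- sb$lib
  cfg <- featurizer_config()
  # transparent model: positive iff the compound contains >= 1 library
  # fragment of 6+ atoms (a function model keeps the oracle trivial)
  big <- library_of_size(lib, min(which(lib$fragments$n_atoms >= 6)))
  model_fn <- function(X) X[, ncol(X)] >= 1
  base <- sb$ds$smiles[1]  # an active: matches fragments
  cf <- find_counterfactuals(model_fn, base, big, n_samples = 300,
                             top_k = 5, seed = 9, config = cfg)
  # oracle: regenerate the same pool, flip-filter and rank by hand
  pool <- perturb_molecule(base, n_samples = 300, seed = 9)
  Xp <- featurize(pool, big, cfg)
  flips <- which(!model_fn(Xp))
  skip_if(length(flips) == 0, "no flips in sampled neighbourhood")
  sims <- as.vector(fragfocus:::tanimoto_matrix(
    Xp[flips, seq_len(cfg$n_bits), drop = FALSE],
    featurize(base, big, cfg)[, seq_len(cfg$n_bits), drop = FALSE]))
  ord <- order(-sims, pool[flips])
  expected <- pool[flips][ord][seq_len(min(5, length(flips)))]
  expect_identical(cf$variant_smiles, expected)
  expect_true(all(diff(cf$similarity_to_base) <= 0))
  expect_true(all(cf$variant_positive != cf$base_positive))
})

test_that("a constant model yields an empty result with a warning", {
  sb <- small_bench()
  always_yes <- function(X) rep(TRUE, nrow(X))
  expect_warning(
    cf <- find_counterfactuals(always_yes, "c1ccccc1CCO", sb$lib,
                               n_samples = 50, seed = 2),
    "no counterfactual")
  expect_equal(nrow(cf), 0)
})

test_that("every reported counterfactual truly flips the ensemble when re-scored", {
  sb <- small_bench()
  sm <- small_model()
  base <- sb$ds$smiles[which(sb$ds$label == "active")[1]]
  cf <- suppressWarnings(
    find_counterfactuals(sm$ens, base, sb$lib, n_samples = 150,
                         top_k = 5, seed = 4))
  skip_if(nrow(cf) == 0, "no flip found in sampled neighbourhood")
  Xv <- featurize(cf$variant_smiles, sb$lib)
  rescored <- predict(sm$ens, Xv, type = "consensus")
  expect_equal(as.logical(rescored), cf$variant_positive)
  expect_true(all(cf$votes_variant >= 0 & cf$votes_variant <= 6))
})

test_that("fragment overlap annotation balances with the base match count", {
  sb <- small_bench()
  base <- sb$ds$smiles[which(sb$ds$label == "active")[1]]
  variant <- perturb_molecule(base, n_samples = 5, seed = 6)[1]
  ann <- annotate_fragment_overlap(base, variant, sb$lib)
  expect_equal(nrow(ann), length(sb$lib))
  base_count <- fragment_match_count(base, sb$lib)
  expect_equal(sum(ann$status %in% c("retained", "lost")), base_count)
  expect_true(all(ann$status %in% c("retained", "lost", "gained", "absent")))
  # a variant identical to the base retains everything it matches
  ann2 <- annotate_fragment_overlap(base, base, sb$lib)
  expect_equal(sum(ann2$status == "retained"), base_count)
  expect_equal(sum(ann2$status %in% c("lost", "gained")), 0)
})
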