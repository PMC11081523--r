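# PAINS alerts and QED druglikeness filtering.
#
# Reference values in this file were computed with an independent
# implementation (RDKit: FilterCatalog for PAINS decisions, QED.qed and
# QED.properties for druglikeness) and frozen.

test_that("PAINS catalogue flags known interference scaffolds and spares clean ones", {
  # quinone / rhodanine / catechol match the same alerts as the reference
  # filter catalogue; methane and benzene match none of the 480 patterns
  hits <- flag_pains(c("O=C1C=CC(=O)C=C1", "O=C1CSC(=S)N1C",
                       "Oc1ccccc1O", "C", "c1ccccc1"),
                     return_ids = TRUE)
  expect_true("quinone_A(370)" %in% hits[[1]])
  expect_true("rhod_sat_A(33)" %in% hits[[2]])
  expect_true("catechol_A(92)" %in% hits[[3]])
  expect_length(hits[[4]], 0)
  expect_length(hits[[5]], 0)
  expect_identical(flag_pains(c("O=C1C=CC(=O)C=C1", "C")), c(TRUE, FALSE))
  expect_error(flag_pains("notasmiles"), "invalid")
})

test_that("QED desirability scoring reproduces the reference implementation", {
  # stage 1: the desirability model itself, fed reference property values
  # (descriptor backends eliminated) must match reference QED to 1e-6
  props <- data.frame(
    MW     = c(46.0690, 94.1130, 151.1650, 206.2850, 255.3610),
    ALOGP  = c(-0.0014, 1.3922, 1.3506, 3.0732, 3.3542),
    HBA    = c(1, 1, 2, 2, 2),
    HBD    = c(1, 1, 2, 1, 0),
    PSA    = c(20.23, 20.23, 49.33, 37.30, 12.47),
    ROTB   = c(0, 0, 1, 4, 6),
    AROM   = c(0, 1, 1, 1, 2),
    ALERTS = c(0, 0, 1, 0, 0))
  ref <- c(0.406808, 0.514730, 0.595026, 0.821600, 0.784550)
  expect_equal(qed_from_properties(props), ref, tolerance = 1e-6)

  # stage 2: end-to-end on pure hydrocarbons, where all descriptor backends
  # agree exactly, the full computation matches the reference to 1e-3
  expect_equal(compute_qed(c("c1ccccc1", "C", "CCCCCCCC")),
               c(0.4426284, 0.3597849, 0.4806106), tolerance = 1e-3)

  # range and invariance contracts
  q <- compute_qed(c("CC(=O)Nc1ccc(O)cc1", "CN1CCC[C@H]1c1cccnc1"))
  expect_true(all(q > 0 & q < 1))
  expect_equal(compute_qed("C1=CC=CC=C1O"), compute_qed("Oc1ccccc1"))
})

test_that("heteroatom descriptor counts match the reference definitions", {
  # HBA/HBD/ROTB/AROM/ALERTS frozen from the reference implementation
  p <- qed_properties(c("O=C(O)c1ccccc1OC(C)=O",   # aspirin
                        "CN(C)CCOC(c1ccccc1)c1ccccc1",
                        "O=[N+]([O-])c1ccccc1",
                        "c1ccc2[nH]ccc2c1"))
  expect_equal(p$HBA, c(4, 2, 2, 0))
  expect_equal(p$HBD, c(1, 0, 0, 1))
  expect_equal(p$ROTB, c(2, 6, 1, 0))
  expect_equal(p$AROM, c(1, 2, 1, 2))
  expect_equal(p$ALERTS, c(2, 0, 2, 0))
})

test_that("prefilters remove PAINS first, then low QED, with exact accounting", {
  smi <- c("O=C1C=CC(=O)C=C1",  # PAINS (quinone), whatever its QED
           "c1ccccc1",          # clean, QED 0.44
           "C",                 # clean, QED 0.36
           "CC(C)Cc1ccc(cc1)C(C)C(=O)O")  # clean, QED 0.82
  ds <- mol_dataset(smi, id = c("q", "bz", "me", "ibu"))
  res <- apply_prefilters(ds, qed_max_removed = 0.40)
  expect_equal(res$report$n_input, 4)
  expect_equal(res$report$n_pains_removed, 1)
  expect_equal(res$report$n_qed_removed, 1)   # methane only
  expect_equal(res$report$n_kept, 2)
  expect_setequal(res$dataset$id, c("bz", "ibu"))
  with(res$report, expect_equal(n_input, n_pains_removed + n_qed_removed + n_kept))

  # the QED threshold is inclusive: a compound at exactly the threshold is
  # removed
  q_bz <- compute_qed("c1ccccc1")
  res2 <- apply_prefilters(mol_dataset("c1ccccc1"), qed_max_removed = q_bz)
  expect_equal(res2$report$n_qed_removed, 1)
  expect_equal(res2$report$n_kept, 0)

  # idempotence: filtering a filtered set removes nothing
  res3 <- apply_prefilters(res$dataset, qed_max_removed = 0.40)
  expect_equal(res3$report$n_kept, nrow(res$dataset))
  expect_equal(res3$report$n_pains_removed + res3$report$n_qed_removed, 0)
})
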