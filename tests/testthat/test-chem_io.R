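# Reading, canonicalization, deduplication and potency labelling.

test_that("canonicalization is idempotent and invariant to SMILES spelling", {
  spellings <- c("C1=CC=CC=C1", "c1ccccc1", "OCC", "C(O)C",
                 "CC(=O)Nc1ccc(O)cc1", "O=C(C)Nc1ccc(O)cc1")
  canon <- canonical_smiles(spellings)
  expect_false(anyNA(canon))
  expect_identical(canonical_smiles(canon), canon)
  expect_identical(canon[1], canon[2])
  expect_identical(canon[3], canon[4])
  expect_identical(canon[5], canon[6])
  expect_true(is.na(canonical_smiles("not_a_molecule")))
})

test_that("bioactivity tables are read, invalid rows dropped and counted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,pot,id",
               "C1=CC=CC=C1,100,a",
               "xyzzy,50,b",
               "OCC,200,c"), f)
  expect_warning(ds <- read_bioactivity_table(f, smiles_col = "smiles",
                                              potency_col = "pot",
                                              id_col = "id"),
                 "unparseable")
  expect_equal(nrow(ds), 2)
  expect_equal(attr(ds, "n_rejected"), 1)
  expect_identical(ds$smiles[1], canonical_smiles("C1=CC=CC=C1"))
  expect_equal(ds$potency_nm, c(100, 200))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,smiles", "CC,CC"), f2)
  expect_error(read_bioactivity_table(f2), "duplicate")

  expect_error(read_bioactivity_table(withr::local_tempfile()), "not found")
})

test_that("deduplication keeps the most potent record per structure", {
  ds <- mol_dataset(smiles = c("c1ccccc1", "C1=CC=CC=C1", "OCC", "OCC"),
                    id = c("a", "b", "c", "d"),
                    potency_nm = c(100, 50, 100, NA))
  out <- deduplicate_keep_most_potent(ds)
  expect_equal(nrow(out), 2)
  # benzene group keeps 50 nM; ethanol group keeps the record with potency
  expect_setequal(out$id, c("b", "c"))
  expect_equal(sort(out$potency_nm), c(50, 100))
  # distinct structures at equal potency are both kept
  ds2 <- mol_dataset(smiles = c("c1ccccc1", "OCC"), potency_nm = c(100, 100))
  expect_equal(nrow(deduplicate_keep_most_potent(ds2)), 2)
  # dedup never grows the set; surviving structures = distinct inputs
  expect_setequal(unique(ds$smiles), out$smiles)
  # empty in, empty out
  empty <- mol_dataset(character(0))
  expect_equal(nrow(deduplicate_keep_most_potent(empty)), 0)
})

test_that("potency labelling uses a strict 10 uM cutoff, boundary inactive", {
  ds <- mol_dataset(smiles = c("CCO", "CCN", "CCC", "CCCC"),
                    potency_nm = c(500, 10000, 25000, 9999.999),
                    potency_type = c("IC50", "Kd", "EC50", "IC50"))
  out <- assign_labels(ds)
  expect_identical(out$label, c("active", "inactive", "inactive", "active"))
  # labels partition the dataset
  expect_equal(sum(out$label == "active") + sum(out$label == "inactive"),
               nrow(out))
  # percent-inhibition records are excluded from cutoff labelling
  ds2 <- mol_dataset(smiles = c("CCO", "CCN"), potency_nm = c(50, 500),
                     potency_type = c("percent_inhibition", "IC50"))
  out2 <- assign_labels(ds2)
  expect_true(is.na(out2$label[1]))
  expect_identical(out2$label[2], "active")
  # a record without potency is an error naming the id
  ds3 <- mol_dataset(smiles = c("CCO", "CCN"), id = c("ok", "bad"),
                     potency_nm = c(100, NA))
  expect_error(assign_labels(ds3), "bad")
})

test_that("dataset CSV round trip is lossless, including empty datasets", {
  ds <- assign_labels(mol_dataset(
    smiles = c("c1ccccc1", "CCO"), id = c("x", "y"),
    potency_nm = c(120.5, 30000), potency_type = c("IC50", "Kd"),
    name = "roundtrip"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_equal(as.data.frame(back), as.data.frame(ds), ignore_attr = TRUE)
  expect_identical(attr(back, "name"), "roundtrip")

  empty <- mol_dataset(character(0), name = "none")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(empty, f2)
  expect_equal(nrow(read_dataset(f2)), 0)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("garbage", f3)
  expect_error(read_dataset(f3), "not a dataset")
})

test_that("SMILES files round trip through read_smi / write_smi", {
  ds <- mol_dataset(c("c1ccccc1", "CCO"), id = c("b1", "e1"))
  f <- withr::local_tempfile(fileext = ".smi")
  write_smi(ds, f)
  back <- read_smi(f)
  expect_identical(back$smiles, ds$smiles)
  expect_identical(back$id, ds$id)
})
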