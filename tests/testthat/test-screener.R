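# Library screening, similarity/diversity analyses and the fragment-match
# activity profile.

test_that("screening is chunk-invariant and thresholds nest", {
  sb <- small_bench()
  sm <- small_model()
  stream <- sb$ds  # reuse benchmark compounds as a pseudo-library
  r1 <- screen_library(stream, sb$lib, sm$ens, threshold = 6, chunk_size = 7)
  r2 <- screen_library(stream, sb$lib, sm$ens, threshold = 6, chunk_size = 1000)
  expect_identical(r1$focused$smiles, r2$focused$smiles)
  expect_identical(r1$report$vote_histogram, r2$report$vote_histogram)

  # file-based streaming gives the same result as in-memory screening
  f <- withr::local_tempfile(fileext = ".smi")
  write_smi(stream, f)
  r3 <- screen_library(f, sb$lib, sm$ens, threshold = 6, chunk_size = 13)
  expect_identical(r3$focused$smiles, r1$focused$smiles)

  # threshold-6 passes are a subset of threshold-4 passes
  r4 <- screen_library(stream, sb$lib, sm$ens, threshold = 4)
  expect_true(all(r1$focused$smiles %in% r4$focused$smiles))

  # report accounting
  rep <- r1$report
  expect_equal(sum(rep$vote_histogram), rep$n_scored)
  expect_equal(rep$n_passed, nrow(r1$focused))
  expect_equal(rep$reduction_fraction, 1 - rep$n_passed / rep$n_scored)
  expect_equal(rep$per_threshold$n_passed[6], rep$n_passed)
  expect_true(all(diff(rep$per_threshold$n_passed) <= 0))
})

test_that("corrupt library records are skipped and counted", {
  sb <- small_bench()
  sm <- small_model()
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 ok1", "xyzzy bad", "CCO ok2"), f)
  r <- screen_library(f, sb$lib, sm$ens, threshold = 1)
  expect_equal(r$report$n_input, 3)
  expect_equal(r$report$n_skipped, 1)
  expect_equal(r$report$n_scored, 2)
})

test_that("similarity matrices are symmetric, unit-diagonal and exact", {
  ds <- mol_dataset(c("c1ccccc1", "Cc1ccccc1", "CCO", "CCCO"),
                    id = c("bz", "tol", "eth", "prop"))
  m <- similarity_matrix(ds)
  expect_equal(dim(m), c(4, 4))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m, t(m))
  # brute-force recomputation with the scalar tanimoto
  fp <- ecfp(ds)
  for (i in 1:4) for (j in 1:4)
    expect_equal(unname(m[i, j]), tanimoto(fp[i, ], fp[j, ]))
  # structurally unrelated molecules share no environment
  m2 <- similarity_matrix(mol_dataset(c("c1ccccc1", "O")))
  expect_equal(unname(m2[1, 2]), 0)
})

test_that("cluster representatives are one per cluster and seeded", {
  sb <- small_bench()
  reps <- select_cluster_representatives(sb$ds, n_clusters = 10, seed = 3)
  expect_equal(nrow(reps), 10)
  expect_equal(reps$cluster, 1:10)
  reps2 <- select_cluster_representatives(sb$ds, n_clusters = 10, seed = 3)
  expect_identical(reps$smiles, reps2$smiles)
  # n = |ds| returns every molecule
  sub <- sb$ds[1:12, ]
  class(sub) <- c("mol_dataset", "data.frame")
  all12 <- select_cluster_representatives(sub, n_clusters = 12)
  expect_setequal(all12$smiles, sub$smiles)
  expect_error(select_cluster_representatives(sub, n_clusters = 50),
               "at least")
})

test_that("chemical-space projection is deterministic and separates families", {
  fam1 <- mol_dataset(paste0("c1ccc2c(c1)cc(", c("C", "CC", "CCC", "CO", "CN"), ")[nH]2"),
                      id = paste0("a", 1:5))
  fam2 <- mol_dataset(paste0("C1CCC(", c("C", "CC", "CCC", "CO", "CN"), ")CC1"),
                      id = paste0("b", 1:5))
  pr <- chemical_space_projection(list(indoles = fam1, hexanes = fam2))
  expect_equal(nrow(pr), 10)
  expect_setequal(unique(pr$set), c("indoles", "hexanes"))
  pr2 <- chemical_space_projection(list(indoles = fam1, hexanes = fam2))
  expect_equal(pr$PC1, pr2$PC1)
  # duplicates map to identical coordinates
  dup <- mol_dataset(c("CCO", "OCC", "c1ccccc1"), id = c("x", "y", "z"))
  prd <- chemical_space_projection(dup)
  expect_equal(prd$PC1[1], prd$PC1[2])
  expect_equal(prd$PC2[1], prd$PC2[2])
  # separated scaffold families: between-centroid distance beats the mean
  # within-family spread
  c1 <- colMeans(pr[pr$set == "indoles", c("PC1", "PC2")])
  c2 <- colMeans(pr[pr$set == "hexanes", c("PC1", "PC2")])
  between <- sqrt(sum((c1 - c2)^2))
  within <- mean(c(
    sqrt(rowSums(sweep(pr[pr$set == "indoles", c("PC1", "PC2")], 2, c1)^2)),
    sqrt(rowSums(sweep(pr[pr$set == "hexanes", c("PC1", "PC2")], 2, c2)^2))))
  expect_gt(between, within)
})

test_that("fragment-match profiles account for every compound", {
  sb <- small_bench()
  prof <- fragment_match_label_profile(sb$ds, sb$lib)
  expect_equal(sum(prof$n), nrow(sb$ds))
  expect_true(all(prof$active_fraction >= 0 & prof$active_fraction <= 1,
                  na.rm = TRUE))
  expect_equal(prof$n_active + prof$n_inactive, prof$n)
  # actives carry the planted scaffolds, so the top bins should be purer
  # than the bottom bin
  nz <- which(prof$n > 0)
  expect_gte(prof$active_fraction[max(nz)], prof$active_fraction[min(nz)])
})
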