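# Fragment mining: support semantics, ring completeness, oracle
# equivalence on small graphs, and library persistence.

test_that("support is the fraction of molecules containing an embedding", {
  ds <- mol_dataset(c("Oc1ccccc1", "OCC"))           # phenol, ethanol
  expect_equal(compute_support("c1ccccc1", ds), 0.5)
  ds2 <- mol_dataset(c("c1ccncc1", "c1ccncc1C", "Cc1ccncc1C"))
  expect_equal(compute_support("c1ccncc1", ds2), 1.0)
  expect_error(compute_support("c1ccccc1", mol_dataset(character(0))),
               "empty")
})

test_that("support thresholds are inclusive at both boundaries", {
  # 200 actives: pyridine and furan in exactly 2 (1.0%); thiophene in 1 (0.5%)
  act <- mol_dataset(c(rep("CCO", 194), "c1ccncc1", "c1ccncc1C",
                       "c1ccoc1C", "c1ccoc1CC",
                       "c1ccsc1", "CCCCN"))
  ina <- mol_dataset(c(rep("CCCCCC", 8), "c1ccoc1", "c1ccoc1C"))  # furan 20%
  lib <- mine_fragments(act, ina,
                        mining_config(min_support_active = 0.01,
                                      max_support_inactive = 0.20,
                                      max_fragment_atoms = 8))
  has_frag <- function(lib, smi) {
    g <- fragfocus:::mol_graphs(smi)[[1]]
    fragfocus:::.cpp_canonical_code(list(g)) %in% lib$codes
  }
  expect_true(has_frag(lib, "c1ccncc1"))    # exactly at min support: kept
  expect_false(has_frag(lib, "c1ccsc1"))    # below min support: absent
  expect_true(has_frag(lib, "c1ccoc1"))     # exactly at max inactive: kept
  i <- which(lib$codes == fragfocus:::.cpp_canonical_code(
    list(fragfocus:::mol_graphs("c1ccncc1")[[1]])))
  expect_equal(lib$fragments$support_active[i], 2 / 200)

  # 21% inactive support excludes regardless of active support
  ina2 <- mol_dataset(c(rep("CCCCCC", 79), rep("c1ccncc1CCCC", 21)))
  lib2 <- mine_fragments(act, ina2,
                         mining_config(min_support_active = 0.01,
                                       max_support_inactive = 0.20,
                                       max_fragment_atoms = 8))
  expect_false(has_frag(lib2, "c1ccncc1"))
})

test_that("mined fragments equal brute-force enumeration on random small sets", {
  # oracle equivalence over seeded random datasets of small molecules
  n_datasets <- 6
  for (s in seq_len(n_datasets)) {
    set.seed(100 + s)
    smi_a <- sample(ORACLE_POOL, sample(5:8, 1), replace = TRUE)
    smi_i <- sample(ORACLE_POOL, sample(4:6, 1), replace = TRUE)
    act <- suppressWarnings(mol_dataset(smi_a, id = paste0("a", seq_along(smi_a))))
    ina <- suppressWarnings(mol_dataset(smi_i, id = paste0("i", seq_along(smi_i))))
    min_s <- sample(c(0.2, 0.4, 0.6), 1)
    max_s <- sample(c(0.2, 0.5, 0.8), 1)
    lib <- mine_fragments(act, ina,
                          mining_config(min_support_active = min_s,
                                        max_support_inactive = max_s,
                                        max_fragment_atoms = 8))
    orc <- oracle_mine(fragfocus:::mol_graphs(act$smiles),
                       fragfocus:::mol_graphs(ina$smiles),
                       min_s, max_s, max_atoms = 8)
    expect_equal(nrow(lib$fragments), length(orc),
                 info = sprintf("seed %d: size mismatch", s))
    # bijection: every oracle fragment appears in the library with the
    # same supports (matching via the independent isomorphism test)
    lib_orc <- lapply(lib$graphs, function(g)
      orc_graph(g, seq_along(g$ba), seq_along(g$elem)))
    for (of in orc) {
      j <- which(vapply(lib_orc, function(lg)
        orc_isomorphic(of$graph, lg), TRUE))
      expect_length(j, 1)
      expect_equal(lib$fragments$support_active[j], of$support_active)
      expect_equal(lib$fragments$support_inactive[j], of$support_inactive)
    }
  }
})

test_that("fragments never contain partial rings and supports are anti-monotone", {
  sb <- small_bench()
  lib <- sb$lib
  # structural ring completeness: in each fragment graph, every edge that
  # lies on a cycle of the fragment has a minimal cycle, and no fragment
  # edge pair closes an incomplete ring (verified via the oracle helper)
  for (g in lib$graphs[seq_len(min(50, length(lib$graphs)))]) {
    ne <- length(g$ba)
    if (ne == 0) next
    ring_cache <- lapply(seq_len(ne), function(e) orc_min_rings_through(g, e))
    expect_true(orc_ring_complete(g, seq_len(ne), ring_cache))
  }
  # anti-monotonicity: single-atom sub-fragments have support >= fragment
  atom_support <- function(elem, arom, ds) {
    g <- list(elem = elem, charge = 0L, arom = arom,
              ba = integer(0), bb = integer(0), bo = integer(0),
              barom = logical(0))
    compute_support(g, ds)
  }
  some <- which(lib$fragments$n_atoms >= 3)[1:5]
  some <- some[!is.na(some)]
  for (j in some) {
    g <- lib$graphs[[j]]
    sa <- lib$fragments$support_active[j]
    for (v in seq_len(min(3, length(g$elem)))) {
      expect_gte(atom_support(g$elem[v], g$arom[v], sb$act), sa)
    }
  }
})

test_that("tightening the thresholds never adds fragments", {
  sb <- small_bench()
  cfg <- mining_config(max_fragment_atoms = 12)
  lib <- sb$lib
  stricter_a <- mine_fragments(sb$act, sb$ina,
                               mining_config(min_support_active = 0.3,
                                             max_fragment_atoms = 12))
  expect_true(all(stricter_a$codes %in% lib$codes))
  stricter_i <- mine_fragments(sb$act, sb$ina,
                               mining_config(max_support_inactive = 0.05,
                                             max_fragment_atoms = 12))
  expect_true(all(stricter_i$codes %in% lib$codes))
})

test_that("planted scaffolds are recovered from the synthetic benchmark", {
  sb <- small_bench()
  for (scaf in sb$bm$scaffolds) {
    g <- fragfocus:::mol_graphs(scaf)[[1]]
    code <- fragfocus:::.cpp_canonical_code(list(g))
    expect_true(code %in% sb$lib$codes, info = scaf)
  }
})

test_that("fragment libraries round trip losslessly in order", {
  lib <- small_bench()$lib
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_library(lib, f)
  back <- read_fragment_library(f)
  expect_identical(back$fragments$smiles, lib$fragments$smiles)
  expect_equal(back$fragments$support_active, lib$fragments$support_active)
  expect_equal(back$fragments$support_inactive, lib$fragments$support_inactive)
  expect_identical(back$codes, lib$codes)
  expect_equal(back$config$min_support_active, lib$config$min_support_active)

  # duplicate fragment lines are rejected
  lines <- readLines(f)
  writeLines(c(lines, lines[5]), f)
  expect_error(read_fragment_library(f), "duplicate")

  # empty library round trip
  empty <- fragfocus:::new_fragment_library(
    lib$fragments[0, ], list(), character(0), lib$config, "none")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_library(empty, f2)
  expect_equal(nrow(read_fragment_library(f2)$fragments), 0)
})
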