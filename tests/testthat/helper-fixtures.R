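# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

as_mol_dataset_subset <- function(ds, keep) {
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, name = attr(ds, "name"),
            class = c("mol_dataset", "data.frame"))
}

# a small labelled benchmark plus its mined library, reused across tests
small_bench <- function() {
  memo("small_bench", {
    bm <- generate_benchmark(benchmark_config(n_active = 25, n_inactive = 95,
                                              seed = 42))
    ds <- bm$dataset
    act <- as_mol_dataset_subset(ds, ds$label == "active")
    ina <- as_mol_dataset_subset(ds, ds$label == "inactive")
    lib <- mine_fragments(act, ina,
                          mining_config(max_fragment_atoms = 12))
    list(bm = bm, ds = ds, act = act, ina = ina, lib = lib)
  })
}

# a fragment library truncated/padded to exactly n fragments
library_of_size <- function(lib, n) {
  stopifnot(nrow(lib$fragments) >= n)
  fragfocus:::new_fragment_library(
    lib$fragments[seq_len(n), , drop = FALSE],
    lib$graphs[seq_len(n)], lib$codes[seq_len(n)],
    lib$config, lib$provenance)
}

# a small trained ensemble on the small benchmark (1-trial tuning: fast,
# deterministic, good enough for interface-level tests)
small_model <- function() {
  memo("small_model", {
    sb <- small_bench()
    X <- featurize(sb$ds, sb$lib)
    ens <- frag_ensemble(X, sb$ds$label,
                         tuning = tuning_config(n_trials = 1, cv_folds = 3,
                                                seed = 31))
    list(X = X, ens = ens)
  })
}

# simple separable 2-class feature data for ensemble tests
separable_data <- function(n = 60, p = 8, seed = 5) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + 6 * y   # wide margin on the first feature
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

# noisy overlapping 2-class data
noisy_data <- function(n = 120, p = 10, shift = 1.2, seed = 9) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.3)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1:3] <- x[, 1:3] + shift * y
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}
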