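# Seeded synthetic benchmark generator.  Emulates the statistical structure
# the pipeline assumes -- an imbalanced bioactivity set whose actives are
# enriched for a small number of planted ring scaffolds, a scaffold-free
# assumed-inactive pool, and a large screening stream -- without attempting
# real target chemistry.  Scaffolds and substituents come from a small
# curated list of valid templates, so every generated SMILES parses by
# construction.

# planted scaffolds: distinctive fused ring systems ({1}/{2} = substituent
# slots).  These are what the miner is expected to recover.
PLANTED_TEMPLATES <- c(
  indole       = "c1cc({2})c2c(c1)cc({1})[nH]2",
  quinazoline  = "c1ccc2nc({1})nc({2})c2c1",
  benzofuran   = "c1cc({2})c2c(c1)cc({1})o2",
  naphthyridine = "c1cc({2})c2ccc({1})nc2n1",
  indazole     = "c1cc({2})c2c(c1)c({1})n[nH]2")

# decoy scaffolds: common single rings that never contain a planted system
DECOY_TEMPLATES <- c(
  benzene     = "c1cc({2})cc({1})c1",
  pyridine    = "c1c({2})cnc({1})c1",
  pyrimidine  = "c1nc({2})nc({1})c1",
  thiophene   = "c1c({2})cc({1})s1",
  furan       = "c1c({2})cc({1})o1",
  cyclohexane = "C1CC({2})CC({1})C1",
  piperidine  = "C1CC({2})N({1})CC1",
  pyran       = "C1CC({2})OC({1})C1",
  pyrrolidine = "C1C({2})CN({1})C1",
  cyclopentane = "C1C({2})CC({1})C1")

SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "CO", "CCO", "CN", "CCN",
                  "OC", "OCC", "N(C)C", "F", "Cl", "Br", "C#N", "C(=O)C",
                  "C(=O)N", "C(=O)O", "CC(=O)N", "S(=O)(=O)C", "C(F)(F)F",
                  "CC#N", "CCF", "COC", "CNC(=O)C")

# polar/H-bonding groups over-represented among actives: besides the
# planted scaffold, active compounds share decoration chemistry, so
# scaffold-free actives still carry a learnable (weaker) signature
ACTIVE_SUBSTITUENTS <- c("C(=O)N", "CC(=O)N", "CNC(=O)C", "S(=O)(=O)C",
                         "C#N", "CC#N", "CCN", "N(C)C")

fill_template <- function(template, subs) {
  # replace each {k} slot: with a substituent branch or nothing
  for (k in seq_along(subs)) {
    pat <- paste0("({", k, "})")
    rep <- if (is.na(subs[k]) || !nzchar(subs[k])) "" else paste0("(", subs[k], ")")
    template <- sub(pat, rep, template, fixed = TRUE)
  }
  # drop any unfilled slots
  gsub("\\(\\{[0-9]+\\}\\)", "", template)
}

n_slots <- function(template) {
  length(gregexpr("\\{[0-9]+\\}", template)[[1]][
    gregexpr("\\{[0-9]+\\}", template)[[1]] > 0])
}

# one decorated molecule from a template; substituent draws use the
# current RNG stream.  `bias` is the probability that a substituent comes
# from the active-enriched pool rather than the common pool.
decorate <- function(template, bias = 0) {
  ns <- n_slots(template)
  subs <- character(ns)
  for (k in seq_len(ns)) {
    subs[k] <- if (stats::runif(1) < 0.85) {
      if (bias > 0 && stats::runif(1) < bias)
        sample(ACTIVE_SUBSTITUENTS, 1)
      else sample(SUBSTITUENTS, 1)
    } else ""
  }
  fill_template(template, subs)
}

# draw unique canonical structures from a template set
draw_unique <- function(templates, n, exclude = character(0), bias = 0) {
  out <- character(0)
  attempts <- 0L
  while (length(out) < n && attempts < 60L * n + 200L) {
    attempts <- attempts + 1L
    tpl <- templates[[sample.int(length(templates), 1)]]
    smi <- canonical_smiles(decorate(tpl, bias = bias))
    if (is.na(smi) || smi %in% out || smi %in% exclude) next
    out <- c(out, smi)
  }
  if (length(out) < n)
    stop("could not draw ", n, " unique structures (template space exhausted)")
  out
}

#' Benchmark configuration
#'
#' @param n_active,n_inactive intended class sizes (default 50 / 450, the
#'   1:9 imbalance of a typical bioactivity table).
#' @param n_scaffolds number of planted scaffolds (default 3, at most 5).
#' @param scaffold_penetrance fraction of actives built on a planted
#'   scaffold (default 0.9).
#' @param inactive_contamination fraction of inactives carrying a planted
#'   scaffold (default 0.02; must be below the penetrance).
#' @param potency_log_mean_active,potency_log_mean_inactive class potency
#'   means on the log10 nM scale (defaults 2.6 and 5.0, i.e. ~400 nM and
#'   ~100 uM).
#' @param potency_log_sd log10 potency spread within class (default 0.5
#'   active, 0.4 inactive).
#' @param substituent_bias probability that an active's substituent is
#'   drawn from the polar/H-bonding active-enriched pool rather than the
#'   common pool (default 0.7); actives share decoration chemistry as
#'   well as scaffolds, so scaffold-free actives remain learnable.
#' @param seed integer seed; everything the generator draws depends on it.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_active = 50L, n_inactive = 450L,
                             n_scaffolds = 3L, scaffold_penetrance = 0.9,
                             inactive_contamination = 0.02,
                             potency_log_mean_active = 2.6,
                             potency_log_mean_inactive = 5.0,
                             potency_log_sd = c(0.5, 0.4),
                             substituent_bias = 0.7,
                             seed = 1L) {
  stopifnot(n_active >= 1, n_inactive >= 1,
            n_scaffolds >= 1, n_scaffolds <= length(PLANTED_TEMPLATES))
  if (scaffold_penetrance <= inactive_contamination)
    stop("scaffold_penetrance must exceed inactive_contamination")
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 n_scaffolds = as.integer(n_scaffolds),
                 scaffold_penetrance = scaffold_penetrance,
                 inactive_contamination = inactive_contamination,
                 potency_log_mean_active = potency_log_mean_active,
                 potency_log_mean_inactive = potency_log_mean_inactive,
                 potency_log_sd = rep_len(potency_log_sd, 2),
                 substituent_bias = substituent_bias,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Generate a labelled synthetic benchmark
#'
#' Actives are planted-scaffold molecules (at the configured penetrance,
#' deterministic count); inactives are single-ring decoys except for a
#' small planted contamination.  Potencies are drawn log-normally per class
#' and labels are then re-derived through the 10,000 nM cutoff, so the
#' generator and [assign_labels()] agree by construction (a few
#' potency-crossover records may land on the other side, as in real
#' tables).
#'
#' @param config a [benchmark_config()].
#' @return list with `dataset` (a labelled [mol_dataset()]) and
#'   `scaffolds` (canonical SMILES of the planted scaffold ring systems).
#' @export
generate_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  set.seed(config$seed)
  planted <- PLANTED_TEMPLATES[seq_len(config$n_scaffolds)]
  scaffold_smiles <- canonical_smiles(
    vapply(planted, function(t) fill_template(t, rep("", 2)), ""))

  n_a <- config$n_active; n_i <- config$n_inactive
  n_a_planted <- ceiling(config$scaffold_penetrance * n_a)
  n_i_planted <- round(config$inactive_contamination * n_i)

  smi_a_planted <- draw_unique(planted, n_a_planted,
                               bias = config$substituent_bias)
  smi_a_decoy <- draw_unique(DECOY_TEMPLATES, n_a - n_a_planted,
                             exclude = smi_a_planted,
                             bias = config$substituent_bias)
  used <- c(smi_a_planted, smi_a_decoy)
  smi_i_planted <- draw_unique(planted, n_i_planted, exclude = used)
  used <- c(used, smi_i_planted)
  smi_i_decoy <- draw_unique(DECOY_TEMPLATES, n_i - n_i_planted, exclude = used)

  smiles <- c(smi_a_planted, smi_a_decoy, smi_i_planted, smi_i_decoy)
  is_active_intent <- rep(c(TRUE, FALSE), c(n_a, n_i))
  mu <- ifelse(is_active_intent, config$potency_log_mean_active,
               config$potency_log_mean_inactive)
  sdv <- ifelse(is_active_intent, config$potency_log_sd[1],
                config$potency_log_sd[2])
  potency <- 10 ^ stats::rnorm(n_a + n_i, mu, sdv)
  ptype <- sample(c("Kd", "EC50", "IC50"), n_a + n_i, replace = TRUE,
                  prob = c(0.2, 0.2, 0.6))
  ds <- mol_dataset(smiles = smiles,
                    id = sprintf("SYN%04d", seq_len(n_a + n_i)),
                    potency_nm = potency, potency_type = ptype,
                    name = paste0("synthetic_benchmark_seed", config$seed))
  ds <- assign_labels(ds, cutoff_nm = 10000)
  list(dataset = ds, scaffolds = scaffold_smiles)
}

#' Generate a scaffold-free assumed-inactive pool
#'
#' Decoy molecules disjoint (by canonical SMILES) from the planted
#' scaffolds and from any structures passed in `exclude` (typically the
#' paired benchmark), standing in for a random commercial-directory
#' sample.
#'
#' @param n pool size (e.g. 990).
#' @param seed integer seed.
#' @param exclude a [mol_dataset()] or character vector of canonical SMILES
#'   the pool must not contain.
#' @return an unlabelled [mol_dataset()].
#' @export
generate_negative_pool <- function(n, seed = 1L, exclude = NULL) {
  stopifnot(n >= 1)
  set.seed(seed + 7919L)  # offset the benchmark stream
  if (inherits(exclude, "mol_dataset")) exclude <- exclude$smiles
  smi <- draw_unique(DECOY_TEMPLATES, n, exclude = c(exclude, character(0)))
  mol_dataset(smiles = smi, id = sprintf("NEG%04d", seq_len(n)),
              name = paste0("negative_pool_seed", seed))
}

#' Generate a screening-library stream
#'
#' Writes a `.smi` file mixing decoy molecules with planted-scaffold
#' molecules at the stated fraction (Bernoulli per record), emulating a
#' large commercial library at desk scale.  Duplicate structures may occur,
#' as in real vendor libraries.
#'
#' @param n number of records.
#' @param planted_active_fraction fraction of records built on a planted
#'   scaffold.
#' @param path output file path.
#' @param seed integer seed.
#' @param n_scaffolds how many planted scaffolds to draw from (default 3,
#'   matching [benchmark_config()]).
#' @param substituent_bias active-enriched substituent probability for the
#'   planted records (default 0.7, matching [benchmark_config()]).
#' @param chunk_size records written per chunk.
#' @return (invisibly) a list with `path`, `n`, `n_planted` and the
#'   logical `planted` flag vector in record order.
#' @export
generate_screening_stream <- function(n, planted_active_fraction = 0.01,
                                      path, seed = 1L, n_scaffolds = 3L,
                                      substituent_bias = 0.7,
                                      chunk_size = 5000L) {
  stopifnot(n >= 1, planted_active_fraction >= 0, planted_active_fraction <= 1)
  set.seed(seed + 104729L)
  planted_tpl <- PLANTED_TEMPLATES[seq_len(n_scaffolds)]
  planted <- stats::runif(n) < planted_active_fraction
  con <- file(path, "w")
  on.exit(close(con))
  done <- 0L
  while (done < n) {
    m <- min(chunk_size, n - done)
    idx <- done + seq_len(m)
    smi <- vapply(idx, function(i) {
      if (planted[i]) {
        decorate(planted_tpl[[sample.int(length(planted_tpl), 1)]],
                 bias = substituent_bias)
      } else {
        decorate(DECOY_TEMPLATES[[sample.int(length(DECOY_TEMPLATES), 1)]])
      }
    }, "")
    writeLines(paste(smi, sprintf("LIB%06d", idx)), con)
    done <- done + m
  }
  invisible(list(path = path, n = n, n_planted = sum(planted),
                 planted = planted))
}
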