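# Counterfactual explanations: minimally modified molecules whose
# predicted class flips.  Variants are generated by seeded local edits on
# the SMILES token stream (atom substitutions, bond-order changes, small
# insertions/deletions); chemical validity is guaranteed by filtering every
# candidate through the parser, and candidates are ranked by fingerprint
# Tanimoto similarity to the base molecule -- the same representation the
# model sees.

SMILES_TOKEN_RE <- paste0(
  "\\[[^]]*\\]|Cl|Br|%[0-9]{2}|[BCNOPSFI]|[bcnops]|[0-9]|[-=#:/\\\\().@+]")

smiles_tokens <- function(s) {
  m <- gregexpr(SMILES_TOKEN_RE, s)[[1]]
  if (m[1] < 0) return(character(0))
  regmatches(s, list(m))[[1]]
}

ALIPHATIC_SUBS <- c("C", "N", "O", "S")
AROMATIC_SUBS <- c("c", "n", "o", "s")

mutate_tokens <- function(tok) {
  n <- length(tok)
  if (n == 0) return(NULL)
  is_aliph <- tok %in% ALIPHATIC_SUBS
  is_arom <- tok %in% AROMATIC_SUBS
  is_atom <- is_aliph | is_arom | tok %in% c("F", "I", "Cl", "Br", "B", "P")
  op <- sample(c("substitute", "insert", "delete", "bond"), 1,
               prob = c(0.4, 0.25, 0.2, 0.15))
  if (op == "substitute") {
    cand <- which(is_aliph | is_arom | tok %in% c("F", "Cl", "Br"))
    if (!length(cand)) return(NULL)
    i <- cand[sample.int(length(cand), 1)]
    pool <- if (tok[i] %in% AROMATIC_SUBS) AROMATIC_SUBS
            else if (tok[i] %in% c("F", "Cl", "Br")) c("F", "Cl", "Br", "C")
            else ALIPHATIC_SUBS
    pool <- setdiff(pool, tok[i])
    tok[i] <- pool[sample.int(length(pool), 1)]
    tok
  } else if (op == "insert") {
    cand <- which(is_aliph)  # grow an aliphatic chain position
    i <- if (length(cand)) cand[sample.int(length(cand), 1)] else n
    ins <- sample(c("C", "CC", "O", "N", "(C)", "(O)", "(N)", "(F)"), 1)
    append(tok, ins, after = i)
  } else if (op == "delete") {
    # only delete a plain atom token not followed by ring digits/branches
    nxt <- c(tok[-1], "")
    cand <- which(is_atom & !(nxt %in% c(as.character(0:9), "(", "%")))
    if (!length(cand)) return(NULL)
    tok[-cand[sample.int(length(cand), 1)]]
  } else {
    i <- sample.int(n, 1)
    if (tok[i] == "=") { tok[i] <- ""; tok }
    else if (tok[i] %in% c("C", "N") && i < n && tok[i + 1] %in% c("C", "N")) {
      append(tok, "=", after = i)
    } else NULL
  }
}

#' Generate local structural variants of a molecule
#'
#' Seeded token-level edits of the SMILES with post-hoc validity filtering:
#' every returned variant parses, is distinct from the base, and the set is
#' reproducible for a seed.
#'
#' @param smiles base structure (single SMILES string).
#' @param n_samples maximum number of unique variants (default 2000).
#' @param seed integer seed.
#' @param max_attempts edit attempts before giving up (default
#'   `8 * n_samples`).
#' @return character vector of canonical variant SMILES (possibly shorter
#'   than `n_samples` when the edit neighbourhood is small).
#' @export
perturb_molecule <- function(smiles, n_samples = 2000L, seed = 1L,
                             max_attempts = 8L * n_samples) {
  stopifnot(length(smiles) == 1)
  base <- canonical_smiles(smiles)
  if (is.na(base)) stop("invalid base structure: ", smiles)
  if (n_samples == 0) return(character(0))
  set.seed(seed)
  tok0 <- smiles_tokens(base)
  raw <- character(0)
  attempts <- 0L
  batch <- max(64L, min(512L, n_samples))
  out <- character(0)
  while (length(out) < n_samples && attempts < max_attempts) {
    raw <- character(0)
    while (length(raw) < batch && attempts < max_attempts) {
      attempts <- attempts + 1L
      mt <- mutate_tokens(tok0)
      if (is.null(mt)) next
      raw <- c(raw, paste(mt, collapse = ""))
    }
    if (!length(raw)) break
    canon <- suppressWarnings(canonical_smiles(raw))
    canon <- canon[!is.na(canon)]
    canon <- canon[canon != base]
    out <- unique(c(out, canon))
  }
  utils::head(out, n_samples)
}

# object may be a frag_ensemble, a fitted member, or a plain function
# X -> logical (useful for custom decision rules and for testing)
predict_positive <- function(object, X) {
  if (is.function(object)) {
    as.logical(object(X))
  } else if (inherits(object, "frag_ensemble")) {
    predict(object, X, type = "consensus")
  } else {
    member_prob(object, X) >= 0.5
  }
}

#' Find counterfactual explanations for a prediction
#'
#' Generates local variants of the base molecule, scores them with the
#' model, keeps those whose predicted class differs from the base, and
#' returns the `top_k` most similar to the base (fingerprint Tanimoto in
#' the featurizer's own representation).  An empty result (no flip found
#' in the sampled neighbourhood) is valid and reported with a warning.
#'
#' @param object a [frag_ensemble()] or a single fitted member from its
#'   `members` list.
#' @param smiles base structure.
#' @param lib the `fragment_library` used for featurization.
#' @param n_samples variants to generate (default 2000).
#' @param top_k counterfactuals to return (default 10).
#' @param seed integer seed.
#' @param config the [featurizer_config()] used in training.
#' @return data.frame of counterfactuals, ranked by decreasing similarity:
#'   `variant_smiles`, `similarity_to_base`, `base_positive`,
#'   `variant_positive`, and `votes_variant` (ensemble only, else NA).
#' @export
find_counterfactuals <- function(object, smiles, lib, n_samples = 2000L,
                                 top_k = 10L, seed = 1L,
                                 config = featurizer_config()) {
  base <- canonical_smiles(smiles)
  if (is.na(base)) stop("invalid base structure")
  variants <- perturb_molecule(base, n_samples = n_samples, seed = seed)
  empty <- data.frame(variant_smiles = character(0),
                      similarity_to_base = numeric(0),
                      base_positive = logical(0),
                      variant_positive = logical(0),
                      votes_variant = integer(0))
  Xb <- featurize(base, lib, config)
  base_pos <- as.logical(predict_positive(object, Xb))
  if (!length(variants)) {
    warning("no valid variants generated")
    return(empty)
  }
  Xv <- featurize(variants, lib, config)
  var_pos <- as.logical(predict_positive(object, Xv))
  votes <- if (inherits(object, "frag_ensemble"))
    predict(object, Xv, type = "votes") else rep(NA_integer_, length(variants))
  flipped <- var_pos != base_pos
  if (!any(flipped)) {
    warning("no counterfactual found among ", length(variants), " variants")
    return(empty)
  }
  sims <- as.vector(tanimoto_matrix(Xv[flipped, seq_len(config$n_bits), drop = FALSE],
                                    Xb[, seq_len(config$n_bits), drop = FALSE]))
  df <- data.frame(variant_smiles = variants[flipped],
                   similarity_to_base = sims,
                   base_positive = base_pos,
                   variant_positive = var_pos[flipped],
                   votes_variant = votes[flipped],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$similarity_to_base, df$variant_smiles), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}

#' Fragment-overlap annotation of a counterfactual
#'
#' For each library fragment, reports whether the base molecule matched it
#' and whether the variant still does: `"retained"`, `"lost"`, `"gained"`,
#' or `"absent"`.
#'
#' @param base_smiles,variant_smiles the base molecule and its
#'   counterfactual variant.
#' @param lib a `fragment_library`.
#' @return data.frame with `fragment` (SMILES), `base_match`,
#'   `variant_match`, `status`.
#' @export
annotate_fragment_overlap <- function(base_smiles, variant_smiles, lib) {
  stopifnot(inherits(lib, "fragment_library"))
  mg <- mol_graphs(c(base_smiles, variant_smiles))
  if (any(vapply(mg, is.null, TRUE))) stop("invalid structure")
  if (nrow(lib$fragments) == 0) {
    return(data.frame(fragment = character(0), base_match = logical(0),
                      variant_match = logical(0), status = character(0)))
  }
  m <- .cpp_match_matrix(lib$graphs, mg)
  status <- ifelse(m[, 1] & m[, 2], "retained",
            ifelse(m[, 1] & !m[, 2], "lost",
            ifelse(!m[, 1] & m[, 2], "gained", "absent")))
  data.frame(fragment = lib$fragments$smiles,
             base_match = m[, 1], variant_match = m[, 2],
             status = status, stringsAsFactors = FALSE)
}
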