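# Feature engineering: each molecule becomes the concatenation of
#   [ n_bits hashed circular fingerprint bits
#   | one Tanimoto similarity per library fragment (library order)
#   | the number of library fragments contained as substructures ].
# With the default 1024 bits and a 266-fragment library this is the
# 1291-column representation used by the ensemble.

#' Featurizer configuration
#'
#' @param n_bits fingerprint length (power of two, default 1024).
#' @param fp_radius circular fingerprint radius in bonds (1-3, default 2,
#'   i.e. the common diameter-4 variant).
#' @param match_definition how the fragment match count is defined:
#'   `"substructure"` (default; substructure containment) or
#'   `"similarity_threshold"` (Tanimoto above `similarity_threshold`).
#' @param similarity_threshold threshold used by the alternative match
#'   definition (default 0.8).
#' @return A `featurizer_config` list.
#' @export
featurizer_config <- function(n_bits = 1024L, fp_radius = 2L,
                              match_definition = c("substructure",
                                                   "similarity_threshold"),
                              similarity_threshold = 0.8) {
  n_bits <- as.integer(n_bits)
  stopifnot(n_bits >= 32, bitwAnd(n_bits, n_bits - 1L) == 0L,
            fp_radius >= 1, fp_radius <= 5)
  structure(list(n_bits = n_bits, fp_radius = as.integer(fp_radius),
                 match_definition = match.arg(match_definition),
                 similarity_threshold = similarity_threshold),
            class = "featurizer_config")
}

#' Circular fingerprints
#'
#' Hashed circular (extended-connectivity) fingerprint bits for each
#' structure; deterministic for a given canonical structure.
#'
#' @param smiles character vector of SMILES (or a [mol_dataset()]).
#' @param config a [featurizer_config()].
#' @return integer 0/1 matrix, one row per molecule, `n_bits` columns.
#' @export
ecfp <- function(smiles, config = featurizer_config()) {
  if (inherits(smiles, "mol_dataset")) smiles <- smiles$smiles
  g <- mol_graphs(smiles)
  if (any(vapply(g, is.null, TRUE)))
    stop("invalid structure(s) in fingerprint input")
  ecfp_from_graphs(g, n_bits = config$n_bits, radius = config$fp_radius)
}

#' Tanimoto similarity of fingerprint vectors
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are all-zero.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# row-wise Tanimoto between two 0/1 matrices: result [nrow(A) x nrow(B)]
tanimoto_matrix <- function(A, B) {
  A <- (A != 0L) + 0; B <- (B != 0L) + 0   # double for fast BLAS products
  inter <- tcrossprod(A, B)
  u <- outer(rowSums(A), rowSums(B), "+") - inter
  out <- inter / u
  out[u == 0] <- 0
  out
}

# fingerprints of the library fragments under a featurizer config,
# computed directly on the fragment graphs (no SMILES round trip, so
# fragments with aromatic atoms outside complete rings are fingerprinted
# faithfully)
fragment_fingerprints <- function(lib, config) {
  if (nrow(lib$fragments) == 0) return(matrix(0L, 0, config$n_bits))
  ecfp_from_graphs(lib$graphs, n_bits = config$n_bits,
                   radius = config$fp_radius)
}

#' Count library fragments contained in molecules
#'
#' Number of library fragments embedded as substructures in each molecule
#' (element/charge/aromaticity-typed subgraph matching).
#'
#' @param smiles character vector of SMILES (or a [mol_dataset()]).
#' @param lib a `fragment_library`.
#' @return integer vector of match counts, each `<= length(lib)`.
#' @export
fragment_match_count <- function(smiles, lib) {
  stopifnot(inherits(lib, "fragment_library"))
  if (inherits(smiles, "mol_dataset")) smiles <- smiles$smiles
  if (!length(smiles)) return(integer(0))
  if (nrow(lib$fragments) == 0) return(integer(length(smiles)))
  mg <- mol_graphs(smiles)
  if (any(vapply(mg, is.null, TRUE)))
    stop("invalid structure(s) in fragment match input")
  m <- .cpp_match_matrix(lib$graphs, mg)
  as.integer(colSums(m))
}

feature_colnames <- function(lib, config) {
  nf <- nrow(lib$fragments)
  c(sprintf("bit_%04d", seq_len(config$n_bits) - 1L),
    if (nf) sprintf("frag_%04d", seq_len(nf)),
    "frag_match_count")
}

#' Featurize molecules against a fragment library
#'
#' Builds the model feature matrix: fingerprint bits, per-fragment Tanimoto
#' similarities (fragment fingerprints computed under the same
#' configuration), and the fragment match count.  Total width is
#' `n_bits + length(lib) + 1`.
#'
#' @param smiles character vector of SMILES or a [mol_dataset()].
#' @param lib a `fragment_library` (column order follows library order).
#' @param config a [featurizer_config()].
#' @return numeric matrix, one row per molecule, with persistent column
#'   names; rows align with input order.
#' @export
featurize <- function(smiles, lib, config = featurizer_config()) {
  stopifnot(inherits(lib, "fragment_library"))
  ids <- NULL
  if (inherits(smiles, "mol_dataset")) {
    ids <- smiles$id
    smiles <- smiles$smiles
  }
  n <- length(smiles)
  graphs <- mol_graphs(smiles)
  if (any(vapply(graphs, is.null, TRUE)))
    stop("invalid structure(s): ",
         paste(utils::head(smiles[vapply(graphs, is.null, TRUE)], 5),
               collapse = ", "))
  fp <- ecfp_from_graphs(graphs, n_bits = config$n_bits,
                         radius = config$fp_radius)
  nf <- nrow(lib$fragments)
  if (nf > 0) {
    ffp <- fragment_fingerprints(lib, config)
    sims <- tanimoto_matrix(fp, ffp)
    if (config$match_definition == "substructure") {
      counts <- as.integer(colSums(.cpp_match_matrix(lib$graphs, graphs)))
    } else {
      counts <- as.integer(rowSums(sims >= config$similarity_threshold))
    }
    X <- cbind(fp, sims, counts)
  } else {
    X <- cbind(fp, integer(n))
  }
  colnames(X) <- feature_colnames(lib, config)
  if (!is.null(ids)) rownames(X) <- ids
  attr(X, "featurizer_config") <- config
  X
}

#' Write / read a feature matrix as CSV
#'
#' @param X matrix from [featurize()].
#' @param path file path.
#' @return `read_feature_matrix` returns the numeric matrix with column
#'   names.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(row_id = if (is.null(rownames(X))) seq_len(nrow(X)) else rownames(X),
                   X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}
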