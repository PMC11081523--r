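# Library screening: stream a large SMILES library through the featurizer
# and ensemble in chunks, keep the consensus positives, and summarize the
# reduction.  Also the diversity analyses used to characterize the focused
# library: pairwise similarity matrices, cluster-representative selection
# and a 2-D chemical-space projection.

#' Screen a compound library down to a focused subset
#'
#' Processes the library in chunks (constant memory in the library size);
#' chunking does not change results.  Unparseable records are skipped and
#' counted.
#'
#' @param library_source path to a `.smi` file or a [mol_dataset()].
#' @param lib the `fragment_library` the model was trained with.
#' @param model a [frag_ensemble()].
#' @param threshold vote threshold (default: the model's, normally 6).
#' @param config the [featurizer_config()] used in training.
#' @param chunk_size compounds per chunk (default 2000).
#' @return list with `focused` (a `mol_dataset` of passing compounds with a
#'   `votes` column) and `report`: `n_input`, `n_skipped`, `n_passed`,
#'   `reduction_fraction`, `vote_histogram` (counts by vote 0..6) and
#'   `per_threshold` pass counts.
#' @export
screen_library <- function(library_source, lib, model, threshold = NULL,
                           config = featurizer_config(),
                           chunk_size = 2000L) {
  stopifnot(inherits(lib, "fragment_library"),
            inherits(model, "frag_ensemble"))
  if (is.null(threshold)) threshold <- model$vote_threshold
  nmem <- length(model$members)
  stopifnot(threshold >= 1, threshold <= nmem)

  if (inherits(library_source, "mol_dataset")) {
    get_chunk <- local({
      done <- FALSE
      function() {
        if (done) return(NULL)
        done <<- TRUE
        data.frame(smiles = library_source$smiles, id = library_source$id,
                   stringsAsFactors = FALSE)
      }
    })
  } else {
    con <- file(library_source, "r")
    on.exit(close(con))
    counter <- 0L
    get_chunk <- function() {
      lines <- readLines(con, n = chunk_size)
      lines <- lines[nzchar(trimws(lines))]
      if (!length(lines)) return(NULL)
      parts <- regmatches(lines, regexpr("[ \t]+", lines), invert = TRUE)
      smi <- vapply(parts, `[`, "", 1L)
      ids <- vapply(parts, function(p) if (length(p) > 1 && nzchar(p[2])) p[2]
                    else NA_character_, "")
      miss <- is.na(ids)
      if (any(miss)) ids[miss] <- paste0("L", counter + which(miss))
      counter <<- counter + length(lines)
      data.frame(smiles = smi, id = ids, stringsAsFactors = FALSE)
    }
  }

  n_input <- 0L; n_skipped <- 0L
  hist_votes <- integer(nmem + 1L)  # votes 0..nmem
  keep_smiles <- character(0); keep_ids <- character(0); keep_votes <- integer(0)
  repeat {
    chunk <- get_chunk()
    if (is.null(chunk) || nrow(chunk) == 0) break
    n_input <- n_input + nrow(chunk)
    canon <- canonical_smiles(chunk$smiles)
    ok <- !is.na(canon)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    X <- featurize(canon[ok], lib, config)
    votes <- predict(model, X, type = "votes")
    hist_votes <- hist_votes + tabulate(votes + 1L, nbins = nmem + 1L)
    pass <- votes >= threshold
    keep_smiles <- c(keep_smiles, canon[ok][pass])
    keep_ids <- c(keep_ids, chunk$id[ok][pass])
    keep_votes <- c(keep_votes, votes[pass])
  }
  n_scored <- n_input - n_skipped
  focused <- mol_dataset(smiles = keep_smiles, id = make.unique(keep_ids),
                         name = "focused_library")
  focused$votes <- keep_votes
  report <- list(
    n_input = n_input, n_skipped = n_skipped, n_scored = n_scored,
    n_passed = length(keep_smiles),
    reduction_fraction = if (n_scored > 0) 1 - length(keep_smiles) / n_scored else NA_real_,
    vote_histogram = stats::setNames(hist_votes, 0:nmem),
    per_threshold = data.frame(
      threshold = seq_len(nmem),
      n_passed = vapply(seq_len(nmem), function(t)
        sum(hist_votes[(t + 1L):(nmem + 1L)]), 0L)))
  list(focused = focused, report = report)
}

#' Pairwise Tanimoto similarity matrix
#'
#' Fingerprint Tanimoto similarities between two compound sets (or one set
#' against itself, giving a symmetric matrix with unit diagonal);
#' exportable as CSV for heatmapping.
#'
#' @param set_a,set_b [mol_dataset()]s (`set_b` defaults to `set_a`).
#' @param config a [featurizer_config()].
#' @return numeric matrix with row/column names from compound ids.
#' @export
similarity_matrix <- function(set_a, set_b = set_a,
                              config = featurizer_config()) {
  stopifnot(inherits(set_a, "mol_dataset"), inherits(set_b, "mol_dataset"))
  fa <- ecfp(set_a, config)
  fb <- ecfp(set_b, config)
  m <- tanimoto_matrix(fa, fb)
  rownames(m) <- set_a$id
  colnames(m) <- set_b$id
  m
}

#' Select diverse cluster representatives
#'
#' Partitions compounds into `n_clusters` groups by k-medoid clustering on
#' fingerprint Tanimoto distance and returns the medoid of each cluster.
#'
#' @param ds a [mol_dataset()] with at least `n_clusters` compounds.
#' @param n_clusters number of clusters (default 30).
#' @param config a [featurizer_config()].
#' @param seed clustering seed.
#' @return `mol_dataset` of the representatives (one per cluster, in
#'   cluster order) with a `cluster` column.
#' @export
select_cluster_representatives <- function(ds, n_clusters = 30L,
                                           config = featurizer_config(),
                                           seed = 1L) {
  stopifnot(inherits(ds, "mol_dataset"))
  if (nrow(ds) < n_clusters)
    stop("dataset has ", nrow(ds), " compounds; need at least ", n_clusters)
  if (nrow(ds) == n_clusters) {
    out <- ds
    out$cluster <- seq_len(nrow(ds))
    return(out)
  }
  fp <- ecfp(ds, config)
  d <- stats::as.dist(1 - tanimoto_matrix(fp, fp))
  set.seed(seed)
  pam <- cluster::pam(d, k = n_clusters, pamonce = 5)
  out <- ds[pam$id.med, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, name = paste0(attr(ds, "name"), "_representatives"),
                   class = c("mol_dataset", "data.frame"))
  out$cluster <- seq_len(n_clusters)
  out
}

#' 2-D chemical-space projection
#'
#' Deterministic principal-component projection of fingerprint vectors for
#' plotting; identical molecules map to identical coordinates.  Component
#' signs are fixed (largest-magnitude loading positive) so the embedding is
#' reproducible.
#'
#' @param sets named list of [mol_dataset()]s (names become the `set`
#'   label), or a single dataset.
#' @param config a [featurizer_config()].
#' @return data.frame with `id`, `set`, `PC1`, `PC2`.
#' @export
chemical_space_projection <- function(sets, config = featurizer_config()) {
  if (inherits(sets, "mol_dataset")) sets <- list(all = sets)
  stopifnot(length(sets) >= 1)
  ids <- unlist(lapply(sets, `[[`, "id"), use.names = FALSE)
  labels <- rep(names(sets), vapply(sets, nrow, 0L))
  smi <- unlist(lapply(sets, `[[`, "smiles"), use.names = FALSE)
  if (length(smi) < 3) stop("need at least 3 molecules")
  fp <- ecfp_from_smiles(smi, n_bits = config$n_bits, radius = config$fp_radius)
  pc <- stats::prcomp(fp, center = TRUE, scale. = FALSE, rank. = 2)
  xy <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) xy[, j] <- -xy[, j]
  }
  data.frame(id = ids, set = labels, PC1 = xy[, 1], PC2 = xy[, 2],
             stringsAsFactors = FALSE)
}

#' Active fraction by fragment match count
#'
#' Bins compounds by how many library fragments they contain and reports
#' per-bin active/inactive counts and the active fraction (the pattern that
#' motivates the fragment features: heavier fragment matching should
#' coincide with activity).
#'
#' @param ds a labelled [mol_dataset()].
#' @param lib a `fragment_library`.
#' @param breaks bin lower edges (default `c(0, 1, 5, 10, 20)`, i.e. bins
#'   0, 1-4, 5-9, 10-19, >=20).
#' @return data.frame with `bin`, `n_active`, `n_inactive`, `n`,
#'   `active_fraction`.
#' @export
fragment_match_label_profile <- function(ds, lib,
                                         breaks = c(0, 1, 5, 10, 20)) {
  stopifnot(inherits(ds, "mol_dataset"))
  if (any(is.na(ds$label))) stop("dataset must be fully labelled")
  counts <- fragment_match_count(ds, lib)
  edges <- c(breaks, Inf)
  labels <- vapply(seq_along(breaks), function(i) {
    lo <- edges[i]; hi <- edges[i + 1] - 1
    if (!is.finite(edges[i + 1])) paste0(">=", lo)
    else if (lo == hi) as.character(lo)
    else paste0(lo, "-", hi)
  }, "")
  bin <- findInterval(counts, breaks)  # 1..length(breaks)
  act <- ds$label == "active"
  n_act <- vapply(seq_along(breaks), function(b) sum(act & bin == b), 0L)
  n_ina <- vapply(seq_along(breaks), function(b) sum(!act & bin == b), 0L)
  data.frame(
    bin = labels,
    n_active = n_act,
    n_inactive = n_ina,
    n = n_act + n_ina,
    active_fraction = ifelse(n_act + n_ina > 0, n_act / (n_act + n_ina), NA_real_),
    row.names = NULL)
}
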