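# Screening-library prefilters: pan-assay interference (PAINS) substructure
# alerts and a QED druglikeness floor.  PAINS is checked first so the
# removal accounting attributes each compound to exactly one filter.

pains_patterns <- function() {
  if (!is.null(.ff$pains)) return(.ff$pains)
  path <- system.file("extdata", "pains_smarts.tsv", package = "fragfocus")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  compiled <- smarts_compile(tab$smarts)
  keep <- !vapply(compiled, is.null, TRUE)
  .ff$pains <- list(id = tab$id[keep], sp = compiled[keep])
  .ff$pains
}

#' Flag PAINS substructure alerts
#'
#' Matches each structure against the published PAINS A/B/C SMARTS catalogue
#' (480 patterns, shipped with the package so results do not depend on the
#' toolkit version).  The patterns use explicit hydrogens, so molecules are
#' hydrogen-expanded before matching.
#'
#' @param smiles character vector of SMILES.
#' @param return_ids if `TRUE`, return a list of matched alert identifiers
#'   per molecule instead of a logical vector.
#' @return logical vector (`TRUE` = at least one PAINS alert matches), or a
#'   list of character vectors when `return_ids = TRUE`.  Invalid structures
#'   raise an error.
#' @examples
#' flag_pains(c("O=C1C=CC(=O)C=C1", "c1ccccc1"))  # quinone is flagged
#' @export
flag_pains <- function(smiles, return_ids = FALSE) {
  if (!length(smiles)) return(if (return_ids) list() else logical(0))
  mols <- ob_parse(smiles)
  if (any(vapply(mols, is.null, TRUE)))
    stop("invalid structure(s): ",
         paste(utils::head(smiles[vapply(mols, is.null, TRUE)], 5), collapse = ", "))
  ns <- ob_ns()
  cat_ <- pains_patterns()
  res <- lapply(mols, function(m) {
    ns$OBMol_AddHydrogens(m)
    hit <- vapply(cat_$sp, function(sp) {
      ns$OBSmartsPattern_Match(sp, m) && ns$OBSmartsPattern_NumMatches(sp) > 0
    }, TRUE)
    cat_$id[hit]
  })
  if (return_ids) res else lengths(res) > 0
}

#' Apply PAINS and QED prefilters to a dataset
#'
#' Removes compounds with at least one PAINS alert, then compounds with
#' QED at or below `qed_max_removed`.  Each removed compound is counted
#' under exactly one filter (PAINS first).
#'
#' @param ds a [mol_dataset()].
#' @param qed_max_removed QED threshold; compounds with QED `<=` this value
#'   are removed (default 0.25).
#' @return list with elements `dataset` (the kept compounds) and `report`
#'   (counts: `n_input`, `n_pains_removed`, `n_qed_removed`, `n_kept`).
#' @export
apply_prefilters <- function(ds, qed_max_removed = 0.25) {
  stopifnot(inherits(ds, "mol_dataset"),
            qed_max_removed >= 0, qed_max_removed <= 1)
  n <- nrow(ds)
  if (n == 0) {
    return(list(dataset = ds,
                report = list(n_input = 0L, n_pains_removed = 0L,
                              n_qed_removed = 0L, n_kept = 0L)))
  }
  pains <- flag_pains(ds$smiles)
  qed <- rep(NA_real_, n)
  qed[!pains] <- compute_qed(ds$smiles[!pains])
  qed_fail <- !pains & !is.na(qed) & qed <= qed_max_removed
  keep <- !pains & !qed_fail
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, name = attr(ds, "name"),
                   class = c("mol_dataset", "data.frame"))
  list(dataset = out,
       report = list(n_input = n, n_pains_removed = sum(pains),
                     n_qed_removed = sum(qed_fail), n_kept = sum(keep)))
}
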