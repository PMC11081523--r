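# Low-level interface to Open Babel through ChemmineOB.  Everything that
# touches a molecule object funnels through here: parsing, canonical SMILES,
# heavy-atom graph extraction (element / formal charge / aromaticity, bond
# order / aromaticity), SMARTS matching and circular fingerprints.

.ff <- new.env(parent = emptyenv())  # package-level caches

ob_ns <- function() getNamespace("ChemmineOB")

#' @keywords internal
ob_parse <- function(smiles, titles = NULL) {
  # Parse a character vector of SMILES into OBMol references.  Invalid
  # entries come back as NULL (Open Babel drops them from the stream; we
  # recover row identity through the title field).
  if (length(smiles) == 0) return(list())
  if (is.null(titles)) titles <- as.character(seq_along(smiles))
  out <- vector("list", length(smiles))
  # pre-validate: the stream reader aborts when the final record fails to
  # parse, so only feed it structures the converter accepts
  valid <- !is.na(smiles) & nzchar(smiles) & !is.na(canonical_smiles(smiles))
  if (!any(valid)) return(out)
  txt <- paste0(smiles[valid], " ", titles[valid], collapse = "\n")
  mols <- tryCatch(ChemmineOB::forEachMol("SMILES", txt, identity),
                   error = function(e) list())
  ns <- ob_ns()
  got <- vapply(mols, function(m) ns$OBMol_GetTitle(m), "")
  keep <- vapply(mols, function(m) ns$OBMol_NumAtoms(m) > 0, TRUE)
  idx <- match(got[keep], titles)
  out[idx[!is.na(idx)]] <- mols[keep][!is.na(idx)]
  out
}

#' Canonicalize SMILES strings
#'
#' Returns the Open Babel canonical aromatic SMILES for each input, or `NA`
#' for strings that do not parse.  Canonicalization is idempotent.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES (`NA` where unparseable).
#' @examples
#' canonical_smiles(c("C1=CC=CC=C1", "OCC"))
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[ \t]", smiles)
  if (any(ok)) out[ok] <- canon_batch(smiles[ok])
  out
}

# batch canonicalization with recovery: the converter aborts its stream at
# a record it cannot parse, losing the records after it, so unmatched
# inputs are retried (the offender alone, then the remainder as a batch)
canon_batch <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  titles <- sprintf("m%d", seq_len(n))
  txt <- paste0(smiles, " ", titles, collapse = "\n")
  res <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", txt),
                  error = function(e) "")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- regmatches(lines, regexpr("[ \t]", lines), invert = TRUE)
    smi <- vapply(parts, `[`, "", 1L)
    ttl <- trimws(vapply(parts, function(p)
      if (length(p) > 1) p[2] else NA_character_, ""))
    idx <- match(ttl, titles)
    out[idx[!is.na(idx)]] <- smi[!is.na(idx)]
  }
  missing <- which(is.na(out))
  if (length(missing) && length(missing) < n) {
    out[missing] <- canon_batch(smiles[missing])
  } else if (length(missing) == n && n > 1) {
    # no progress: the first record is the offender; isolate it
    out[1] <- canon_batch(smiles[1])
    out[-1] <- canon_batch(smiles[-1])
  }
  out
}

# Heavy-atom molecular graph: list(elem, charge, arom, ba, bb, bo, barom).
# Atom indices are 1-based; hydrogens are implicit (explicit H are removed).
mol_graph_one <- function(m) {
  ns <- ob_ns()
  ns$OBMol_DeleteHydrogens(m)
  na <- ns$OBMol_NumAtoms(m)
  nb <- ns$OBMol_NumBonds(m)
  elem <- integer(na); chg <- integer(na); ar <- logical(na)
  for (i in seq_len(na)) {
    a <- ns$OBMol_GetAtom(m, i)
    elem[i] <- ns$OBAtom_GetAtomicNum(a)
    chg[i] <- ns$OBAtom_GetFormalCharge(a)
    ar[i] <- ns$OBAtom_IsAromatic(a)
  }
  ba <- integer(nb); bb <- integer(nb); bo <- integer(nb); barom <- logical(nb)
  for (j in seq_len(nb)) {
    b <- ns$OBMol_GetBond(m, j - 1L)
    ba[j] <- ns$OBBond_GetBeginAtomIdx(b)
    bb[j] <- ns$OBBond_GetEndAtomIdx(b)
    bo[j] <- ns$OBBond_GetBondOrder(b)
    barom[j] <- ns$OBBond_IsAromatic(b)
  }
  list(elem = elem, charge = chg, arom = ar,
       ba = ba, bb = bb, bo = bo, barom = barom)
}

#' @keywords internal
mol_graphs <- function(smiles) {
  mols <- ob_parse(smiles)
  lapply(mols, function(m) if (is.null(m)) NULL else mol_graph_one(m))
}

# --- SMARTS -----------------------------------------------------------------

smarts_compile <- function(patterns) {
  ns <- ob_ns()
  lapply(patterns, function(p) {
    sp <- ns$OBSmartsPattern()
    if (!ns$OBSmartsPattern_Init(sp, p)) return(NULL)
    sp
  })
}

# number of unique matches of one compiled pattern in one OBMol
smarts_count <- function(sp, mol) {
  ns <- ob_ns()
  if (is.null(sp)) return(0L)
  if (!ns$OBSmartsPattern_Match(sp, mol)) return(0L)
  length(ns$OBSmartsPattern_GetUMapList(sp))
}

# --- fingerprints -----------------------------------------------------------

# Hashed circular fingerprint (atom environments up to `radius` bonds) on
# the heavy-atom graph; see src/fragments.cpp.  Unparseable molecules get
# all-zero rows.
ecfp_from_graphs <- function(graphs, n_bits = 1024L, radius = 2L) {
  stopifnot(radius >= 1, radius <= 5, n_bits >= 32,
            bitwAnd(n_bits, n_bits - 1L) == 0L)
  .cpp_ecfp(graphs, as.integer(n_bits), as.integer(radius))
}

ecfp_from_smiles <- function(smiles, n_bits = 1024L, radius = 2L) {
  ecfp_from_graphs(mol_graphs(smiles), n_bits = n_bits, radius = radius)
}
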