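# Compound datasets: reading bioactivity tables and SMILES libraries,
# canonicalization, duplicate resolution and potency-cutoff labelling.
#
# A mol_dataset is a data.frame with columns
#   id, smiles (canonical), potency_nm, potency_type, label
# plus attributes `name` (dataset name) and class "mol_dataset".

POTENCY_TYPES <- c("Kd", "EC50", "IC50", "percent_inhibition")

#' Construct a compound dataset
#'
#' Canonicalizes SMILES, drops unparseable structures with a warning, and
#' enforces unique ids.  Duplicate canonical structures are allowed at this
#' stage; see [deduplicate_keep_most_potent()].
#'
#' @param smiles character vector of SMILES strings.
#' @param id compound identifiers (default `"M1"`, `"M2"`, ...).
#' @param potency_nm optional potency values in nM (must be positive).
#' @param potency_type optional measurement types
#'   (`"Kd"`, `"EC50"`, `"IC50"`, `"percent_inhibition"`).
#' @param label optional activity labels (`"active"`/`"inactive"`).
#' @param name dataset name carried through provenance.
#' @return A `mol_dataset` (data.frame subclass).
#' @export
mol_dataset <- function(smiles, id = NULL, potency_nm = NULL,
                        potency_type = NULL, label = NULL, name = "dataset") {
  n <- length(smiles)
  if (is.null(id)) id <- sprintf("M%d", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("compound ids must be unique")
  if (is.null(potency_nm)) potency_nm <- rep(NA_real_, n)
  if (is.null(potency_type)) potency_type <- rep(NA_character_, n)
  if (is.null(label)) label <- rep(NA_character_, n)
  potency_nm <- as.numeric(potency_nm)
  if (any(!is.na(potency_nm) & potency_nm <= 0))
    stop("potency_nm must be positive")
  bad_type <- !is.na(potency_type) & !(potency_type %in% POTENCY_TYPES)
  if (any(bad_type))
    stop("unknown potency_type: ", paste(unique(potency_type[bad_type]), collapse = ", "))
  bad_lab <- !is.na(label) & !(label %in% c("active", "inactive"))
  if (any(bad_lab)) stop("labels must be 'active' or 'inactive'")

  canon <- canonical_smiles(smiles)
  drop <- is.na(canon)
  if (any(drop)) {
    warning(sum(drop), " unparseable structure(s) dropped: ",
            paste(utils::head(id[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ...")
  }
  df <- data.frame(id = id, smiles = canon, potency_nm = potency_nm,
                   potency_type = as.character(potency_type),
                   label = as.character(label),
                   stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, name = name, n_rejected = sum(drop),
            class = c("mol_dataset", "data.frame"))
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat(sprintf("<mol_dataset '%s': %d compounds", attr(x, "name"), nrow(x)))
  if (any(!is.na(x$label)))
    cat(sprintf(", %d active / %d inactive",
                sum(x$label == "active", na.rm = TRUE),
                sum(x$label == "inactive", na.rm = TRUE)))
  cat(">\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Read a bioactivity table from CSV
#'
#' Reads a CSV with (at least) a SMILES column, canonicalizes structures and
#' drops unparseable rows with a warning.
#'
#' @param path CSV file path.
#' @param smiles_col,id_col,potency_col,type_col,label_col column names in the
#'   file; `id_col` etc. may be `NULL` when absent.
#' @param name dataset name.
#' @return A [mol_dataset()].
#' @export
read_bioactivity_table <- function(path, smiles_col = "smiles",
                                   id_col = NULL, potency_col = NULL,
                                   type_col = NULL, label_col = NULL,
                                   name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  if (anyDuplicated(names(hdr))) stop("duplicate column names in ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(smiles_col, id_col, potency_col, type_col, label_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  smi <- as.character(df[[smiles_col]])
  if (any(is.na(smi) | !nzchar(smi))) stop("empty SMILES entries in ", path)
  ds <- mol_dataset(
    smiles = smi,
    id = if (!is.null(id_col)) df[[id_col]] else NULL,
    potency_nm = if (!is.null(potency_col)) df[[potency_col]] else NULL,
    potency_type = if (!is.null(type_col)) df[[type_col]] else NULL,
    label = if (!is.null(label_col)) df[[label_col]] else NULL,
    name = name)
  if (nrow(ds) == 0) stop("no parseable rows in ", path)
  ds
}

# stereo-stripped canonical form, used only for duplicate grouping
strip_stereo <- function(smiles) {
  s <- gsub("@{1,2}", "", smiles)
  s <- gsub("[\\\\/]", "-", s)
  canonical_smiles(s)
}

#' Collapse duplicate structures, keeping the most potent record
#'
#' Records sharing a canonical structure are collapsed to the one with the
#' lowest (most potent) `potency_nm`; records without potency lose ties to
#' records that have one.  Structures that differ only by unspecified
#' stereochemistry are treated as duplicates; distinct fully specified
#' stereoisomers are kept apart.
#'
#' @param ds a [mol_dataset()].
#' @return A deduplicated `mol_dataset`.
#' @export
deduplicate_keep_most_potent <- function(ds) {
  stopifnot(inherits(ds, "mol_dataset"))
  if (nrow(ds) == 0) return(ds)
  base_key <- strip_stereo(ds$smiles)
  base_key[is.na(base_key)] <- ds$smiles[is.na(base_key)]
  has_stereo <- grepl("[@\\\\/]", ds$smiles)
  key <- base_key
  grp <- split(seq_len(nrow(ds)), base_key)
  for (g in grp) {
    # all members stereo-specified and structurally distinct: keep apart
    if (length(g) > 1 && all(has_stereo[g]) &&
        length(unique(ds$smiles[g])) > 1)
      key[g] <- ds$smiles[g]
  }
  pick <- vapply(split(seq_len(nrow(ds)), key), function(g) {
    p <- ds$potency_nm[g]
    if (all(is.na(p))) return(g[1])
    g[which.min(replace(p, is.na(p), Inf))]
  }, 0L)
  out <- ds[sort(unname(pick)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, name = attr(ds, "name"),
            class = c("mol_dataset", "data.frame"))
}

#' Label compounds by a potency cutoff
#'
#' Potency strictly below `cutoff_nm` is labelled active; at or above the
#' cutoff, inactive (a value exactly at the cutoff is assigned the
#' conservative, inactive side).  Percent-inhibition records are excluded
#' from cutoff labelling and keep an `NA` label.
#'
#' @param ds a [mol_dataset()] whose records carry `potency_nm`.
#' @param cutoff_nm positive potency cutoff in nM (default 10000).
#' @return The dataset with the `label` column filled in.
#' @export
assign_labels <- function(ds, cutoff_nm = 10000) {
  stopifnot(inherits(ds, "mol_dataset"), cutoff_nm > 0)
  pct <- !is.na(ds$potency_type) & ds$potency_type == "percent_inhibition"
  need <- !pct
  if (any(need & is.na(ds$potency_nm)))
    stop("records lack potency_nm: ",
         paste(utils::head(ds$id[need & is.na(ds$potency_nm)], 10), collapse = ", "))
  ds$label[need] <- ifelse(ds$potency_nm[need] < cutoff_nm, "active", "inactive")
  ds$label[pct] <- NA_character_
  ds
}

#' Write / read a dataset as CSV
#'
#' Lossless round trip of the five record fields plus the dataset name
#' (stored in a leading `# name:` comment line).
#'
#' @param ds a [mol_dataset()].
#' @param path file path.
#' @return `read_dataset` returns a `mol_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mol_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# name: ", attr(ds, "name")), con)
  utils::write.csv(as.data.frame(ds), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# name:")) stop("not a dataset file: ", path)
  nm <- trimws(sub("^# name:", "", first))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = "")
  need <- c("id", "smiles", "potency_nm", "potency_type", "label")
  if (!all(need %in% names(df))) stop("truncated or malformed dataset file: ", path)
  ds <- data.frame(id = as.character(df$id), smiles = as.character(df$smiles),
                   potency_nm = as.numeric(df$potency_nm),
                   potency_type = as.character(df$potency_type),
                   label = as.character(df$label), stringsAsFactors = FALSE)
  structure(ds, name = nm, class = c("mol_dataset", "data.frame"))
}

#' Read / write SMILES (.smi) files
#'
#' One `SMILES<whitespace>ID` record per line.  Unparseable lines are dropped
#' with a warning on read.
#'
#' @param path file path.
#' @param name dataset name.
#' @param ds a [mol_dataset()] to write.
#' @return `read_smi` returns a `mol_dataset`.
#' @export
read_smi <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty SMILES file: ", path)
  parts <- regmatches(lines, regexpr("[ \t]+", lines), invert = TRUE)
  smi <- vapply(parts, `[`, "", 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1 && nzchar(p[2])) p[2] else NA_character_, "")
  ids[is.na(ids)] <- paste0("L", which(is.na(ids)))
  mol_dataset(smiles = smi, id = make.unique(ids), name = name)
}

#' @rdname read_smi
#' @export
write_smi <- function(ds, path) {
  stopifnot(inherits(ds, "mol_dataset"))
  writeLines(paste(ds$smiles, ds$id), path)
  invisible(path)
}

#' Read compounds from an SDF file
#'
#' @param path SDF file path.
#' @param name dataset name.
#' @return A [mol_dataset()].
#' @export
read_sdf_dataset <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sdf <- ChemmineR::read.SDFset(path)
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  ids <- ChemmineR::sdfid(sdf)
  mol_dataset(smiles = smi, id = make.unique(as.character(ids)), name = name)
}
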