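# Fragment mining: class-discriminative, ring-complete frequent
# substructures.  The search enumerates all connected ring-complete
# subgraphs occurring in the active class (units = bridge bonds and minimal
# rings, so partial rings never appear), deduplicates candidates by a
# canonical graph code, prunes with the anti-monotone active-support
# threshold (Apriori-style over remove-one-unit parents), and counts
# support by subgraph-isomorphism embedding, molecule-level (a molecule
# either contains the fragment or it does not; embedding multiplicity is
# ignored).

#' Mining configuration
#'
#' @param min_support_active minimum fraction of active molecules that must
#'   contain a fragment (default 0.01).
#' @param max_support_inactive maximum fraction of inactive molecules that
#'   may contain a retained fragment (default 0.20).
#' @param ring_mining kept for interface completeness; ring-complete
#'   enumeration is the only supported mode (partial rings never appear).
#' @param max_fragment_atoms largest fragment size in heavy atoms (default 15).
#' @param min_fragment_atoms smallest fragment size in heavy atoms (default 1).
#' @param max_subgraphs_per_mol safety cap on per-molecule subgraph
#'   enumeration.
#' @return A `mining_config` list.
#' @export
mining_config <- function(min_support_active = 0.01,
                          max_support_inactive = 0.20,
                          ring_mining = TRUE,
                          max_fragment_atoms = 15L,
                          min_fragment_atoms = 1L,
                          max_subgraphs_per_mol = 200000L) {
  stopifnot(min_support_active > 0, min_support_active <= 1,
            max_support_inactive >= 0, max_support_inactive <= 1,
            max_fragment_atoms >= 1,
            min_fragment_atoms >= 1,
            min_fragment_atoms <= max_fragment_atoms)
  if (!isTRUE(ring_mining))
    stop("only ring-complete mining is supported (ring_mining = TRUE)")
  structure(list(min_support_active = min_support_active,
                 max_support_inactive = max_support_inactive,
                 ring_mining = TRUE,
                 max_fragment_atoms = as.integer(max_fragment_atoms),
                 min_fragment_atoms = as.integer(min_fragment_atoms),
                 max_subgraphs_per_mol = as.integer(max_subgraphs_per_mol)),
            class = "mining_config")
}

# --- fragment graph <-> text encodings -------------------------------------

ELEMENT_SYMBOLS <- c("1" = "H", "5" = "B", "6" = "C", "7" = "N", "8" = "O",
                     "9" = "F", "14" = "Si", "15" = "P", "16" = "S",
                     "17" = "Cl", "34" = "Se", "35" = "Br", "53" = "I")
ORGANIC_SUBSET <- c(5, 6, 7, 8, 9, 15, 16, 17, 35, 53)
AROMATIC_OK <- c(5, 6, 7, 8, 15, 16, 34)

encode_graph <- function(g) {
  atoms <- paste(g$elem, g$charge, as.integer(g$arom), sep = ".",
                 collapse = "|")
  if (length(g$ba)) {
    bonds <- paste(g$ba, g$bb, g$bo, as.integer(g$barom), sep = ".",
                   collapse = "|")
  } else bonds <- ""
  paste(atoms, bonds, sep = ";")
}

decode_graph <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  am <- do.call(rbind, lapply(strsplit(strsplit(parts[1], "|", fixed = TRUE)[[1]],
                                       ".", fixed = TRUE), as.integer))
  g <- list(elem = am[, 1], charge = am[, 2], arom = am[, 3] == 1L)
  if (length(parts) > 1 && nzchar(parts[2])) {
    bm <- do.call(rbind, lapply(strsplit(strsplit(parts[2], "|", fixed = TRUE)[[1]],
                                         ".", fixed = TRUE), as.integer))
    g$ba <- bm[, 1]; g$bb <- bm[, 2]; g$bo <- bm[, 3]; g$barom <- bm[, 4] == 1L
  } else {
    g$ba <- integer(0); g$bb <- integer(0); g$bo <- integer(0)
    g$barom <- logical(0)
  }
  g
}

# Display SMILES for a fragment graph.  Standard SMILES except that an
# aromatic atom may occur without its complete ring (it is then written
# lowercase anyway); such strings are for reading and fingerprinting, not
# round-tripping, which uses the explicit graph encoding.
frag_smiles <- function(g) {
  n <- length(g$elem)
  if (n == 0) return("")
  nb <- length(g$ba)
  adj <- vector("list", n)
  for (e in seq_len(nb)) {
    adj[[g$ba[e]]] <- c(adj[[g$ba[e]]], e)
    adj[[g$bb[e]]] <- c(adj[[g$bb[e]]], e)
  }
  other <- function(e, v) if (g$ba[e] == v) g$bb[e] else g$ba[e]
  visited <- logical(n)
  used_edge <- logical(nb)
  next_digit <- 0L

  atom_token <- function(v) {
    sym <- ELEMENT_SYMBOLS[as.character(g$elem[v])]
    if (is.na(sym)) sym <- paste0("#", g$elem[v])
    arom <- g$arom[v] && g$elem[v] %in% AROMATIC_OK
    if (arom && nchar(sym) <= 2) sym_a <- tolower(sym) else sym_a <- sym
    plain <- g$charge[v] == 0 && g$elem[v] %in% ORGANIC_SUBSET &&
      (!g$arom[v] || g$elem[v] %in% AROMATIC_OK)
    if (plain) {
      if (arom) sym_a else sym
    } else {
      chg <- if (g$charge[v] > 0) paste0("+", if (g$charge[v] > 1) g$charge[v] else "")
             else if (g$charge[v] < 0) paste0("-", if (g$charge[v] < -1) -g$charge[v] else "")
             else ""
      paste0("[", if (arom) sym_a else sym, chg, "]")
    }
  }
  bond_token <- function(e) {
    if (g$barom[e]) return("")
    if (g$bo[e] == 2) return("=")
    if (g$bo[e] == 3) return("#")
    # single bond between two aromatic atoms must be explicit
    if (g$arom[g$ba[e]] && g$arom[g$bb[e]]) return("-")
    ""
  }
  digit_token <- function(d) if (d < 10) as.character(d) else paste0("%", d)

  # pass 1: DFS classifies tree edges and ring-closure (back) edges and
  # assigns closure digits to both endpoints
  tree_children <- vector("list", n)
  closure_at <- vector("list", n)  # per vertex: list(e, digit)
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    for (e in adj[[v]]) {
      if (used_edge[e]) next
      w <- other(e, v)
      used_edge[e] <<- TRUE
      if (visited[w]) {
        next_digit <<- next_digit + 1L
        closure_at[[v]] <<- c(closure_at[[v]], list(list(e = e, d = next_digit)))
        closure_at[[w]] <<- c(closure_at[[w]], list(list(e = e, d = next_digit)))
      } else {
        tree_children[[v]] <<- c(tree_children[[v]], list(list(e = e, w = w)))
        dfs1(w)
      }
    }
  }
  dfs1(1L)
  # pass 2: emit tokens along the DFS tree
  emit <- function(v, via) {
    out <- character(0)
    if (!is.null(via)) out <- c(out, bond_token(via))
    out <- c(out, atom_token(v))
    for (cl in closure_at[[v]]) out <- c(out, bond_token(cl$e), digit_token(cl$d))
    kids <- tree_children[[v]]
    for (k in seq_along(kids)) {
      sub <- emit(kids[[k]]$w, kids[[k]]$e)
      if (k < length(kids)) sub <- c("(", sub, ")")
      out <- c(out, sub)
    }
    out
  }
  paste(emit(1L, NULL), collapse = "")
}

# --- fragment library -------------------------------------------------------

new_fragment_library <- function(df, graphs, codes, config, provenance) {
  stopifnot(nrow(df) == length(graphs), nrow(df) == length(codes))
  structure(list(fragments = df, graphs = graphs, codes = codes,
                 config = config, provenance = provenance),
            class = "fragment_library")
}

#' @export
length.fragment_library <- function(x) nrow(x$fragments)

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library: %d fragments (%s)>\n",
              nrow(x$fragments), x$provenance))
  print(utils::head(x$fragments, 8))
  if (nrow(x$fragments) > 8)
    cat("... ", nrow(x$fragments) - 8, " more fragments\n", sep = "")
  invisible(x)
}

# deterministic library order: most active-supported first, then smallest,
# then lexicographic, so downstream feature columns are stable across runs
order_library <- function(df) {
  order(-df$support_active, df$n_atoms, df$smiles, method = "radix")
}

#' Mine class-discriminative ring-complete fragments
#'
#' Enumerates every connected, ring-complete substructure occurring in the
#' active class (up to `max_fragment_atoms` heavy atoms) and retains those
#' contained in at least `min_support_active` of the actives and at most
#' `max_support_inactive` of the inactives.  Support is molecule-level:
#' the fraction of molecules with at least one substructure embedding.
#'
#' @param actives,inactives [mol_dataset()]s of the two classes (both
#'   non-empty).
#' @param config a [mining_config()].
#' @return A `fragment_library`: a data.frame of fragments
#'   (`smiles`, `n_atoms`, `support_active`, `support_inactive`) in
#'   deterministic order, plus the mining configuration and provenance.
#' @export
mine_fragments <- function(actives, inactives, config = mining_config()) {
  stopifnot(inherits(actives, "mol_dataset"), inherits(inactives, "mol_dataset"),
            inherits(config, "mining_config"))
  if (nrow(actives) == 0) stop("active class is empty")
  if (nrow(inactives) == 0) stop("inactive class is empty")

  ga <- mol_graphs(actives$smiles)
  gi <- mol_graphs(inactives$smiles)
  ga <- ga[!vapply(ga, is.null, TRUE)]
  gi <- gi[!vapply(gi, is.null, TRUE)]
  na <- length(ga); ni <- length(gi)

  enum <- .cpp_enumerate_fragments(ga, config$max_fragment_atoms,
                                   config$max_subgraphs_per_mol)
  nc <- length(enum$code)
  if (nc == 0) stop("no candidate fragments enumerated")

  # Apriori: process candidates in increasing atom count; a candidate is
  # evaluated only if all its recorded remove-one-unit parents passed.
  ord <- order(enum$n_atoms)
  passed <- logical(nc)
  evaluated <- logical(nc)
  supp_a <- rep(NA_real_, nc)
  sizes <- sort(unique(enum$n_atoms))
  for (s in sizes) {
    ids <- ord[enum$n_atoms[ord] == s]
    elig <- vapply(ids, function(i) {
      p <- enum$parents[[i]]
      length(p) == 0 || all(passed[p])
    }, TRUE)
    ids <- ids[elig]
    if (!length(ids)) next
    counts <- .cpp_support_counts(enum$graph[ids], ga)
    supp_a[ids] <- counts / na
    evaluated[ids] <- TRUE
    passed[ids] <- supp_a[ids] >= config$min_support_active
  }

  keep <- passed & enum$n_atoms >= config$min_fragment_atoms
  idx <- which(keep)
  if (!length(idx)) {
    df <- data.frame(smiles = character(0), n_atoms = integer(0),
                     support_active = numeric(0), support_inactive = numeric(0),
                     stringsAsFactors = FALSE)
    return(new_fragment_library(df, list(), character(0), config,
                                provenance = paste0(attr(actives, "name"), "|",
                                                    attr(inactives, "name"))))
  }
  counts_i <- .cpp_support_counts(enum$graph[idx], gi)
  supp_i <- counts_i / ni
  sel <- supp_i <= config$max_support_inactive
  idx <- idx[sel]
  supp_i <- supp_i[sel]

  graphs <- enum$graph[idx]
  df <- data.frame(
    smiles = vapply(graphs, frag_smiles, ""),
    n_atoms = enum$n_atoms[idx],
    support_active = supp_a[idx],
    support_inactive = supp_i,
    stringsAsFactors = FALSE)
  o <- order_library(df)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  new_fragment_library(df, graphs[o], enum$code[idx][o], config,
                       provenance = paste0(attr(actives, "name"), "|",
                                           attr(inactives, "name")))
}

#' Molecule-level support of a fragment in a dataset
#'
#' Fraction of molecules containing at least one embedding of the fragment
#' (substructure monomorphism on element/charge/aromaticity-typed atoms and
#' order/aromaticity-typed bonds).
#'
#' @param fragment a fragment SMILES string, or a fragment graph from a
#'   `fragment_library`.
#' @param ds a non-empty [mol_dataset()].
#' @return support fraction in \[0, 1\].
#' @export
compute_support <- function(fragment, ds) {
  stopifnot(inherits(ds, "mol_dataset"))
  if (nrow(ds) == 0) stop("empty dataset")
  g <- if (is.character(fragment)) mol_graphs(fragment)[[1]] else fragment
  if (is.null(g)) stop("invalid fragment")
  mg <- mol_graphs(ds$smiles)
  mg <- mg[!vapply(mg, is.null, TRUE)]
  .cpp_support_counts(list(g), mg) / length(mg)
}

#' Write / read a fragment library
#'
#' Tab-separated text: one fragment per line (`smiles`, `n_atoms`,
#' `support_active`, `support_inactive`, `graph`), with the mining
#' configuration and provenance in `#`-prefixed header lines.  The `graph`
#' column is an explicit atom/bond encoding making the round trip lossless
#' even for fragments whose aromatic typing standard SMILES cannot carry.
#'
#' @param lib a `fragment_library`.
#' @param path file path.
#' @return `read_fragment_library` returns a `fragment_library`.
#' @export
write_fragment_library <- function(lib, path) {
  stopifnot(inherits(lib, "fragment_library"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- lib$config
  writeLines(c(
    paste0("# fragment_library v1"),
    paste0("# provenance: ", lib$provenance),
    sprintf("# config: min_support_active=%.17g max_support_inactive=%.17g ring_mining=%d max_fragment_atoms=%d min_fragment_atoms=%d",
            cfg$min_support_active, cfg$max_support_inactive,
            as.integer(cfg$ring_mining), cfg$max_fragment_atoms,
            cfg$min_fragment_atoms),
    "smiles\tn_atoms\tsupport_active\tsupport_inactive\tgraph"), con)
  if (nrow(lib$fragments)) {
    lines <- sprintf("%s\t%d\t%.17g\t%.17g\t%s",
                     lib$fragments$smiles, lib$fragments$n_atoms,
                     lib$fragments$support_active,
                     lib$fragments$support_inactive,
                     vapply(lib$graphs, encode_graph, ""))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_fragment_library
#' @export
read_fragment_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "# fragment_library v1")
    stop("not a fragment library file: ", path)
  prov <- trimws(sub("^# provenance:", "", lines[2]))
  cfg_line <- sub("^# config: ", "", lines[3])
  kv <- strsplit(strsplit(cfg_line, " ")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  config <- mining_config(
    min_support_active = as.numeric(vals["min_support_active"]),
    max_support_inactive = as.numeric(vals["max_support_inactive"]),
    ring_mining = vals["ring_mining"] == "1",
    max_fragment_atoms = as.integer(vals["max_fragment_atoms"]),
    min_fragment_atoms = as.integer(vals["min_fragment_atoms"]))
  body <- lines[-seq_len(4)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    df <- data.frame(smiles = character(0), n_atoms = integer(0),
                     support_active = numeric(0), support_inactive = numeric(0),
                     stringsAsFactors = FALSE)
    return(new_fragment_library(df, list(), character(0), config, prov))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5)) stop("malformed fragment line in ", path)
  graphs <- lapply(parts, function(p) decode_graph(p[5]))
  codes <- .cpp_canonical_code(graphs)
  if (anyDuplicated(codes)) stop("duplicate fragment lines in ", path)
  df <- data.frame(
    smiles = vapply(parts, `[`, "", 1),
    n_atoms = as.integer(vapply(parts, `[`, "", 2)),
    support_active = as.numeric(vapply(parts, `[`, "", 3)),
    support_inactive = as.numeric(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE)
  new_fragment_library(df, graphs, codes, config, prov)
}
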