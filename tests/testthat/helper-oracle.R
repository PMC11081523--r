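# Independent brute-force oracle for fragment mining: enumerates all edge
# subsets of each active molecule, filters connected ring-complete
# subgraphs, groups them by labelled-graph isomorphism (own backtracking
# matcher), and counts support by direct embedding tests.  Shares nothing
# with the package's C++ search except the molecule parser.

# labelled-graph container used by the oracle: adjacency list with atom
# labels "elem/charge/arom" and edge labels (0 = aromatic else order)
orc_graph <- function(g, edge_ids = NULL, atom_ids = NULL) {
  if (is.null(edge_ids)) edge_ids <- seq_along(g$ba)
  if (is.null(atom_ids)) {
    atom_ids <- sort(unique(c(g$ba[edge_ids], g$bb[edge_ids])))
  }
  amap <- match(seq_along(g$elem), atom_ids)
  n <- length(atom_ids)
  alab <- paste(g$elem[atom_ids], g$charge[atom_ids],
                as.integer(g$arom[atom_ids]), sep = "/")
  elab <- ifelse(g$barom[edge_ids], 0L, g$bo[edge_ids])
  adj <- replicate(n, list())
  ea <- amap[g$ba[edge_ids]]; eb <- amap[g$bb[edge_ids]]
  for (k in seq_along(edge_ids)) {
    adj[[ea[k]]] <- c(adj[[ea[k]]], list(c(eb[k], elab[k])))
    adj[[eb[k]]] <- c(adj[[eb[k]]], list(c(ea[k], elab[k])))
  }
  list(n = n, alab = alab, adj = adj,
       ea = ea, eb = eb, elab = elab)
}

orc_connected <- function(gr) {
  if (gr$n == 0) return(FALSE)
  seen <- logical(gr$n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (nb in gr$adj[[v]]) if (!seen[nb[1]]) { seen[nb[1]] <- TRUE; queue <- c(queue, nb[1]) }
  }
  all(seen)
}

# all simple paths a->b (as edge-index sequences over 'edges' rows) -- used
# for minimal-ring discovery on small molecules
orc_min_rings_through <- function(g, eid) {
  # minimal cycles through edge eid: shortest simple paths between its
  # endpoints avoiding eid, plus eid itself; returns list of edge-id sets
  a <- g$ba[eid]; b <- g$bb[eid]
  n <- length(g$elem)
  best <- Inf; found <- list()
  walk <- function(v, path_e, path_v) {
    if (length(path_e) > best) return()
    if (v == b) {
      if (length(path_e) < best) { best <<- length(path_e); found <<- list() }
      if (length(path_e) == best) found[[length(found) + 1L]] <<- path_e
      return()
    }
    for (k in seq_along(g$ba)) {
      if (k == eid || k %in% path_e) next
      w <- if (g$ba[k] == v) g$bb[k] else if (g$bb[k] == v) g$ba[k] else next
      if (w %in% path_v) next
      walk(w, c(path_e, k), c(path_v, w))
    }
  }
  walk(a, integer(0), a)
  lapply(found, function(p) sort(c(p, eid)))
}

orc_ring_complete <- function(g, edge_ids, ring_cache) {
  for (e in edge_ids) {
    rings <- ring_cache[[e]]
    if (!length(rings)) next  # bridge bond
    ok <- any(vapply(rings, function(r) all(r %in% edge_ids), TRUE))
    if (!ok) return(FALSE)
  }
  TRUE
}

# graph isomorphism (exact, labelled) by backtracking
orc_isomorphic <- function(g1, g2) {
  if (g1$n != g2$n) return(FALSE)
  if (length(g1$ea) != length(g2$ea)) return(FALSE)
  if (!identical(sort(g1$alab), sort(g2$alab))) return(FALSE)
  deg1 <- lengths(g1$adj); deg2 <- lengths(g2$adj)
  assign_next <- function(map, used) {
    v <- which(map == 0L)[1]
    if (is.na(v)) return(TRUE)
    for (w in seq_len(g2$n)) {
      if (used[w] || g1$alab[v] != g2$alab[w] || deg1[v] != deg2[w]) next
      ok <- TRUE
      for (nb in g1$adj[[v]]) {
        if (map[nb[1]] == 0L) next
        hit <- any(vapply(g2$adj[[w]], function(nb2)
          nb2[1] == map[nb[1]] && nb2[2] == nb[2], TRUE))
        if (!hit) { ok <- FALSE; break }
      }
      if (!ok) next
      map[v] <- w; used[w] <- TRUE
      if (assign_next(map, used)) return(TRUE)
      map[v] <- 0L; used[w] <- FALSE
    }
    FALSE
  }
  assign_next(integer(g1$n), logical(g2$n))
}

# subgraph monomorphism: does fragment fr embed in molecule mo?
orc_embeds <- function(fr, mo) {
  if (fr$n > mo$n) return(FALSE)
  degf <- lengths(fr$adj); degm <- lengths(mo$adj)
  # BFS order over the (connected) fragment
  ord <- 1L; seen <- logical(fr$n); seen[1] <- TRUE
  i <- 1L
  while (i <= length(ord)) {
    for (nb in fr$adj[[ord[i]]]) if (!seen[nb[1]]) { seen[nb[1]] <- TRUE; ord <- c(ord, nb[1]) }
    i <- i + 1L
  }
  place <- function(k, map, used) {
    if (k > length(ord)) return(TRUE)
    v <- ord[k]
    for (w in seq_len(mo$n)) {
      if (used[w] || fr$alab[v] != mo$alab[w] || degm[w] < degf[v]) next
      ok <- TRUE
      for (nb in fr$adj[[v]]) {
        if (map[nb[1]] == 0L) next
        hit <- any(vapply(mo$adj[[w]], function(nb2)
          nb2[1] == map[nb[1]] && nb2[2] == nb[2], TRUE))
        if (!hit) { ok <- FALSE; break }
      }
      if (!ok) next
      map[v] <- w; used[w] <- TRUE
      if (place(k + 1L, map, used)) return(TRUE)
      map[v] <- 0L; used[w] <- FALSE
    }
    FALSE
  }
  place(1L, integer(fr$n), logical(mo$n))
}

orc_invariant <- function(gr) {
  paste(gr$n, length(gr$ea),
        paste(sort(gr$alab), collapse = ","),
        paste(sort(gr$elab), collapse = ","),
        paste(sort(paste(gr$alab, lengths(gr$adj))), collapse = ","),
        sep = ";")
}

# enumerate distinct connected ring-complete subgraphs (as orc_graphs) of
# one molecule graph, up to max_atoms heavy atoms, single atoms included
orc_subgraphs <- function(g, max_atoms) {
  ne <- length(g$ba)
  ring_cache <- lapply(seq_len(ne), function(e) orc_min_rings_through(g, e))
  out <- list()
  # single atoms
  for (v in seq_along(g$elem)) {
    out[[length(out) + 1L]] <- list(
      n = 1L, alab = paste(g$elem[v], g$charge[v], as.integer(g$arom[v]), sep = "/"),
      adj = list(list()), ea = integer(0), eb = integer(0), elab = integer(0))
  }
  if (ne > 0) {
    for (mask in seq_len(2^ne - 1L)) {
      edge_ids <- which(bitwAnd(mask, 2^(seq_len(ne) - 1L)) > 0)
      gr <- orc_graph(g, edge_ids)
      if (gr$n > max_atoms) next
      if (!orc_connected(gr)) next
      if (!orc_ring_complete(g, edge_ids, ring_cache)) next
      out[[length(out) + 1L]] <- gr
    }
  }
  out
}

# full oracle: mine fragments by brute force
oracle_mine <- function(act_graphs, ina_graphs, min_support_active,
                        max_support_inactive, max_atoms = 8) {
  # collect distinct fragments across actives
  frags <- list(); invs <- character(0)
  for (g in act_graphs) {
    for (gr in orc_subgraphs(g, max_atoms)) {
      inv <- orc_invariant(gr)
      dup <- FALSE
      for (j in which(invs == inv)) {
        if (orc_isomorphic(gr, frags[[j]])) { dup <- TRUE; break }
      }
      if (!dup) { frags[[length(frags) + 1L]] <- gr; invs <- c(invs, inv) }
    }
  }
  act_o <- lapply(act_graphs, function(g) orc_graph(g, seq_along(g$ba), seq_along(g$elem)))
  ina_o <- lapply(ina_graphs, function(g) orc_graph(g, seq_along(g$ba), seq_along(g$elem)))
  keep <- list()
  for (fr in frags) {
    sa <- mean(vapply(act_o, function(mo) orc_embeds(fr, mo), TRUE))
    if (sa < min_support_active) next
    si <- mean(vapply(ina_o, function(mo) orc_embeds(fr, mo), TRUE))
    if (si > max_support_inactive) next
    keep[[length(keep) + 1L]] <- list(graph = fr, support_active = sa,
                                      support_inactive = si)
  }
  keep
}

# pool of small molecules (<= 8 heavy atoms) for oracle datasets
ORACLE_POOL <- c("CCO", "CCN", "c1ccccc1", "C1CCCCC1", "CC(=O)O",
                 "c1ccncc1", "C1CCOC1", "CC(C)C", "C=CC", "N#CC",
                 "OCC(O)C", "C1CC1", "CC1CCC1", "CC(=O)N", "c1ccoc1",
                 "CC=O", "CCS", "ClCC", "c1ccsc1", "OC1CCC1",
                 "Cc1ccccc1", "CCOC", "NCC(=O)O", "C1CCNC1")
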