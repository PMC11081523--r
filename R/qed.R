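# Quantitative estimate of drug-likeness (QED): the mean-weighted
# desirability score of Bickerton et al. (2012).  Eight molecular properties
# (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS) are each mapped through an
# asymmetric double sigmoidal desirability function d(x) fitted to the
# property distribution of approved oral drugs; QED is the geometric
# weighted mean of the eight desirabilities.
#
# Property backends: MW, Wildman-Crippen ALOGP and TPSA come from Open
# Babel; HBA/HBD/ROTB are SMARTS counts (definitions chosen to reproduce the
# reference implementation); AROM is the number of fully aromatic minimal
# rings; ALERTS counts matched structural-alert patterns (shipped in
# extdata).

# ADS parameters (A..F, DMAX) per property, from the original publication
QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140))

# mean weights (QED_w,mo)
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# hydrogen-bond acceptor SMARTS (summed unique matches)
QED_ACCEPTORS <- c(
  "[oH0;X2]", "[OH1;X2;v2]", "[OH0;X2;v2]", "[OH0;X1;v2]", "[O-;X1]",
  "[SH0;X2;v2]", "[SH0;X1;v2]", "[S-;X1]", "[nH0;X2]", "[NH0;X1;v3]",
  "[$([N;+0;X3;v3]);!$(N[C,S]=O)]")

QED_HBD_SMARTS <- "[$([N;!H0;v3]),$([N;!H0;+1;v4]),$([O,S;H1;+0]),$([n;H1;+0])]"

# strict rotatable-bond pattern (excludes terminal, triple-bond-adjacent,
# amide and symmetric-top bonds)
QED_ROTB_SMARTS <- paste0(
  "[!$(*#*)&!D1&!$(C(F)(F)F)&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)&",
  "!$(C([CH3])([CH3])[CH3])&!$([CD3](=[N,O,S])-!@[#7,O,S!D1])&",
  "!$([#7,O,S!D1]-!@[CD3]=[N,O,S])&!$([CD3](=[N+])-!@[#7!D1])&",
  "!$([#7!D1]-!@[CD3]=[N+])]-!@[!$(*#*)&!D1&!$(C(F)(F)F)&",
  "!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)&!$(C([CH3])([CH3])[CH3])]")

qed_alert_patterns <- function() {
  if (!is.null(.ff$qed_alerts)) return(.ff$qed_alerts)
  path <- system.file("extdata", "qed_alert_smarts.txt", package = "fragfocus")
  pats <- readLines(path)
  pats <- pats[!startsWith(pats, "#") & nzchar(pats)]
  # two multi-component count patterns are handled as counting rules
  count_rules <- list()
  plain <- character(0)
  for (p in pats) {
    if (grepl(".", p, fixed = TRUE) &&
        length(unique(strsplit(p, ".", fixed = TRUE)[[1]])) == 1L) {
      comp <- strsplit(p, ".", fixed = TRUE)[[1]]
      count_rules[[length(count_rules) + 1L]] <-
        list(smarts = comp[1], min_count = length(comp))
    } else {
      plain <- c(plain, p)
    }
  }
  compiled <- smarts_compile(plain)
  keep <- !vapply(compiled, is.null, TRUE)
  crules <- lapply(count_rules, function(r) {
    sp <- smarts_compile(r$smarts)[[1]]
    list(sp = sp, min_count = r$min_count)
  })
  .ff$qed_alerts <- list(plain = compiled[keep], count = crules)
  .ff$qed_alerts
}

ads <- function(x, p) {
  # asymmetric double sigmoidal desirability, normalised to its maximum
  a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]; dmax <- p[7]
  v <- a + b / (1 + exp(-(x - c + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - c - d / 2) / f)))
  v / dmax
}

#' QED molecular properties
#'
#' Computes the eight property values underlying the QED score for each
#' structure: molecular weight, Wildman-Crippen logP, hydrogen-bond
#' acceptor and donor counts, topological polar surface area, rotatable
#' bonds, aromatic ring count, and structural-alert matches.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns MW, ALOGP, HBA, HBD, PSA, ROTB, AROM,
#'   ALERTS; rows of unparseable structures are NA.
#' @export
qed_properties <- function(smiles) {
  mols <- ob_parse(smiles)
  ok <- !vapply(mols, is.null, TRUE)
  n <- length(smiles)
  out <- data.frame(MW = rep(NA_real_, n), ALOGP = NA_real_, HBA = NA_real_,
                    HBD = NA_real_, PSA = NA_real_, ROTB = NA_real_,
                    AROM = NA_real_, ALERTS = NA_real_)
  if (!any(ok)) return(out)
  props <- ChemmineOB::prop_OB(mols[ok])
  out$MW[ok] <- props$MW
  out$ALOGP[ok] <- props$logP
  out$PSA[ok] <- props$TPSA
  if (is.null(.ff$qed_smarts)) {
    .ff$qed_smarts <- list(
      acc = smarts_compile(QED_ACCEPTORS),
      hbd = smarts_compile(QED_HBD_SMARTS)[[1]],
      rotb = smarts_compile(QED_ROTB_SMARTS)[[1]])
  }
  qs <- .ff$qed_smarts
  al <- qed_alert_patterns()
  hba <- hbd <- rotb <- alerts <- numeric(sum(ok))
  for (i in seq_along(which(ok))) {
    m <- mols[ok][[i]]
    hba[i] <- sum(vapply(qs$acc, smarts_count, 0L, mol = m))
    hbd[i] <- smarts_count(qs$hbd, m)
    rotb[i] <- smarts_count(qs$rotb, m)
    nal <- sum(vapply(al$plain, function(sp) smarts_count(sp, m) > 0, TRUE))
    nal <- nal + sum(vapply(al$count, function(r) smarts_count(r$sp, m) >= r$min_count, TRUE))
    alerts[i] <- nal
  }
  out$HBA[ok] <- hba
  out$HBD[ok] <- hbd
  out$ROTB[ok] <- rotb
  out$ALERTS[ok] <- alerts
  gr <- mol_graphs(smiles[ok])
  rc <- .cpp_ring_counts(gr)
  out$AROM[ok] <- rc[, "aromatic_rings"]
  out
}

#' QED score from property values
#'
#' Applies the desirability functions and the weighted geometric mean to
#' already-computed property values; exposed so the scoring step can be
#' tested independently of the descriptor backend.
#'
#' @param props data.frame as returned by [qed_properties()].
#' @return numeric vector of QED scores in \[0, 1\].
#' @export
qed_from_properties <- function(props) {
  stopifnot(all(names(QED_ADS) %in% names(props)))
  d <- vapply(names(QED_ADS), function(nm) {
    pmin(pmax(ads(props[[nm]], QED_ADS[[nm]]), 1e-12), 1)
  }, numeric(nrow(props)))
  d <- matrix(d, nrow = nrow(props))
  w <- QED_WEIGHTS[names(QED_ADS)]
  exp(as.vector(log(d) %*% w) / sum(w))
}

#' Quantitative estimate of drug-likeness
#'
#' Mean-weighted QED score in \[0, 1\]; higher is more drug-like.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of scores (`NA` for unparseable input).
#' @examples
#' compute_qed("CC(=O)Nc1ccc(O)cc1")  # paracetamol
#' @export
compute_qed <- function(smiles) {
  if (!length(smiles)) return(numeric(0))
  props <- qed_properties(smiles)
  out <- rep(NA_real_, length(smiles))
  ok <- stats::complete.cases(props)
  if (any(ok)) out[ok] <- qed_from_properties(props[ok, , drop = FALSE])
  out
}
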