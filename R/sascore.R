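# Synthetic accessibility score (Ertl-Schuffenhauer heuristic).
#
# score = fragment-frequency term - (size, spiro, bridgehead, macrocycle
# penalties) + symmetry correction, rescaled to [1, 10] (1 = easy). The
# published method calibrates fragment contributions on ~1M PubChem
# compounds; that table cannot be bundled here, so contributions are
# computed from a reference corpus (default: a small built-in synthetic
# calibration set of common medicinal-chemistry moieties). Unknown
# fragments get the floor contribution of -4, so the score is a relative,
# not absolute, measure - adequate for the ordering comparisons it is used
# for in this package.

# Built-in calibration set: common drug-like moieties, hand-picked for this
# package (synthetic stand-in for a PubChem-derived frequency table).
.SAS_CALIBRATION <- c(
  "CC", "CCC", "CCCC", "CC(C)C", "CCO", "CCN", "CCOC", "CC(C)=O", "CC(=O)O",
  "CC(=O)N", "CC(=O)NC", "CCS", "CCCl", "CCF", "CCBr",
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "COc1ccccc1", "Clc1ccccc1", "Fc1ccccc1", "CC(=O)c1ccccc1",
  "OC(=O)c1ccccc1", "NC(=O)c1ccccc1", "CNc1ccccc1", "CN(C)c1ccccc1",
  "c1ccncc1", "Cc1ccncc1", "c1ccc2ccccc2c1", "c1cc[nH]c1", "c1ccsc1",
  "c1ccoc1", "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "CN1CCCCC1", "C1CCNC1",
  "O=C1CCCCC1", "CC1CCCCC1", "c1ccc(-c2ccccc2)cc1", "OCC1CCCCC1",
  "CC(N)C(=O)O", "NCCO", "OCCO", "CNC", "CN(C)C", "CC#N", "CC=C", "C=CC=C",
  "CS(=O)(=O)C", "NS(=O)(=O)c1ccccc1", "O=[N+]([O-])c1ccccc1",
  "CC(C)(C)C", "CC(C)O", "CC(C)N", "CCCCCCCC", "Cn1ccnc1", "OC1CCCCC1"
)

.sas_env <- new.env(parent = emptyenv())

# Fragment contributions from a reference corpus: log10 of each circular
# fragment's count relative to the mean count, clipped to [-4, 4].
sas_fragment_table <- function(corpus) {
  counts <- new.env(parent = emptyenv(), size = 2048L)
  for (s in corpus) {
    inv <- unlist(morgan_invariants(parse_smiles(s), 2L), use.names = FALSE)
    for (k in as.character(inv)) {
      assign(k, get0(k, counts, ifnotfound = 0L) + 1L, counts)
    }
  }
  keys <- ls(counts)
  vals <- as.numeric(unlist(mget(keys, counts), use.names = FALSE))
  contrib <- pmin(pmax(log10(vals / mean(vals)), -4), 4)
  stats::setNames(contrib, keys)
}

sas_default_table <- function() {
  tbl <- get0("table", .sas_env)
  if (is.null(tbl)) {
    tbl <- sas_fragment_table(.SAS_CALIBRATION)
    assign("table", tbl, .sas_env)
  }
  tbl
}

#' Ertl-Schuffenhauer synthetic accessibility score
#'
#' @param smiles a SMILES string
#' @param frag_table named numeric vector of fragment contributions (default:
#'   built from the package's calibration set)
#' @return score in `[1, 10]`, lower = easier to synthesize
#' @export
sascore <- function(smiles, frag_table = sas_default_table()) {
  mol <- as_mg_mol(smiles)
  n_heavy <- mg_n_heavy(mol)
  if (n_heavy == 0L) return(1)
  inv <- unlist(morgan_invariants(mol, 2L), use.names = FALSE)
  keys <- as.character(inv)
  contrib <- frag_table[keys]
  contrib[is.na(contrib)] <- -4
  score1 <- sum(contrib) / length(contrib)

  adj <- mg_adj(mol)
  ringb <- mg_ring_bonds(mol, adj)
  rings <- find_small_rings(mol, adj, ringb, max_size = 12L)
  n_macro <- sum(lengths(rings) > 8L)
  # spiro atom: sole shared atom of two rings; bridgehead: in the >=2-atom
  # overlap of two rings that is not just a fused bond pair's both atoms
  n_spiro <- 0L; n_bridge <- 0L
  if (length(rings) >= 2L) {
    for (a in seq_len(length(rings) - 1L)) {
      for (b in seq.int(a + 1L, length(rings))) {
        ov <- intersect(rings[[a]], rings[[b]])
        if (length(ov) == 1L) n_spiro <- n_spiro + 1L
        if (length(ov) > 2L) n_bridge <- n_bridge + 1L
      }
    }
  }
  size_penalty <- n_heavy^1.005 - n_heavy
  spiro_penalty <- log10(n_spiro + 1)
  bridge_penalty <- log10(n_bridge + 1)
  macro_penalty <- if (n_macro > 0L) log10(2) else 0
  score2 <- -size_penalty - spiro_penalty - bridge_penalty - macro_penalty
  n_frag_distinct <- length(unique(keys))
  score3 <- if (n_heavy > n_frag_distinct) log(n_heavy / n_frag_distinct) * 0.5 else 0

  raw <- score1 + score2 + score3
  sa <- 11 - (raw + 4 + 1) / (2.5 + 4 + 1) * 9
  if (sa > 8) sa <- 8 + log(sa + 1 - 9)
  min(max(sa, 1), 10)
}
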