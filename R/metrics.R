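# Evaluation metrics: novelty, diversity, corpus novelty, physicochemical
# panel, Murcko scaffolds, PAINS screening, pluggable complexity scoring.

#' Mean Tanimoto distance of generated molecules to a parent
#'
#' @param parent parent molecule (SMILES, record or internal object)
#' @param generated character vector of generated SMILES
#' @param cfg a [fingerprint_config()]
#' @return mean of (1 - Tanimoto similarity) in `[0, 1]`
#' @export
novelty <- function(parent, generated, cfg = fingerprint_config()) {
  if (!length(generated)) stop_mg("mg_undefined_error", "novelty of an empty set is undefined")
  fp0 <- morgan_fp(parent, cfg)
  mean(vapply(generated, function(s) 1 - tanimoto(fp0, morgan_fp(s, cfg)), 0))
}

#' Mean pairwise Tanimoto distance within a generated set
#'
#' Exact over all pairs when the set is small; otherwise estimated on
#' `repeats` seeded random subsets of size `subsample` (mean and spread over
#' the repeats).
#'
#' @param generated character vector of SMILES (>= 2)
#' @param cfg a [fingerprint_config()]
#' @param subsample subset size triggering estimation (default 1000)
#' @param repeats number of seeded subsamples (default 5)
#' @param seed RNG seed for subsampling
#' @return list with `mean`, `spread` (sd over repeats; 0 when exact) and
#'   `exact`
#' @export
diversity <- function(generated, cfg = fingerprint_config(), subsample = 1000L,
                      repeats = 5L, seed = NULL) {
  if (length(generated) < 2L) {
    stop_mg("mg_undefined_error", "diversity needs at least 2 molecules")
  }
  pair_mean <- function(smiles) {
    fps <- lapply(smiles, morgan_fp, cfg = cfg)
    n <- length(fps)
    tot <- 0
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) tot <- tot + (1 - tanimoto(fps[[i]], fps[[j]]))
    }
    tot / (n * (n - 1L) / 2L)
  }
  if (length(generated) <= subsample) {
    return(list(mean = pair_mean(generated), spread = 0, exact = TRUE))
  }
  vals <- with_seed(seed, vapply(seq_len(repeats), function(k) {
    pair_mean(sample(generated, subsample))
  }, 0))
  list(mean = mean(vals), spread = stats::sd(vals), exact = FALSE)
}

#' Percentage of generated molecules absent from the fragmentation corpus
#'
#' @param generated character vector of canonical SMILES
#' @param corpus character vector of canonical SMILES
#' @return percentage in `[0, 100]`
#' @export
corpus_novelty <- function(generated, corpus) {
  generated <- unique(generated)
  if (!length(generated)) stop_mg("mg_undefined_error", "corpus novelty of an empty set is undefined")
  100 * sum(!(generated %in% corpus)) / length(generated)
}

.ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
                  I = 126.904)

#' Molecular weight (average atomic masses, implicit H included)
#' @param mol molecule
#' @return weight in g/mol
#' @export
mol_weight <- function(mol) {
  mol <- as_mg_mol(mol)
  heavy <- mol$elem[mol$elem != "*"]
  sum(.ATOMIC_MASS[heavy]) + sum(mol$nH[mol$elem != "*"]) * .ATOMIC_MASS[["H"]]
}

#' Physicochemical property panel
#'
#' Nine descriptors: HBD (N/O atoms bearing >= 1 H), HBA (N + O count), MW,
#' logP (coarse Crippen-style atom contributions - indicative, not
#' toolkit-identical), RTB (acyclic single bonds between non-terminal heavy
#' atoms, triple-bond ends excluded), TPSA (Ertl N/O contributions),
#' NumRings (cyclomatic number), Csp3 (fraction of saturated carbons) and
#' fmf (fraction of heavy atoms in the Murcko framework).
#'
#' @param mol molecule (SMILES, record or internal object)
#' @return one-row data.frame with the nine named columns
#' @export
property_panel <- function(mol) {
  mol <- as_mg_mol(mol)
  adj <- mg_adj(mol)
  ringb <- mg_ring_bonds(mol, adj)
  n <- mg_natoms(mol)
  deg <- tabulate(c(mol$bond_a, mol$bond_b), nbins = n)
  is_no <- mol$elem %in% c("N", "O")
  hbd <- sum(is_no & mol$nH >= 1L)
  hba <- sum(is_no)
  mw <- mol_weight(mol)
  # rotatable bonds
  triple_atom <- logical(n)
  if (mg_nbonds(mol)) {
    t3 <- mol$border == 3
    triple_atom[unique(c(mol$bond_a[t3], mol$bond_b[t3]))] <- TRUE
  }
  rtb <- 0L
  for (b in seq_len(mg_nbonds(mol))) {
    a1 <- mol$bond_a[b]; a2 <- mol$bond_b[b]
    if (mol$border[b] == 1 && !ringb[b] && deg[a1] >= 2L && deg[a2] >= 2L &&
        !triple_atom[a1] && !triple_atom[a2]) rtb <- rtb + 1L
  }
  nrings <- mg_nbonds(mol) - n + max(mg_components(mol, adj), 0L)
  carbons <- mol$elem == "C"
  sp3 <- carbons & !mol$arom
  if (any(sp3)) {
    for (b in seq_len(mg_nbonds(mol))) {
      if (mol$border[b] > 1) {
        sp3[mol$bond_a[b]] <- FALSE
        sp3[mol$bond_b[b]] <- FALSE
      }
    }
  }
  csp3 <- if (sum(carbons)) sum(sp3 & carbons) / sum(carbons) else 0
  scaf <- murcko_scaffold(mol)
  fmf <- if (nzchar(scaf)) mg_n_heavy(parse_smiles(scaf)) / mg_n_heavy(mol) else 0
  data.frame(HBD = hbd, HBA = hba, MW = mw, logP = crippen_logp(mol),
             RTB = rtb, TPSA = tpsa(mol), NumRings = as.integer(nrings),
             Csp3 = csp3, fmf = fmf)
}

# Coarse Crippen-style logP: one contribution per atom class plus hydrogen
# terms. Chosen to track the sign and rough magnitude of the published
# atom-contribution scheme; values are indicative only.
crippen_logp <- function(mol) {
  mol <- as_mg_mol(mol)
  adj <- mg_adj(mol)
  lp <- 0
  hetero <- c("N", "O", "S", "P", "F", "Cl", "Br", "I")
  for (i in seq_len(mg_natoms(mol))) {
    e <- mol$elem[i]
    nbr_elems <- mol$elem[adj$nbr[[i]]]
    has_het <- any(nbr_elems %in% hetero)
    c_i <- switch(e,
      C = if (mol$arom[i]) { if (has_het) 0.10 else 0.16 }
          else { if (has_het) -0.20 else 0.14 },
      N = if (mol$arom[i]) -0.60 else -1.02,
      O = {
        dbl <- any(mol$border[adj$bond[[i]]] == 2)
        if (mol$arom[i]) 0.11 else if (dbl) -0.12 else if (mol$nH[i] > 0L) -0.39 else -0.27
      },
      S = 0.65, P = 0.86, F = 0.42, Cl = 0.69, Br = 0.85, I = 0.89, B = -0.04,
      0)
    h_i <- if (e == "C") 0.12 * mol$nH[i] else if (e %in% hetero) -0.27 * mol$nH[i] else 0
    lp <- lp + c_i + h_i
  }
  round(lp, 3)
}

# Ertl topological polar surface area, N/O contributions.
tpsa <- function(mol) {
  mol <- as_mg_mol(mol)
  adj <- mg_adj(mol)
  total <- 0
  for (i in seq_len(mg_natoms(mol))) {
    e <- mol$elem[i]
    if (!(e %in% c("N", "O"))) next
    orders <- mol$border[adj$bond[[i]]]
    ns <- sum(orders == 1); nd <- sum(orders == 2); nt <- sum(orders == 3)
    na_ <- sum(orders == 1.5)
    h <- mol$nH[i]; ch <- mol$charge[i]
    in3 <- in_three_ring(mol, adj, i)
    contrib <-
      if (e == "N" && !mol$arom[i] && ch == 0L) {
        if (h == 0L && ns == 3 && nd == 0 && nt == 0) { if (in3) 3.01 else 3.24 }
        else if (h == 0L && ns == 1 && nd == 1) 12.36
        else if (h == 0L && nt == 1 && ns == 0) 23.79
        else if (h == 0L && ns == 1 && nd == 2) 11.68
        else if (h == 1L && ns == 2) { if (in3) 21.94 else 12.03 }
        else if (h == 1L && nd == 1 && ns == 0) 23.85
        else if (h == 2L && ns == 1) 26.02
        else 11.68
      } else if (e == "N" && !mol$arom[i] && ch == 1L) {
        if (h == 0L && ns == 4) 0.00
        else if (h == 0L && ns == 2 && nd == 1) 3.01
        else if (h == 0L && nt == 1) 4.36
        else if (h == 1L && ns == 3) 4.44
        else if (h == 1L && ns == 1 && nd == 1) 13.97
        else if (h == 2L && ns == 2) 16.61
        else if (h == 2L && nd == 1) 25.59
        else if (h == 3L) 27.64
        else 4.44
      } else if (e == "N" && mol$arom[i]) {
        if (ch == 1L) { if (h == 1L) 14.14 else if (ns == 1) 3.88 else 4.10 }
        else if (h >= 1L) 15.79
        else if (na_ + ns + nd >= 3) { if (ns >= 1) 4.93 else if (nd >= 1) 8.39 else 4.41 }
        else 12.89
      } else if (e == "O" && !mol$arom[i]) {
        if (ch == -1L) 23.06
        else if (nd >= 1) 17.07
        else if (h >= 1L) 20.23
        else if (in3) 12.53
        else 9.23
      } else if (e == "O" && mol$arom[i]) 13.14
      else 0
    total <- total + contrib
  }
  round(total, 2)
}

in_three_ring <- function(mol, adj, i) {
  nb <- adj$nbr[[i]]
  if (length(nb) < 2L) return(FALSE)
  for (a in seq_len(length(nb) - 1L)) {
    for (b in seq.int(a + 1L, length(nb))) {
      if (any((mol$bond_a == nb[a] & mol$bond_b == nb[b]) |
              (mol$bond_b == nb[a] & mol$bond_a == nb[b]))) return(TRUE)
    }
  }
  FALSE
}

#' Bemis-Murcko scaffold (ring systems plus linkers)
#'
#' Terminal atoms attached by single bonds are pruned iteratively; atoms
#' double- or triple-bonded to the framework are retained. Acyclic molecules
#' return the empty string.
#'
#' @param mol molecule (SMILES, record or internal object)
#' @return canonical scaffold SMILES, or `""`
#' @export
murcko_scaffold <- function(mol) {
  mol <- as_mg_mol(mol)
  n <- mg_natoms(mol)
  if (n == 0L || mg_nbonds(mol) == 0L) return("")
  # framework = fixed point of removing terminal atoms (any bond order):
  # rings plus the linkers between them
  keep <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    for (b in seq_len(mg_nbonds(mol))) {
      a1 <- mol$bond_a[b]; a2 <- mol$bond_b[b]
      if (keep[a1] && keep[a2]) { deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L }
    }
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return("")
  # re-attach atoms multiply bonded straight onto the framework (exocyclic
  # =O and the like stay part of the scaffold)
  repeat {
    added <- FALSE
    for (b in seq_len(mg_nbonds(mol))) {
      if (mol$border[b] < 2) next
      a1 <- mol$bond_a[b]; a2 <- mol$bond_b[b]
      if (keep[a1] != keep[a2]) {
        keep[a1] <- keep[a2] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  gain <- integer(n)
  for (b in seq_len(mg_nbonds(mol))) {
    a1 <- mol$bond_a[b]; a2 <- mol$bond_b[b]
    if (keep[a1] != keep[a2]) {
      kept <- if (keep[a1]) a1 else a2
      gain[kept] <- gain[kept] + (if (mol$border[b] == 2) 2L else if (mol$border[b] == 3) 3L else 1L)
    }
  }
  scaf <- mg_subgraph(mol, which(keep))
  scaf$nH <- scaf$nH + gain[attr(scaf, "src")]
  if (mg_nbonds(scaf) == 0L || !any(mg_ring_bonds(scaf))) return("")
  canonical_smiles(scaf)
}

#' Scaffold novelty across generation iterations
#'
#' @param generated_by_iteration list of SMILES character vectors, one per
#'   iteration
#' @param corpus character vector of corpus SMILES
#' @return data.frame with per-iteration and cumulative distinct-scaffold
#'   counts and novel percentages (acyclic molecules, which have no
#'   scaffold, are skipped)
#' @export
scaffold_novelty <- function(generated_by_iteration, corpus) {
  corpus_scafs <- unique(vapply(corpus, murcko_scaffold, "", USE.NAMES = FALSE))
  corpus_scafs <- corpus_scafs[nzchar(corpus_scafs)]
  cum <- character(0L)
  rows <- lapply(seq_along(generated_by_iteration), function(it) {
    scafs <- unique(vapply(generated_by_iteration[[it]], murcko_scaffold, "",
                           USE.NAMES = FALSE))
    scafs <- scafs[nzchar(scafs)]
    cum <<- union(cum, scafs)
    data.frame(
      iteration = it,
      n_scaffolds = length(scafs),
      pct_novel = if (length(scafs)) 100 * mean(!(scafs %in% corpus_scafs)) else 0,
      n_cumulative = length(cum),
      pct_novel_cumulative = if (length(cum)) 100 * mean(!(cum %in% corpus_scafs)) else 0
    )
  })
  do.call(rbind, rows)
}

#' Load a SMARTS catalog (e.g. PAINS patterns)
#'
#' @param path TSV file with columns `name` and `smarts` (no header)
#' @return data.frame with compiled patterns attached
#' @export
load_smarts_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop_mg("mg_config_error", "catalog rows must be 'name<TAB>smarts'")
  }
  name <- vapply(parts, `[[`, "", 1L)
  smarts <- vapply(parts, `[[`, "", 2L)
  compiled <- lapply(seq_along(smarts), function(i) {
    tryCatch(parse_smarts(smarts[i]), mg_smarts_error = function(e) {
      stop_mg("mg_config_error", "invalid SMARTS for '%s': %s", name[i],
              conditionMessage(e))
    })
  })
  structure(data.frame(name = name, smarts = smarts),
            compiled = compiled, class = c("smarts_catalog", "data.frame"))
}

#' Names of catalog patterns matching a molecule
#'
#' @param mol molecule (SMILES, record or internal object)
#' @param catalog a catalog from [load_smarts_catalog()]
#' @return character vector of matching pattern names
#' @export
pains_matches <- function(mol, catalog) {
  mol <- as_mg_mol(mol)
  if (!nrow(catalog)) return(character(0L))
  ft <- smarts_mol_features(mol)
  compiled <- attr(catalog, "compiled")
  hit <- vapply(compiled, function(p) length(match_smarts_rooted(mol, ft, p)) > 0L, TRUE)
  catalog$name[hit]
}

# ---- pluggable complexity scoring ---------------------------------------

.scorers <- new.env(parent = emptyenv())

#' Register a synthetic-complexity scorer
#'
#' @param name scorer name
#' @param fn function taking a canonical SMILES and returning a numeric
#' @export
register_scorer <- function(name, fn) {
  assign(name, fn, .scorers)
  invisible(name)
}

#' Synthetic-complexity score of a molecule
#'
#' The built-in `"sascore"` implements the Ertl-Schuffenhauer heuristic
#' (fragment-frequency term plus size/ring-complexity penalties), clamped to
#' `[1, 10]`. Any registered or supplied function can be used instead, e.g.
#' an external learned model.
#'
#' @param mol molecule (SMILES, record or internal object)
#' @param scorer scorer name or function
#' @return numeric score
#' @export
complexity_score <- function(mol, scorer = "sascore") {
  s <- if (is.function(scorer)) scorer else get0(scorer, .scorers)
  if (is.null(s)) stop_mg("mg_config_error", "unknown scorer '%s'", scorer)
  mol <- as_mg_mol(mol)
  s(canonical_smiles(mol))
}
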