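# Synthetic fixture corpora with known interchangeability structure, plus a
# brute-force oracle that re-derives fragment databases and mutate outputs
# by direct enumeration. The oracle shares only the SMILES toolkit (parser,
# canonicalizer, pair canonicalization) with the main pipeline; cut-set
# enumeration, ring detection, component labelling, context truncation and
# splicing are reimplemented here with different algorithms (adjacency-
# matrix reachability instead of DFS/BFS) to catch order-dependent bugs.

#' Generate a synthetic fixture corpus
#'
#' Kinds: `homologs` (n-alkylbenzenes C1..Cn), `decorated_aromatics`
#' (benzene with 1-3 sampled substituents), `linkers`
#' (alpha,omega-disubstituted alkyl chains), `pains_free` (decorated
#' aromatics plus linkers, purged of molecules matching `exclude_smarts`).
#'
#' @param kind corpus kind
#' @param n number of molecules to generate (before deduplication /
#'   purging)
#' @param seed RNG seed
#' @param exclude_smarts pattern rejected by the `pains_free` kind (default:
#'   aryl alkyl ether, the scaled-down undesirable motif)
#' @return a `fixture_corpus` list with `molecules` (canonical SMILES) and
#'   `description`
#' @export
synth_corpus <- function(kind = c("homologs", "decorated_aromatics", "linkers",
                                  "pains_free"),
                         n = 10L, seed = 1L,
                         exclude_smarts = "c[OX2][CX4]") {
  if (n < 1L) stop_mg("mg_param_error", "n must be >= 1")
  kind <- match.arg(kind)
  smiles <- switch(kind,
    homologs = vapply(seq_len(n), function(k) {
      paste0(strrep("C", k), "c1ccccc1")
    }, ""),
    decorated_aromatics = with_seed(seed, decorated_aromatics(n)),
    linkers = with_seed(seed, linker_chains(n)),
    pains_free = {
      base <- c(with_seed(seed, decorated_aromatics(n)),
                with_seed(seed + 1L, linker_chains(n)))
      pat <- parse_smarts(exclude_smarts)
      base[!vapply(base, function(s) has_substructure(s, pat), TRUE)]
    })
  canon <- unique(vapply(smiles, function(s) canonical_smiles(s), "", USE.NAMES = FALSE))
  structure(list(molecules = canon,
                 description = sprintf("%s fixture corpus (n = %d, seed = %d)",
                                       kind, n, seed)),
            class = "fixture_corpus")
}

.AROMATIC_SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "N", "NC",
                            "N(C)C", "F", "Cl", "Br", "C(=O)C", "C(=O)O",
                            "C(=O)N", "C#N", "S", "SC", "CO", "CC(=O)O")

decorated_aromatics <- function(n) {
  vapply(seq_len(n), function(k) {
    nsub <- sample(1:3, 1L)
    pos <- sample(2:6, nsub)
    subs <- sample(.AROMATIC_SUBSTITUENTS, nsub, replace = TRUE)
    branch <- rep("", 6L)
    branch[pos] <- subs
    paste0("c1",
           paste0("c", ifelse(nzchar(branch[2:5]), paste0("(", branch[2:5], ")"), ""),
                  collapse = ""),
           "c1", branch[6L])
  }, "")
}

.LINKER_CAPS_PRE <- c("O", "N", "C", "CO", "Cl", "OC(=O)")
.LINKER_CAPS_SUF <- c("O", "N", "C", "OC", "Cl", "C(=O)O")

linker_chains <- function(n) {
  vapply(seq_len(n), function(k) {
    m <- sample(1:4, 1L)
    paste0(sample(.LINKER_CAPS_PRE, 1L), strrep("C", m + 1L),
           sample(.LINKER_CAPS_SUF, 1L))
  }, "")
}

# ---- brute-force oracle --------------------------------------------------

oracle_adjacency <- function(mol) {
  n <- mg_natoms(mol)
  A <- matrix(0, n, n)
  for (b in seq_len(mg_nbonds(mol))) {
    A[mol$bond_a[b], mol$bond_b[b]] <- 1
    A[mol$bond_b[b], mol$bond_a[b]] <- 1
  }
  A
}

# reachability by repeated matrix multiplication
oracle_reach <- function(A) {
  n <- nrow(A)
  R <- A + diag(n)
  repeat {
    R2 <- (R %*% R > 0) * 1
    if (all(R2 == R)) return(R)
    R <- R2
  }
}

oracle_ring_bond <- function(mol, b) {
  A <- oracle_adjacency(mol)
  A[mol$bond_a[b], mol$bond_b[b]] <- 0
  A[mol$bond_b[b], mol$bond_a[b]] <- 0
  R <- oracle_reach(A)
  R[mol$bond_a[b], mol$bond_b[b]] > 0
}

# components as label vector, via reachability matrix
oracle_components <- function(A) {
  R <- oracle_reach(A)
  labels <- integer(nrow(A))
  cur <- 0L
  for (i in seq_len(nrow(A))) {
    if (labels[i] == 0L) {
      cur <- cur + 1L
      labels[R[i, ] > 0] <- cur
    }
  }
  labels
}

# distance-limited atom set via matrix powers
oracle_within <- function(A, sources, radius) {
  n <- nrow(A)
  reach <- rep(FALSE, n)
  reach[sources] <- TRUE
  frontier <- reach
  for (r in seq_len(radius)) {
    frontier <- as.vector(A %*% frontier > 0)
    reach <- reach | frontier
  }
  which(reach)
}

oracle_fragmentations <- function(mol, max_cuts = 4L) {
  n0 <- mg_natoms(mol)
  heavy <- !(mol$elem %in% c("H", "*"))
  elig <- which(vapply(seq_len(mg_nbonds(mol)), function(b) {
    mol$border[b] == 1 && heavy[mol$bond_a[b]] && heavy[mol$bond_b[b]] &&
      !oracle_ring_bond(mol, b)
  }, TRUE))
  recs <- list()
  for (k in seq_len(min(max_cuts, length(elig)))) {
    for (cs in safe_combn(elig, k)) {
      frag <- mol
      keep <- setdiff(seq_len(mg_nbonds(mol)), cs)
      ca <- mol$bond_a[cs]; cb <- mol$bond_b[cs]
      frag$bond_a <- frag$bond_a[keep]; frag$bond_b <- frag$bond_b[keep]
      frag$border <- frag$border[keep]
      for (i in seq_len(k)) {
        frag$elem <- c(frag$elem, "*", "*"); frag$arom <- c(frag$arom, FALSE, FALSE)
        frag$charge <- c(frag$charge, 0L, 0L); frag$nH <- c(frag$nH, 0L, 0L)
        frag$map <- c(frag$map, i, i); frag$isotope <- c(frag$isotope, 0L, 0L)
        frag <- mg_add_bond(frag, ca[i], n0 + 2L * i - 1L, 1)
        frag <- mg_add_bond(frag, cb[i], n0 + 2L * i, 1)
      }
      comp <- oracle_components(oracle_adjacency(frag))
      dummies <- n0 + seq_len(2L * k)
      for (ci in unique(comp)) {
        dmaps <- frag$map[dummies[comp[dummies] == ci]]
        if (length(dmaps) == k && setequal(dmaps, seq_len(k))) {
          core <- mg_subgraph(frag, which(comp == ci))
          ctxt <- mg_subgraph(frag, which(comp != ci))
          recs[[length(recs) + 1L]] <- list(core = core, context = ctxt)
        }
      }
    }
  }
  # hydrogen cuts
  h_core <- parse_smiles("[H][*:1]", sanitize = FALSE)
  seen <- character(0L)
  for (i in which(mol$nH >= 1L & heavy)) {
    ctxt <- mol
    ctxt$nH[i] <- ctxt$nH[i] - 1L
    ctxt$elem <- c(ctxt$elem, "*"); ctxt$arom <- c(ctxt$arom, FALSE)
    ctxt$charge <- c(ctxt$charge, 0L); ctxt$nH <- c(ctxt$nH, 0L)
    ctxt$map <- c(ctxt$map, 1L); ctxt$isotope <- c(ctxt$isotope, 0L)
    ctxt <- mg_add_bond(ctxt, i, n0 + 1L, 1)
    key <- canonical_smiles(ctxt)
    if (key %in% seen) next
    seen <- c(seen, key)
    recs[[length(recs) + 1L]] <- list(core = h_core, context = ctxt)
  }
  recs
}

oracle_truncate <- function(ctxt, radius) {
  A <- oracle_adjacency(ctxt)
  dummies <- which(mg_is_dummy(ctxt))
  keep <- oracle_within(A, dummies, radius)
  if (length(keep) == mg_natoms(ctxt)) return(ctxt)
  inkeep <- seq_len(mg_natoms(ctxt)) %in% keep
  gain <- integer(mg_natoms(ctxt))
  for (b in seq_len(mg_nbonds(ctxt))) {
    a1 <- ctxt$bond_a[b]; a2 <- ctxt$bond_b[b]
    if (xor(inkeep[a1], inkeep[a2])) {
      h <- c(`1` = 1L, `1.5` = 1L, `2` = 2L, `3` = 3L)[[as.character(ctxt$border[b])]]
      keep_atom <- if (inkeep[a1]) a1 else a2
      gain[keep_atom] <- gain[keep_atom] + h
    }
  }
  sub <- mg_subgraph(ctxt, keep)
  sub$nH <- sub$nH + gain[attr(sub, "src")]
  sub
}

#' Brute-force oracle: interchangeable (context, core) table for a corpus
#'
#' Re-derives, by direct enumeration, exactly what [build_db()] computes;
#' used as ground truth in tests.
#'
#' @param corpus a `fixture_corpus`, or character vector of SMILES
#' @param radius context radius
#' @param max_cuts maximum simultaneous cuts
#' @return data.frame with columns radius, context, core, n_heavy, count,
#'   sorted by (context, core)
#' @export
oracle_interchangeable <- function(corpus, radius, max_cuts = 4L) {
  mols <- if (inherits(corpus, "fixture_corpus")) corpus$molecules else corpus
  mols <- unique(vapply(mols, function(s) canonical_smiles(s), "", USE.NAMES = FALSE))
  counts <- new.env(parent = emptyenv())
  sizes <- new.env(parent = emptyenv())
  for (s in mols) {
    mol <- parse_smiles(s)
    seen <- character(0L)
    for (rec in oracle_fragmentations(mol, max_cuts)) {
      tr <- oracle_truncate(rec$context, radius)
      cp <- canonicalize_pair(tr, rec$core)
      for (core_s in cp$cores) {
        key <- paste(cp$context, core_s, sep = "\t")
        if (key %in% seen) next
        seen <- c(seen, key)
        assign(key, get0(key, counts, ifnotfound = 0L) + 1L, counts)
        assign(key, mg_n_heavy(rec$core), sizes)
      }
    }
  }
  keys <- sort(ls(counts, sorted = FALSE), method = "radix")
  if (!length(keys)) {
    return(data.frame(radius = integer(), context = character(),
                      core = character(), n_heavy = integer(),
                      count = integer()))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  data.frame(
    radius = as.integer(radius),
    context = vapply(parts, `[[`, "", 1L),
    core = vapply(parts, `[[`, "", 2L),
    n_heavy = as.integer(unlist(mget(keys, sizes), use.names = FALSE)),
    count = as.integer(unlist(mget(keys, counts), use.names = FALSE))
  )
}

# Independent splice: rebuilds atom/bond arrays directly.
oracle_splice <- function(ctxt, core) {
  if (all(core$elem %in% c("H", "*"))) {
    # hydrogen core
    d <- which(mg_is_dummy(ctxt))
    anchor <- setdiff(c(ctxt$bond_a[ctxt$bond_a == d | ctxt$bond_b == d],
                        ctxt$bond_b[ctxt$bond_a == d | ctxt$bond_b == d]), d)
    out <- ctxt
    out$nH[anchor] <- out$nH[anchor] + 1L
    out <- mg_subgraph(out, setdiff(seq_len(mg_natoms(out)), d))
    mg_sanitize(out)
    return(canonical_smiles(out))
  }
  nc <- mg_natoms(ctxt)
  all_elem <- c(ctxt$elem, core$elem)
  out <- mg_mol(
    elem = all_elem, arom = c(ctxt$arom, core$arom),
    charge = c(ctxt$charge, core$charge), nH = c(ctxt$nH, core$nH),
    map = c(ctxt$map, core$map), isotope = c(ctxt$isotope, core$isotope),
    bond_a = c(ctxt$bond_a, core$bond_a + nc),
    bond_b = c(ctxt$bond_b, core$bond_b + nc),
    border = c(ctxt$border, core$border))
  for (m in sort(ctxt$map[mg_is_dummy(ctxt)])) {
    dc <- which(out$elem == "*" & out$map == m & seq_len(mg_natoms(out)) <= nc)
    dk <- which(out$elem == "*" & out$map == m & seq_len(mg_natoms(out)) > nc)
    anchor_c <- setdiff(unique(c(out$bond_a[out$bond_a == dc | out$bond_b == dc],
                                 out$bond_b[out$bond_a == dc | out$bond_b == dc])), dc)
    anchor_k <- setdiff(unique(c(out$bond_a[out$bond_a == dk | out$bond_b == dk],
                                 out$bond_b[out$bond_a == dk | out$bond_b == dk])), dk)
    out <- mg_add_bond(out, anchor_c, anchor_k, 1)
  }
  out <- mg_subgraph(out, which(out$elem != "*"))
  mg_sanitize(out)
  canonical_smiles(out)
}

#' Brute-force oracle for MUTATE
#'
#' Enumerates every fragmentation of the parent and every interchangeable
#' candidate in the corpus table by naive splicing.
#'
#' @param parent parent SMILES
#' @param corpus fixture corpus or character vector
#' @param radius context radius
#' @param params a [generation_params()] bundle (exhaustive settings:
#'   `max_replacements` is ignored)
#' @return sorted character vector of product SMILES
#' @export
oracle_mutate <- function(parent, corpus, radius, params = generation_params(radius = radius)) {
  tab <- oracle_interchangeable(corpus, radius, params$max_cuts)
  parent_mol <- parse_smiles(if (is.list(parent)) parent$smiles else parent)
  parent_canon <- canonical_smiles(parent_mol)
  ph <- mg_n_heavy(parent_mol)
  out <- character(0L)
  for (rec in oracle_fragmentations(parent_mol, params$max_cuts)) {
    s <- mg_n_heavy(rec$core)
    if (s < params$min_size || s > params$max_size) next
    if (!is.null(params$max_rel_size) && s / ph > params$max_rel_size) next
    tr <- oracle_truncate(rec$context, radius)
    cp <- canonicalize_pair(tr, rec$core)
    cands <- tab[tab$context == cp$context &
                 tab$count >= params$min_freq &
                 tab$n_heavy - s >= params$min_inc &
                 tab$n_heavy - s <= params$max_inc, , drop = FALSE]
    if (!nrow(cands)) next
    ctxt <- rec$context
    d <- mg_is_dummy(ctxt)
    ctxt$map[d] <- cp$map_old_to_new[ctxt$map[d]]
    for (cs in cands$core) {
      prod <- tryCatch(oracle_splice(ctxt, parse_smiles(cs, sanitize = FALSE)),
                       mg_error = function(e) NA_character_)
      if (!is.na(prod) && prod != parent_canon) out <- c(out, prod)
    }
  }
  sort(unique(out), method = "radix")
}

#' Brute-force oracle for LINK
#'
#' @param parent_a,parent_b the two molecules to link
#' @inheritParams oracle_mutate
#' @export
oracle_link <- function(parent_a, parent_b, corpus, radius,
                        params = generation_params(radius = radius)) {
  tab <- oracle_interchangeable(corpus, radius, params$max_cuts)
  ma <- parse_smiles(parent_a); mb <- parse_smiles(parent_b)
  excl <- c(canonical_smiles(ma), canonical_smiles(mb))
  ha <- Filter(function(r) all(r$core$elem %in% c("H", "*")), oracle_fragmentations(ma, 1L))
  hb <- Filter(function(r) all(r$core$elem %in% c("H", "*")), oracle_fragmentations(mb, 1L))
  out <- character(0L)
  for (a in ha) {
    for (b in hb) {
      cb <- b$context
      cb$map[mg_is_dummy(cb)] <- 2L
      ctxt <- mg_union(a$context, cb)
      placeholder <- mg_mol(elem = c("*", "*"), arom = c(FALSE, FALSE),
                            charge = c(0L, 0L), nH = c(0L, 0L), map = c(1L, 2L),
                            isotope = c(0L, 0L))
      tr <- oracle_truncate(ctxt, radius)
      cp <- canonicalize_pair(tr, placeholder)
      cands <- tab[tab$context == cp$context & tab$count >= params$min_freq &
                   tab$n_heavy >= max(1L, params$min_inc) &
                   tab$n_heavy <= params$max_inc, , drop = FALSE]
      if (!nrow(cands)) next
      d <- mg_is_dummy(ctxt)
      ctxt2 <- ctxt
      ctxt2$map[d] <- cp$map_old_to_new[ctxt2$map[d]]
      for (cs in cands$core) {
        prod <- tryCatch(oracle_splice(ctxt2, parse_smiles(cs, sanitize = FALSE)),
                         mg_error = function(e) NA_character_)
        if (!is.na(prod) && !(prod %in% excl)) out <- c(out, prod)
      }
    }
  }
  sort(unique(out), method = "radix")
}
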