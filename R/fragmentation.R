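# Matched-molecular-pair style fragmentation.
#
# Molecules are cut on up to `max_cuts` acyclic single bonds between heavy
# atoms; hydrogens are cut by a separate pathway. Each cut produces a core
# (the replaceable fragment, carrying numbered attachment dummies [*:i]) and
# its context (the remainder of the molecule). Context keys are the
# canonically renumbered radius-r environments of the attachment points.

as_mg_mol <- function(x, sanitize = TRUE) {
  if (inherits(x, "mg_mol")) return(x)
  if (is.list(x) && !is.null(x$smiles)) x <- x$smiles
  parse_smiles(x, sanitize = sanitize)
}

#' A molecule record
#'
#' Canonicalizes and sanitizes a SMILES string, keeping an optional
#' identifier.
#'
#' @param smiles SMILES string
#' @param id optional identifier
#' @return a `molecule_record` list with elements `smiles` and `id`
#' @export
molecule_record <- function(smiles, id = NA_character_) {
  mol <- parse_smiles(smiles)
  structure(list(smiles = canonical_smiles(mol), id = id),
            class = "molecule_record")
}

#' Enumerate all cut sets of acyclic heavy-atom single bonds
#'
#' @param mol SMILES string, `molecule_record`, or internal molecule
#' @param max_cuts maximum number of simultaneous cuts (default 4)
#' @param max_core_size optional upper bound on the heavy-atom size of any
#'   core of interest; cut sets whose bonds are pairwise further apart than
#'   `max_core_size - 1` bonds cannot produce such a core and are pruned (a
#'   core touching every cut bond bounds their pairwise distance by its own
#'   size). Exhaustive when `Inf`.
#' @return list of integer vectors of bond indices, ordered by size then
#'   lexicographically by bond index
#' @export
enumerate_cut_sets <- function(mol, max_cuts = 4L, max_core_size = Inf) {
  if (max_cuts < 1L) stop_mg("mg_param_error", "max_cuts must be >= 1")
  mol <- as_mg_mol(mol)
  eligible <- which(cuttable_bonds(mol))
  compatible <- NULL
  if (is.finite(max_core_size) && length(eligible) > 1L) {
    adj <- mg_adj(mol)
    dmat <- vapply(eligible, function(b) {
      d <- mg_bfs_dist(mol, c(mol$bond_a[b], mol$bond_b[b]), adj)
      pmin(d[mol$bond_a[eligible]], d[mol$bond_b[eligible]])
    }, numeric(length(eligible)))
    compatible <- dmat <= max(max_core_size - 1, 0)
  }
  out <- list()
  for (k in seq_len(min(max_cuts, length(eligible)))) {
    sets <- safe_combn(seq_along(eligible), k)
    for (idx in sets) {
      if (!is.null(compatible) && k > 1L &&
          !all(compatible[idx, idx])) next
      out[[length(out) + 1L]] <- eligible[idx]
    }
  }
  out
}

# combn() treats a scalar first argument as seq_len(); guard against it
safe_combn <- function(x, k) {
  if (length(x) == 1L) {
    if (k == 1L) return(list(x))
    return(list())
  }
  utils::combn(x, k, simplify = FALSE)
}

# Union-find component labelling straight off the edge list; much cheaper
# than building an adjacency list for every candidate cut set.
uf_components <- function(n, bond_a, bond_b) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(bond_a)) {
    ra <- find(bond_a[e]); rb <- find(bond_b[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

cuttable_bonds <- function(mol) {
  heavy <- !(mol$elem %in% c("H", "*"))
  single <- mol$border == 1
  ring <- mg_ring_bonds(mol)
  single & !ring & heavy[mol$bond_a] & heavy[mol$bond_b]
}

#' Fragment a molecule on a specific cut set
#'
#' Cuts every bond in `cut_set`, labels the two new attachment dummies of cut
#' i with atom map i, and emits one fragmentation record per component that
#' touches all cuts (that component is the core). For a single cut both
#' components qualify and two records are produced.
#'
#' @param mol molecule (SMILES, record or internal object)
#' @param cut_set integer vector of bond indices from [enumerate_cut_sets()]
#' @param source_id identifier stored in the records
#' @param .cuttable precomputed [cuttable_bonds()] mask (internal, avoids
#'   recomputing ring perception per cut set)
#' @return list of fragmentation records (`core`, `context_full`,
#'   `core_src_atoms`, `cut_bonds`, `source_id`)
#' @export
fragment_on_cut_set <- function(mol, cut_set, source_id = NA_character_,
                                .cuttable = NULL) {
  mol <- as_mg_mol(mol)
  okay <- if (is.null(.cuttable)) cuttable_bonds(mol) else .cuttable
  if (any(!okay[cut_set])) {
    stop_mg("mg_contract_error", "cut set contains a ring, multiple-order or hydrogen bond")
  }
  k <- length(cut_set)
  frag <- mol
  keep <- setdiff(seq_len(mg_nbonds(mol)), cut_set)
  cut_a <- mol$bond_a[cut_set]; cut_b <- mol$bond_b[cut_set]
  frag$bond_a <- frag$bond_a[keep]; frag$bond_b <- frag$bond_b[keep]
  frag$border <- frag$border[keep]
  n0 <- mg_natoms(mol)
  for (i in seq_len(k)) {
    # one dummy on each side of cut i, both mapped i
    frag$elem <- c(frag$elem, "*", "*"); frag$arom <- c(frag$arom, FALSE, FALSE)
    frag$charge <- c(frag$charge, 0L, 0L); frag$nH <- c(frag$nH, 0L, 0L)
    frag$map <- c(frag$map, i, i); frag$isotope <- c(frag$isotope, 0L, 0L)
    da <- n0 + 2L * i - 1L; db <- n0 + 2L * i
    frag <- mg_add_bond(frag, cut_a[i], da, 1)
    frag <- mg_add_bond(frag, cut_b[i], db, 1)
  }
  comp <- uf_components(mg_natoms(frag), frag$bond_a, frag$bond_b)
  dummy_idx <- n0 + seq_len(2L * k)
  comp_maps <- split(frag$map[dummy_idx], comp[dummy_idx])
  cores <- names(comp_maps)[vapply(comp_maps, function(m) length(m) == k && setequal(m, seq_len(k)), TRUE)]
  records <- list()
  for (ci in as.integer(cores)) {
    core_atoms <- which(comp == ci)
    core <- mg_subgraph(frag, core_atoms)
    ctxt <- mg_subgraph(frag, which(comp != ci))
    src_core <- attr(core, "src")
    records[[length(records) + 1L]] <- structure(list(
      core = core,
      context_full = ctxt,
      core_src_atoms = src_core[src_core <= n0],
      cut_bonds = cbind(cut_a, cut_b),
      source_id = source_id
    ), class = "fragmentation_record")
  }
  records
}

#' Hydrogen cuts: one record per symmetry-distinct H position
#'
#' Every heavy atom carrying at least one hydrogen yields a record with the
#' hydrogen core `[H][*:1]` and the full molecule (minus that hydrogen) as
#' context. Records with identical canonical context are merged.
#'
#' @inheritParams fragment_on_cut_set
#' @return list of fragmentation records
#' @export
hydrogen_cuts <- function(mol, source_id = NA_character_) {
  mol <- as_mg_mol(mol)
  h_core <- mg_mol(elem = c("H", "*"), arom = c(FALSE, FALSE),
                   charge = c(0L, 0L), nH = c(0L, 0L), map = c(0L, 1L),
                   isotope = c(0L, 0L), bond_a = 1L, bond_b = 2L, border = 1)
  n0 <- mg_natoms(mol)
  seen <- character()
  records <- list()
  for (i in which(mol$nH >= 1L & !(mol$elem %in% c("H", "*")))) {
    ctxt <- mol
    ctxt$nH[i] <- ctxt$nH[i] - 1L
    ctxt$elem <- c(ctxt$elem, "*"); ctxt$arom <- c(ctxt$arom, FALSE)
    ctxt$charge <- c(ctxt$charge, 0L); ctxt$nH <- c(ctxt$nH, 0L)
    ctxt$map <- c(ctxt$map, 1L); ctxt$isotope <- c(ctxt$isotope, 0L)
    ctxt <- mg_add_bond(ctxt, i, n0 + 1L, 1)
    key <- as.character(mg_write_smiles(ctxt, mg_canon_ranks(ctxt, use_maps = TRUE)))
    if (key %in% seen) next
    seen <- c(seen, key)
    records[[length(records) + 1L]] <- structure(list(
      core = h_core,
      context_full = ctxt,
      core_src_atoms = i,   # protection applies to the H-bearing atom
      cut_bonds = NULL,
      source_id = source_id
    ), class = "fragmentation_record")
  }
  records
}

#' All fragmentation records of a molecule (bond cuts plus hydrogen cuts)
#'
#' @inheritParams enumerate_cut_sets
#' @param source_id identifier stored in the records
#' @param hydrogens include the hydrogen-cut pathway
#' @return list of fragmentation records
#' @export
fragment_molecule <- function(mol, max_cuts = 4L, source_id = NA_character_,
                              hydrogens = TRUE, max_core_size = Inf) {
  mol <- as_mg_mol(mol)
  recs <- list()
  okay <- cuttable_bonds(mol)
  for (cs in enumerate_cut_sets(mol, max_cuts, max_core_size)) {
    recs <- c(recs, fragment_on_cut_set(mol, cs, source_id, .cuttable = okay))
  }
  if (hydrogens) recs <- c(recs, hydrogen_cuts(mol, source_id))
  recs
}

#' Truncate a context to a given radius around its attachment points
#'
#' Keeps every atom within `radius` bonds of an attachment dummy (the dummy
#' itself is at distance 0, its anchor at 1). Valences opened by dropping
#' frontier bonds are filled with implicit hydrogens (one per single or
#' aromatic bond, two per double, three per triple).
#'
#' @param context_full internal molecule with attachment dummies
#' @param radius integer radius >= 1
#' @return truncated internal molecule
#' @export
truncate_context <- function(context_full, radius) {
  if (!is.numeric(radius) || radius < 1) {
    stop_mg("mg_param_error", "radius must be >= 1")
  }
  mol <- as_mg_mol(context_full, sanitize = FALSE)
  dummies <- which(mg_is_dummy(mol))
  d <- mg_bfs_dist(mol, dummies)
  keep <- which(d <= radius)
  if (length(keep) == mg_natoms(mol)) return(mol)
  lost_h <- integer(mg_natoms(mol))
  inkeep <- seq_len(mg_natoms(mol)) %in% keep
  for (b in seq_len(mg_nbonds(mol))) {
    a1 <- mol$bond_a[b]; a2 <- mol$bond_b[b]
    if (inkeep[a1] != inkeep[a2]) {
      o <- mol$border[b]
      h <- if (o == 2) 2L else if (o == 3) 3L else 1L
      if (inkeep[a1]) lost_h[a1] <- lost_h[a1] + h else lost_h[a2] <- lost_h[a2] + h
    }
  }
  sub <- mg_subgraph(mol, keep)
  sub$nH <- sub$nH + lost_h[attr(sub, "src")]
  sub
}

#' Canonicalize a context/core pair
#'
#' The context is ranked with atom maps excluded, attachment points are
#' renumbered 1..k in order of first appearance in the canonical context
#' string, and the renumbering is applied to the core. Attachment points
#' whose context environments are symmetry-equivalent generate one stored
#' core variant per distinct permutation of their labels.
#'
#' @param context internal molecule or SMILES (the radius-r context)
#' @param core internal molecule or SMILES with matching map numbers
#' @return list with `context` (canonical SMILES), `cores` (character vector
#'   of canonical core variants, first = identity renumbering),
#'   `map_old_to_new` (named integer vector)
#' @export
canonicalize_pair <- function(context, core) {
  ctxt <- as_mg_mol(context, sanitize = FALSE)
  core <- as_mg_mol(core, sanitize = FALSE)
  ctxt_maps <- sort(ctxt$map[ctxt$map > 0L])
  core_maps <- sort(core$map[core$map > 0L])
  k <- length(ctxt_maps)
  if (!identical(ctxt_maps, core_maps) || !identical(ctxt_maps, seq_len(k))) {
    stop_mg("mg_contract_error", "context and core map numbers must both be exactly 1..k")
  }
  ranks <- mg_canon_ranks(ctxt, use_maps = FALSE)
  pass1 <- mg_write_smiles(ctxt, ranks)
  ord <- attr(pass1, "atom_order")
  dummy_in_order <- ord[mg_is_dummy(ctxt)[ord]]
  new_map <- integer(mg_natoms(ctxt))
  new_map[dummy_in_order] <- seq_len(k)
  old2new <- integer(k)
  old2new[ctxt$map[dummy_in_order]] <- seq_len(k)
  ctx_smiles <- as.character(mg_write_smiles(ctxt, ranks, map_override = new_map))
  # symmetry classes of attachment points: equal map-agnostic refined ranks
  ctx0 <- mg_canon_ctx(ctxt)
  refined <- mg_refine(mg_initial_ranks(ctxt, use_maps = FALSE), ctx0)
  dummy_idx <- which(mg_is_dummy(ctxt))
  classes <- split(new_map[dummy_idx], refined[dummy_idx])
  perms <- label_permutations(classes, k)
  base <- old2new
  cores <- character(0L)
  for (p in perms) {
    m2 <- core
    m2$map[m2$map > 0L] <- p[base[core$map[core$map > 0L]]]
    s <- as.character(mg_write_smiles(m2, mg_canon_ranks(m2, use_maps = TRUE)))
    cores <- c(cores, s)
  }
  cores <- unique(cores)
  list(context = ctx_smiles, cores = cores,
       map_old_to_new = stats::setNames(old2new, seq_len(k)))
}

# All permutations sigma of 1..k (sigma[l] = replacement label for l) that
# only permute labels within the same symmetry class; identity first.
label_permutations <- function(classes, k) {
  perms <- list(seq_len(k))
  for (cls in classes) {
    if (length(cls) < 2L) next
    cls_perms <- permn(cls)
    new_perms <- list()
    for (p in perms) {
      for (cp in cls_perms) {
        q <- p
        q[cls] <- cp
        new_perms <- c(new_perms, list(q))
      }
    }
    perms <- new_perms
  }
  keys <- vapply(perms, paste, "", collapse = ",")
  perms <- perms[order(keys != paste(seq_len(k), collapse = ","), keys,
                       method = "radix")]
  unique(perms)
}

permn <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permn(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}
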