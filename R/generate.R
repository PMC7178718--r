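# Structure generation: MUTATE / GROW / LINK.
#
# All three modes share one engine: fragment the parent, canonicalize each
# context at the working radius, look interchangeable cores up in the
# fragment database, filter them by occurrence and size rules, splice them
# back into the untruncated context, and sanitize. Chemical validity of the
# output is guaranteed by construction: splicing only re-forms single bonds
# at attachment points whose valence was freed by the cut.

#' Tuning parameters for one replacement call
#'
#' Defaults mirror a conservative local-exploration setup: hydrogens are
#' replaceable (`min_size = 0`), replaced fragments of up to 10 heavy atoms,
#' replacing fragments within two heavy atoms of the replaced one.
#'
#' @param radius context radius (must be built in the database)
#' @param min_size,max_size heavy-atom bounds on the replaced core
#' @param max_rel_size optional cap on replaced-core size relative to the
#'   parent's heavy-atom count (in (0, 1])
#' @param min_inc,max_inc signed bounds on (replacing - replaced) heavy atoms
#' @param min_freq minimum occurrence count of a replacing core
#' @param max_replacements optional cap on randomly sampled (site, candidate)
#'   pairs; `NULL` means exhaustive
#' @param protected_atoms parent atom indices that must not be modified
#' @param max_cuts maximum simultaneous bond cuts when fragmenting the parent
#' @param seed RNG seed used when `max_replacements` is set
#' @return a `generation_params` list
#' @export
generation_params <- function(radius = 3L, min_size = 0L, max_size = 10L,
                              max_rel_size = NULL, min_inc = -2L, max_inc = 2L,
                              min_freq = 0L, max_replacements = NULL,
                              protected_atoms = integer(0L), max_cuts = 4L,
                              seed = NULL) {
  if (min_size > max_size) stop_mg("mg_param_error", "min_size > max_size")
  if (min_inc > max_inc) stop_mg("mg_param_error", "min_inc > max_inc")
  if (!is.null(max_rel_size) && (max_rel_size <= 0 || max_rel_size > 1)) {
    stop_mg("mg_param_error", "max_rel_size must be in (0, 1]")
  }
  structure(list(radius = as.integer(radius), min_size = as.integer(min_size),
                 max_size = as.integer(max_size), max_rel_size = max_rel_size,
                 min_inc = as.integer(min_inc), max_inc = as.integer(max_inc),
                 min_freq = as.integer(min_freq),
                 max_replacements = max_replacements,
                 protected_atoms = as.integer(protected_atoms),
                 max_cuts = as.integer(max_cuts), seed = seed),
            class = "generation_params")
}

# Run expr with a local RNG state (global .Random.seed is restored).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Splice a replacement core into a fragmentation record's context
#'
#' Bonds attachment i of the replacement to the context anchor of cut i,
#' removes the dummies, folds explicit hydrogens back into implicit counts,
#' sanitizes and canonicalizes.
#'
#' @param record a fragmentation record (or any molecule with mapped dummies
#'   acting as the full context)
#' @param replacement core molecule or SMILES with matching map numbers
#' @return canonical SMILES of the spliced molecule
#' @export
splice <- function(record, replacement) {
  ctxt <- if (inherits(record, "fragmentation_record")) record$context_full else as_mg_mol(record, sanitize = FALSE)
  core <- as_mg_mol(replacement, sanitize = FALSE)
  cmaps <- sort(ctxt$map[mg_is_dummy(ctxt)])
  kmaps <- sort(core$map[mg_is_dummy(core)])
  if (!identical(cmaps, kmaps) || anyDuplicated(kmaps)) {
    stop_mg("mg_contract_error", "context and replacement attachment maps differ")
  }
  n1 <- mg_natoms(ctxt)
  u <- mg_union(ctxt, core)
  adj <- mg_adj(u)
  for (m in cmaps) {
    dc <- which(mg_is_dummy(u) & u$map == m & seq_len(mg_natoms(u)) <= n1)
    dk <- which(mg_is_dummy(u) & u$map == m & seq_len(mg_natoms(u)) > n1)
    ac <- adj$nbr[[dc]]; fc <- adj$nbr[[dk]]
    if (length(ac) != 1L || length(fc) != 1L) {
      stop_mg("mg_splice_error", "attachment dummy %d is not univalent", m)
    }
    u <- mg_add_bond(u, ac, fc, 1)
  }
  u <- mg_remove_atoms(u, which(mg_is_dummy(u)))
  # fold explicit hydrogens (e.g. the [H][*:1] core) into implicit counts
  hs <- which(u$elem == "H")
  if (length(hs)) {
    adj2 <- mg_adj(u)
    for (h in hs) {
      nb <- adj2$nbr[[h]]
      if (length(nb) == 1L) u$nH[nb] <- u$nH[nb] + 1L
    }
    u <- mg_remove_atoms(u, hs)
  }
  ok <- tryCatch({ mg_sanitize(u); TRUE },
                 mg_sanitize_error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) stop_mg("mg_splice_error", "splice product fails sanitization: %s", ok)
  canonical_smiles(u)
}

# Apply the old->new attachment renumbering of a canonicalized pair to the
# untruncated context so stored candidate cores splice consistently.
renumber_context <- function(context_full, old2new) {
  d <- mg_is_dummy(context_full)
  context_full$map[d] <- old2new[context_full$map[d]]
  context_full
}

# Memoized canonicalize_pair: keyed on identity-order writes of the pair,
# which are cheap and identical for structurally identical sites (frequent
# along homologous chains and symmetric rings).
cp_cached <- function(ctx_r, core, cache) {
  key <- paste(as.character(mg_write_smiles(ctx_r, seq_len(mg_natoms(ctx_r)))),
               as.character(mg_write_smiles(core, seq_len(mg_natoms(core)))),
               sep = "\r")
  cp <- get0(key, cache)
  if (is.null(cp)) {
    cp <- canonicalize_pair(ctx_r, core)
    assign(key, cp, cache)
  }
  cp
}

# Shared generation engine over a prepared list of fragmentation records.
generate_engine <- function(records, parent_heavy, db, params,
                            min_candidate_size = 0L, exclude = character(0L)) {
  radius <- params$radius
  if (!radius %in% db$radii) {
    stop_mg("mg_param_error", "radius %d was not built in this database", radius)
  }
  cp_cache <- new.env(parent = emptyenv())
  q_cache <- new.env(parent = emptyenv())
  sites <- list()
  for (rec in records) {
    s <- mg_n_heavy(rec$core)
    if (s < params$min_size || s > params$max_size) next
    if (!is.null(params$max_rel_size) && parent_heavy > 0L &&
        s / parent_heavy > params$max_rel_size) next
    if (length(params$protected_atoms) &&
        any(rec$core_src_atoms %in% params$protected_atoms)) next
    ctx_r <- truncate_context(rec$context_full, radius)
    cp <- cp_cached(ctx_r, rec$core, cp_cache)
    entries <- get0(cp$context, q_cache)
    if (is.null(entries)) {
      entries <- query(db, radius, cp$context)
      assign(cp$context, entries, q_cache)
    }
    if (nrow(entries) == 0L) next
    keep <- entries$count >= params$min_freq &
      entries$n_heavy - s >= params$min_inc &
      entries$n_heavy - s <= params$max_inc &
      entries$n_heavy >= min_candidate_size
    entries <- entries[keep, , drop = FALSE]
    if (nrow(entries) == 0L) next
    ctxt_full <- renumber_context(rec$context_full, cp$map_old_to_new)
    sites[[length(sites) + 1L]] <- list(context = ctxt_full, cores = entries$core)
  }
  if (!length(sites)) return(character(0L))
  pair_site <- rep.int(seq_along(sites), vapply(sites, function(x) length(x$cores), 0L))
  pair_core <- unlist(lapply(sites, `[[`, "cores"), use.names = FALSE)
  if (!is.null(params$max_replacements) && length(pair_core) > params$max_replacements) {
    idx <- with_seed(params$seed,
                     sample.int(length(pair_core), params$max_replacements))
    idx <- sort(idx)
    pair_site <- pair_site[idx]; pair_core <- pair_core[idx]
  }
  out <- character(0L)
  core_cache <- new.env(parent = emptyenv())
  for (t in seq_along(pair_core)) {
    cs <- pair_core[t]
    core <- get0(cs, core_cache)
    if (is.null(core)) {
      core <- parse_smiles(cs, sanitize = FALSE)
      assign(cs, core, core_cache)
    }
    prod <- tryCatch(splice(sites[[pair_site[t]]]$context, core),
                     mg_splice_error = function(e) NA_character_,
                     mg_sanitize_error = function(e) NA_character_)
    if (!is.na(prod)) out <- c(out, prod)
  }
  sort(setdiff(unique(out), exclude), method = "radix")
}

#' MUTATE: replace an arbitrary fragment of the parent
#'
#' @param parent SMILES, `molecule_record` or internal molecule
#' @param db a fragment database from [build_db()]
#' @param params a [generation_params()] bundle
#' @return sorted character vector of canonical product SMILES (never
#'   containing the parent itself)
#' @export
mutate <- function(parent, db, params = generation_params()) {
  mol <- as_mg_mol(parent)
  cap <- params$max_size
  if (!is.null(params$max_rel_size)) {
    cap <- min(cap, floor(params$max_rel_size * mg_n_heavy(mol)))
  }
  records <- fragment_molecule(mol, max_cuts = params$max_cuts,
                               max_core_size = cap)
  generate_engine(records, mg_n_heavy(mol), db, params,
                  exclude = canonical_smiles(mol))
}

#' GROW: replace a hydrogen of the parent with a fragment
#'
#' A special case of [mutate()] restricted to hydrogen cores, with replacing
#' cores of at least one heavy atom.
#'
#' @inheritParams mutate
#' @export
grow <- function(parent, db, params = generation_params()) {
  mol <- as_mg_mol(parent)
  params$min_size <- 0L
  records <- hydrogen_cuts(mol)
  generate_engine(records, mg_n_heavy(mol), db, params,
                  min_candidate_size = 1L, exclude = canonical_smiles(mol))
}

#' LINK: join two molecules through a two-attachment fragment
#'
#' Replaces one hydrogen in each parent and searches the database for
#' two-attachment cores whose combined context matches.
#'
#' @param parent_a,parent_b the two molecules to link
#' @inheritParams mutate
#' @export
link <- function(parent_a, parent_b, db, params = generation_params()) {
  ma <- as_mg_mol(parent_a)
  mb <- as_mg_mol(parent_b)
  ra <- hydrogen_cuts(ma)
  rb <- hydrogen_cuts(mb)
  records <- list()
  for (a in ra) {
    for (b in rb) {
      ctxt_b <- b$context_full
      ctxt_b$map[mg_is_dummy(ctxt_b)] <- 2L
      ctxt <- mg_union(a$context_full, ctxt_b)
      core <- mg_mol(elem = c("*", "*"), arom = c(FALSE, FALSE),
                     charge = c(0L, 0L), nH = c(0L, 0L), map = c(1L, 2L),
                     isotope = c(0L, 0L))
      records[[length(records) + 1L]] <- structure(list(
        core = core, context_full = ctxt,
        core_src_atoms = integer(0L), cut_bonds = NULL,
        source_id = NA_character_), class = "fragmentation_record")
    }
  }
  params$min_size <- 0L
  heavy <- mg_n_heavy(ma) + mg_n_heavy(mb)
  generate_engine(records, heavy, db, params, min_candidate_size = 1L,
                  exclude = c(canonical_smiles(ma), canonical_smiles(mb)))
}
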