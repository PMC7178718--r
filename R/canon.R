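# Canonical atom ranking and SMILES output.
#
# Ranking follows the classic refine-and-tie-break scheme: atom invariants
# (element, aromaticity, degree, H count, charge, isotope, optionally the
# atom map) are iteratively refined by neighbour ranks; remaining ties are
# broken by branching on each member of the first tied class and keeping the
# branch whose finished SMILES string is lexicographically smallest. That
# makes the output invariant under any permutation of the input atom order,
# which is what the fragment database keys rely on.

.BOND_KEY <- function(border) match(border, c(1, 1.5, 2, 3))

# One refinement pass produces, per atom, the row (rank, sorted neighbour
# codes) with code = bond_key * (n + 1) + neighbour_rank; rows are ranked
# lexicographically. Numeric throughout - no string keys in the hot path.
mg_neighbor_matrix <- function(ranks, ctx) {
  M <- matrix(0L, nrow = ctx$n, ncol = 1L + ctx$maxdeg)
  M[, 1L] <- ranks
  if (length(ctx$ends)) {
    codes <- ctx$bcode * (ctx$n + 1L) + ranks[ctx$other]
    o <- order(ctx$ends, codes, method = "radix")
    e2 <- ctx$ends[o]
    M[cbind(e2, ctx$pos + 1L)] <- codes[o]
  }
  M
}

mg_rank_rows <- function(M) {
  n <- nrow(M)
  cols <- lapply(seq_len(ncol(M)), function(j) M[, j])
  o <- do.call(order, c(cols, list(method = "radix")))
  r <- integer(n)
  r[o[1L]] <- 1L
  if (n > 1L) {
    same <- rowSums(abs(M[o[-1L], , drop = FALSE] - M[o[-n], , drop = FALSE])) == 0
    r[o[-1L]] <- 1L + cumsum(!same)
  }
  r
}

mg_refine <- function(ranks, ctx) {
  repeat {
    new_ranks <- mg_rank_rows(mg_neighbor_matrix(ranks, ctx))
    if (max(new_ranks) == max(ranks)) return(new_ranks)
    ranks <- new_ranks
  }
}

# Precomputed connectivity context shared by all refinement passes.
mg_canon_ctx <- function(mol) {
  n <- mg_natoms(mol)
  bkey <- .BOND_KEY(mol$border)
  ends <- c(mol$bond_a, mol$bond_b)
  other <- c(mol$bond_b, mol$bond_a)
  bcode <- c(bkey, bkey)
  deg <- tabulate(ends, nbins = n)
  # slot index within each atom's neighbour group when `ends` is sorted
  # ascending; the secondary (code) sort order inside a group doesn't move
  # entries across groups, so this alignment holds every refinement pass
  pos <- if (length(ends)) sequence(deg[sort.int(unique(ends))]) else integer(0L)
  list(n = n, ends = ends, other = other, bcode = bcode,
       maxdeg = if (n > 0L && length(ends)) max(deg) else 0L,
       pos = pos)
}

mg_initial_ranks <- function(mol, use_maps) {
  elem_num <- match(mol$elem, c("*", "H", ORGANIC_ELEMENTS))
  deg <- tabulate(c(mol$bond_a, mol$bond_b), nbins = mg_natoms(mol))
  keys <- sprintf("%02d%d%d%02d%+03d%03d%03d",
                  elem_num, as.integer(mol$arom), deg, mol$nH, mol$charge,
                  mol$isotope, if (use_maps) mol$map else integer(mg_natoms(mol)))
  # radix = C-locale byte order, independent of the runtime collation
  match(keys, sort(unique(keys), method = "radix"))
}

mg_canon_ranks <- function(mol, use_maps = FALSE) {
  n <- mg_natoms(mol)
  if (n == 0L) return(integer(0L))
  ctx <- mg_canon_ctx(mol)
  init <- mg_initial_ranks(mol, use_maps)
  ranks <- mg_refine(init, ctx)
  # signature of a complete ranking: rows (initial invariant, sorted
  # neighbour codes) read off in rank order. Rankings related by a graph
  # automorphism share the signature, so picking the minimum is canonical.
  signature <- function(r) {
    M <- cbind(init, mg_neighbor_matrix(r, ctx))
    paste(t(M[order(r), , drop = FALSE]), collapse = ",")
  }
  resolve <- function(ranks) {
    dup <- ranks[duplicated(ranks)]
    if (!length(dup)) return(list(ranks = ranks, sig = NULL))
    cls <- which(ranks == min(dup))
    best <- NULL
    for (a in cls) {
      r2 <- mg_rank_rows(matrix(ranks * 2L - (seq_len(n) == a), ncol = 1L))
      r2 <- mg_refine(r2, ctx)
      res <- resolve(r2)
      sig <- res$sig
      if (is.null(sig)) sig <- signature(res$ranks)
      if (is.null(best) || (sig != best$sig &&
                            order(c(sig, best$sig), method = "radix")[1L] == 1L)) {
        best <- list(ranks = res$ranks, sig = sig)
      }
    }
    best
  }
  resolve(ranks)$ranks
}

# ---- writer --------------------------------------------------------------

# Emit SMILES for `mol` under a complete atom ranking (rank 1 printed first
# within its component). Components are sorted by their map-stripped strings
# so that atom-map labels never influence the canonical component order.
# attr(result, "atom_order") gives atom indices in emission order.
mg_write_smiles <- function(mol, ranks, map_override = NULL, strip_maps = FALSE) {
  n <- mg_natoms(mol)
  if (n == 0L) return("")
  adj <- mg_adj(mol)
  comp <- mg_components(mol, adj)
  maps <- if (strip_maps) integer(n) else if (!is.null(map_override)) map_override else mol$map

  emit_component <- function(atoms) {
    start <- atoms[which.min(ranks[atoms])]
    visited <- logical(n)
    tree_child <- vector("list", n)
    ring_open <- vector("list", n)   # per atom: list of (partner, bond)
    # DFS pass 1: classify edges into tree bonds and ring closures
    visited[start] <- TRUE
    seen_bond <- logical(mg_nbonds(mol))
    dfs1 <- function(v, pb) {
      nbrs <- adj$nbr[[v]]; bnds <- adj$bond[[v]]
      o <- order(ranks[nbrs])
      for (t in o) {
        b <- bnds[t]; w <- nbrs[t]
        if (b == pb || seen_bond[b]) next
        seen_bond[b] <<- TRUE
        if (visited[w]) {
          ring_open[[v]] <<- c(ring_open[[v]], list(list(partner = w, bond = b)))
          ring_open[[w]] <<- c(ring_open[[w]], list(list(partner = v, bond = b)))
        } else {
          visited[w] <<- TRUE
          tree_child[[v]] <<- c(tree_child[[v]], list(list(atom = w, bond = b)))
          dfs1(w, b)
        }
      }
    }
    dfs1(start, 0L)
    # digit allocation
    digit_of_bond <- integer(mg_nbonds(mol))
    free_digits <- 1:99
    atom_order <- integer(0L)
    emit <- function(v, in_bond) {
      out <- character(0L)
      if (in_bond > 0L) out <- c(out, bond_token(mol, in_bond))
      out <- c(out, atom_token(mol, v, maps[v]))
      atom_order <<- c(atom_order, v)
      rc <- ring_open[[v]]
      if (length(rc)) {
        ord <- order(vapply(rc, function(x) ranks[x$partner], numeric(1)))
        for (x in rc[ord]) {
          b <- x$bond
          if (digit_of_bond[b] == 0L) {
            d <- free_digits[1L]; free_digits <<- free_digits[-1L]
            digit_of_bond[b] <<- d
          } else {
            d <- digit_of_bond[b]
            free_digits <<- sort(c(free_digits, d))
          }
          out <- c(out, bond_token(mol, b), if (d < 10) as.character(d) else sprintf("%%%02d", d))
        }
      }
      ch <- tree_child[[v]]
      if (length(ch)) {
        for (t in seq_along(ch)) {
          sub <- emit(ch[[t]]$atom, ch[[t]]$bond)
          if (t < length(ch)) out <- c(out, "(", sub, ")") else out <- c(out, sub)
        }
      }
      out
    }
    s <- paste(emit(start, 0L), collapse = "")
    list(smiles = s, atom_order = atom_order)
  }

  comps <- sort(unique(comp))
  pieces <- lapply(comps, function(ci) emit_component(which(comp == ci)))
  strs <- vapply(pieces, `[[`, "", "smiles")
  # sort key: the same string with any map labels removed, then the mapped
  # string itself as a deterministic tiebreak
  stripped <- gsub(":[0-9]+\\]", "]", strs)
  o <- order(stripped, strs, method = "radix")
  out <- paste(strs[o], collapse = ".")
  attr(out, "atom_order") <- unlist(lapply(pieces[o], `[[`, "atom_order"))
  out
}

bond_token <- function(mol, b) {
  o <- mol$border[b]
  a1 <- mol$bond_a[b]; a2 <- mol$bond_b[b]
  both_arom <- mol$arom[a1] && mol$arom[a2]
  if (o == 1) { if (both_arom) "-" else "" }
  else if (o == 1.5) { if (both_arom) "" else ":" }
  else if (o == 2) "="
  else if (o == 3) "#"
  else stop_mg("mg_write_error", "unsupported bond order %s", format(o))
}

atom_token <- function(mol, i, map_i) {
  e <- mol$elem[i]
  sym <- if (mol$arom[i]) tolower(e) else e
  need_bracket <- mol$charge[i] != 0L || mol$isotope[i] != 0L || map_i > 0L ||
    e %in% c("H", "*")
  if (!need_bracket) {
    # bracket when the implicit-H inference would not reproduce nH
    bs <- sum(mol$border[mol$bond_a == i | mol$bond_b == i])
    need <- ceiling(bs - 1e-9)
    allowed <- .VALENCES[[e]]
    inferred <- 0L
    if (!is.null(allowed)) {
      v <- allowed[allowed >= need]
      if (length(v)) inferred <- as.integer(v[1L] - need)
    }
    if (mol$arom[i] && e %in% c("O", "S")) inferred <- 0L
    if (inferred != mol$nH[i]) need_bracket <- TRUE
  }
  if (!need_bracket) return(sym)
  h <- if (mol$nH[i] == 0L) "" else if (mol$nH[i] == 1L) "H" else paste0("H", mol$nH[i])
  ch <- mol$charge[i]
  chs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-" else sprintf("%+d", ch)
  iso <- if (mol$isotope[i] > 0L) as.character(mol$isotope[i]) else ""
  mp <- if (map_i > 0L) paste0(":", map_i) else ""
  paste0("[", iso, sym, h, chs, mp, "]")
}

#' Canonical SMILES of a molecule
#'
#' Atom-map numbers, when present, are treated as part of atom identity
#' (`use_maps = TRUE`, the convention for stored fragment cores). Set
#' `use_maps = FALSE` to rank atoms map-agnostically, as done for context
#' keys.
#'
#' @param x a SMILES string or an internal molecule object
#' @param use_maps include atom maps in the canonical ranking
#' @param sanitize validate valences when `x` is a string
#' @return a single canonical SMILES string
#' @export
canonical_smiles <- function(x, use_maps = TRUE, sanitize = TRUE) {
  mol <- if (inherits(x, "mg_mol")) x else parse_smiles(x, sanitize = sanitize)
  ranks <- mg_canon_ranks(mol, use_maps = use_maps && any(mol$map > 0L))
  as.character(mg_write_smiles(mol, ranks))
}

write_smiles <- function(mol) {
  as.character(mg_write_smiles(mol, mg_canon_ranks(mol, use_maps = any(mol$map > 0L))))
}
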