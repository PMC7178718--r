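# Internal molecular graph container.
#
# A molecule is a plain list (class "mg_mol") of parallel atom vectors plus a
# bond table. Hydrogens are implicit (per-atom counts); dummy atoms (element
# "*") carry atom-map numbers that pair fragment attachment points with their
# context. Bond orders are 1, 2, 3 or 1.5 (aromatic).

ORGANIC_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

mg_mol <- function(elem = character(), arom = logical(), charge = integer(),
                   nH = integer(), map = integer(), isotope = integer(),
                   bond_a = integer(), bond_b = integer(), border = numeric()) {
  structure(list(
    elem = as.character(elem),
    arom = as.logical(arom),
    charge = as.integer(charge),
    nH = as.integer(nH),
    map = as.integer(map),
    isotope = as.integer(isotope),
    bond_a = as.integer(bond_a),
    bond_b = as.integer(bond_b),
    border = as.numeric(border)
  ), class = "mg_mol")
}

mg_natoms <- function(mol) length(mol$elem)
mg_nbonds <- function(mol) length(mol$bond_a)

#' @export
print.mg_mol <- function(x, ...) {
  cat(sprintf("<mg_mol: %d atoms, %d bonds> %s\n",
              mg_natoms(x), mg_nbonds(x), write_smiles(x)))
  invisible(x)
}

# Adjacency: list with $nbr[[i]] neighbour atom indices and $bond[[i]] the
# corresponding bond indices.
mg_adj <- function(mol) {
  n <- mg_natoms(mol)
  nbr <- vector("list", n)
  bnd <- vector("list", n)
  if (mg_nbonds(mol) > 0L) {
    ends <- c(mol$bond_a, mol$bond_b)
    other <- c(mol$bond_b, mol$bond_a)
    bid <- rep.int(seq_len(mg_nbonds(mol)), 2L)
    o <- order(ends)
    ends <- ends[o]; other <- other[o]; bid <- bid[o]
    runs <- split(seq_along(ends), ends)
    for (k in names(runs)) {
      i <- as.integer(k)
      nbr[[i]] <- other[runs[[k]]]
      bnd[[i]] <- bid[runs[[k]]]
    }
  }
  list(nbr = nbr, bond = bnd)
}

# Connected-component labels (1-based, by first-seen order).
mg_components <- function(mol, adj = mg_adj(mol)) {
  n <- mg_natoms(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj$nbr[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# BFS bond distances from a set of source atoms; unreachable = Inf.
mg_bfs_dist <- function(mol, sources, adj = mg_adj(mol)) {
  n <- mg_natoms(mol)
  d <- rep(Inf, n)
  d[sources] <- 0
  queue <- sources
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj$nbr[[v]]) {
      if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; queue <- c(queue, w) }
    }
  }
  d
}

# TRUE for bonds that lie on a cycle (non-bridges), found by DFS low-link.
mg_ring_bonds <- function(mol, adj = mg_adj(mol)) {
  n <- mg_natoms(mol)
  m <- mg_nbonds(mol)
  if (m == 0L) return(logical(0L))
  disc <- integer(n); low <- integer(n)
  is_bridge <- logical(m)
  timer <- 0L
  # iterative DFS storing (vertex, parent-bond, child-pointer)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack_v <- root; stack_pb <- 0L; stack_ci <- 1L
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack_v)) {
      top <- length(stack_v)
      v <- stack_v[top]; pb <- stack_pb[top]; ci <- stack_ci[top]
      nbrs <- adj$nbr[[v]]; bnds <- adj$bond[[v]]
      if (ci <= length(nbrs)) {
        stack_ci[top] <- ci + 1L
        b <- bnds[ci]; w <- nbrs[ci]
        if (b == pb) next
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack_v <- c(stack_v, w); stack_pb <- c(stack_pb, b)
          stack_ci <- c(stack_ci, 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        # retreat
        stack_v <- stack_v[-top]; stack_pb <- stack_pb[-top]
        stack_ci <- stack_ci[-top]
        if (length(stack_v)) {
          parent <- stack_v[length(stack_v)]
          low[parent] <- min(low[parent], low[v])
          if (low[v] > disc[parent]) is_bridge[pb] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

# Extract the induced sub-molecule on `atoms` (integer indices). Returns the
# sub-molecule; attribute "src" maps new atom index -> original index.
mg_subgraph <- function(mol, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  idx <- integer(mg_natoms(mol))
  idx[atoms] <- seq_along(atoms)
  keep <- idx[mol$bond_a] > 0L & idx[mol$bond_b] > 0L
  sub <- mg_mol(
    elem = mol$elem[atoms], arom = mol$arom[atoms],
    charge = mol$charge[atoms], nH = mol$nH[atoms],
    map = mol$map[atoms], isotope = mol$isotope[atoms],
    bond_a = idx[mol$bond_a[keep]], bond_b = idx[mol$bond_b[keep]],
    border = mol$border[keep]
  )
  attr(sub, "src") <- atoms
  sub
}

# Disjoint union of two molecules; atom indices of `b` are shifted.
mg_union <- function(a, b) {
  na <- mg_natoms(a)
  mg_mol(
    elem = c(a$elem, b$elem), arom = c(a$arom, b$arom),
    charge = c(a$charge, b$charge), nH = c(a$nH, b$nH),
    map = c(a$map, b$map), isotope = c(a$isotope, b$isotope),
    bond_a = c(a$bond_a, b$bond_a + na), bond_b = c(a$bond_b, b$bond_b + na),
    border = c(a$border, b$border)
  )
}

mg_add_bond <- function(mol, i, j, order = 1) {
  mol$bond_a <- c(mol$bond_a, as.integer(i))
  mol$bond_b <- c(mol$bond_b, as.integer(j))
  mol$border <- c(mol$border, order)
  mol
}

mg_remove_atoms <- function(mol, atoms) {
  keep <- setdiff(seq_len(mg_natoms(mol)), atoms)
  mg_subgraph(mol, keep)
}

# Heavy atoms exclude dummies ("*") and explicit hydrogens.
mg_n_heavy <- function(mol) sum(!(mol$elem %in% c("*", "H")))

mg_is_dummy <- function(mol) mol$elem == "*"

# ---- valence model -------------------------------------------------------

# Allowed valence lists for neutral atoms of the organic subset (smallest
# value consistent with the bond-order sum is used for implicit hydrogens).
.VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, H = 1
)

mg_max_valence <- function(elem, charge) {
  base <- switch(elem,
    B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
    F = 1, Cl = 1, Br = 1, I = 1, H = 1, `*` = Inf, NA_real_)
  if (is.na(base)) return(NA_real_)
  if (charge == 0) {
    if (elem %in% c("N", "P")) base <- 5
    return(base)
  }
  switch(elem,
    N = 3 + charge, P = 5 + min(charge, 0), O = 2 + charge, S = 6 + min(charge, 0),
    C = 4 - abs(charge), B = 3 - charge,
    base)
}

# Bond-order sum per atom; aromatic bonds count 1 sigma each plus a single
# shared pi electron allowance handled by the caller.
mg_bond_order_sums <- function(mol) {
  n <- mg_natoms(mol)
  s <- numeric(n)
  nar <- integer(n)
  m <- mg_nbonds(mol)
  if (m > 0L) {
    for (k in seq_len(m)) {
      o <- mol$border[k]
      a <- mol$bond_a[k]; b <- mol$bond_b[k]
      s[a] <- s[a] + o; s[b] <- s[b] + o
      if (o == 1.5) { nar[a] <- nar[a] + 1L; nar[b] <- nar[b] + 1L }
    }
  }
  list(sum = s, n_arom = nar)
}

#' Validate a molecule under standard valence rules
#'
#' Checks the element filter (organic subset plus dummies/explicit H) and that
#' every atom's total connection count (bond orders + implicit hydrogens) does
#' not exceed the maximum valence allowed for its element and formal charge.
#' Aromatic atoms get a slack of one for the delocalised pi system.
#'
#' @param mol internal molecule object
#' @param allowed_elements character vector of permitted element symbols
#' @return `TRUE` invisibly; signals `mg_sanitize_error` on violation
#' @keywords internal
mg_sanitize <- function(mol, allowed_elements = ORGANIC_ELEMENTS) {
  bad <- !(mol$elem %in% c(allowed_elements, "H", "*"))
  if (any(bad)) {
    stop_mg("mg_sanitize_error", sprintf(
      "disallowed element(s): %s", paste(unique(mol$elem[bad]), collapse = ", ")))
  }
  bs <- mg_bond_order_sums(mol)
  # aromatic bonds count one sigma each; the shared pi electron is left out,
  # which accepts lone-pair donors (furan O, pyrrole NH) while still
  # catching gross violations
  total <- bs$sum - 0.5 * bs$n_arom + mol$nH
  for (i in seq_len(mg_natoms(mol))) {
    if (mol$elem[i] == "*") next
    mx <- mg_max_valence(mol$elem[i], mol$charge[i])
    if (is.na(mx) || total[i] > mx + 1e-9) {
      stop_mg("mg_sanitize_error", sprintf(
        "valence violation at atom %d (%s%s): total %.1f exceeds %s",
        i, mol$elem[i],
        if (mol$charge[i] != 0) sprintf("%+d", mol$charge[i]) else "",
        total[i], format(mx)))
    }
  }
  invisible(TRUE)
}

# Condition helper: classed errors so callers can distinguish failure modes.
stop_mg <- function(class, msg, ...) {
  stop(structure(class = c(class, "mg_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
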