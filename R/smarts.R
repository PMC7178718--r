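# A deliberately small SMARTS matcher.
#
# Supports the subset needed for substructure filters of the PAINS kind:
# atom primitives (element symbols, aromatic lowercase, a/A/*, #n, X<n>,
# D<n>, H<n>, R/R0, charges, recursive $(...)), logical operators ! , & ;
# bond primitives - = # : ~ and the single-or-aromatic default, branches and
# ring closures. Not supported (rejected at parse time): r<n>, v<n>, x<n>,
# stereo, @-bonds, component-level grouping.

#' Compile a SMARTS pattern (supported subset)
#'
#' Atom primitives: element symbols, aromatic lowercase, a/A/*, #n, X<n>,
#' D<n>, H<n>, R/R0, charges, recursive $(...), combined with ! , & ; and
#' plain juxtaposition. Bond primitives: - = # : ~ plus the
#' single-or-aromatic default. Unsupported constructs (r<n>, v<n>, stereo)
#' are rejected with an error.
#'
#' @param pattern SMARTS string
#' @return a compiled pattern for [has_substructure()]
#' @export
parse_smarts <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  nc <- length(chars)
  atoms <- list()
  ba <- integer(); bb <- integer(); bpred <- character()
  prev <- 0L; pending <- NA_character_
  stack <- integer(); ring <- list()
  i <- 1L
  add_atom <- function(spec) {
    atoms[[length(atoms) + 1L]] <<- spec
    a <- length(atoms)
    if (prev > 0L) {
      ba[length(ba) + 1L] <<- prev; bb[length(bb) + 1L] <<- a
      bpred[length(bpred) + 1L] <<- if (is.na(pending)) "default" else pending
    }
    prev <<- a; pending <<- NA_character_
  }
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (!length(stack)) stop_mg("mg_smarts_error", "unmatched ')' in '%s'", pattern)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    }
    else if (ch == "-") { pending <- "single"; i <- i + 1L }
    else if (ch == "=") { pending <- "double"; i <- i + 1L }
    else if (ch == "#") { pending <- "triple"; i <- i + 1L }
    else if (ch == ":") { pending <- "aromatic"; i <- i + 1L }
    else if (ch == "~") { pending <- "any"; i <- i + 1L }
    else if (grepl("[0-9]", ch)) {
      if (is.null(ring[[ch]])) {
        ring[[ch]] <- list(atom = prev, pred = pending)
      } else {
        open <- ring[[ch]]; ring[[ch]] <- NULL
        p <- pending
        if (is.na(p)) p <- open$pred
        if (is.na(p) || is.null(p)) p <- "default"
        ba[length(ba) + 1L] <- open$atom; bb[length(bb) + 1L] <- prev
        bpred[length(bpred) + 1L] <- p
      }
      pending <- NA_character_; i <- i + 1L
    }
    else if (ch == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= nc && depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth > 0L) stop_mg("mg_smarts_error", "unclosed '[' in '%s'", pattern)
      body <- paste(chars[(i + 1L):(j - 2L)], collapse = "")
      add_atom(parse_smarts_atom(body, pattern))
      i <- j
    }
    else {
      sym <- ch
      if (i < nc && paste0(ch, chars[i + 1L]) %in% .TWO_CHAR) {
        sym <- paste0(ch, chars[i + 1L]); i <- i + 1L
      }
      spec <- if (sym == "*") list(list(list(kind = "any")))
      else if (sym == "a") list(list(list(kind = "arom", value = TRUE)))
      else if (sym == "A") list(list(list(kind = "arom", value = FALSE)))
      else if (sym %in% .ORGANIC_UPPER) list(list(list(kind = "elem", value = sym, arom = FALSE)))
      else if (sym %in% .ORGANIC_LOWER) list(list(list(kind = "elem", value = toupper(sym), arom = TRUE)))
      else stop_mg("mg_smarts_error", "unexpected '%s' in '%s'", sym, pattern)
      add_atom(spec)
      i <- i + 1L
    }
  }
  if (length(stack) || length(ring)) {
    stop_mg("mg_smarts_error", "unbalanced branches or ring bonds in '%s'", pattern)
  }
  list(atoms = atoms, bond_a = ba, bond_b = bb, bond_pred = bpred)
}

# Bracket atom body -> OR-list of AND-lists of primitive tests.
# ';' and '&' both behave as AND here, as does plain juxtaposition
# ([CX4H2] == [C&X4&H2]); ',' is OR.
parse_smarts_atom <- function(body, pattern) {
  or_parts <- split_top_level(body, ",")
  lapply(or_parts, function(part) {
    and_parts <- unlist(lapply(split_top_level(part, ";"), split_top_level, "&"))
    unlist(lapply(and_parts, lex_smarts_prims, pattern = pattern),
           recursive = FALSE)
  })
}

# Lex a run of juxtaposed primitives, e.g. "!OX2H" or "$(cc)R".
lex_smarts_prims <- function(s, pattern) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  i <- 1L
  prims <- list()
  grab_digits <- function(j) {
    k <- j
    while (k <= n && grepl("[0-9]", chars[k])) k <- k + 1L
    list(num = if (k > j) as.integer(paste(chars[j:(k - 1L)], collapse = "")) else NA_integer_,
         nxt = k)
  }
  while (i <= n) {
    neg <- FALSE
    while (i <= n && chars[i] == "!") { neg <- !neg; i <- i + 1L }
    if (i > n) stop_mg("mg_smarts_error", "dangling '!' in '%s'", pattern)
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    spec <- NULL
    if (ch == "$" && i < n && chars[i + 1L] == "(") {
      depth <- 1L; j <- i + 2L
      while (j <= n && depth > 0L) {
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth > 0L) stop_mg("mg_smarts_error", "unclosed '$(' in '%s'", pattern)
      inner <- paste(chars[(i + 2L):(j - 2L)], collapse = "")
      spec <- list(kind = "rec", value = parse_smarts(inner))
      i <- j
    } else if (ch == "*") { spec <- list(kind = "any"); i <- i + 1L }
    else if (ch == "a") { spec <- list(kind = "arom", value = TRUE); i <- i + 1L }
    else if (ch == "A") { spec <- list(kind = "arom", value = FALSE); i <- i + 1L }
    else if (ch == "#") {
      g <- grab_digits(i + 1L)
      if (is.na(g$num)) stop_mg("mg_smarts_error", "bad '#' in '%s'", pattern)
      spec <- list(kind = "anum", value = g$num); i <- g$nxt
    } else if (ch == "X") {
      g <- grab_digits(i + 1L)
      spec <- list(kind = "conn", value = if (is.na(g$num)) 1L else g$num); i <- g$nxt
    } else if (ch == "D") {
      g <- grab_digits(i + 1L)
      spec <- list(kind = "deg", value = if (is.na(g$num)) 1L else g$num); i <- g$nxt
    } else if (ch == "H") {
      g <- grab_digits(i + 1L)
      spec <- list(kind = "hcount", value = if (is.na(g$num)) 1L else g$num); i <- g$nxt
    } else if (ch == "R") {
      g <- grab_digits(i + 1L)
      spec <- if (!is.na(g$num) && g$num == 0L) list(kind = "ring", value = FALSE)
              else list(kind = "ring", value = TRUE)
      i <- g$nxt
    } else if (ch == "+" || ch == "-") {
      sgn <- if (ch == "+") 1L else -1L
      reps <- 1L; j <- i + 1L
      while (j <= n && chars[j] == ch) { reps <- reps + 1L; j <- j + 1L }
      g <- grab_digits(j)
      val <- if (!is.na(g$num)) sgn * g$num else sgn * reps
      spec <- list(kind = "charge", value = val); i <- g$nxt
    } else if (grepl("[0-9]", ch)) {
      g <- grab_digits(i)
      spec <- list(kind = "isotope", value = g$num); i <- g$nxt
    } else if (two %in% .TWO_CHAR) {
      spec <- list(kind = "elem", value = two, arom = FALSE); i <- i + 2L
    } else if (ch %in% .ORGANIC_UPPER) {
      spec <- list(kind = "elem", value = ch, arom = FALSE); i <- i + 1L
    } else if (ch %in% .ORGANIC_LOWER) {
      spec <- list(kind = "elem", value = toupper(ch), arom = TRUE); i <- i + 1L
    } else {
      stop_mg("mg_smarts_error", "unsupported SMARTS primitive at '%s' in '%s'", ch, pattern)
    }
    spec$negate <- neg
    prims[[length(prims) + 1L]] <- spec
  }
  prims
}

split_top_level <- function(s, sep) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L; out <- character(); cur <- character()
  for (ch in chars) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (ch == sep && depth == 0L) { out <- c(out, paste(cur, collapse = "")); cur <- character() }
    else cur <- c(cur, ch)
  }
  c(out, paste(cur, collapse = ""))
}

.ANUM <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L, S = 16L,
           Cl = 17L, Br = 35L, I = 53L)

# Pre-computed per-atom features used by primitive tests.
smarts_mol_features <- function(mol) {
  n <- mg_natoms(mol)
  adj <- mg_adj(mol)
  ringb <- mg_ring_bonds(mol, adj)
  in_ring <- logical(n)
  if (length(ringb) && any(ringb)) {
    in_ring[unique(c(mol$bond_a[ringb], mol$bond_b[ringb]))] <- TRUE
  }
  deg <- tabulate(c(mol$bond_a, mol$bond_b), nbins = n)
  list(adj = adj, in_ring = in_ring, deg = deg, conn = deg + mol$nH)
}

atom_matches <- function(mol, ft, i, spec) {
  for (and_list in spec) {
    ok <- TRUE
    for (prim in and_list) {
      v <- switch(prim$kind,
        any = TRUE,
        arom = mol$arom[i] == prim$value,
        elem = mol$elem[i] == prim$value && mol$arom[i] == prim$arom,
        anum = !is.na(.ANUM[mol$elem[i]]) && .ANUM[mol$elem[i]] == prim$value,
        conn = ft$conn[i] == prim$value,
        deg = ft$deg[i] == prim$value,
        hcount = mol$nH[i] == prim$value,
        ring = ft$in_ring[i] == prim$value,
        charge = mol$charge[i] == prim$value,
        isotope = mol$isotope[i] == prim$value,
        rec = length(match_smarts_rooted(mol, ft, prim$value, i)) > 0L,
        FALSE)
      if (isTRUE(prim$negate)) v <- !v
      if (!v) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

bond_matches <- function(mol, b, pred) {
  o <- mol$border[b]
  arom <- o == 1.5
  switch(pred,
    default = o == 1 || arom,
    single = o == 1,
    double = o == 2,
    triple = o == 3,
    aromatic = arom,
    any = TRUE,
    FALSE)
}

# Backtracking subgraph match; returns the first embedding (atom indices per
# pattern atom) or integer(0). If `root` is given, pattern atom 1 must map
# to it (used for recursive SMARTS).
match_smarts_rooted <- function(mol, ft, pat, root = NULL) {
  np <- length(pat$atoms)
  if (np == 0L) return(integer(0L))
  # pattern adjacency
  padj <- vector("list", np)
  for (b in seq_along(pat$bond_a)) {
    a1 <- pat$bond_a[b]; a2 <- pat$bond_b[b]
    padj[[a1]] <- c(padj[[a1]], list(list(other = a2, pred = pat$bond_pred[b])))
    padj[[a2]] <- c(padj[[a2]], list(list(other = a1, pred = pat$bond_pred[b])))
  }
  n <- mg_natoms(mol)
  assign_vec <- integer(np)
  used <- logical(n)
  try_assign <- function(pi_) {
    if (pi_ > np) return(TRUE)
    # candidates: neighbours of an already-assigned pattern neighbour
    anchor <- NULL
    for (e in padj[[pi_]]) {
      if (assign_vec[e$other] > 0L) { anchor <- e; break }
    }
    cands <- if (pi_ == 1L && !is.null(root)) root
    else if (is.null(anchor)) which(!used)
    else ft$adj$nbr[[assign_vec[anchor$other]]]
    for (mi in cands) {
      if (used[mi]) next
      if (!atom_matches(mol, ft, mi, pat$atoms[[pi_]])) next
      okb <- TRUE
      for (e in padj[[pi_]]) {
        mo <- assign_vec[e$other]
        if (mo == 0L) next
        bidx <- which((mol$bond_a == mi & mol$bond_b == mo) |
                      (mol$bond_b == mi & mol$bond_a == mo))
        if (!length(bidx) || !bond_matches(mol, bidx[1L], e$pred)) { okb <- FALSE; break }
      }
      if (!okb) next
      assign_vec[pi_] <<- mi; used[mi] <<- TRUE
      if (try_assign(pi_ + 1L)) return(TRUE)
      assign_vec[pi_] <<- 0L; used[mi] <<- FALSE
    }
    FALSE
  }
  if (try_assign(1L)) assign_vec else integer(0L)
}

#' Substructure match with the supported SMARTS subset
#'
#' @param mol molecule (SMILES, record or internal object)
#' @param pattern SMARTS string, or a pre-parsed pattern
#' @return `TRUE` if the pattern occurs in the molecule
#' @export
has_substructure <- function(mol, pattern) {
  mol <- as_mg_mol(mol)
  pat <- if (is.character(pattern)) parse_smarts(pattern) else pattern
  ft <- smarts_mol_features(mol)
  length(match_smarts_rooted(mol, ft, pat)) > 0L
}
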