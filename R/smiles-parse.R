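# SMILES reader for the organic subset.
#
# Supported: organic-subset atoms (B C N O P S F Cl Br I), aromatic lowercase
# (b c n o p s), bracket atoms with isotope / charge / explicit H / atom map,
# dummy atoms `*`, branches, ring closures (incl. %nn), dots, bond symbols
# - = # : (plus / and \\ read as single; tetrahedral marks @/@@ are dropped —
# stereochemistry is deliberately out of scope of the fragment keys).

.TWO_CHAR <- c("Cl", "Br")
.ORGANIC_UPPER <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.ORGANIC_LOWER <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into the internal molecule representation
#'
#' Implicit hydrogens are assigned to unbracketed atoms from the standard
#' valence model; bracket atoms carry exactly the hydrogens they declare.
#' Kekule aromatic rings (alternating single/double) are perceived and
#' converted to the aromatic form so that `C1=CC=CC=C1` and `c1ccccc1` yield
#' the same molecule.
#'
#' @param smiles a single SMILES string
#' @param sanitize check valences after parsing (default `TRUE`)
#' @param strip_isotopes drop isotope labels (default `TRUE`)
#' @return an internal `mg_mol` object
#' @export
parse_smiles <- function(smiles, sanitize = TRUE, strip_isotopes = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop_mg("mg_parse_error", "smiles must be a single string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  nc <- length(chars)

  elem <- character(); arom <- logical(); charge <- integer()
  nHex <- integer()   # explicit H from brackets, NA for organic-subset atoms
  map <- integer(); iso <- integer()
  ba <- integer(); bb <- integer(); bo <- numeric()

  prev <- 0L                # previous atom index (0 = none, e.g. after '.')
  pending_bond <- NA_real_  # bond symbol seen since previous atom
  stack <- integer()        # open branch atoms
  ring <- list()            # closure digit -> list(atom, order)
  i <- 1L

  add_atom <- function(e, ar, ch, nh, mp, is) {
    elem[length(elem) + 1L] <<- e
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    nHex[length(nHex) + 1L] <<- nh
    map[length(map) + 1L] <<- mp
    iso[length(iso) + 1L] <<- is
    a <- length(elem)
    if (prev > 0L) {
      o <- pending_bond
      if (is.na(o)) o <- if (ar && arom[prev]) 1.5 else 1
      ba[length(ba) + 1L] <<- prev
      bb[length(bb) + 1L] <<- a
      bo[length(bo) + 1L] <<- o
    }
    prev <<- a
    pending_bond <<- NA_real_
    invisible(a)
  }

  while (i <= nc) {
    ch <- chars[i]
    if (ch == "(") {
      if (prev == 0L) stop_mg("mg_parse_error", "branch with no preceding atom in '%s'", smiles)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop_mg("mg_parse_error", "unmatched ')' in '%s'", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; pending_bond <- NA_real_; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- 1.5; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > nc) stop_mg("mg_parse_error", "bad %% ring closure in '%s'", smiles)
        key <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        key <- ch; i <- i + 1L
      }
      if (prev == 0L) stop_mg("mg_parse_error", "ring closure with no atom in '%s'", smiles)
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, order = pending_bond)
      } else {
        open <- ring[[key]]; ring[[key]] <- NULL
        o <- pending_bond
        if (is.na(o)) o <- open$order
        if (is.na(o)) o <- if (arom[prev] && arom[open$atom]) 1.5 else 1
        ba[length(ba) + 1L] <- open$atom
        bb[length(bb) + 1L] <- prev
        bo[length(bo) + 1L] <- o
      }
      pending_bond <- NA_real_
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= nc && chars[j] != "]") j <- j + 1L
      if (j > nc) stop_mg("mg_parse_error", "unclosed '[' in '%s'", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      add_atom(at$elem, at$arom, at$charge, at$nH, at$map, at$iso)
      i <- j + 1L
    } else {
      # organic-subset atom
      sym <- ch
      if (i < nc && paste0(ch, chars[i + 1L]) %in% .TWO_CHAR) {
        sym <- paste0(ch, chars[i + 1L]); i <- i + 1L
      }
      if (sym %in% .ORGANIC_UPPER) {
        add_atom(sym, FALSE, 0L, NA_integer_, 0L, 0L)
      } else if (sym %in% .ORGANIC_LOWER) {
        add_atom(toupper(sym), TRUE, 0L, NA_integer_, 0L, 0L)
      } else if (sym == "*") {
        add_atom("*", FALSE, 0L, 0L, 0L, 0L)
      } else {
        stop_mg("mg_parse_error", "unexpected character '%s' in '%s'", sym, smiles)
      }
      i <- i + 1L
    }
  }
  if (length(stack)) stop_mg("mg_parse_error", "unclosed branch in '%s'", smiles)
  if (length(ring)) stop_mg("mg_parse_error", "unclosed ring bond in '%s'", smiles)

  if (strip_isotopes) iso[] <- 0L
  mol <- mg_mol(elem, arom, charge, ifelse(is.na(nHex), 0L, nHex), map, iso,
                ba, bb, bo)
  # implicit H are assigned from the orders as written (Kekule or aromatic),
  # then aromaticity is perceived; perception never changes hydrogen counts,
  # so C1=CC=CN1 keeps its N-H when it becomes the aromatic pyrrole.
  mol$nH <- assign_implicit_h(mol, explicit = !is.na(nHex), nHex = nHex)
  mol <- perceive_aromaticity(mol)
  if (sanitize) mg_sanitize(mol)
  mol
}

parse_bracket_atom <- function(body, smiles) {
  rx <- "^([0-9]*)(#[0-9]+|[A-Z][a-z]?|[a-z]|\\*)((?:@{1,2})?)(H[0-9]*)?((?:\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?)(:([0-9]+))?$"
  m <- regmatches(body, regexec(rx, body))[[1L]]
  if (!length(m)) stop_mg("mg_parse_error", "cannot parse bracket atom [%s] in '%s'", body, smiles)
  iso <- if (nzchar(m[2L])) as.integer(m[2L]) else 0L
  sym <- m[3L]
  ar <- FALSE
  if (startsWith(sym, "#")) {
    num <- as.integer(substring(sym, 2L))
    tbl <- c(`1` = "H", `5` = "B", `6` = "C", `7` = "N", `8` = "O", `9` = "F",
             `15` = "P", `16` = "S", `17` = "Cl", `35` = "Br", `53` = "I")
    sym <- tbl[as.character(num)]
    if (is.na(sym)) stop_mg("mg_parse_error", "unsupported atomic number in [%s]", body)
  } else if (sym == tolower(sym) && sym != "*") {
    ar <- TRUE
    sym <- paste0(toupper(substring(sym, 1L, 1L)), substring(sym, 2L))
  }
  hs <- m[5L]
  nH <- if (!nzchar(hs)) 0L else if (hs == "H") 1L else as.integer(substring(hs, 2L))
  chs <- m[6L]
  chg <- 0L
  if (nzchar(chs)) {
    if (grepl("^[+-][0-9]+$", chs)) {
      chg <- as.integer(chs)
    } else {
      chg <- (nchar(chs)) * (if (startsWith(chs, "+")) 1L else -1L)
    }
  }
  mp <- if (nzchar(m[7L])) as.integer(m[8L]) else 0L
  list(elem = sym, arom = ar, charge = chg, nH = nH, map = mp, iso = iso)
}

# Implicit hydrogens for unbracketed atoms: smallest allowed valence that
# accommodates the bond-order sum. Aromatic unbracketed atoms use the
# ceil(sum with aromatic bonds at 1.5) convention, which reproduces the
# standard readings (benzene c -> 1H, pyridine n -> 0H, furan o -> 0H).
assign_implicit_h <- function(mol, explicit, nHex) {
  bs <- mg_bond_order_sums(mol)
  nH <- integer(mg_natoms(mol))
  for (i in seq_len(mg_natoms(mol))) {
    if (explicit[i]) { nH[i] <- nHex[i]; next }
    if (mol$elem[i] == "*") { nH[i] <- 0L; next }
    need <- ceiling(bs$sum[i] - 1e-9)
    allowed <- .VALENCES[[mol$elem[i]]]
    if (is.null(allowed)) { nH[i] <- 0L; next }
    v <- allowed[allowed >= need]
    if (!length(v)) { nH[i] <- 0L; next }
    nH[i] <- as.integer(v[1L] - need)
    if (mol$arom[i] && mol$elem[i] %in% c("O", "S")) nH[i] <- 0L
  }
  nH
}

# Convert alternating Kekule rings to aromatic form. Only simple rings of
# size 5-7 are considered, with a 4n+2 electron count over contributions:
# atom in a ring double bond -> 1; heteroatom (N, O, S) with lone pair and no
# double bond -> 2; exocyclic double bond or anything else -> not aromatic.
perceive_aromaticity <- function(mol) {
  m <- mg_nbonds(mol)
  if (m == 0L || all(mol$arom)) return(mol)
  adj <- mg_adj(mol)
  ringb <- mg_ring_bonds(mol, adj)
  if (!any(ringb)) return(mol)
  rings <- find_small_rings(mol, adj, ringb, max_size = 7L)
  if (!length(rings)) return(mol)
  dbl_part <- integer(mg_natoms(mol))  # partner atom across a double bond
  for (k in seq_len(m)) {
    if (mol$border[k] == 2) {
      dbl_part[mol$bond_a[k]] <- mol$bond_b[k]
      dbl_part[mol$bond_b[k]] <- mol$bond_a[k]
    }
  }
  arom_atoms <- which(mol$arom)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (ring in rings) {
      if (all(ring %in% arom_atoms)) next
      pi_e <- 0L
      ok <- TRUE
      for (a in ring) {
        if (mol$elem[a] %in% c("F", "Cl", "Br", "I", "*", "H")) { ok <- FALSE; break }
        p <- dbl_part[a]
        if (p != 0L && p %in% ring) {
          pi_e <- pi_e + 1L
        } else if (a %in% arom_atoms) {
          # fusion atom shared with an already-aromatic ring: one pi electron
          pi_e <- pi_e + 1L
        } else if (p != 0L && !(p %in% ring)) {
          ok <- FALSE; break  # exocyclic double bond blocks (simplified model)
        } else if (mol$elem[a] %in% c("N", "O", "S") &&
                   mol$charge[a] == 0L) {
          pi_e <- pi_e + 2L
        } else {
          ok <- FALSE; break
        }
      }
      if (ok && pi_e >= 2L && (pi_e - 2L) %% 4L == 0L) {
        arom_atoms <- union(arom_atoms, ring)
        changed <- TRUE
      }
    }
  }
  if (!length(arom_atoms)) return(mol)
  mol$arom[arom_atoms] <- TRUE
  in_ar <- seq_len(mg_natoms(mol)) %in% arom_atoms
  for (k in seq_len(m)) {
    if (ringb[k] && in_ar[mol$bond_a[k]] && in_ar[mol$bond_b[k]] &&
        mol$border[k] %in% c(1, 2)) {
      # only bonds inside a perceived aromatic ring flip to order 1.5
      if (bond_in_some_ring(rings, arom_atoms, mol$bond_a[k], mol$bond_b[k])) {
        mol$border[k] <- 1.5
      }
    }
  }
  mol
}

bond_in_some_ring <- function(rings, arom_atoms, a, b) {
  for (ring in rings) {
    if (all(ring %in% arom_atoms) && a %in% ring && b %in% ring) {
      n <- length(ring)
      pos_a <- match(a, ring); pos_b <- match(b, ring)
      if (abs(pos_a - pos_b) == 1L || abs(pos_a - pos_b) == n - 1L) return(TRUE)
    }
  }
  FALSE
}

# Smallest ring through each ring bond (an SSSR stand-in adequate for simple
# and ortho-fused systems): shortest path between bond endpoints avoiding the
# bond itself.
find_small_rings <- function(mol, adj, ringb, max_size = 7L) {
  rings <- list()
  seen <- character()
  for (k in which(ringb)) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    path <- shortest_path_avoiding(mol, adj, a, b, k)
    if (is.null(path) || length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- path
  }
  rings
}

shortest_path_avoiding <- function(mol, adj, from, to, avoid_bond) {
  n <- mg_natoms(mol)
  prev <- integer(n)
  prev[from] <- -1L
  queue <- from
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nbrs <- adj$nbr[[v]]; bnds <- adj$bond[[v]]
    for (t in seq_along(nbrs)) {
      if (bnds[t] == avoid_bond) next
      w <- nbrs[t]
      if (prev[w] == 0L) {
        prev[w] <- v
        if (w == to) {
          path <- w
          while (prev[path[1L]] != -1L) path <- c(prev[path[1L]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}
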