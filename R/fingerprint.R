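# Hashed circular (Morgan-style) fingerprints.
#
# Atom environments of increasing radius are hashed from (initial atom
# invariant, sorted neighbour (bond, invariant) pairs) and folded modulo
# n_bits. The construction is deterministic and self-consistent; bit
# positions are NOT interchangeable with any other toolkit's Morgan bits,
# which is irrelevant for the Tanimoto-based metrics computed here.

#' Fingerprint configuration
#'
#' @param n_bits fingerprint length (default 2048)
#' @param fp_radius circular radius (default 2)
#' @return a `fingerprint_config` list
#' @export
fingerprint_config <- function(n_bits = 2048L, fp_radius = 2L) {
  structure(list(n_bits = as.integer(n_bits), fp_radius = as.integer(fp_radius)),
            class = "fingerprint_config")
}

.FP_PRIME <- 33554467  # < 2^26 so 31*h + x stays exact in doubles

fp_hash <- function(values) {
  h <- 5381
  for (x in values) h <- (h * 31 + x) %% .FP_PRIME
  h
}

# Per-atom environment identifiers for radii 0..fp_radius (a list of integer
# vectors, one per radius).
morgan_invariants <- function(mol, fp_radius = 2L) {
  n <- mg_natoms(mol)
  if (n == 0L) return(list(integer(0L)))
  adj <- mg_adj(mol)
  ringb <- mg_ring_bonds(mol, adj)
  in_ring <- logical(n)
  if (length(ringb)) {
    in_ring[unique(c(mol$bond_a[ringb], mol$bond_b[ringb]))] <- TRUE
  }
  elem_num <- match(mol$elem, c("*", "H", ORGANIC_ELEMENTS))
  deg <- tabulate(c(mol$bond_a, mol$bond_b), nbins = n)
  inv <- vapply(seq_len(n), function(i) {
    fp_hash(c(elem_num[i], deg[i], mol$nH[i], mol$charge[i] + 10,
              as.integer(mol$arom[i]), as.integer(in_ring[i])))
  }, numeric(1))
  out <- list(inv)
  bkey <- .BOND_KEY(mol$border)
  for (r in seq_len(fp_radius)) {
    nxt <- vapply(seq_len(n), function(i) {
      nb <- adj$nbr[[i]]
      if (!length(nb)) return(fp_hash(c(r, inv[i])))
      codes <- sort(bkey[adj$bond[[i]]] * .FP_PRIME + inv[nb])
      fp_hash(c(r, inv[i], codes))
    }, numeric(1))
    out[[r + 1L]] <- nxt
    inv <- nxt
  }
  out
}

#' Morgan-style fingerprint as a set of on-bit positions
#'
#' @param mol molecule (SMILES, record or internal object)
#' @param cfg a [fingerprint_config()]
#' @return sorted integer vector of on-bit positions in `[0, n_bits)`
#' @export
morgan_fp <- function(mol, cfg = fingerprint_config()) {
  mol <- as_mg_mol(mol)
  inv <- unlist(morgan_invariants(mol, cfg$fp_radius), use.names = FALSE)
  sort(unique(as.integer(round(inv) %% cfg$n_bits)))
}

#' Tanimoto similarity of two bit sets
#'
#' @param a,b integer vectors of on-bit positions
#' @return similarity in `[0, 1]`; two empty sets have similarity 1
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
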