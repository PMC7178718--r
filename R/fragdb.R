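# The key-value database of interchangeable fragments.
#
# Keys are (radius, canonical context); values are canonically renumbered
# cores with their heavy-atom size and occurrence count (number of distinct
# corpus molecules contributing the triple). Storage is a data.table keyed
# on (radius, context); the interchange format is a plain TSV.

#' Build a fragment database from a molecule corpus
#'
#' Every corpus molecule is exhaustively fragmented (bond cuts up to
#' `max_cuts`, hydrogens separately); each record's context is truncated at
#' every requested radius, canonicalized together with its core, and all
#' symmetry-equivalent core variants are stored. A (radius, context, core)
#' triple's count increases at most once per distinct source molecule.
#'
#' @param corpus character vector of SMILES, or list of
#'   [molecule_record()]s; duplicates (by canonical SMILES) are dropped
#' @param radii integer vector of context radii to build
#' @param max_cuts maximum simultaneous bond cuts
#' @param progress print a note every 10 molecules
#' @return a `frag_db` object
#' @importFrom data.table data.table setkeyv
#' @export
build_db <- function(corpus, radii = 1:3, max_cuts = 4L, progress = FALSE) {
  if (length(radii) == 0L) stop_mg("mg_param_error", "radii must be non-empty")
  radii <- sort(unique(as.integer(radii)))
  if (any(radii < 1L)) stop_mg("mg_param_error", "radii must be >= 1")
  smiles <- corpus_smiles(corpus)
  canon <- unique(vapply(smiles, function(s) canonical_smiles(s), "", USE.NAMES = FALSE))
  counter <- new.env(parent = emptyenv(), size = 4096L)
  meta <- new.env(parent = emptyenv(), size = 4096L)
  cp_cache <- new.env(parent = emptyenv(), size = 4096L)
  for (mi in seq_along(canon)) {
    mol <- parse_smiles(canon[mi])
    recs <- fragment_molecule(mol, max_cuts = max_cuts)
    seen <- new.env(parent = emptyenv())
    for (rec in recs) {
      s <- mg_n_heavy(rec$core)
      for (r in radii) {
        ctx_r <- truncate_context(rec$context_full, r)
        cp <- cp_cached(ctx_r, rec$core, cp_cache)
        for (core_s in cp$cores) {
          key <- paste(r, cp$context, core_s, sep = "\t")
          if (!is.null(get0(key, seen))) next
          assign(key, TRUE, seen)
          cnt <- get0(key, counter, ifnotfound = 0L)
          assign(key, cnt + 1L, counter)
          if (cnt == 0L) assign(key, s, meta)
        }
      }
    }
    if (progress && mi %% 10L == 0L) message(sprintf("fragmented %d/%d molecules", mi, length(canon)))
  }
  keys <- sort(ls(counter, sorted = FALSE), method = "radix")
  if (length(keys)) {
    parts <- strsplit(keys, "\t", fixed = TRUE)
    entries <- data.table::data.table(
      radius = as.integer(vapply(parts, `[[`, "", 1L)),
      context = vapply(parts, `[[`, "", 2L),
      core = vapply(parts, `[[`, "", 3L),
      n_heavy = as.integer(unlist(mget(keys, meta), use.names = FALSE)),
      count = as.integer(unlist(mget(keys, counter), use.names = FALSE))
    )
  } else {
    entries <- empty_entries()
  }
  new_frag_db(entries, radii, length(canon))
}

corpus_smiles <- function(corpus) {
  if (is.character(corpus)) return(corpus)
  if (is.data.frame(corpus)) return(as.character(corpus$smiles))
  if (is.list(corpus)) {
    return(vapply(corpus, function(x) if (is.list(x)) x$smiles else as.character(x), ""))
  }
  stop_mg("mg_param_error", "unsupported corpus type")
}

empty_entries <- function() {
  data.table::data.table(radius = integer(), context = character(),
                         core = character(), n_heavy = integer(),
                         count = integer())
}

new_frag_db <- function(entries, radii, corpus_size) {
  data.table::setkeyv(entries, c("radius", "context", "core"))
  structure(list(entries = entries, radii = as.integer(radii),
                 corpus_size = as.integer(corpus_size)),
            class = "frag_db")
}

#' @export
print.frag_db <- function(x, ...) {
  cat(sprintf("<frag_db: %d entries, radii {%s}, corpus of %d molecules>\n",
              nrow(x$entries), paste(x$radii, collapse = ", "), x$corpus_size))
  invisible(x)
}

#' Query interchangeable cores for a canonical context
#'
#' @param db a `frag_db`
#' @param radius context radius (must have been built)
#' @param context canonical context SMILES (as produced by
#'   [canonicalize_pair()])
#' @return data.frame of matching entries, ordered by descending count then
#'   core string
#' @export
query <- function(db, radius, context) {
  radius <- as.integer(radius)
  if (!radius %in% db$radii) {
    stop_mg("mg_param_error", "radius %d was not built in this database", radius)
  }
  .r <- radius; .ctx <- context  # avoid capture of same-named columns in the join
  hits <- db$entries[list(.r, .ctx), on = c("radius", "context"),
                     nomatch = NULL]
  hits <- as.data.frame(hits)
  hits[order(-hits$count, hits$core, method = "radix"), , drop = FALSE]
}

#' Filter database entries by occurrence and core size
#'
#' @param entries data.frame of entries (as returned by [query()])
#' @param min_freq minimum occurrence count
#' @param min_size,max_size heavy-atom bounds on the core
#' @return the surviving subset, input order preserved
#' @export
filter_entries <- function(entries, min_freq = 0L, min_size = 0L, max_size = Inf) {
  if (min_size > max_size || min_freq < 0L || min_size < 0L) {
    stop_mg("mg_param_error", "invalid filter bounds")
  }
  keep <- entries$count >= min_freq & entries$n_heavy >= min_size &
    entries$n_heavy <= max_size
  entries[keep, , drop = FALSE]
}

#' Per-radius database statistics
#'
#' @param db a `frag_db`
#' @return data.frame with columns `radius` and `n_pairs` (distinct
#'   (context, core) pairs at that radius)
#' @export
db_stats <- function(db) {
  counts <- table(factor(db$entries$radius, levels = db$radii))
  data.frame(radius = db$radii, n_pairs = as.integer(counts))
}

#' Write / read a fragment database as TSV
#'
#' The format is a header line `radius context core n_heavy count`
#' (tab-separated) followed by one row per entry, sorted by
#' (radius, context, core).
#'
#' @param db a `frag_db`
#' @param path file path
#' @return `write_db` returns `path` invisibly; `read_db` returns a
#'   `frag_db`
#' @export
write_db <- function(db, path) {
  e <- db$entries[order(radius, context, core)]
  lines <- c("radius\tcontext\tcore\tn_heavy\tcount",
             sprintf("%d\t%s\t%s\t%d\t%d", e$radius, e$context, e$core,
                     e$n_heavy, e$count))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @param corpus_size corpus size to record in the restored object (the TSV
#'   carries entries only)
#' @rdname write_db
#' @export
read_db <- function(path, corpus_size = NA_integer_) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "radius\tcontext\tcore\tn_heavy\tcount") {
    stop_mg("mg_format_error", "line 1: missing or malformed header")
  }
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) {
    stop_mg("mg_format_error", "line %d: expected 5 tab-separated fields, found %d",
            bad[1L] + 1L, lengths(parts)[bad[1L]])
  }
  if (!length(body)) {
    return(new_frag_db(empty_entries(), integer(0L), corpus_size))
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  suppress_na <- function(x, line_off) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) stop_mg("mg_format_error", "line %d: non-integer numeric field",
                          which(is.na(v))[1L] + 1L)
    v
  }
  entries <- data.table::data.table(
    radius = suppress_na(m[, 1L]), context = m[, 2L], core = m[, 3L],
    n_heavy = suppress_na(m[, 4L]), count = suppress_na(m[, 5L]))
  new_frag_db(entries, sort(unique(entries$radius)), corpus_size)
}
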