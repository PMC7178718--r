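# Plain-text SMILES file handling: one molecule per line, optional
# tab-separated identifier. Lines that fail sanitization are skipped with a
# warning, as is conventional for corpus readers.

#' Read a SMILES file
#'
#' @param path file path
#' @param sanitize validate molecules and drop failing lines
#' @return data.frame with columns `smiles` (canonical) and `id`
#' @export
read_smiles_file <- function(path, sanitize = TRUE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  raw <- vapply(parts, `[[`, "", 1L)
  id <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_, "")
  keep <- logical(length(raw))
  canon <- character(length(raw))
  for (i in seq_along(raw)) {
    res <- tryCatch(canonical_smiles(raw[i], sanitize = sanitize),
                    mg_error = function(e) NA_character_)
    if (is.na(res)) {
      warning(sprintf("line %d: skipping unparsable SMILES '%s'", i, raw[i]),
              call. = FALSE)
    } else {
      keep[i] <- TRUE
      canon[i] <- res
    }
  }
  data.frame(smiles = canon[keep], id = id[keep])
}

#' Write SMILES (with optional ids) to a file
#'
#' @param smiles character vector
#' @param path file path
#' @param id optional identifier vector
#' @return `path`, invisibly
#' @export
write_smiles_file <- function(smiles, path, id = NULL) {
  lines <- if (is.null(id)) smiles else paste(smiles, id, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
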