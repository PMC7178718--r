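# Shared fixtures and helpers.

# small reference corpora, built once per test run
h4_corpus <- function() synth_corpus("homologs", 4)$molecules

toluene_ethylbenzene_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- build_db(c("Cc1ccccc1", "CCc1ccccc1"), radii = 1)
    db
  }
})

# python/rdkit cross-check helper: returns RDKit canonical SMILES, or NULL
# when python/rdkit is unavailable (it is pre-installed in the reference
# image; the guard only keeps the suite portable)
rdkit_canon <- function(smiles) {
  tmp_in <- tempfile(fileext = ".smi")
  tmp_out <- tempfile(fileext = ".txt")
  writeLines(smiles, tmp_in)
  script <- sprintf(paste0(
    "from rdkit import Chem\n",
    "rows = [l.strip() for l in open('%s') if l.strip()]\n",
    "out = [Chem.MolToSmiles(Chem.MolFromSmiles(s)) if Chem.MolFromSmiles(s) else 'PARSE_FAIL' for s in rows]\n",
    "open('%s', 'w').write('\\n'.join(out) + '\\n')\n"), tmp_in, tmp_out)
  tmp_py <- tempfile(fileext = ".py")
  writeLines(script, tmp_py)
  status <- suppressWarnings(system2("python", tmp_py, stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(tmp_out)) return(NULL)
  readLines(tmp_out)
}

# compare a frag_db with the brute-force oracle table
expect_db_equals_oracle <- function(corpus, radius, max_cuts = 4L) {
  db <- build_db(corpus, radii = radius, max_cuts = max_cuts)
  ora <- oracle_interchangeable(corpus, radius, max_cuts)
  dbdf <- as.data.frame(db$entries)[, c("radius", "context", "core", "n_heavy", "count")]
  dbdf <- dbdf[order(dbdf$context, dbdf$core), ]
  ora <- ora[order(ora$context, ora$core), ]
  rownames(dbdf) <- rownames(ora) <- NULL
  expect_identical(dbdf, ora)
  invisible(db)
}
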