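# Fragment database: build, query, filter, stats, serialization.

test_that("build_db stores interchangeable cores under shared contexts", {
  db <- toluene_ethylbenzene_db()
  expect_s3_class(db, "frag_db")
  expect_identical(db$corpus_size, 2L)
  # the aromatic-anchor context (where ethyl was cut off) holds methyl,
  # ethyl and hydrogen cores
  e <- as.data.frame(db$entries)
  ctx <- e$context[e$core == "[*:1]CC"][1]
  hits <- query(db, 1, ctx)
  h_core <- canonical_smiles("[H][*:1]")
  expect_true(all(c("[*:1]C", "[*:1]CC", h_core) %in% hits$core))
  # count semantics: one increment per distinct source molecule
  expect_identical(hits$count[hits$core == h_core], 2L)
  expect_identical(hits$count[hits$core == "[*:1]CC"], 1L)
})

test_that("build_db deduplicates corpus molecules before counting", {
  db1 <- build_db(c("Cc1ccccc1", "CCc1ccccc1"), radii = 1)
  db2 <- build_db(c("Cc1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCc1ccccc1"), radii = 1)
  expect_identical(as.data.frame(db1$entries), as.data.frame(db2$entries))
  expect_identical(db2$corpus_size, 2L)
})

test_that("degenerate build inputs behave per contract", {
  empty <- build_db(character(0L), radii = 1)
  expect_identical(nrow(empty$entries), 0L)
  expect_identical(db_stats(empty)$n_pairs, 0L)
  expect_error(build_db("CC", radii = integer(0L)), class = "mg_param_error")
  expect_error(build_db("CC", radii = 0L), class = "mg_param_error")
})

test_that("query is an exact key lookup with deterministic order", {
  db <- toluene_ethylbenzene_db()
  expect_identical(nrow(query(db, 1, "[*:1]N")), 0L)
  e <- as.data.frame(db$entries)
  ctx <- e$context[e$core == "[*:1]C" & e$n_heavy == 1L][1]
  hits <- query(db, 1, ctx)
  expect_false(is.unsorted(rev(hits$count)))   # descending count
  within_count <- split(hits$core, hits$count)
  expect_true(all(vapply(within_count, function(x) !is.unsorted(x), TRUE)))
  expect_error(query(db, 2, ctx), class = "mg_param_error")  # unbuilt radius
})

test_that("filter_entries is a monotone identity-preserving filter", {
  entries <- data.frame(radius = 1L, context = "x", core = c("a", "b", "c"),
                        n_heavy = c(1L, 3L, 5L), count = c(1L, 2L, 3L))
  expect_identical(filter_entries(entries, 0L, 0L, Inf), entries)
  expect_identical(nrow(filter_entries(entries, min_freq = 2L)), 2L)
  for (f in 0:4) {
    expect_gte(nrow(filter_entries(entries, min_freq = f)),
               nrow(filter_entries(entries, min_freq = f + 1L)))
  }
  expect_identical(nrow(filter_entries(entries, min_size = 2L, max_size = 4L)), 1L)
  expect_error(filter_entries(entries, min_size = 5L, max_size = 2L),
               class = "mg_param_error")
})

test_that("db_stats counts distinct pairs per radius and is radius-monotone", {
  fc <- synth_corpus("decorated_aromatics", 8, seed = 5)
  db <- build_db(fc$molecules, radii = 1:3)
  st <- db_stats(db)
  expect_identical(st$radius, 1:3)
  expect_false(is.unsorted(st$n_pairs))
  for (r in 1:3) {
    expect_identical(st$n_pairs[st$radius == r],
                     nrow(oracle_interchangeable(fc, r)))
  }
})

test_that("TSV round trip is lossless and rejects malformed files", {
  db <- toluene_ethylbenzene_db()
  path <- tempfile(fileext = ".tsv")
  write_db(db, path)
  db2 <- read_db(path, corpus_size = db$corpus_size)
  expect_identical(as.data.frame(db$entries[order(radius, context, core)]),
                   as.data.frame(db2$entries[order(radius, context, core)]))
  expect_identical(db_stats(db), db_stats(db2))
  # empty round trip
  p2 <- tempfile(); write_db(build_db(character(0), radii = 1), p2)
  expect_identical(nrow(read_db(p2)$entries), 0L)
  # malformed rows
  writeLines(c("radius\tcontext\tcore\tn_heavy\tcount", "1\tx\ty\t2"), p2)
  expect_error(read_db(p2), class = "mg_format_error")
  writeLines(c("wrong header"), p2)
  expect_error(read_db(p2), class = "mg_format_error")
})

test_that("count conservation bound holds on a fixture corpus", {
  fc <- synth_corpus("linkers", 8, seed = 9)
  db <- build_db(fc$molecules, radii = 1)
  e <- as.data.frame(db$entries)
  expect_true(all(e$count >= 1L))
  expect_true(all(e$count <= db$corpus_size))
})
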