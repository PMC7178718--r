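# Generation modes: MUTATE, GROW, LINK, splice.

test_that("mutate reproduces the hand-derived homolog example", {
  db <- toluene_ethylbenzene_db()
  p <- generation_params(radius = 1, min_size = 1, max_size = 2,
                         min_inc = -1, max_inc = 1)
  out <- mutate("Cc1ccccc1", db, p)
  # methyl -> ethyl and methyl -> H; ring positions blocked by min_size
  expect_setequal(out, c("CCc1ccccc1", "c1ccccc1"))
  expect_identical(out, oracle_mutate("Cc1ccccc1", c("Cc1ccccc1", "CCc1ccccc1"), 1, p))
})

test_that("a single-molecule db still interchanges symmetry-matched sites", {
  # at radius 3 toluene's methyl context (5-atom aromatic path) matches the
  # meta/para H contexts, so H<->CH3 swaps are genuine; verified against the
  # independent oracle
  db <- build_db("Cc1ccccc1", radii = 3)
  p <- generation_params(radius = 3)
  out <- mutate("Cc1ccccc1", db, p)
  expect_identical(out, oracle_mutate("Cc1ccccc1", "Cc1ccccc1", 3, p))
  expect_setequal(out, c("c1ccccc1", "Cc1ccc(C)cc1", "Cc1cccc(C)c1"))
})

test_that("protected atoms are never part of a replaced core", {
  db <- toluene_ethylbenzene_db()
  mol <- molgraft:::as_mg_mol("Cc1ccccc1")
  methyl_idx <- which(mol$elem == "C" & !mol$arom)
  p <- generation_params(radius = 1, min_size = 1, max_size = 2,
                         min_inc = -1, max_inc = 1,
                         protected_atoms = methyl_idx)
  expect_length(mutate(mol, db, p), 0L)
})

test_that("grow is hydrogen replacement with growing cores only", {
  db <- build_db("Cc1ccccc1", radii = 1)
  out <- grow("c1ccccc1", db, generation_params(radius = 1, min_inc = 0, max_inc = 10))
  expect_identical(out, "Cc1ccccc1")
  # no hydrogens -> nothing to grow
  expect_length(grow("FC(F)(F)F", db, generation_params(radius = 1, min_inc = 0, max_inc = 10)), 0L)
})

test_that("grow results are contained in mutate with min_size 0", {
  fc <- synth_corpus("decorated_aromatics", 8, seed = 7)
  db <- build_db(fc$molecules, radii = 1)
  p <- generation_params(radius = 1, min_size = 0, max_size = 8,
                         min_inc = -2, max_inc = 2)
  for (parent in c("Cc1ccccc1", fc$molecules[1])) {
    g <- grow(parent, db, p)
    m <- mutate(parent, db, p)
    expect_true(all(g %in% m))
  }
})

test_that("link joins two molecules through a matched two-point core", {
  db <- build_db("CCC", radii = 1)
  p <- generation_params(radius = 1, min_inc = 0, max_inc = 5)
  out <- link("C", "C", db, p)
  expect_identical(out, "CCC")
  expect_identical(link("C", "C", db, p), link("C", "C", db, p))
  # symmetry in the parents
  db2 <- build_db(c("CCC", "CCO"), radii = 1)
  expect_identical(link("C", "O", db2, p), link("O", "C", db2, p))
  # db without 2-attachment cores
  db3 <- build_db("C", radii = 1)
  expect_length(link("C", "C", db3, p), 0L)
})

test_that("splice validates maps and drops impossible valences", {
  rec <- fragment_on_cut_set("Cc1ccccc1", 1L)[[1]]
  expect_identical(splice(rec, rec$core), "Cc1ccccc1")
  ethyl <- parse_smiles("[*:1]CC", sanitize = FALSE)
  expect_identical(splice(rec, ethyl), "CCc1ccccc1")
  bad_map <- parse_smiles("[*:2]CC", sanitize = FALSE)
  expect_error(splice(rec, bad_map), class = "mg_contract_error")
  pentavalent <- parse_smiles("[*:1]C(C)(C)(C)C", sanitize = FALSE)
  expect_error(splice(rec, pentavalent), class = "mg_splice_error")
})

test_that("max_replacements sampling is seeded and reproducible", {
  fc <- synth_corpus("decorated_aromatics", 10, seed = 3)
  db <- build_db(fc$molecules, radii = 1)
  p1 <- generation_params(radius = 1, max_size = 8, max_replacements = 10, seed = 99L)
  a <- mutate("Cc1ccccc1", db, p1)
  b <- mutate("Cc1ccccc1", db, p1)
  expect_identical(a, b)
  full <- mutate("Cc1ccccc1", db, generation_params(radius = 1, max_size = 8))
  expect_true(all(a %in% full))
  expect_lte(length(a), 10L)
  expect_gt(length(full), length(a))
})

test_that("all generated structures are valid by construction", {
  fc <- synth_corpus("pains_free", 10, seed = 21)
  db <- build_db(fc$molecules, radii = 1:2)
  outs <- c(mutate("Cc1ccccc1", db, generation_params(radius = 1, max_size = 8)),
            grow("c1ccccc1", db, generation_params(radius = 2, min_inc = 0, max_inc = 6)),
            link("C", "CO", db, generation_params(radius = 1, min_inc = 0, max_inc = 6)))
  for (s in outs) {
    expect_silent(parse_smiles(s))
    expect_identical(canonical_smiles(s), s)
  }
})

test_that("radius nesting: higher-radius outputs are subsets", {
  fc <- synth_corpus("homologs", 4)
  db <- build_db(fc$molecules, radii = 1:3)
  for (parent in fc$molecules[1:2]) {
    outs <- lapply(1:3, function(r) {
      mutate(parent, db, generation_params(radius = r, max_size = 8,
                                           min_inc = -2, max_inc = 2))
    })
    expect_true(all(outs[[2]] %in% outs[[1]]))
    expect_true(all(outs[[3]] %in% outs[[2]]))
  }
})

test_that("unbuilt radius raises a parameter error", {
  db <- toluene_ethylbenzene_db()
  expect_error(mutate("Cc1ccccc1", db, generation_params(radius = 2)),
               class = "mg_param_error")
})
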