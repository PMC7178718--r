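# Fragmentation: cut-set enumeration, record construction, context
# truncation, pair canonicalization.

test_that("enumerate_cut_sets handles ring-only, single-bond and chain cases", {
  expect_length(enumerate_cut_sets("c1ccccc1"), 0L)      # all bonds in-ring
  expect_length(enumerate_cut_sets("Cc1ccccc1"), 1L)     # unique acyclic bond
  # n-butane: 3 acyclic bonds -> 3 singles + 3 pairs + 1 triple
  expect_length(enumerate_cut_sets("CCCC", max_cuts = 4L), 7L)
  expect_length(enumerate_cut_sets("CCCC", max_cuts = 1L), 3L)
  expect_error(enumerate_cut_sets("CCCC", max_cuts = 0L), class = "mg_param_error")
})

test_that("distance pruning of cut sets only drops oversized cores", {
  long <- paste0(strrep("C", 12), "c1ccccc1")
  full <- enumerate_cut_sets(long)
  pruned <- enumerate_cut_sets(long, max_core_size = 3L)
  expect_lt(length(pruned), length(full))
  # every surviving multi-cut set is a subset of the full enumeration
  keys <- vapply(full, paste, "", collapse = ",")
  expect_true(all(vapply(pruned, paste, "", collapse = ",") %in% keys))
  # pruned-away sets would only have produced cores above the bound
  dropped <- full[!(keys %in% vapply(pruned, paste, "", collapse = ","))]
  for (cs in dropped[seq_len(min(20, length(dropped)))]) {
    for (rec in fragment_on_cut_set(long, cs)) {
      expect_gt(molgraft:::mg_n_heavy(rec$core), 3L)
    }
  }
})

test_that("fragment_on_cut_set emits cores per the incidence rule", {
  # 1 cut: both sides qualify
  recs <- fragment_on_cut_set("Cc1ccccc1", enumerate_cut_sets("Cc1ccccc1")[[1]])
  expect_length(recs, 2L)
  cores <- vapply(recs, function(r) canonical_smiles(r$core), "")
  expect_setequal(cores, c("[*:1]C", "[*:1]c1ccccc1"))
  # 2 cuts on butane: only the middle CH2 touches both
  recs2 <- fragment_on_cut_set("CCCC", c(1L, 2L))
  expect_length(recs2, 1L)
  expect_identical(canonical_smiles(recs2[[1]]$core), "[*:1]C[*:2]")
  expect_identical(canonical_smiles(recs2[[1]]$context_full), "[*:1]C.[*:2]CC")
  # 3 cuts on butane: no component touches all three
  expect_length(fragment_on_cut_set("CCCC", c(1L, 2L, 3L)), 0L)
  # illegal cut
  expect_error(fragment_on_cut_set("c1ccccc1", 1L), class = "mg_contract_error")
})

test_that("round-trip: splicing a record's own core reproduces the source", {
  for (s in c("Cc1ccccc1", "CCc1ccc(O)cc1", "CC(C)COC", "NCCCC(=O)O")) {
    ref <- canonical_smiles(s)
    for (rec in fragment_molecule(s)) {
      expect_identical(splice(rec, rec$core), ref)
    }
  }
})

test_that("hydrogen cuts deduplicate symmetry-equivalent positions", {
  expect_length(hydrogen_cuts("c1ccccc1"), 1L)
  expect_length(hydrogen_cuts("C"), 1L)
  expect_length(hydrogen_cuts("Cc1ccccc1"), 4L)  # methyl, ortho, meta, para
  expect_length(hydrogen_cuts("FC(F)(F)F"), 0L)  # no hydrogens at all
  h <- hydrogen_cuts("C")[[1]]
  expect_identical(canonical_smiles(h$core), canonical_smiles("[H][*:1]"))
  expect_identical(molgraft:::mg_n_heavy(h$core), 0L)
})

test_that("truncate_context keeps exactly the radius-r ball and fills H", {
  rec <- fragment_on_cut_set("Cc1ccccc1", 1L)
  methyl <- rec[[which(vapply(rec, function(r) canonical_smiles(r$core), "") == "[*:1]C")]]
  t1 <- truncate_context(methyl$context_full, 1)
  expect_identical(molgraft:::mg_n_heavy(t1), 1L)           # single aromatic carbon
  expect_true(t1$arom[t1$elem == "C"])
  hb <- hydrogen_cuts("c1ccccc1")[[1]]
  t2 <- truncate_context(hb$context_full, 2)
  expect_identical(molgraft:::mg_n_heavy(t2), 3L)           # 3-atom aromatic path
  # identity at large radius
  big <- truncate_context(methyl$context_full, 50)
  expect_identical(canonical_smiles(big), canonical_smiles(methyl$context_full))
  expect_error(truncate_context(methyl$context_full, 0), class = "mg_param_error")
})

test_that("truncation is nested in the radius", {
  for (s in c("CCc1ccc(O)cc1", "CCCCOC(=O)c1ccccc1")) {
    for (rec in fragment_molecule(s)[c(1, 3, 5)]) {
      sizes <- vapply(1:6, function(r) {
        molgraft:::mg_n_heavy(truncate_context(rec$context_full, r))
      }, 0L)
      expect_false(is.unsorted(sizes))
    }
  }
})

test_that("canonicalize_pair renumbers and enumerates symmetry permutations", {
  # k = 1: nothing to permute
  rec <- fragment_on_cut_set("Cc1ccccc1", 1L)[[1]]
  cp <- canonicalize_pair(truncate_context(rec$context_full, 1), rec$core)
  expect_length(cp$cores, 1L)
  # three attachment points, two with identical radius-1 context -> exactly
  # 2 stored core variants (the equivalent labels swap)
  ctx <- parse_smiles("C[*:1].C[*:2].O[*:3]", sanitize = FALSE)
  core <- parse_smiles("[*:1]CC([*:3])C(O)[*:2]", sanitize = FALSE)
  cp3 <- canonicalize_pair(ctx, core)
  expect_length(cp3$cores, 2L)
  # k = 2 with non-equivalent environments -> 1 variant
  cp2 <- canonicalize_pair(parse_smiles("C[*:1].O[*:2]", sanitize = FALSE),
                           parse_smiles("[*:1]CC[*:2]", sanitize = FALSE))
  expect_length(cp2$cores, 1L)
  # map-number mismatch
  expect_error(canonicalize_pair(parse_smiles("C[*:1]", sanitize = FALSE),
                                 parse_smiles("[*:2]C", sanitize = FALSE)),
               class = "mg_contract_error")
})

test_that("canonicalize_pair is idempotent and label/order invariant", {
  set.seed(31)
  ctx <- parse_smiles("C[*:1].C[*:2].O[*:3]", sanitize = FALSE)
  core <- parse_smiles("[*:1]CC([*:3])C(O)[*:2]", sanitize = FALSE)
  ref <- canonicalize_pair(ctx, core)
  relabelings <- list(c(2L, 3L, 1L), c(3L, 1L, 2L), c(2L, 1L, 3L))
  for (perm in relabelings) {
    ctx2 <- ctx; core2 <- core
    ctx2$map[ctx2$map > 0] <- perm[ctx2$map[ctx2$map > 0]]
    core2$map[core2$map > 0] <- perm[core2$map[core2$map > 0]]
    # also scramble atom order through a random rendering
    ctx2 <- parse_smiles(as.character(
      molgraft:::mg_write_smiles(ctx2, sample(molgraft:::mg_natoms(ctx2)))),
      sanitize = FALSE)
    got <- canonicalize_pair(ctx2, core2)
    expect_identical(got$context, ref$context)
    expect_identical(sort(got$cores), sort(ref$cores))
  }
  # permutation count bounded by k!
  expect_lte(length(ref$cores), factorial(3))
})

test_that("no emitted record ever comes from cutting a ring or multiple bond", {
  for (s in c("c1ccc2ccccc2c1", "CC(=O)Nc1ccccc1", "C=CCO")) {
    mol <- molgraft:::as_mg_mol(s)
    ringb <- molgraft:::mg_ring_bonds(mol)
    for (cs in enumerate_cut_sets(mol)) {
      expect_true(all(mol$border[cs] == 1))
      expect_false(any(ringb[cs]))
    }
  }
})
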