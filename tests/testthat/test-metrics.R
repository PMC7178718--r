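# Metrics: fingerprints, novelty/diversity, descriptors, scaffolds, PAINS,
# complexity scoring.

test_that("novelty matches an independent bit-arithmetic computation", {
  expect_identical(novelty("c1ccccc1", "c1ccccc1"), 0)
  # two copies of one molecule: mean of equal terms
  m <- "CCO"
  t1 <- novelty("c1ccccc1", c(m, m))
  expect_equal(t1, novelty("c1ccccc1", m))
  # independent route: tabulate-based intersection/union on the bit vectors
  fp_a <- morgan_fp("c1ccccc1")
  fp_b <- morgan_fp("CCCCCC")
  tab <- tabulate(c(fp_a, fp_b) + 1L, nbins = 2048L)
  t_ind <- sum(tab == 2L) / sum(tab >= 1L)
  expect_equal(novelty("c1ccccc1", "CCCCCC"), 1 - t_ind)
  expect_error(novelty("c1ccccc1", character(0)), class = "mg_undefined_error")
})

test_that("diversity agrees with the exhaustive all-pairs oracle", {
  expect_identical(diversity(c("CCO", "CCO"))$mean, 0)
  set.seed(4)
  mols <- c("c1ccccc1", "CCO", "CCCCCC", "Cc1ccccc1", "CCN", "c1ccncc1",
            "CC(C)O", "CCOC", "CC(=O)O", "ClCCCl")
  d <- diversity(mols)
  fps <- lapply(mols, morgan_fp)
  acc <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    acc <- c(acc, 1 - tanimoto(fps[[i]], fps[[j]]))
  }
  expect_equal(d$mean, mean(acc))
  expect_true(d$exact)
  # subsampled equals exhaustive when the set fits in one subsample
  d2 <- diversity(mols, subsample = 100L)
  expect_identical(d2$mean, d$mean)
  # subsampling path is seeded and in range
  d3 <- diversity(mols, subsample = 5L, repeats = 3L, seed = 1L)
  expect_false(d3$exact)
  expect_identical(d3$mean, diversity(mols, subsample = 5L, repeats = 3L, seed = 1L)$mean)
  expect_true(d3$mean >= 0 && d3$mean <= 1)
  expect_error(diversity("CCO"), class = "mg_undefined_error")
})

test_that("corpus_novelty is a set-membership percentage", {
  corpus <- c("CCO", "CCC")
  expect_identical(corpus_novelty(c("CCO", "CCC"), corpus), 0)
  expect_identical(corpus_novelty(c("CCN", "CCF"), corpus), 100)
  expect_identical(corpus_novelty(c("CCO", "CCN", "CCF", "CCCl"), corpus), 75)
  expect_error(corpus_novelty(character(0), corpus), class = "mg_undefined_error")
})

test_that("property panel values follow their definitions", {
  b <- property_panel("c1ccccc1")
  expect_identical(b$HBD, 0L); expect_identical(b$HBA, 0L)
  expect_identical(b$NumRings, 1L); expect_identical(b$RTB, 0L)
  expect_identical(b$Csp3, 0); expect_identical(b$fmf, 1)
  expect_equal(b$MW, 78.11, tolerance = 1e-3)
  h <- property_panel("CCCCCC")
  expect_identical(h$NumRings, 0L)
  expect_identical(h$fmf, 0)
  expect_identical(h$Csp3, 1)
  expect_identical(h$RTB, 3L)
  # donors/acceptors and TPSA on a mixed molecule (Ertl contributions:
  # primary amine 26.02 + hydroxyl 20.23)
  p <- property_panel("NCCO")
  expect_identical(p$HBD, 2L); expect_identical(p$HBA, 2L)
  expect_equal(p$TPSA, 46.25, tolerance = 0.01)
})

test_that("Murcko scaffolds strip side chains and are idempotent", {
  expect_identical(murcko_scaffold("Cc1ccccc1"), "c1ccccc1")
  expect_identical(murcko_scaffold("CCCCCC"), "")
  expect_identical(murcko_scaffold("CCc1ccc(CC(=O)O)cc1"), "c1ccccc1")
  biphenyl_linked <- "c1ccc(CCc2ccccc2)cc1"
  s <- murcko_scaffold(biphenyl_linked)
  expect_identical(s, canonical_smiles(biphenyl_linked))  # linker retained
  expect_identical(murcko_scaffold(s), s)
})

test_that("scaffold_novelty accumulates monotonically", {
  corpus <- c("Cc1ccccc1", "CCc1ccncc1")
  gens <- list(c("CCc1ccccc1", "Cc1ccncc1"),        # both scaffolds known
               c("Cc1ccsc1", "CCCCC"),              # one new (thiophene), one acyclic
               c("Cc1ccoc1"))                        # another new
  sn <- scaffold_novelty(gens, corpus)
  expect_identical(sn$pct_novel, c(0, 100, 100))
  expect_identical(sn$n_cumulative, c(2L, 3L, 4L))
  expect_false(is.unsorted(sn$n_cumulative))
  expect_identical(sn$pct_novel_cumulative[1], 0)
  all_known <- scaffold_novelty(list(c("CCc1ccccc1")), corpus)
  expect_identical(all_known$pct_novel, 0)
})

test_that("PAINS screening matches the published example family", {
  catalog <- load_smarts_catalog(system.file("extdata", "pains-subset.tsv",
                                             package = "molgraft"))
  expect_length(pains_matches("c1ccccc1", catalog), 0L)
  # para-methoxy N,N-dialkyl aniline: the motif reported to survive at
  # context radius 5
  expect_true("anil_di_alk_para_methoxy" %in%
                pains_matches("COc1ccc(N(C)C)cc1", catalog))
  # the same molecule without the para-methoxy does not match that alert
  expect_false("anil_di_alk_para_methoxy" %in%
                 pains_matches("Cc1ccc(N(C)C)cc1", catalog))
  empty <- catalog[0, , drop = FALSE]
  expect_length(pains_matches("COc1ccc(N(C)C)cc1", empty), 0L)
  bad <- tempfile(); writeLines("broken\t[Qq", bad)
  expect_error(load_smarts_catalog(bad), class = "mg_config_error")
})

test_that("complexity scoring is pluggable and respects the SAScore range", {
  for (s in c("CC", "c1ccccc1", "CC(=O)Nc1ccc(S(N)(=O)=O)cc1",
              "CC1(C)C2CCC1(C)C(=O)C2")) {
    v <- complexity_score(s, "sascore")
    expect_true(v >= 1 && v <= 10)
  }
  # simple molecules score lower than a decorated polycycle
  expect_lt(complexity_score("CC"), complexity_score("CC1(C)C2CCC1(C)C(=O)C2Cc1ccc2ccccc2c1"))
  register_scorer("const7", function(s) 7)
  expect_identical(complexity_score("CCO", "const7"), 7)
  expect_identical(complexity_score("CCO", function(s) 0.25), 0.25)
  expect_error(complexity_score("CCO", "no_such_scorer"), class = "mg_config_error")
})
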