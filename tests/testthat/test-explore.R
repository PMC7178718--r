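# Search workflows: MW-binned stochastic exploration and the goal-directed
# optimizer.

test_that("mw_bin_select partitions by weight and is seeded", {
  mols <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC",
            "CCCCCCCC", "CCCCCCCCC", "CCCCCCCCCC")
  sel <- mw_bin_select(mols, 5, seed = 1)
  expect_length(sel, 5L)
  # one molecule from each MW quintile (here: sorted pairs)
  mw <- vapply(sel, mol_weight, 0)
  expect_false(is.unsorted(mw))
  for (k in 1:5) {
    expect_true(sel[k] %in% mols[(2 * k - 1):(2 * k)])
  }
  expect_identical(sel, mw_bin_select(mols, 5, seed = 1))
  # fewer molecules than bins: all returned
  expect_setequal(mw_bin_select(c("C", "CC"), 5, seed = 1), c("C", "CC"))
  expect_length(mw_bin_select(character(0), 5, seed = 1), 0L)
})

test_that("stochastic exploration records survivors and respects the MW cap", {
  fc <- synth_corpus("decorated_aromatics", 10, seed = 3)
  db <- build_db(fc$molecules, radii = 1)
  params <- exploration_params(radius = 1, iterations = 4,
                               max_replacements = 150, mw_cap = 250, seed = 7)
  res <- stochastic_explore("c1ccccc1", db, params)
  expect_lte(length(res$iterations), 4L)
  expect_gt(length(res$iterations), 0L)
  for (it in seq_along(res$iterations)) {
    mw <- vapply(res$iterations[[it]], mol_weight, 0)
    expect_true(all(mw <= 250))
    expect_lte(length(res$selections[[it + 1]]), params$n_bins)
  }
  # reproducibility
  res2 <- stochastic_explore("c1ccccc1", db, params)
  expect_identical(res$iterations, res2$iterations)
})

test_that("an empty database terminates exploration at iteration one", {
  db <- build_db("C", radii = 1)   # nothing interchangeable for benzene
  expect_message(
    res <- stochastic_explore("c1ccccc1", db,
                              exploration_params(radius = 1, iterations = 5, seed = 1)),
    "no products")
  expect_length(res$iterations, 0L)
  expect_identical(res$selections[[1]], "c1ccccc1")
})

test_that("patience escalations fire after 3, 10 and 33 stalled iterations", {
  db <- build_db("C", radii = 1)   # empty pools keep the score flat
  res <- goal_directed_optimize("c1ccccc1", db, function(s) 0.5,
                                optimizer_params(radius = 1, max_iter = 40,
                                                 replacements = 10,
                                                 reseed = FALSE, seed = 1))
  ev <- sub("^[0-9]+:", "", res$events)
  it <- as.integer(sub(":.*$", "", res$events))
  expect_identical(ev[1:3], c("patience1", "patience2", "reseed"))
  # stall counts between events: 3, then 10, then 33 non-improving iterations
  expect_identical(diff(it[1:3]), c(7L, 23L))
  expect_false(is.unsorted(res$trace))
})

test_that("optimizer reaches a target verified reachable in two steps", {
  fc <- synth_corpus("homologs", 4)
  db <- build_db(fc$molecules, radii = 1)
  target <- canonical_smiles("CCCc1ccccc1")
  # exhaustive two-step reachability from toluene
  p <- generation_params(radius = 1, max_size = 8, min_inc = -2, max_inc = 2)
  step1 <- mutate("Cc1ccccc1", db, p)
  step2 <- unique(c(step1, unlist(lapply(step1, mutate, db = db, params = p))))
  expect_true(target %in% step2)
  fp_t <- morgan_fp(target)
  score <- function(s) tanimoto(morgan_fp(s), fp_t)
  res <- goal_directed_optimize("Cc1ccccc1", db, score,
                                optimizer_params(radius = 1, max_iter = 8,
                                                 replacements = 200,
                                                 reseed = FALSE, seed = 1))
  expect_identical(res$best_score, 1)
  expect_true(target %in% res$best)
  expect_false(is.unsorted(res$trace))
})

test_that("scores outside [0,1] violate the contract", {
  db <- build_db(h4_corpus(), radii = 1)
  expect_error(
    goal_directed_optimize("Cc1ccccc1", db, function(s) 2,
                           optimizer_params(radius = 1, max_iter = 2, seed = 1)),
    class = "mg_score_error")
})

test_that("parameter bundles validate their invariants", {
  expect_error(optimizer_params(low = 0.9, high = 0.8), class = "mg_param_error")
  expect_error(optimizer_params(patience = c(3, 3, 33)), class = "mg_param_error")
  expect_error(exploration_params(n_bins = 0), class = "mg_param_error")
  expect_error(exploration_params(mw_cap = -5), class = "mg_param_error")
  expect_error(generation_params(min_size = 5, max_size = 2), class = "mg_param_error")
  expect_error(generation_params(min_inc = 2, max_inc = -2), class = "mg_param_error")
  expect_error(generation_params(max_rel_size = 1.5), class = "mg_param_error")
  expect_identical(optimizer_params(pop_size = 3)$pop_size, 10L)
})
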