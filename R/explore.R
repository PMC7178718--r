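# Search workflows: stochastic chemical-space exploration and greedy
# goal-directed optimization with adaptive step sizes and three patience
# levels.

#' Parameters for stochastic exploration
#'
#' Defaults reproduce the published setup: replaced fragments of 0-8 heavy
#' atoms, relative size at most 0.3, replacing fragments within one heavy
#' atom of the replaced one, at most 25000 randomly chosen replacements,
#' 500 Da weight cap, 5 molecular-weight bins, 100 iterations.
#'
#' @param radius context radius
#' @param iterations iteration cap
#' @param min_size,max_size replaced-core heavy-atom bounds
#' @param max_rel_size relative-size cap
#' @param min_inc,max_inc replacing-core size-delta bounds
#' @param max_replacements cap on sampled replacements per mutate call
#' @param min_freq minimum core occurrence
#' @param mw_cap molecular-weight cap in g/mol
#' @param n_bins number of MW bins for selection
#' @param seed RNG seed
#' @return an `exploration_params` list
#' @export
exploration_params <- function(radius = 3L, iterations = 100L, min_size = 0L,
                               max_size = 8L, max_rel_size = 0.3,
                               min_inc = -1L, max_inc = 1L,
                               max_replacements = 25000L, min_freq = 0L,
                               mw_cap = 500, n_bins = 5L, seed = 42L) {
  if (n_bins < 1L) stop_mg("mg_param_error", "n_bins must be >= 1")
  if (mw_cap <= 0) stop_mg("mg_param_error", "mw_cap must be positive")
  structure(as.list(environment()), class = "exploration_params")
}

#' Select one molecule per molecular-weight bin
#'
#' Molecules are sorted by weight and partitioned into `n_bins` contiguous
#' near-equal-count bins; one molecule is drawn from each non-empty bin.
#'
#' @param mols character vector of SMILES
#' @param n_bins number of bins
#' @param seed RNG seed
#' @return character vector of at most `n_bins` SMILES
#' @export
mw_bin_select <- function(mols, n_bins = 5L, seed = NULL) {
  mols <- unique(mols)
  if (!length(mols)) return(character(0L))
  mw <- vapply(mols, mol_weight, 0, USE.NAMES = FALSE)
  mols <- mols[order(mw)]
  bin <- ceiling(seq_along(mols) * n_bins / length(mols))
  with_seed(seed, {
    vapply(split(mols, bin), function(b) if (length(b) == 1L) b else sample(b, 1L), "",
           USE.NAMES = FALSE)
  })
}

#' Iterative stochastic exploration of chemical space
#'
#' Each iteration mutates the current selection, discards products above the
#' weight cap, records the survivors, and carries one molecule per MW bin to
#' the next iteration. Stops at the iteration cap or when an iteration
#' produces nothing.
#'
#' @param seed_mol starting molecule (e.g. benzene)
#' @param db fragment database
#' @param params an [exploration_params()] bundle
#' @return list with `iterations` (list of per-iteration product sets) and
#'   `selections` (molecules carried forward)
#' @export
stochastic_explore <- function(seed_mol, db, params = exploration_params()) {
  selection <- canonical_smiles(as_mg_mol(seed_mol))
  iterations <- list()
  selections <- list(selection)
  for (it in seq_len(params$iterations)) {
    it_seed <- (params$seed + it * 10007L) %% 2147483562L
    products <- character(0L)
    for (j in seq_along(selection)) {
      gp <- generation_params(
        radius = params$radius, min_size = params$min_size,
        max_size = params$max_size, max_rel_size = params$max_rel_size,
        min_inc = params$min_inc, max_inc = params$max_inc,
        min_freq = params$min_freq,
        max_replacements = params$max_replacements,
        seed = (it_seed + j) %% 2147483562L)
      products <- union(products, mutate(selection[j], db, gp))
    }
    if (length(products)) {
      mw <- vapply(products, mol_weight, 0, USE.NAMES = FALSE)
      products <- products[mw <= params$mw_cap]
    }
    if (!length(products)) {
      message(sprintf("exploration stopped at iteration %d: no products", it))
      break
    }
    iterations[[it]] <- sort(products, method = "radix")
    selection <- mw_bin_select(products, params$n_bins, seed = it_seed)
    selections[[it + 1L]] <- selection
  }
  list(iterations = iterations, selections = selections)
}

#' Parameters for goal-directed optimization
#'
#' Score bands set the replacing-fragment size window: far from the goal
#' (score <= `low`) steps of up to +/-10 heavy atoms, close to it
#' (score > `high`) +/-4, with the window interpolated over 9..5 in
#' between. Three patience levels escalate exploration after 3, 10 and 33
#' consecutive non-improving iterations (window +1 / replacements +100,
#' window +10 / replacements +500, reseed keeping the best).
#'
#' @param radius context radius
#' @param low,high score thresholds of the adaptive bands
#' @param min_size,max_size replaced-core bounds
#' @param replacements per-compound cap on randomly chosen mutations
#' @param patience the three escalation thresholds
#' @param pop_size population carried between iterations (at least 10)
#' @param max_iter iteration cap
#' @param min_freq minimum core occurrence
#' @param reseed allow random reseeding at the third patience level (disable
#'   when the seed structure is fixed by the task)
#' @param seed RNG seed
#' @return an `optimizer_params` list
#' @export
optimizer_params <- function(radius = 3L, low = 0.3, high = 0.8,
                             min_size = 0L, max_size = 10L,
                             replacements = 1000L,
                             patience = c(3L, 10L, 33L), pop_size = 10L,
                             max_iter = 100L, min_freq = 0L, reseed = TRUE,
                             seed = 42L) {
  if (low >= high) stop_mg("mg_param_error", "low must be < high")
  if (is.unsorted(patience, strictly = TRUE)) {
    stop_mg("mg_param_error", "patience thresholds must be strictly increasing")
  }
  pop_size <- as.integer(max(pop_size, 10L))
  structure(as.list(environment()), class = "optimizer_params")
}

size_window <- function(score, params) {
  if (score <= params$low) 10L
  else if (score > params$high) 4L
  else as.integer(round(9 - (score - params$low) / (params$high - params$low) * 4))
}

#' Greedy goal-directed optimization with adaptive steps
#'
#' @param seeds character vector of seed SMILES (also the reseeding pool)
#' @param db fragment database
#' @param score_fn pure function: canonical SMILES -> score in `[0, 1]`,
#'   higher is better
#' @param params an [optimizer_params()] bundle
#' @return list with `best` (top-scored molecules found), `best_score`,
#'   `trace` (best score per iteration, non-decreasing) and `events`
#'   (patience escalations / reseeds, as "iteration:event" strings)
#' @export
goal_directed_optimize <- function(seeds, db, score_fn,
                                   params = optimizer_params()) {
  seeds <- unique(vapply(seeds, function(s) canonical_smiles(as_mg_mol(s)), ""))
  score_cache <- new.env(parent = emptyenv(), size = 4096L)
  score_of <- function(s) {
    v <- get0(s, score_cache)
    if (is.null(v)) {
      v <- score_fn(s)
      if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
        stop_mg("mg_score_error", "score_fn returned %s for %s (must be in [0,1])",
                format(v), s)
      }
      assign(s, v, score_cache)
    }
    v
  }
  population <- utils::head(seeds, params$pop_size)
  visited <- new.env(parent = emptyenv(), size = 4096L)
  best_score <- -Inf
  best <- character(0L)
  trace <- numeric(0L)
  events <- character(0L)
  stall <- 0L
  window_bonus <- 0L
  repl_bonus <- 0L
  prev_knobs <- NULL
  for (it in seq_len(params$max_iter)) {
    scores <- vapply(population, score_of, 0)
    cur <- max(scores)
    improved <- cur > best_score + 1e-12
    if (improved) {
      best_score <- cur
      best <- population[scores >= best_score - 1e-12]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- c(trace, best_score)
    if (best_score >= 1 - 1e-12) break
    if (stall == params$patience[1L]) {
      window_bonus <- window_bonus + 1L
      repl_bonus <- repl_bonus + 100L
      events <- c(events, sprintf("%d:patience1", it))
    } else if (stall == params$patience[2L]) {
      window_bonus <- window_bonus + 10L
      repl_bonus <- repl_bonus + 500L
      events <- c(events, sprintf("%d:patience2", it))
    } else if (stall == params$patience[3L]) {
      events <- c(events, sprintf("%d:reseed", it))
      if (params$reseed && length(seeds)) {
        population <- with_seed((params$seed + it) %% 2147483562L,
                                sample(seeds, min(params$pop_size, length(seeds))))
      }
      visited <- new.env(parent = emptyenv(), size = 4096L)
      stall <- 0L
      window_bonus <- 0L
      repl_bonus <- 0L
      next
    }
    w <- size_window(best_score, params) + window_bonus
    repl <- params$replacements + repl_bonus
    knobs <- c(w, repl)
    if (!is.null(prev_knobs) && !identical(knobs, prev_knobs)) {
      # visited list is cleared after any change of generator parameters
      visited <- new.env(parent = emptyenv(), size = 4096L)
    }
    prev_knobs <- knobs
    pool <- character(0L)
    for (j in seq_along(population)) {
      s <- population[j]
      if (!is.null(get0(s, visited))) next
      gp <- generation_params(
        radius = params$radius, min_size = params$min_size,
        max_size = params$max_size, min_inc = -w, max_inc = w,
        min_freq = params$min_freq, max_replacements = repl,
        seed = (params$seed + it * 131L + j) %% 2147483562L)
      pool <- union(pool, mutate(s, db, gp))
      assign(s, TRUE, visited)
    }
    pool <- pool[vapply(pool, function(s) is.null(get0(s, visited)), TRUE)]
    if (!length(pool)) next
    pool_scores <- vapply(pool, score_of, 0)
    keep <- order(-pool_scores, pool, method = "radix")[seq_len(min(params$pop_size, length(pool)))]
    population <- pool[keep]
  }
  list(best = sort(best, method = "radix"), best_score = best_score, trace = trace, events = events)
}
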