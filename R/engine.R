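# Generational loop: evaluate -> rank + niche -> select -> cross ->
# mutate, with elitism and budget/stall stop criteria.

#' Run configuration
#'
#' @param population_size Population size (at least 4).
#' @param max_generations Generation budget.
#' @param stall_generations Stop after this many generations without the
#'   best-so-far overall score improving by more than `stall_tol`.
#' @param crossover_prob Probability a selected pair is recombined.
#' @param mutation_rates See [mutation_rates()]; `NULL` uses per-p
#'   defaults.
#' @param base_seed Seed for the whole run (population initialization,
#'   operators, and CV plans via `base_seed + generation`).
#' @param weights Objective weights for the weighted overall score.
#' @param bounds Hyperparameter gene bounds.
#' @param k_folds CV folds per generation.
#' @param k_max Prescreen list length / fs_k upper bound.
#' @param sigma_share Fitness-sharing kernel support.
#' @param s_max Split-complexity budget.
#' @param stall_tol Minimum improvement counted as progress.
#' @return An `eb_config` list.
#' @export
evoboost_config <- function(population_size = 50L, max_generations = 100L,
                            stall_generations = 20L, crossover_prob = 0.9,
                            mutation_rates = NULL, base_seed = 1L,
                            weights = NULL, bounds = hyperparam_bounds(),
                            k_folds = 10L, k_max = 50L, sigma_share = 0.2,
                            s_max = 256, stall_tol = 1e-6) {
  stopifnot(population_size >= 4L, crossover_prob >= 0, crossover_prob <= 1)
  structure(
    list(population_size = as.integer(population_size),
         max_generations = as.integer(max_generations),
         stall_generations = as.integer(stall_generations),
         crossover_prob = crossover_prob, mutation_rates = mutation_rates,
         base_seed = as.integer(base_seed), weights = weights,
         bounds = bounds, k_folds = as.integer(k_folds),
         k_max = as.integer(k_max), sigma_share = sigma_share,
         s_max = s_max, stall_tol = stall_tol),
    class = "eb_config"
  )
}

# Tournament comparison: lower front, then higher niched score, then
# lower chromosome key for full determinism.
tournament_winner <- function(i, j, ranking, keys) {
  if (ranking$front_index[i] != ranking$front_index[j])
    return(if (ranking$front_index[i] < ranking$front_index[j]) i else j)
  if (ranking$niched_score[i] != ranking$niched_score[j])
    return(if (ranking$niched_score[i] > ranking$niched_score[j]) i else j)
  if (keys[i] <= keys[j]) i else j
}

#' Binary-tournament parent selection
#'
#' Two random candidates are compared by (lower front index, then higher
#' niched score, then lower chromosome key); the winner becomes a
#' parent.
#'
#' @param ranking An `eb_ranking` of the current population.
#' @param keys Chromosome keys of the population (deterministic final
#'   tie-break).
#' @param n_pairs Number of parent pairs to draw.
#' @return Integer matrix `n_pairs` x 2 of population indices.
#' @export
select_parents <- function(ranking, keys, n_pairs) {
  n <- length(ranking$front_index)
  stopifnot(n >= 2L)
  pick <- function() {
    cand <- sample.int(n, 2L, replace = TRUE)
    tournament_winner(cand[1L], cand[2L], ranking, keys)
  }
  matrix(vapply(seq_len(2L * n_pairs), function(i) pick(), 0L),
         ncol = 2L, byrow = TRUE)
}

evaluate_population <- function(chroms, dataset, index, plan, config) {
  cache <- new.env(parent = emptyenv())
  lapply(chroms, function(ch) {
    key <- chromosome_key(ch)
    if (!is.null(cache[[key]])) return(cache[[key]])
    sol <- evaluate_solution(ch, dataset, index, plan,
                             weights = config$weights,
                             bounds = config$bounds, s_max = config$s_max)
    cache[[key]] <- sol
    sol
  })
}

rank_population <- function(population, config) {
  pareto_rank(population, sigma_share = config$sigma_share,
              bounds = config$bounds, k_max = config$k_max)
}

append_eval_log <- function(path, generation, population) {
  if (is.null(path)) return(invisible())
  lines <- vapply(population, function(s) {
    as.character(jsonlite::toJSON(
      list(generation = generation, chromosome = s$key,
           objectives = as.list(s$objectives), overall = s$overall,
           n_active = s$n_active, best_iterations = s$best_iterations),
      auto_unbox = TRUE, digits = NA))
  }, "")
  cat(lines, file = path, sep = "\n", append = TRUE)
}

history_row <- function(state) {
  overalls <- vapply(state$population, function(s) s$overall, 0)
  data.frame(
    generation = state$generation,
    best_overall = max(overalls),
    median_overall = stats::median(overalls),
    best_so_far = state$best_so_far,
    front0_size = length(state$ranking$fronts[[1L]]),
    mean_active = mean(vapply(state$population, function(s) s$n_active, 0L))
  )
}

update_best <- function(state) {
  overalls <- vapply(state$population, function(s) s$overall, 0)
  b <- which.max(overalls)
  if (is.null(state$best_so_far) || overalls[b] > state$best_so_far) {
    state$best_so_far <- overalls[b]
    state$best_solution <- state$population[[b]]
  }
  state
}

#' Advance the run by one generation
#'
#' Builds the generation's CV plan (seed `base_seed + generation`),
#' evaluates the population under it, ranks and niches, copies elites
#' (the first front, capped at half the population, kept by highest
#' niched score) into the next population and fills the remainder with
#' mutated crossover offspring.
#'
#' @param state Run state from [evoboost_run()]'s loop.
#' @param config An `eb_config`.
#' @param dataset An `eb_dataset`.
#' @param index An `eb_prescreen`.
#' @return The updated state, generation counter advanced by one.
#' @export
step_generation <- function(state, config, dataset, index) {
  ranking <- state$ranking
  pop <- state$population
  keys <- vapply(pop, function(s) s$key, "")
  size <- config$population_size
  # elites: first front capped at half the population
  f0 <- ranking$fronts[[1L]]
  cap <- max(1L, size %/% 2L)
  elite_order <- f0[order(-ranking$niched_score[f0], keys[f0])]
  elites <- lapply(pop[utils::head(elite_order, cap)],
                   function(s) s$chromosome)
  n_off <- size - length(elites)
  rates <- config$mutation_rates %||% mutation_rates(length(pop[[1L]]$chromosome$mask))
  offspring <- list()
  while (length(offspring) < n_off) {
    pair <- select_parents(ranking, keys, 1L)[1L, ]
    pa <- pop[[pair[1L]]]$chromosome
    pb <- pop[[pair[2L]]]$chromosome
    kids <- if (stats::runif(1L) < config$crossover_prob)
      crossover(pa, pb, config$bounds) else list(pa, pb)
    kids <- lapply(kids, mutate, rates = rates, bounds = config$bounds,
                   k_max = config$k_max)
    offspring <- c(offspring, kids)
  }
  next_chroms <- c(elites, utils::head(offspring, n_off))
  gen <- state$generation + 1L
  plan <- make_cv_plan(dataset$y, config$k_folds, config$base_seed, gen)
  population <- evaluate_population(next_chroms, dataset, index, plan, config)
  state$generation <- gen
  state$population <- population
  state$ranking <- rank_population(population, config)
  state <- update_best(state)
  state$history <- rbind(state$history, history_row(state))
  state
}

#' Run the evolutionary search
#'
#' Seeds the RNG with `config$base_seed`, initializes the population,
#' then iterates [step_generation()] until the generation budget is
#' exhausted or the best-so-far overall score has stalled for
#' `stall_generations` generations. Because every generation re-scores
#' solutions under a fresh CV plan, per-generation best scores
#' fluctuate; progress (and the stall criterion) is tracked on the
#' best-so-far curve, which elitism keeps non-decreasing.
#'
#' @param dataset A preprocessed `eb_dataset`.
#' @param config An `eb_config`.
#' @param index Optional pre-built `eb_prescreen` (built from the
#'   dataset when `NULL`).
#' @param verbose Print a per-generation progress line.
#' @param log_path Optional JSON-lines file; one record per evaluated
#'   solution and generation (chromosome key, objectives, active-feature
#'   count, per-fold best iterations).
#' @return An `eb_run`: final `population`, `ranking`, `history` data
#'   frame, best-so-far `best_solution`, the final first front
#'   (`front0`), `config` and the prescreen `index`.
#' @export
evoboost_run <- function(dataset, config = evoboost_config(), index = NULL,
                         verbose = FALSE, log_path = NULL) {
  stopifnot(inherits(dataset, "eb_dataset"))
  set.seed(config$base_seed)
  index <- index %||% build_prescreen_index(dataset, config$k_max)
  p <- ncol(dataset$X)
  chroms <- init_population(p, config$population_size, config$bounds,
                            config$k_max)
  plan <- make_cv_plan(dataset$y, config$k_folds, config$base_seed, 0L)
  population <- evaluate_population(chroms, dataset, index, plan, config)
  state <- list(generation = 0L, population = population,
                ranking = rank_population(population, config),
                best_so_far = NULL, best_solution = NULL, history = NULL)
  state <- update_best(state)
  state$history <- history_row(state)
  append_eval_log(log_path, 0L, population)
  stall <- 0L
  best_at_stall_check <- state$best_so_far
  while (state$generation < config$max_generations) {
    state <- step_generation(state, config, dataset, index)
    append_eval_log(log_path, state$generation, state$population)
    if (state$best_so_far > best_at_stall_check + config$stall_tol) {
      stall <- 0L
      best_at_stall_check <- state$best_so_far
    } else {
      stall <- stall + 1L
    }
    if (verbose)
      message(sprintf(
        "gen %3d  best %.4f  best-so-far %.4f  front0 %2d  mean active %.1f",
        state$generation, max(vapply(state$population, function(s) s$overall, 0)),
        state$best_so_far, length(state$ranking$fronts[[1L]]),
        mean(vapply(state$population, function(s) s$n_active, 0L))))
    if (stall >= config$stall_generations) break
  }
  front0 <- state$population[state$ranking$fronts[[1L]]]
  structure(
    list(population = state$population, ranking = state$ranking,
         history = state$history, best_solution = state$best_solution,
         best_so_far = state$best_so_far, front0 = front0,
         config = config, index = index,
         feature_names = dataset$feature_names),
    class = "eb_run"
  )
}

#' Export the final first front as JSON
#'
#' @param run An `eb_run`.
#' @param path JSON file path.
#' @return Invisibly, `path`.
#' @export
write_front <- function(run, path) {
  out <- lapply(run$front0, function(s) {
    list(chromosome = chromosome_to_list(s$chromosome),
         objectives = as.list(s$objectives), overall = s$overall,
         n_active = s$n_active,
         features = run$feature_names[s$active])
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.eb_run <- function(x, ...) {
  cat(sprintf("<eb_run> %d generations, best overall %.4f, front-0 size %d\n",
              max(x$history$generation), x$best_so_far, length(x$front0)))
  invisible(x)
}
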