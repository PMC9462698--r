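# Regularized evolution: a bounded FIFO population of fitted functionals,
# tournament selection of parents, and an mutate -> fit -> evaluate -> insert
# loop in which the oldest individual (not the worst) is evicted once the
# population exceeds its cap.

#' Create an individual
#'
#' @param functional Fitted \code{xc_functional}.
#' @param params Fitted parameter values.
#' @param J_train,J_val Training and validation WRMSD (kcal/mol); an unfit
#'   (invalid) individual carries \code{Inf} and fitness \code{-Inf}.
#' @param insertion_index Monotone counter assigned by the population.
#' @param provenance Parent digest and mutation rule, for history.
#' @return An \code{xc_individual}.
#' @export
new_individual <- function(functional, params, J_train, J_val,
                           insertion_index = NA_integer_,
                           provenance = NULL) {
  structure(list(functional = functional, params = params,
                 J_train = J_train, J_val = J_val,
                 fitness = if (is.finite(J_val)) -J_val else -Inf,
                 insertion_index = insertion_index,
                 provenance = provenance),
            class = "xc_individual")
}

#' Create a bounded FIFO population
#'
#' @param max_size Population cap; once exceeded, the oldest member is
#'   evicted (aging), independent of fitness.
#' @return An \code{xc_population} (environment-backed).
#' @export
new_population <- function(max_size = 100L) {
  env <- new.env(parent = emptyenv())
  env$members <- list()
  env$counter <- 0L
  env$max_size <- as.integer(max_size)
  structure(env, class = "xc_population")
}

population_size <- function(population) length(population$members)

population_members <- function(population) population$members

#' Insert an individual; evict the oldest if over capacity
#'
#' The insert-plus-evict pair is a single atomic operation on the population.
#'
#' @param population An \code{xc_population}.
#' @param individual An \code{xc_individual}.
#' @return The inserted individual (with its insertion index), invisibly.
#' @export
population_insert <- function(population, individual) {
  population$counter <- population$counter + 1L
  individual$insertion_index <- population$counter
  population$members <- c(population$members, list(individual))
  if (length(population$members) > population$max_size) {
    population$members <- population$members[-1L]
  }
  invisible(individual)
}

#' Tournament selection
#'
#' Samples \code{tournament_size} members uniformly without replacement
#' (clamped to the population size) and returns the one with the highest
#' fitness; ties are broken toward the most recently inserted.
#'
#' @param population Nonempty \code{xc_population}.
#' @param tournament_size Number of members drawn.
#' @return The selected \code{xc_individual}.
#' @export
tournament_select <- function(population, tournament_size) {
  n <- population_size(population)
  if (n == 0L) stop("empty population")
  k <- min(tournament_size, n)
  idx <- if (k == n) seq_len(n) else sample.int(n, k)
  members <- population$members[idx]
  fit <- vapply(members, `[[`, numeric(1), "fitness")
  ins <- vapply(members, `[[`, numeric(1), "insertion_index")
  members[[order(-fit, -ins)[1]]]
}

#' Evolution run configuration
#'
#' @param population_size FIFO cap (default 100).
#' @param tournament_size Tournament subset size (default 25; the
#'   proof-of-principle search uses 10).
#' @param budget Number of mutations (evolution steps).
#' @param mutation An \code{\link{mutation_config}}.
#' @param fit An \code{\link{fit_config}}.
#' @param probe An \code{\link{probe_spec}} for the equivalence cache.
#' @param workers Parallel mutate+fit workers per round; insertions remain
#'   sequential and atomic, so population semantics are identical to the
#'   serial mode.  Default 1 (bit-reproducible).
#' @return An \code{xc_evolution_config}.
#' @export
evolution_config <- function(population_size = 100L, tournament_size = 25L,
                             budget = 1000L, mutation = mutation_config(),
                             fit = fit_config(), probe = probe_spec(),
                             workers = 1L) {
  structure(list(population_size = as.integer(population_size),
                 tournament_size = as.integer(tournament_size),
                 budget = as.integer(budget), mutation = mutation,
                 fit = fit, probe = probe, workers = as.integer(workers)),
            class = "xc_evolution_config")
}

# Fit-or-reuse: consult the fingerprint cache, fit on a miss, and return the
# evaluated individual plus bookkeeping.
evaluate_child <- function(functional, compiled, config, cache,
                           provenance = NULL) {
  digest <- fingerprint_functional(functional, config$probe)
  hit <- seen_before(cache, digest)
  if (hit$hit) {
    rec <- hit$record
    ind <- new_individual(functional, rec$params, rec$J_train, rec$J_val,
                          provenance = c(provenance, list(digest = digest,
                                                          cache_hit = TRUE)))
    return(list(individual = ind, digest = digest, cache_hit = TRUE,
                evals = 0L))
  }
  fit <- fit_parameters(functional, compiled, config$fit)
  J_val <- if (fit$valid) {
    evaluate_wrmsd(functional, fit$params, compiled, "validation")
  } else Inf
  cache_store(cache, digest,
              list(params = fit$params, J_train = fit$J_train, J_val = J_val,
                   expression = render_expression(
                     canonicalize(functional$programs$x))))
  ind <- new_individual(functional, fit$params, fit$J_train, J_val,
                        provenance = c(provenance, list(digest = digest,
                                                        cache_hit = FALSE)))
  list(individual = ind, digest = digest, cache_hit = FALSE,
       evals = fit$evals)
}

#' One evolution step
#'
#' Tournament-select a parent, mutate it, fit the child (or reuse a cached
#' fit for an equivalent form), evaluate its validation error, and insert it;
#' when the population exceeds its cap the oldest member is evicted.  Unfit
#' children are inserted with fitness \code{-Inf} so the FIFO aging clock
#' stays faithful.
#'
#' @param population An \code{xc_population}.
#' @param compiled Compiled dataset.
#' @param config An \code{\link{evolution_config}}.
#' @param cache Fitness cache.
#' @return History record for the step (list).
#' @export
evolve_step <- function(population, compiled, config, cache) {
  parent <- tournament_select(population, config$tournament_size)
  child_fun <- mutate_functional(parent$functional, config$mutation)
  prov <- attr(child_fun, "provenance")
  prov$parent <- parent$insertion_index
  res <- evaluate_child(child_fun, compiled, config, cache, provenance = prov)
  ind <- population_insert(population, res$individual)
  list(individual = ind, digest = res$digest, cache_hit = res$cache_hit,
       evals = res$evals)
}

#' Run a regularized evolution
#'
#' Seeds the population with the initial functional(s) (fitted first), then
#' performs \code{budget} mutate-fit-insert steps.  Every evaluated form is
#' recorded in the history; the best-by-validation individual is returned.
#' An optional \code{success_check} is called whenever a new
#' best-by-validation individual appears and stops the run early when it
#' returns \code{TRUE}.
#'
#' @param initial A single \code{xc_functional} or list of them; the empty
#'   functional (no instructions, constant zero) is a legal start.
#' @param dataset Dataset (compiled or not).
#' @param config An \code{\link{evolution_config}}.
#' @param cache Optional pre-warmed fitness cache (for resumed runs).
#' @param population Optional pre-filled population (for resumed runs).
#' @param success_check Optional \code{function(individual) -> logical}.
#' @param history_file Optional path; history records are appended as JSON
#'   lines while the run progresses.
#' @return List with \code{history} (data.frame), \code{best}
#'   (\code{xc_individual}), \code{population}, \code{cache},
#'   \code{n_mutations}, and \code{success} (logical; did
#'   \code{success_check} fire).
#' @export
run_evolution <- function(initial, dataset, config = evolution_config(),
                          cache = NULL, population = NULL,
                          success_check = NULL, history_file = NULL) {
  compiled <- as_compiled(dataset)
  cache <- cache %||% new_fitness_cache()
  if (is.null(population)) {
    population <- new_population(config$population_size)
    inits <- if (inherits(initial, "xc_functional")) list(initial) else initial
    for (fun in inits) {
      res <- evaluate_child(fun, compiled, config, cache,
                            provenance = list(channel = NA, rule = "seed"))
      population_insert(population, res$individual)
    }
  }
  best <- NULL
  for (m in population_members(population)) {
    if (is.null(best) || m$fitness > best$fitness) best <- m
  }
  history <- vector("list", config$budget)
  success <- FALSE
  n_done <- 0L
  steps_left <- config$budget
  workers <- max(1L, config$workers)
  while (steps_left > 0L && !success) {
    batch <- if (workers == 1L) 1L else min(workers, steps_left)
    recs <- if (batch == 1L) {
      list(evolve_step(population, compiled, config, cache))
    } else {
      parallel_round(population, compiled, config, cache, batch)
    }
    for (rec in recs) {
      n_done <- n_done + 1L
      steps_left <- steps_left - 1L
      ind <- rec$individual
      row <- list(step = n_done,
                  expression = render_expression(
                    canonicalize(ind$functional$programs$x)),
                  digest = rec$digest, cache_hit = rec$cache_hit,
                  rule = ind$provenance$rule %||% NA_character_,
                  J_train = ind$J_train, J_val = ind$J_val)
      history[[n_done]] <- row
      if (!is.null(history_file)) {
        cat(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), "\n",
            sep = "", file = history_file, append = TRUE)
      }
      if (ind$fitness > best$fitness) {
        best <- ind
        if (!is.null(success_check) && isTRUE(success_check(ind))) {
          success <- TRUE
          break
        }
      }
    }
  }
  history <- history[seq_len(n_done)]
  hist_df <- if (n_done) {
    data.frame(step = vapply(history, `[[`, numeric(1), "step"),
               expression = vapply(history, `[[`, character(1), "expression"),
               digest = vapply(history, `[[`, character(1), "digest"),
               cache_hit = vapply(history, `[[`, logical(1), "cache_hit"),
               rule = vapply(history, function(h) as.character(h$rule),
                             character(1)),
               J_train = vapply(history, `[[`, numeric(1), "J_train"),
               J_val = vapply(history, `[[`, numeric(1), "J_val"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(step = integer(0), expression = character(0),
               digest = character(0), cache_hit = logical(0),
               rule = character(0), J_train = numeric(0),
               J_val = numeric(0))
  }
  list(history = hist_df, best = best, population = population,
       cache = cache, n_mutations = n_done, success = success)
}

# One asynchronous-style round: `batch` parents are selected and their
# children mutated and fitted in parallel processes; insert+evict is then
# applied sequentially (atomically) per child.  Cache lookups use the state
# at round start; new fits are merged back afterwards.
parallel_round <- function(population, compiled, config, cache, batch) {
  tasks <- lapply(seq_len(batch), function(i) {
    parent <- tournament_select(population, config$tournament_size)
    child <- mutate_functional(parent$functional, config$mutation)
    prov <- attr(child, "provenance")
    prov$parent <- parent$insertion_index
    list(functional = child, provenance = prov,
         seed = sample.int(.Machine$integer.max, 1L))
  })
  results <- parallel::mclapply(tasks, function(task) {
    set.seed(task$seed)
    evaluate_child(task$functional, compiled, config, cache,
                   provenance = task$provenance)
  }, mc.cores = batch)
  for (res in results) {
    if (!res$cache_hit && !seen_before(cache, res$digest)$hit) {
      ind <- res$individual
      cache_store(cache, res$digest,
                  list(params = ind$params, J_train = ind$J_train,
                       J_val = ind$J_val,
                       expression = render_expression(
                         canonicalize(ind$functional$programs$x))))
    }
  }
  lapply(results, function(res) {
    res$individual <- population_insert(population, res$individual)
    res
  })
}

#' Cumulative minimum validation error over a run history
#'
#' The standard convention for plotting evolution progress: the running
#' minimum of \code{J_val} as a function of mutation count (non-increasing
#' by construction).
#'
#' @param history History data.frame from \code{\link{run_evolution}}.
#' @return Numeric vector, one value per step.
#' @export
cumulative_min_jval <- function(history) {
  cummin(ifelse(is.finite(history$J_val), history$J_val, Inf))
}
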