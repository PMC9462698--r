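# Regularized evolution: tournament selection, FIFO aging, step semantics.

make_individual <- function(jval, fun = NULL) {
  new_individual(fun %||% new_functional(), numeric(), jval, jval)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tournament selection returns the fittest of the drawn subset", {
  pop <- new_population(10)
  for (j in c(5, 3, 9)) population_insert(pop, make_individual(j))
  # Full tournament: global argmax fitness (-3).
  best <- tournament_select(pop, 3)
  expect_equal(best$J_val, 3)
  # Tournament of one is a uniform draw; over many draws all members appear.
  set.seed(1)
  seen <- unique(replicate(60, tournament_select(pop, 1)$J_val))
  expect_setequal(seen, c(5, 3, 9))
  # Oversized tournaments clamp to the population.
  expect_equal(tournament_select(pop, 99)$J_val, 3)
  # Ties break toward the most recent insertion.
  population_insert(pop, make_individual(3))
  b <- tournament_select(pop, 10)
  expect_equal(b$insertion_index, 4)
  expect_error(tournament_select(new_population(5), 2), "empty")
})

test_that("the population is a bounded FIFO: oldest evicted, order preserved", {
  pop <- new_population(3)
  for (j in 1:5) population_insert(pop, make_individual(j))
  members <- population_members(pop)
  expect_length(members, 3)
  expect_equal(vapply(members, `[[`, numeric(1), "insertion_index"),
               c(3, 4, 5))
  # Aging invariant: nobody survives more than max_size insertions.
  expect_true(all(pop$counter -
                    vapply(members, `[[`, numeric(1), "insertion_index") <
                    pop$max_size))
})

test_that("unfit individuals are inserted with -Inf fitness, keeping the clock", {
  pop <- new_population(2)
  population_insert(pop, make_individual(1))
  population_insert(pop, make_individual(Inf))  # unfit
  expect_length(population_members(pop), 2)
  expect_identical(population_members(pop)[[2]]$fitness, -Inf)
  population_insert(pop, make_individual(2))
  # The unfit member is NOT evicted early; eviction is strictly by age.
  fits <- vapply(population_members(pop), `[[`, numeric(1), "fitness")
  expect_identical(fits, c(-Inf, -2))
})

test_that("selection pressure: chosen parents beat the population mean", {
  set.seed(10)
  pop <- new_population(100)
  jvals <- runif(100, 0, 10)
  for (j in jvals) population_insert(pop, make_individual(j))
  mean_fit <- mean(-jvals)
  sel <- replicate(1000, tournament_select(pop, 25)$fitness)
  expect_gt(mean(sel), mean_fit)
})

test_that("an evolution step inserts exactly one child and evicts the oldest at cap", {
  fx <- tiny_b97_dataset(seed = 2, n_systems = 8, points = 4,
                         n_datapoints = 24)
  compiled <- compile_dataset(fx$dataset)
  cfg <- evolution_config(
    population_size = 5, tournament_size = 3, budget = 10,
    mutation = demo_mutation_config(),
    fit = fit_config(n_restarts = 1, max_evals_per_dim = 40))
  cache <- new_fitness_cache()
  pop <- new_population(5)
  set.seed(33)
  seed_ind <- make_individual(10, new_functional(
    x = new_program(demo_workspace(), list(), max_instructions = 6)))
  for (i in 1:5) population_insert(pop, seed_ind)
  oldest <- population_members(pop)[[1]]$insertion_index
  rec <- evolve_step(pop, compiled, cfg, cache)
  expect_length(population_members(pop), 5)
  expect_false(any(vapply(population_members(pop), `[[`, numeric(1),
                          "insertion_index") == oldest))
  # Re-submitting an equivalent child costs zero optimizer evaluations.
  hit <- seen_before(cache, rec$digest)
  expect_true(hit$hit)
})

test_that("short runs are reproducible and their cumulative minimum never rises", {
  fx <- tiny_b97_dataset(seed = 4, n_systems = 8, points = 4,
                         n_datapoints = 24)
  compiled <- compile_dataset(fx$dataset)
  empty <- new_functional(x = new_program(demo_workspace(), list(),
                                          max_instructions = 6))
  cfg <- evolution_config(
    population_size = 20, tournament_size = 5, budget = 40,
    mutation = demo_mutation_config(),
    fit = fit_config(n_restarts = 2, max_evals_per_dim = 60,
                     j_stop = 1e-6 * data_scale(compiled, "train")))
  set.seed(77)
  run1 <- run_evolution(empty, compiled, cfg)
  set.seed(77)
  run2 <- run_evolution(empty, compiled, cfg)
  expect_identical(run1$history$digest, run2$history$digest)
  expect_identical(run1$history$J_val, run2$history$J_val)
  expect_equal(run1$n_mutations, 40)

  cmin <- cumulative_min_jval(run1$history)
  expect_true(all(diff(cmin) <= 0))
  # The best individual matches the history's minimum validation error.
  expect_equal(run1$best$J_val, min(cmin))
})

test_that("budget 0 returns the best of the initial population untouched", {
  fx <- tiny_b97_dataset(seed = 6, n_systems = 8, points = 4,
                         n_datapoints = 24)
  compiled <- compile_dataset(fx$dataset)
  bp <- fx$truth
  cfg <- evolution_config(
    budget = 0, mutation = demo_mutation_config(),
    fit = fit_config(n_restarts = 8, max_evals_per_dim = 2000,
                     j_stop = 1e-6 * data_scale(compiled, "train")))
  set.seed(1)
  run <- run_evolution(bp$functional, compiled, cfg)
  expect_equal(nrow(run$history), 0)
  # The seeded ground-truth form fits its own data essentially perfectly.
  expect_lt(run$best$J_val, 1e-3 * data_scale(compiled, "validation"))
})

test_that("parallel rounds keep population size bounds and eviction order", {
  fx <- tiny_b97_dataset(seed = 8, n_systems = 8, points = 4,
                         n_datapoints = 24)
  compiled <- compile_dataset(fx$dataset)
  empty <- new_functional(x = new_program(demo_workspace(), list(),
                                          max_instructions = 6))
  cfg <- evolution_config(
    population_size = 6, tournament_size = 3, budget = 12, workers = 2,
    mutation = demo_mutation_config(),
    fit = fit_config(n_restarts = 1, max_evals_per_dim = 40))
  set.seed(5)
  run <- run_evolution(empty, compiled, cfg)
  expect_equal(run$n_mutations, 12)
  members <- population_members(run$population)
  expect_lte(length(members), 6)
  idx <- vapply(members, `[[`, numeric(1), "insertion_index")
  expect_true(all(diff(idx) > 0))  # FIFO order intact
  expect_equal(max(idx), run$population$counter)
})
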