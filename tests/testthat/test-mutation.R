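# Mutation rules: closure under validity, applicability handling,
# determinism.

test_that("mutation of a valid functional always yields a valid functional", {
  cfg <- demo_mutation_config()
  parent <- b97_functional()$functional
  set.seed(100)
  current <- parent
  for (i in 1:3000) {
    child <- mutate_functional(current, cfg)
    expect_length(validate_functional(child), 0)
    prov <- attr(child, "provenance")
    expect_true(prov$channel %in% "x")
    # Random walk: occasionally continue from the child to cover deep states.
    if (i %% 3 == 0) current <- child
  }
})

test_that("exactly one program changes per mutation, parent untouched", {
  cfg <- mutation_config(max_instructions = 6, param_budget = 4)
  g <- gas22_functional()$functional
  snapshot <- functional_to_json(g)
  set.seed(5)
  for (i in 1:50) {
    child <- mutate_functional(g, cfg)
    if (isTRUE(attr(child, "noop"))) next
    ch <- attr(child, "provenance")$channel
    for (c2 in c("x", "c_ss", "c_os")) {
      same <- identical(program_to_json(child$programs[[c2]]),
                        program_to_json(g$programs[[c2]]))
      if (c2 == ch) expect_false(same) else expect_true(same)
    }
  }
  expect_identical(functional_to_json(g), snapshot)
})

test_that("inapplicable rules are handled: remove on empty is a no-op when forced", {
  cfg <- mutation_config(rule_weights = c(remove = 1),
                         allowed_ops = c("add", "mac", "pow",
                                         "gamma_transform"),
                         channels = "x")
  empty <- new_functional(x = new_program(demo_workspace(), list(),
                                          max_instructions = 6))
  set.seed(2)
  child <- mutate_functional(empty, cfg)
  expect_true(attr(child, "noop"))
})

test_that("insert at the cap resamples; children never exceed the cap", {
  cfg <- demo_mutation_config()
  full <- b97_functional()$functional
  # Pad to the 6-instruction cap.
  full$programs$x$instructions <- c(full$programs$x$instructions,
                                    list(i_add("F", "F", "c0")))
  set.seed(9)
  for (i in 1:200) {
    child <- mutate_functional(full, cfg)
    expect_lte(length(child$programs$x$instructions), 6)
  }
})

test_that("insert shifts subsequent instructions, preserving their content", {
  cfg <- mutation_config(rule_weights = c(insert = 1),
                         allowed_ops = "add", max_instructions = 10,
                         channels = "x")
  prog <- b97_program(max_instructions = 10)
  ser <- function(p) vapply(p$instructions, function(ins)
    paste(deparse(unclass(ins)), collapse = ""), character(1))
  orig <- ser(prog)
  set.seed(14)
  for (i in 1:50) {
    child <- apply_rule(prog, "insert", cfg)
    expect_length(child$instructions, 6)
    kept <- ser(child)
    # Removing exactly one instruction restores the original list in order.
    restored <- vapply(seq_along(kept), function(k)
      identical(kept[-k], orig), logical(1))
    expect_true(any(restored))
    expect_length(validate_program(child), 0)
  }
})

test_that("change_op replaces with an arity-compatible op", {
  cfg <- mutation_config(allowed_ops = c("add", "sub", "mul", "div", "mac",
                                         "pow", "gamma_transform"),
                         max_instructions = 6)
  prog <- new_program(demo_workspace(),
                      list(i_add("F", "c0", "c1")), max_instructions = 6)
  set.seed(31)
  seen <- character(0)
  for (i in 1:100) {
    child <- apply_rule(prog, "change_op", cfg)
    op <- child$instructions[[1]]$op
    seen <- union(seen, op)
    expect_true(op %in% c("sub", "mul", "div", "mac"))
  }
  expect_setequal(seen, c("sub", "mul", "div", "mac"))
})

test_that("change_arg never writes to a non-variable and draws kind-legal symbols", {
  cfg <- demo_mutation_config()
  prog <- b97_program()
  kinds <- vapply(prog$workspace, function(s) s$kind, character(1))
  names(kinds) <- vapply(prog$workspace, function(s) s$name, character(1))
  set.seed(77)
  for (i in 1:300) {
    child <- apply_rule(prog, "change_arg", cfg)
    for (ins in child$instructions) {
      expect_identical(unname(kinds[ins$output]), "variable")
      # gamma parameters never appear as free arguments
      expect_false("gamma0" %in% ins$inputs)
    }
    expect_length(validate_program(child), 0)
  }
})

test_that("same parent and seed give an identical child", {
  cfg <- demo_mutation_config()
  parent <- b97_functional()$functional
  set.seed(123)
  a <- mutate_functional(parent, cfg)
  set.seed(123)
  b <- mutate_functional(parent, cfg)
  expect_identical(functional_to_json(a), functional_to_json(b))
  expect_identical(attr(a, "provenance"), attr(b, "provenance"))
})

test_that("repeated mutation from the empty program reaches the B97 family", {
  # Small-space reachability: random walks (biased toward insertion) must be
  # able to construct a program whose rendered expression is quadratic in u.
  cfg <- mutation_config(rule_weights = c(insert = 0.55, remove = 0.05,
                                          change_op = 0.2, change_arg = 0.2),
                         allowed_ops = c("add", "mac", "pow",
                                         "gamma_transform"),
                         allowed_exponents = 2, max_instructions = 6,
                         param_budget = 4, channels = "x")
  target_params <- list(c0 = 0.8094, c1 = 0.5073, c2 = 0.7481,
                        gamma0 = 0.004)
  set.seed(2024)
  found <- FALSE
  for (walk in 1:400) {
    fun <- new_functional(x = new_program(demo_workspace(), list(),
                                          max_instructions = 6))
    for (step in 1:25) {
      fun <- mutate_functional(fun, cfg)
      prog <- fun$programs$x
      if (length(prog$instructions) >= 3 &&
          is_b97_equivalent(prog, target_params, tol = 1e-8,
                            require_quadratic = TRUE)) {
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})
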