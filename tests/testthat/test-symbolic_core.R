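# The instruction-program representation: execution, validation, rendering,
# serialization.

test_that("the five-instruction B97 program evaluates its closed form", {
  bp <- b97_functional()
  prog <- bp$functional$programs$x
  # At x2 = 0 the transform vanishes and only the constant survives.
  res <- execute_program(prog, list(x2 = 0), bp$params)
  expect_true(res$valid)
  expect_equal(res$values, 0.8094, tolerance = 1e-12)
  # gamma*x2 = 1 so u = 1/2: c0 + c1/2 + c2/4 (hand evaluation).
  res <- execute_program(prog, list(x2 = 250), bp$params)
  expect_equal(res$values, 0.8094 + 0.5073 * 0.5 + 0.7481 * 0.25,
               tolerance = 1e-12)
  expect_equal(res$values, 1.2500750, tolerance = 1e-12)
})

test_that("executor agrees with direct closed-form evaluation on random inputs", {
  set.seed(11)
  x2 <- 10^runif(1000, -4, 4)
  bp <- b97_functional()
  vm <- execute_program(bp$functional$programs$x, list(x2 = x2), bp$params)
  direct <- b97_enhancement(x2, 0.8094, 0.5073, 0.7481, 0.004)
  expect_equal(vm$values, direct, tolerance = 1e-12)

  e5 <- eq5_program()
  p5 <- c(c0 = 0.8504, c1 = 0.7480, c2 = 0.3394, gamma0 = 0.004)
  vm5 <- execute_program(e5, list(x2 = x2), p5)
  expect_equal(vm5$values, eq5_enhancement(x2, 0.8504, 0.7480, 0.3394, 0.004),
               tolerance = 1e-12)
})

test_that("variables start at zero: the empty program outputs exactly 0", {
  prog <- new_program(demo_workspace(), list(), max_instructions = 6)
  res <- execute_program(prog, list(x2 = c(1, 2, 3)),
                         c(c0 = 1, c1 = 2, c2 = 3, gamma0 = 0.1))
  expect_identical(res$values, c(0, 0, 0))
  expect_true(res$valid)
  expect_identical(render_expression(prog), "0")
})

test_that("non-finite intermediates flag the evaluation invalid, not an error", {
  ws <- list(ws_feature("x2"), ws_parameter("c0"), ws_variable("v0"),
             ws_variable("F"))
  div0 <- new_program(ws, list(i_div("F", "c0", "v0")))  # v0 is 0
  res <- execute_program(div0, list(x2 = 1), c(c0 = 1))
  expect_false(res$valid)
  expect_identical(res$failed_at, 1L)

  # Fractional power of a negative argument is invalid (no complex values).
  negroot <- new_program(ws, list(i_sub("v0", "v0", "c0"),
                                  i_pow("F", "v0", 1 / 2)))
  res <- execute_program(negroot, list(x2 = 1), c(c0 = 2))
  expect_false(res$valid)
  expect_identical(res$failed_at, 2L)
})

test_that("validate_program reports violations with instruction indices", {
  bp <- b97_functional()
  expect_length(validate_program(bp$functional$programs$x), 0)

  # Writing to a feature.
  ws <- demo_workspace()
  bad <- new_program(ws, list(new_instruction("add", "x2", c("c0", "c1"))))
  v <- validate_program(bad)
  expect_length(v, 1)
  expect_match(v, "instruction 1.*not a variable")

  # Cap violation: 7 instructions under a cap of 6.
  many <- replicate(7, i_add("F", "F", "c0"), simplify = FALSE)
  over <- new_program(ws, many, max_instructions = 6)
  expect_match(validate_program(over), "cap", all = FALSE)

  # Undeclared symbol.
  ghost <- new_program(ws, list(i_add("F", "F", "nope")))
  expect_match(validate_program(ghost), "not declared", all = FALSE)

  # Missing readout.
  nof <- new_program(list(ws_feature("x2"), ws_variable("v0")), list())
  expect_match(validate_program(nof), "'F' missing", all = FALSE)
})

test_that("workspace declaration order never changes the output", {
  bp <- b97_functional()
  prog <- bp$functional$programs$x
  set.seed(4)
  x2 <- 10^runif(50, -3, 3)
  ref <- execute_program(prog, list(x2 = x2), bp$params)$values
  for (i in 1:5) {
    shuffled <- prog
    shuffled$workspace <- prog$workspace[sample(length(prog$workspace))]
    expect_identical(execute_program(shuffled, list(x2 = x2),
                                     bp$params)$values, ref)
  }
})

test_that("rendered expressions evaluate identically to the executor", {
  set.seed(21)
  progs <- list(b97_program(), eq5_program(),
                gas22_functional()$functional$programs$c_ss)
  params <- list(c(c0 = 0.8094, c1 = 0.5073, c2 = 0.7481, gamma0 = 0.004),
                 c(c0 = 0.8504, c1 = 0.7480, c2 = 0.3394, gamma0 = 0.004),
                 gas22_functional()$params)
  for (k in seq_along(progs)) {
    x2 <- 10^runif(200, -4, 4)
    w <- runif(200, -1, 1)
    vals <- list(x2 = x2, w = w)
    vm <- execute_program(progs[[k]], vals, params[[k]])$values
    rendered <- evaluate_expression(render_expression(progs[[k]]),
                                    c(vals, as.list(params[[k]])))
    expect_equal(vm, rendered, tolerance = 1e-10)
  }
})

test_that("the rediscovered form renders to the re-parameterized B97 family", {
  # c0^2 + c1 (c2 + u)^2 via symbolic substitution of the 6-instruction
  # program, checked numerically at random points.
  expr <- render_expression(eq5_program())
  set.seed(3)
  for (i in 1:20) {
    env <- list(x2 = 10^runif(1, -3, 3), c0 = rnorm(1), c1 = rnorm(1),
                c2 = rnorm(1), gamma0 = abs(rnorm(1)))
    u <- env$gamma0 * env$x2 / (1 + env$gamma0 * env$x2)
    expect_equal(evaluate_expression(expr, env),
                 env$c0^2 + env$c1 * (env$c2 + u)^2, tolerance = 1e-12)
  }
})

test_that("JSON serialization round-trips programs and functionals losslessly", {
  for (prog in list(b97_program(), eq5_program(), minimal <- new_program(
    list(ws_variable("F")), list()))) {
    back <- program_from_json(program_to_json(prog))
    expect_equal(back, prog)
  }
  # Fractional exponents survive exactly.
  g <- gas22_functional()
  back <- functional_from_json(functional_to_json(g$functional,
                                                  params = g$params))
  expect_equal(back$functional, g$functional)
  expect_equal(back$params, g$params)
  ex <- back$functional$programs$c_os$instructions[[5]]$exponent
  expect_identical(ex, 1 / 2)
})
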