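# Feature transforms, LDA densities, published enhancement factors, and the
# semilocal energy quadrature.

test_that("feature transforms satisfy their defining identities", {
  f <- compute_features(rho = c(1, 2), grad_norm = c(0, 0))
  expect_equal(f$x, c(0, 0))
  expect_equal(f$x2, c(0, 0))
  expect_equal(f$s, c(0, 0))
  # Inversion of the Wigner-Seitz definition.
  f <- compute_features(rho = 3 / (4 * pi * 125), x2 = 0)
  expect_equal(f$rs, 5, tolerance = 1e-12)
  # Fixed point of the finite-domain transform: x2 = 1/gamma gives u = 1/2.
  for (g in c(0.004, 0.1, 3)) {
    expect_equal(u_transform(1 / g, g), 0.5, tolerance = 1e-12)
  }
  expect_error(compute_features(rho = c(1, -1), x2 = 0), "positive")
})

test_that("u is monotone in x2 and bounded in [0, 1)", {
  x2 <- sort(10^runif(500, -6, 6))
  u <- u_transform(x2, 0.05)
  expect_true(all(diff(u) > 0))
  expect_true(all(u >= 0 & u < 1))
})

test_that("LDA exchange has the right value and homogeneity", {
  d <- lda_energy_densities(1)
  expect_equal(d$e_x, -(3 / 4) * (3 / pi)^(1 / 3), tolerance = 1e-14)
  rho <- 10^runif(20, -2, 1)
  d1 <- lda_energy_densities(rho)
  d2 <- lda_energy_densities(2 * rho)
  expect_equal(d2$e_x / d1$e_x, rep(2^(4 / 3), 20), tolerance = 1e-12)
  expect_error(lda_energy_densities(0), "positive")
})

test_that("the re-parameterized family expands onto the printed B97 coefficients", {
  b <- expand_to_b97(0.8504, 0.7480, 0.3394)
  expect_lt(abs(b[["b0"]] - 0.8094), 1e-3)
  expect_lt(abs(b[["b2"]] - 0.7481), 1e-3)
  # Degenerate member: no quadratic part.
  expect_equal(unname(expand_to_b97(0.9, 0, 5)), c(0.81, 0, 0))
  # The expansion is an exact algebraic identity, pointwise.
  set.seed(8)
  x2 <- 10^runif(1000, -4, 4)
  c <- rnorm(3); g <- 0.02
  b2 <- expand_to_b97(c[1], c[2], c[3])
  expect_equal(b97_enhancement(x2, b2[1], b2[2], b2[3], g),
               eq5_enhancement(x2, c[1], c[2], c[3], g), tolerance = 1e-12)
})

test_that("B97 enhancement limits", {
  expect_equal(b97_enhancement(0, 0.8, 0.5, 0.7, 0.004), 0.8)
  expect_equal(b97_enhancement(1e12, 0.8, 0.5, 0.7, 0.004), 2.0,
               tolerance = 1e-6)
})

test_that("power-series enhancement respects its term subsets", {
  expect_equal(wb97mv_enhancement("x", u = 0.3, w = -0.2,
                                  coefficients = c("00" = 1)), 1)
  expect_equal(wb97mv_enhancement("c_ss", u = 0.5, w = 0.5,
                                  coefficients = c("00" = 0)), 0)
  # c21 means w^2 u^1 (brute-force polynomial oracle at (w, u) = (2, 3)).
  expect_equal(wb97mv_enhancement("c_os", u = 3, w = 2,
                                  coefficients = c("21" = 1)), 12)
  expect_error(wb97mv_enhancement("x", u = 0.1, w = 0.1,
                                  coefficients = c("21" = 1)),
               "outside the x term subset")
})

test_that("GAS22 closed forms match their printed anchors", {
  expect_equal(gas22_enhancement("x", x = 0, w = 0), 0.862)
  expect_equal(gas22_enhancement("c_os", x = 0, w = 0), 0.805)
  expect_equal(gas22_enhancement("c_ss", x = 0, w = 0), 0)
})

test_that("program encodings agree with closed forms (cross-representation)", {
  set.seed(17)
  x2 <- 10^runif(1000, -4, 4)
  x <- sqrt(x2)
  w <- runif(1000, -1, 1)
  g <- gas22_functional()
  fx <- execute_program(g$functional$programs$x, list(x2 = x2, w = w),
                        g$params)
  expect_equal(fx$values, gas22_enhancement("x", x2 = x2, w = w),
               tolerance = 1e-12)
  for (ch in c("c_ss", "c_os")) {
    vm <- execute_program(g$functional$programs[[ch]],
                          list(x2 = x2, x = x, w = w), g$params)
    direct <- gas22_enhancement(ch, x = x, x2 = x2, w = w)
    expect_equal(vm$values, direct, tolerance = 1e-10)
  }
  wf <- wb97mv_functional()
  tab <- wb97mv_coefficients()
  for (ch in c("x", "c_ss", "c_os")) {
    vm <- execute_program(wf$functional$programs[[ch]],
                          list(x2 = x2, w = w), wf$params)
    direct <- wb97mv_enhancement(ch, u_transform(x2, tab$gamma[[ch]]), w)
    expect_equal(vm$values, direct, tolerance = 1e-10)
  }
})

test_that("semilocal energy quadrature reduces to hand values", {
  # Single point, weight 2, e_x = -1 (rho chosen so), F_x = 1.5: energy -3.
  rho1 <- (4 / (3 * (3 / pi)^(1 / 3)))^(3 / 4)  # e_x(rho1) = -1
  sys <- new_grid_system("one", rho = rho1, x2 = 0, w = 0, quad_weights = 2)
  ws <- list(ws_parameter("c"), ws_variable("F"))
  fun <- new_functional(x = new_program(ws, list(i_add("F", "F", "c"))))
  res <- exc_semilocal(sys, fun, c(c = 1.5))
  expect_true(res$valid)
  expect_equal(res$energy, -3, tolerance = 1e-12)

  # All-zero programs give exactly zero energy.
  res0 <- exc_semilocal(sys, new_functional(), numeric())
  expect_identical(res0$energy, 0)

  # F_x == 1, correlation 0: the plain LDA exchange integral of the grid.
  sys2 <- tiny_system(n = 7, seed = 3)
  fun1 <- new_functional(x = new_program(ws, list(i_add("F", "F", "c"))))
  res1 <- exc_semilocal(sys2, fun1, c(c = 1))
  expect_equal(res1$energy,
               sum(sys2$quad_weights * lda_energy_densities(sys2$rho)$e_x),
               tolerance = 1e-12)
})

test_that("semilocal energy is linear in each enhancement factor", {
  sys <- tiny_system(n = 6, seed = 9)
  ws <- list(ws_feature("x2"), ws_parameter("c"), ws_variable("F"))
  fun <- new_functional(c_ss = new_program(ws, list(i_mac("F", "c", "x2"))))
  e1 <- exc_semilocal(sys, fun, c(c = 1))$energy
  e3 <- exc_semilocal(sys, fun, c(c = 3))$energy
  expect_equal(e3, 3 * e1, tolerance = 1e-10)
})

test_that("combined F_xc behaves as a weighted ratio and is finite on the diagnostic grid", {
  feats <- list(rho = c(0.5, 2), x2 = c(1, 10), w = c(0, 0.5))
  ws <- list(ws_parameter("c"), ws_variable("F"))
  one <- function() new_program(ws, list(i_add("F", "F", "c")))
  fun <- new_functional(x = one(), c_ss = one(), c_os = one())
  res <- combined_fxc(feats, fun, c(c = 1))
  expect_equal(res$fxc, c(1, 1), tolerance = 1e-12)

  # With zero correlation densities, F_xc equals F_x.
  lda_x_only <- function(rho) {
    d <- lda_energy_densities(rho)
    list(e_x = d$e_x, e_c_ss = 0 * rho, e_c_os = 0 * rho)
  }
  res2 <- combined_fxc(feats, new_functional(x = one()), c(c = 2.5),
                       lda = lda_x_only)
  expect_equal(res2$fxc, c(2.5, 2.5), tolerance = 1e-12)

  # Published meta-GGA forms produce finite curves over the standard axes.
  g <- gas22_functional()
  curves <- fxc_curves(g$functional, g$params,
                       s = seq(0, 3, length.out = 100),
                       rs = c(0.5, 1, 2, 3, 5), w = c(-1, 0, 1))
  expect_equal(nrow(curves), 100 * 5 * 3)
  expect_true(all(is.finite(curves$fxc)))
  wf <- wb97mv_functional()
  curves2 <- fxc_curves(wf$functional, wf$params,
                        s = seq(0, 3, length.out = 20), rs = c(1, 5),
                        w = c(-1, 0, 1))
  expect_true(all(is.finite(curves2$fxc)))
})
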