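# Synthetic grids, systems and energy datasets.  The generator emulates the
# statistical shape of MGCDB84-style data -- multiple data types with
# per-type sample weights, data points formed as signed combinations of
# system energies, and train/validation/test splits -- with reference
# energies computed from a chosen ground-truth functional, so the whole
# search stack runs end-to-end without any external dataset.

#' Specification for synthetic data generation
#'
#' @param n_systems Number of grid systems ("molecules").
#' @param points_per_system Grid points per system.
#' @param rho_range Density range; sampled log-uniformly (a.u.).
#' @param x2_range Squared-reduced-gradient range; sampled log-uniformly.
#' @param w_range Range of the bounded kinetic-energy-density feature.
#' @param quad_weight_range Quadrature-weight range; sampled uniformly.
#' @param n_datapoints Number of energetic data points.
#' @param recipe Fractions of single-energy, pairwise-difference and
#'   multi-term (3-4 systems, signed integer coefficients) data points; must
#'   sum to 1.
#' @param data_types Type labels cycled over the data points.
#' @param type_weights Named per-type sample weights.
#' @param split_fractions Train/validation/test fractions (default 60/20/20).
#' @param split_by_type When \code{TRUE}, whole data types are assigned to
#'   splits (stressing transferability) instead of a random shuffle.
#' @param noise_sd Gaussian noise added to reference energies (kcal/mol;
#'   default 0 so recovery experiments are well-posed).
#' @param offset_sd SD of per-system non-XC energy offsets (hartree).
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return An \code{xc_synthetic_spec}.
#' @export
synthetic_spec <- function(n_systems = 60L, points_per_system = 8L,
                           rho_range = c(1e-2, 10), x2_range = c(1e-4, 1e4),
                           w_range = c(-1, 1), quad_weight_range = c(0.1, 2),
                           n_datapoints = 300L,
                           recipe = c(single = 0.2, pair = 0.5, multi = 0.3),
                           data_types = "TCE",
                           type_weights = DEFAULT_TYPE_WEIGHTS,
                           split_fractions = c(train = 0.6,
                                               validation = 0.2,
                                               test = 0.2),
                           split_by_type = FALSE, noise_sd = 0,
                           offset_sd = 0, seed = 1L) {
  stopifnot(abs(sum(recipe) - 1) < 1e-9, abs(sum(split_fractions) - 1) < 1e-9,
            all(data_types %in% names(type_weights)))
  structure(as.list(environment()), class = "xc_synthetic_spec")
}

#' Generate grid systems from a spec
#'
#' Seeded and reproducible: densities log-uniform and positive, squared
#' reduced gradients log-uniform, \code{w} uniform in its range, quadrature
#' weights uniform and non-negative.
#'
#' @param spec An \code{\link{synthetic_spec}}.
#' @return Named list of \code{xc_grid_system}s.
#' @export
generate_systems <- function(spec) {
  set.seed(spec$seed)
  labels <- sprintf("sys%03d", seq_len(spec$n_systems))
  systems <- lapply(labels, function(lab) {
    n <- spec$points_per_system
    new_grid_system(
      label = lab,
      rho = 10^runif(n, log10(spec$rho_range[1]), log10(spec$rho_range[2])),
      x2 = 10^runif(n, log10(spec$x2_range[1]), log10(spec$x2_range[2])),
      w = runif(n, spec$w_range[1], spec$w_range[2]),
      quad_weights = runif(n, spec$quad_weight_range[1],
                           spec$quad_weight_range[2]))
  })
  names(systems) <- labels
  systems
}

sample_terms <- function(kind, labels) {
  switch(kind,
    single = list(labels = sample(labels, 1L), coeffs = 1),
    pair = {
      pick <- sample(labels, 2L)
      list(labels = pick, coeffs = c(1, -1))
    },
    multi = {
      k <- sample(3:4, 1L)
      pick <- sample(labels, k)
      coeffs <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
      list(labels = pick, coeffs = coeffs)
    })
}

#' Generate an energy dataset from a ground-truth functional
#'
#' Reference values are the signed combinations of semilocal XC energies
#' (plus per-system offsets) evaluated under the ground-truth functional,
#' converted to kcal/mol, with optional Gaussian noise; splits are assigned
#' by a seeded shuffle (or by type).
#'
#' @param spec An \code{\link{synthetic_spec}}.
#' @param functional Ground-truth \code{xc_functional}.
#' @param params Its parameter values.
#' @param lda Energy-density provider.
#' @return An \code{xc_energy_dataset}.
#' @export
generate_dataset <- function(spec, functional, params,
                             lda = lda_energy_densities) {
  systems <- generate_systems(spec)
  labels <- names(systems)
  offsets <- setNames(rnorm(length(systems), sd = spec$offset_sd), labels)
  energies <- vapply(systems, function(sys) {
    res <- exc_semilocal(sys, functional, params, lda = lda)
    if (!res$valid) stop("ground-truth functional invalid on system ",
                         sys$label)
    res$energy
  }, numeric(1))

  n <- spec$n_datapoints
  kinds <- sample(names(spec$recipe), n, replace = TRUE, prob = spec$recipe)
  types <- rep_len(spec$data_types, n)
  terms <- character(n)
  reference <- numeric(n)
  for (i in seq_len(n)) {
    t <- sample_terms(kinds[i], labels)
    terms[i] <- format_terms(t$labels, t$coeffs)
    reference[i] <- sum(t$coeffs * (offsets[t$labels] +
                                      energies[t$labels])) * HARTREE_TO_KCAL
  }
  if (spec$noise_sd > 0) reference <- reference + rnorm(n, sd = spec$noise_sd)

  split <- character(n)
  if (spec$split_by_type && length(unique(types)) > 1L) {
    type_split <- sample(names(spec$split_fractions),
                         length(unique(types)), replace = TRUE,
                         prob = spec$split_fractions)
    names(type_split) <- unique(types)
    split <- type_split[types]
  } else {
    counts <- floor(spec$split_fractions * n)
    counts[1] <- n - sum(counts[-1])
    split <- sample(rep(names(spec$split_fractions), times = counts))
  }

  dp <- data.frame(id = sprintf("dp%04d", seq_len(n)), data_type = types,
                   weight = unname(spec$type_weights[types]),
                   reference = reference, terms = terms,
                   split = unname(split), stringsAsFactors = FALSE)
  new_energy_dataset(systems, dp, offsets)
}

#' Proof-of-principle fixture: rediscovering the B97 exchange form
#'
#' Packages the exact search space of the from-scratch experiment -- four
#' instructions (\code{s = p + q}, \code{s = s + p*q}, \code{s = p^2},
#' \code{s = gamma*p/(1 + gamma*p)}), at most six instructions per program, a
#' workspace of one feature (\code{x2}), four parameters and three variables,
#' tournament size 10 -- together with a synthetic dataset whose reference
#' energies come from the B97 exchange enhancement factor, and an empty
#' starting functional on that workspace.
#'
#' @param seed RNG seed for the synthetic data.
#' @param n_systems,points_per_system,n_datapoints Dataset sizing (desk
#'   scale).
#' @param budget Mutation budget.
#' @return List with \code{dataset}, \code{config}
#'   (\code{\link{evolution_config}}), \code{initial} (the empty
#'   functional), \code{truth} (ground-truth functional and parameters).
#' @export
b97_demo_fixture <- function(seed = 1L, n_systems = 40L,
                             points_per_system = 6L, n_datapoints = 200L,
                             budget = 4000L) {
  truth <- b97_functional()
  spec <- synthetic_spec(n_systems = n_systems,
                         points_per_system = points_per_system,
                         n_datapoints = n_datapoints, seed = seed)
  dataset <- generate_dataset(spec, truth$functional, truth$params)

  workspace <- list(ws_feature("x2"),
                    ws_parameter("c0"), ws_parameter("c1"),
                    ws_parameter("c2"),
                    ws_parameter("gamma0", gamma = TRUE),
                    ws_variable("v0"), ws_variable("v1"), ws_variable("F"))
  empty <- new_functional(x = new_program(workspace, list(),
                                          max_instructions = 6L))

  config <- evolution_config(
    population_size = 100L, tournament_size = 10L, budget = budget,
    mutation = mutation_config(
      allowed_ops = c("add", "mac", "pow", "gamma_transform"),
      allowed_exponents = 2, max_instructions = 6L, param_budget = 4L,
      channels = "x"),
    fit = fit_config(n_restarts = 10L, sigma0 = 0.3, bounds = c(-10, 10),
                     max_evals_per_dim = 2000L,
                     j_stop = 1e-6 * data_scale(dataset, "train")),
    probe = probe_spec())
  list(dataset = dataset, config = config, initial = empty, truth = truth,
       spec = spec)
}
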