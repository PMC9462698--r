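# Shared fixtures: tiny grids and datasets built in code at test time.

tiny_system <- function(label = "sysA", n = 5, seed = 1) {
  set.seed(seed)
  new_grid_system(label,
                  rho = 10^runif(n, -1, 1),
                  x2 = 10^runif(n, -2, 3),
                  w = runif(n, -1, 1),
                  quad_weights = runif(n, 0.1, 2))
}

# A small noiseless dataset generated from the B97 exchange ground truth.
tiny_b97_dataset <- function(seed = 7, n_systems = 12, points = 5,
                             n_datapoints = 40) {
  truth <- b97_functional()
  spec <- synthetic_spec(n_systems = n_systems, points_per_system = points,
                         n_datapoints = n_datapoints, seed = seed)
  list(dataset = generate_dataset(spec, truth$functional, truth$params),
       truth = truth, spec = spec)
}

# Workspace matching the proof-of-principle search space.
demo_workspace <- function() {
  list(ws_feature("x2"),
       ws_parameter("c0"), ws_parameter("c1"), ws_parameter("c2"),
       ws_parameter("gamma0", gamma = TRUE),
       ws_variable("v0"), ws_variable("v1"), ws_variable("F"))
}

demo_mutation_config <- function() {
  mutation_config(allowed_ops = c("add", "mac", "pow", "gamma_transform"),
                  allowed_exponents = 2, max_instructions = 6L,
                  param_budget = 4L, channels = "x")
}
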