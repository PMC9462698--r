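# Objective and parameter fitting.  Energetic data points are signed
# combinations of per-system total energies with reference values, typed
# labels and sample weights; the objective is the weighted RMSD over a split.
# Scalar parameters of a fixed functional form are fitted by multi-restart
# CMA-ES with all parameters treated as nonlinear and constrained to the box
# [-10, 10].

# Default per-type sample weights for MGCDB84-style data types.
DEFAULT_TYPE_WEIGHTS <- c(TCD = 0.1, TCE = 1, AE18 = 1, NCD = 10, ID = 10,
                          BH = 10, NCE = 100, IE = 100, RG10 = 10000)

parse_terms <- function(terms) {
  parts <- strsplit(terms, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  list(labels = vapply(kv, `[[`, character(1), 1),
       coeffs = as.numeric(vapply(kv, `[[`, character(1), 2)))
}

format_terms <- function(labels, coeffs) {
  paste(paste0(labels, ":", coeffs), collapse = ";")
}

#' Create an energy dataset
#'
#' @param systems Named list of \code{\link{new_grid_system}} objects.
#' @param datapoints data.frame with columns \code{id}, \code{data_type},
#'   \code{weight}, \code{reference} (kcal/mol), \code{terms} (string
#'   \code{"label:coeff;label:coeff"}), \code{split} (one of \code{train},
#'   \code{validation}, \code{test}).
#' @param offsets Named numeric of per-system non-XC energy offsets
#'   (hartree); defaults to zero.
#' @return An \code{xc_energy_dataset}.
#' @export
new_energy_dataset <- function(systems, datapoints, offsets = NULL) {
  stopifnot(is.list(systems), length(names(systems)) == length(systems))
  if (is.null(offsets)) {
    offsets <- setNames(numeric(length(systems)), names(systems))
  }
  stopifnot(all(names(systems) %in% names(offsets)))
  needed <- c("id", "data_type", "weight", "reference", "terms", "split")
  stopifnot(all(needed %in% names(datapoints)),
            all(datapoints$split %in% c("train", "validation", "test")),
            all(datapoints$weight > 0))
  for (t in datapoints$terms) {
    lab <- parse_terms(t)$labels
    if (!all(lab %in% names(systems))) {
      stop("datapoint term references unknown system(s): ",
           paste(setdiff(lab, names(systems)), collapse = ", "))
    }
  }
  structure(list(systems = systems, offsets = offsets[names(systems)],
                 datapoints = datapoints),
            class = "xc_energy_dataset")
}

#' Precompute the fixed parts of the energy objective
#'
#' Concatenates all grids, evaluates the LDA energy densities once, and
#' builds the datapoint-by-system signed-coefficient matrix, so that fitting
#' only re-executes the three enhancement-factor programs per objective
#' evaluation.
#'
#' @param dataset An \code{xc_energy_dataset}.
#' @param lda Energy-density provider.
#' @return An \code{xc_compiled_dataset}.
#' @export
compile_dataset <- function(dataset, lda = lda_energy_densities) {
  sys_names <- names(dataset$systems)
  rho <- unlist(lapply(dataset$systems, `[[`, "rho"), use.names = FALSE)
  x2 <- unlist(lapply(dataset$systems, `[[`, "x2"), use.names = FALSE)
  w <- unlist(lapply(dataset$systems, `[[`, "w"), use.names = FALSE)
  qw <- unlist(lapply(dataset$systems, `[[`, "quad_weights"),
               use.names = FALSE)
  sys_index <- rep(seq_along(sys_names),
                   vapply(dataset$systems, function(s) length(s$rho),
                          integer(1)))
  feats <- unclass(compute_features(rho, x2 = x2, w = w))
  dens <- lda(rho)
  prefac <- list(x = qw * dens$e_x, c_ss = qw * dens$e_c_ss,
                 c_os = qw * dens$e_c_os)
  dp <- dataset$datapoints
  Tm <- matrix(0, nrow = nrow(dp), ncol = length(sys_names),
               dimnames = list(dp$id, sys_names))
  for (i in seq_len(nrow(dp))) {
    t <- parse_terms(dp$terms[i])
    agg <- tapply(t$coeffs, t$labels, sum)  # duplicate labels accumulate
    Tm[i, names(agg)] <- Tm[i, names(agg)] + as.numeric(agg)
  }
  splits <- split(seq_len(nrow(dp)), dp$split)
  structure(list(sys_names = sys_names, n_points = length(rho),
                 feats = feats, prefac = prefac, sys_index = sys_index,
                 offsets = unname(dataset$offsets[sys_names]),
                 term_matrix = Tm, reference = dp$reference,
                 weight = dp$weight, splits = splits,
                 datapoints = dp),
            class = "xc_compiled_dataset")
}

as_compiled <- function(dataset, lda = lda_energy_densities) {
  if (inherits(dataset, "xc_compiled_dataset")) dataset
  else compile_dataset(dataset, lda)
}

#' Weighted root-mean-square deviation
#'
#' \code{sqrt(mean(weights * (predictions - reference)^2))}, the objective
#' evaluated on the training, validation or test split (kcal/mol).
#'
#' @param predictions,reference Numeric vectors of per-datapoint energies.
#' @param weights Positive sample weights.
#' @return Non-negative scalar.
#' @export
wrmsd <- function(predictions, reference, weights = 1) {
  stopifnot(length(predictions) == length(reference),
            length(predictions) > 0)
  sqrt(mean(weights * (predictions - reference)^2))
}

# Per-datapoint energies for given parameter values over a compiled dataset.
predict_compiled <- function(plans, params, compiled) {
  point_sum <- 0
  any_prog <- FALSE
  for (ch in CHANNELS) {
    plan <- plans[[ch]]
    if (length(plan$ops) == 0L) next  # empty program: factor identically 0
    any_prog <- TRUE
    res <- exec_plan(plan, compiled$feats, params, n = compiled$n_points)
    if (!res$valid) return(list(energies = NULL, valid = FALSE))
    point_sum <- point_sum + compiled$prefac[[ch]] * res$values
  }
  e_sys <- if (any_prog) {
    rowsum(point_sum, compiled$sys_index, reorder = TRUE)[, 1]
  } else {
    numeric(length(compiled$sys_names))
  }
  energies <- as.vector(compiled$term_matrix %*% (compiled$offsets + e_sys)) *
    HARTREE_TO_KCAL
  list(energies = energies, valid = TRUE)
}

#' Predict per-datapoint energies
#'
#' \code{E_i = sum_terms coeff * (offset_sys + E_xc_semilocal(sys))},
#' converted to kcal/mol.  Invalid functional evaluations propagate as
#' \code{valid = FALSE}.
#'
#' @param functional An \code{xc_functional}.
#' @param params Named parameter values.
#' @param dataset An \code{xc_energy_dataset} or \code{xc_compiled_dataset}.
#' @return List with \code{energies} (in datapoint order) and \code{valid}.
#' @export
predict_datapoints <- function(functional, params, dataset) {
  compiled <- as_compiled(dataset)
  plans <- lapply(functional$programs, compile_program)
  predict_compiled(plans, as.list(params), compiled)
}

#' Evaluate the WRMSD of a functional on one split
#'
#' @param functional,params Functional form and parameter values.
#' @param dataset Dataset (compiled or not).
#' @param split \code{"train"}, \code{"validation"} or \code{"test"}.
#' @return J (kcal/mol), or \code{Inf} for invalid evaluations.
#' @export
evaluate_wrmsd <- function(functional, params, dataset, split = "train") {
  compiled <- as_compiled(dataset)
  idx <- compiled$splits[[split]]
  if (is.null(idx) || !length(idx)) stop("empty split: ", split)
  pred <- predict_datapoints(functional, params, compiled)
  if (!pred$valid) return(Inf)
  wrmsd(pred$energies[idx], compiled$reference[idx], compiled$weight[idx])
}

#' Scale of a dataset split
#'
#' The WRMSD of the all-zero prediction,
#' \code{sqrt(mean(w * reference^2))}; used to express fit quality relative
#' to the energies being fitted.
#'
#' @param dataset Dataset (compiled or not).
#' @param split Split name.
#' @return Positive scalar (kcal/mol).
#' @export
data_scale <- function(dataset, split = "validation") {
  compiled <- as_compiled(dataset)
  idx <- compiled$splits[[split]]
  sqrt(mean(compiled$weight[idx] * compiled$reference[idx]^2))
}

#' Fitting configuration
#'
#' @param n_restarts Independent CMA-ES restarts, each initialized from a
#'   standard-normal draw; the restart with the lowest training error wins.
#' @param sigma0 Initial CMA-ES step size.
#' @param bounds Box constraint applied to every parameter.
#' @param max_evals_per_dim Objective-evaluation budget per restart, per
#'   parameter dimension.
#' @param j_stop Training error at which remaining restarts are skipped
#'   (0 = only a perfect fit stops early).
#' @return An \code{xc_fit_config}.
#' @export
fit_config <- function(n_restarts = 5L, sigma0 = 0.3, bounds = c(-10, 10),
                       max_evals_per_dim = 200L, j_stop = 0) {
  stopifnot(n_restarts >= 1L, sigma0 > 0, length(bounds) == 2,
            bounds[1] < bounds[2])
  structure(list(n_restarts = as.integer(n_restarts), sigma0 = sigma0,
                 bounds = bounds, max_evals_per_dim = as.integer(max_evals_per_dim),
                 j_stop = j_stop),
            class = "xc_fit_config")
}

UNFIT_OBJECTIVE <- 1e15

# Batched training objective: evaluates the WRMSD of k candidate parameter
# vectors (columns of theta) in one vectorized pass by tiling the grid
# features k times and broadcasting each candidate's parameters over its
# block.  Candidate validity is judged from the finiteness of its final
# datapoint energies (the strict per-instruction check is applied to the
# winning candidate afterwards); invalid candidates receive a worst-case
# objective rather than poisoning the batch.
make_batch_objective <- function(plans, compiled, base, act, idx, ref, wt) {
  P <- compiled$n_points
  S <- length(compiled$sys_names)
  tiled <- new.env(parent = emptyenv())  # per-k tiling cache

  get_tiling <- function(k) {
    key <- as.character(k)
    if (!is.null(tiled[[key]])) return(tiled[[key]])
    t <- list(
      feats = lapply(compiled$feats, rep, times = k),
      prefac = lapply(compiled$prefac, rep, times = k),
      gidx = rep((seq_len(k) - 1L) * S, each = P) +
        rep(compiled$sys_index, k))
    tiled[[key]] <- t
    t
  }

  function(theta) {
    if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1L)
    k <- ncol(theta)
    t <- get_tiling(k)
    params <- base
    for (j in seq_along(act)) {
      params[[act[j]]] <- rep(theta[j, ], each = P)
    }
    point_sum <- 0
    any_prog <- FALSE
    for (ch in CHANNELS) {
      plan <- plans[[ch]]
      if (length(plan$ops) == 0L) next
      any_prog <- TRUE
      res <- exec_plan(plan, t$feats, params, n = P * k, check = FALSE)
      point_sum <- point_sum + t$prefac[[ch]] * res$values
    }
    e_sys <- if (any_prog) {
      matrix(rowsum(point_sum, t$gidx, reorder = TRUE), nrow = S, ncol = k)
    } else {
      matrix(0, nrow = S, ncol = k)
    }
    pred <- (compiled$term_matrix %*% (compiled$offsets + e_sys)) *
      HARTREE_TO_KCAL
    resid2 <- (pred[idx, , drop = FALSE] - ref)^2
    j_val <- sqrt(colMeans(wt * resid2))
    j_val[!is.finite(j_val)] <- UNFIT_OBJECTIVE
    j_val
  }
}

#' Fit the scalar parameters of a functional form
#'
#' Minimizes the training-split WRMSD over the parameters that actually
#' influence the functional's output (parameters outside the backward slice
#' of any readout are fixed at zero).  Runs \code{n_restarts} independent
#' CMA-ES optimizations with standard-normal initial guesses and the box
#' constraint from \code{config}, and returns the best training error found.
#' Deterministic given the RNG state on entry.
#'
#' @param functional An \code{xc_functional}.
#' @param dataset Dataset (compiled or not).
#' @param config An \code{\link{fit_config}}.
#' @return List with \code{params} (full named vector; inactive parameters
#'   0), \code{J_train}, \code{valid} (FALSE when every restart was
#'   non-finite), and \code{evals}.
#' @export
fit_parameters <- function(functional, dataset, config = fit_config()) {
  compiled <- as_compiled(dataset)
  idx <- compiled$splits[["train"]]
  if (is.null(idx) || !length(idx)) stop("empty training split")
  ref <- compiled$reference[idx]
  wt <- compiled$weight[idx]
  all_names <- functional_parameters(functional)
  act <- active_parameters(functional)
  plans <- lapply(functional$programs, compile_program)
  base <- as.list(setNames(numeric(length(all_names)), all_names))

  objective <- function(theta) {
    p <- base
    p[act] <- theta
    pred <- predict_compiled(plans, p, compiled)
    if (!pred$valid) return(UNFIT_OBJECTIVE)
    wrmsd(pred$energies[idx], ref, wt)
  }

  d <- length(act)
  if (d == 0L) {
    j <- objective(numeric(0))
    return(list(params = setNames(numeric(length(all_names)), all_names),
                J_train = j, valid = j < UNFIT_OBJECTIVE, evals = 1L))
  }

  batch_objective <- make_batch_objective(plans, compiled, base, act,
                                          idx, ref, wt)
  best <- list(value = Inf, par = numeric(d))
  evals <- 0L
  for (r in seq_len(config$n_restarts)) {
    x0 <- rnorm(d)
    res <- cma_es_minimize(batch_objective, x0, sigma0 = config$sigma0,
                           lower = config$bounds[1], upper = config$bounds[2],
                           max_evals = config$max_evals_per_dim * d)
    evals <- evals + res$evals
    if (res$value < best$value) best <- res
    if (best$value <= config$j_stop) break
  }
  j <- objective(best$par)  # exact J at the clipped optimum, strict validity
  params <- setNames(numeric(length(all_names)), all_names)
  params[act] <- pmin(pmax(best$par, config$bounds[1]), config$bounds[2])
  list(params = params, J_train = j, valid = j < UNFIT_OBJECTIVE,
       evals = evals)
}
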