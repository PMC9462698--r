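# Program execution.  Programs are compiled once into an integer-indexed plan
# so the fitting hot loop avoids name lookups; execution is elementwise over
# grid points with variables initialized to zero.

compile_program <- function(program) {
  nm <- ws_names(program)
  kinds <- ws_kinds(program)
  idx <- setNames(seq_along(nm), nm)
  ops <- lapply(program$instructions, function(ins) {
    list(op = ins$op,
         out = idx[[ins$output]],
         a = idx[[ins$inputs[1]]],
         b = if (length(ins$inputs) > 1) idx[[ins$inputs[2]]] else NA_integer_,
         exponent = ins$exponent,
         gamma = if (!is.null(ins$bound_parameter)) idx[[ins$bound_parameter]]
                 else NA_integer_)
  })
  structure(list(names = nm, kinds = unname(kinds[nm]), index = idx,
                 features = nm[kinds[nm] == "feature"],
                 parameters = nm[kinds[nm] == "parameter"],
                 variables = nm[kinds[nm] == "variable"],
                 f_index = idx[["F"]],
                 ops = ops),
            class = "xc_plan")
}

# Core evaluator over a compiled plan.  feature_values: named list of numeric
# vectors (common length); parameter_values: named numeric.  Any non-finite
# intermediate (division by ~0, fractional power of a negative, overflow)
# flags the whole evaluation invalid rather than raising.
exec_plan <- function(plan, feature_values, parameter_values, n = NULL,
                      check = TRUE) {
  if (is.null(n)) {
    n <- if (length(plan$features)) length(feature_values[[plan$features[1]]])
         else 1L
  }
  vals <- vector("list", length(plan$names))
  for (f in plan$features) {
    fv <- feature_values[[f]]
    if (is.null(fv)) stop("feature '", f, "' not supplied")
    vals[[plan$index[[f]]]] <- if (length(fv) == n) fv else rep_len(fv, n)
  }
  for (p in plan$parameters) {
    pv <- parameter_values[[p]]
    if (is.null(pv) || anyNA(pv)) stop("parameter '", p, "' not supplied")
    vals[[plan$index[[p]]]] <- pv
  }
  zero <- numeric(n)
  for (v in plan$variables) vals[[plan$index[[v]]]] <- zero
  for (k in seq_along(plan$ops)) {
    o <- plan$ops[[k]]
    val <- switch(o$op,
      add = vals[[o$a]] + vals[[o$b]],
      sub = vals[[o$a]] - vals[[o$b]],
      mul = vals[[o$a]] * vals[[o$b]],
      div = vals[[o$a]] / vals[[o$b]],
      mac = vals[[o$out]] + vals[[o$a]] * vals[[o$b]],
      pow = vals[[o$a]]^o$exponent,
      gamma_transform = {
        g <- vals[[o$gamma]]
        gp <- g * vals[[o$a]]
        gp / (1 + gp)
      })
    if (check && !all(is.finite(val))) {
      return(list(values = rep(NA_real_, n), valid = FALSE, failed_at = k))
    }
    vals[[o$out]] <- if (length(val) == n) val else rep_len(val, n)
  }
  list(values = vals[[plan$f_index]], valid = TRUE, failed_at = NA_integer_)
}

#' Execute an instruction program over grid points
#'
#' Runs the instructions in list order, elementwise over grid points, with all
#' variables initialized to zero, and returns the final value of the readout
#' variable \code{F}.  Non-finite intermediates (division by zero, fractional
#' powers of negative arguments, overflow) mark the evaluation invalid instead
#' of raising, so that degenerate children in an evolutionary search propagate
#' as unfit individuals rather than crashes.
#'
#' @param program A valid \code{xc_program}.
#' @param feature_values Named list mapping each feature to a numeric vector
#'   over grid points.
#' @param parameter_values Named numeric vector/list of scalar parameter
#'   values.
#' @param n Number of grid points; inferred from the features when omitted.
#' @return List with \code{values} (numeric vector of \code{F}),
#'   \code{valid} (logical), and \code{failed_at} (index of the first
#'   instruction producing a non-finite value, or \code{NA}).
#' @export
execute_program <- function(program, feature_values = list(),
                            parameter_values = numeric(), n = NULL) {
  assert_valid_program(program)
  exec_plan(compile_program(program), feature_values,
            as.list(parameter_values), n = n)
}
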