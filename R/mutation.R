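# The four mutation rules that generate child functionals: insert an
# instruction, remove one, change an instruction's operation, change one
# argument.  All sampling is uniform unless weighted in the config; children
# are always valid programs (or the mutation is a flagged no-op).

#' Mutation configuration
#'
#' @param rule_weights Probabilities over \code{insert}, \code{remove},
#'   \code{change_op}, \code{change_arg}; normalized to sum to 1.
#' @param allowed_ops Subset of the instruction set available to the search.
#' @param allowed_exponents Exponents available to the power op.
#' @param max_instructions Program-length cap of the search space.
#' @param param_budget Maximum number of parameter symbols per program
#'   workspace; a fresh transform gamma is allocated only while under budget,
#'   otherwise an existing gamma is reused.
#' @param channels Enhancement-factor channels open to mutation; one is
#'   chosen uniformly per mutation.
#' @param max_retries Resampling budget when a drawn rule is inapplicable.
#' @return An \code{xc_mutation_config}.
#' @export
mutation_config <- function(rule_weights = c(insert = 0.25, remove = 0.25,
                                             change_op = 0.25,
                                             change_arg = 0.25),
                            allowed_ops = OP_TAGS,
                            allowed_exponents = POW_EXPONENTS,
                            max_instructions = 6L,
                            param_budget = 4L,
                            channels = CHANNELS,
                            max_retries = 20L) {
  stopifnot(all(names(rule_weights) %in%
                  c("insert", "remove", "change_op", "change_arg")),
            length(allowed_ops) > 0, all(allowed_ops %in% OP_TAGS),
            all(channels %in% CHANNELS))
  rule_weights <- rule_weights / sum(rule_weights)
  structure(list(rule_weights = rule_weights,
                 allowed_ops = allowed_ops,
                 allowed_exponents = allowed_exponents,
                 max_instructions = as.integer(max_instructions),
                 param_budget = as.integer(param_budget),
                 channels = channels,
                 max_retries = as.integer(max_retries)),
            class = "xc_mutation_config")
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Symbols legal in a free argument slot: features, variables and non-gamma
# parameters (transform gammas are bound, never free arguments).
legal_arguments <- function(program) {
  c(ws_of_kind(program, "feature"), ws_free_parameters(program),
    ws_of_kind(program, "variable"))
}

# Pick (possibly allocating) a gamma parameter for a transform instruction.
# Returns list(name, workspace) or NULL when impossible.
pick_gamma <- function(program, config) {
  gammas <- ws_gamma_parameters(program)
  n_params <- length(ws_of_kind(program, "parameter"))
  if (n_params < config$param_budget) {
    fresh <- paste0("gamma", length(gammas))
    while (fresh %in% ws_names(program)) fresh <- paste0(fresh, "_")
    ws <- c(program$workspace, list(ws_parameter(fresh, gamma = TRUE)))
    return(list(name = fresh, workspace = ws))
  }
  if (length(gammas)) {
    return(list(name = sample1(gammas), workspace = program$workspace))
  }
  NULL
}

sample_instruction <- function(program, config) {
  op <- sample1(config$allowed_ops)
  out <- sample1(ws_of_kind(program, "variable"))
  args <- legal_arguments(program)
  ws <- program$workspace
  if (op == "pow") {
    ins <- new_instruction("pow", out, sample1(args),
                           exponent = sample1(config$allowed_exponents))
  } else if (op == "gamma_transform") {
    g <- pick_gamma(program, config)
    if (is.null(g)) return(NULL)
    ws <- g$workspace
    ins <- new_instruction("gamma_transform", out, sample1(args),
                           bound_parameter = g$name)
  } else {
    ins <- new_instruction(op, out, c(sample1(args), sample1(args)))
  }
  list(instruction = ins, workspace = ws)
}

#' Apply one mutation rule to a program
#'
#' @param program A valid \code{xc_program}.
#' @param rule One of \code{"insert"}, \code{"remove"}, \code{"change_op"},
#'   \code{"change_arg"}.
#' @param config An \code{\link{mutation_config}}.
#' @return The mutated program, or \code{NULL} when the rule is inapplicable
#'   (remove/change on an empty program, insert at the cap, no alternative
#'   symbol or op available).
#' @export
apply_rule <- function(program, rule, config) {
  n <- length(program$instructions)
  cap <- min(program$max_instructions, config$max_instructions)
  out <- program
  switch(rule,
    insert = {
      if (n >= cap) return(NULL)
      drawn <- sample_instruction(program, config)
      if (is.null(drawn)) return(NULL)
      pos <- sample.int(n + 1L, 1L)  # insert before position pos
      out$workspace <- drawn$workspace
      out$instructions <- append(program$instructions,
                                 list(drawn$instruction), after = pos - 1L)
      out
    },
    remove = {
      if (n == 0L) return(NULL)
      out$instructions <- program$instructions[-sample.int(n, 1L)]
      out
    },
    change_op = {
      if (n == 0L) return(NULL)
      k <- sample.int(n, 1L)
      ins <- program$instructions[[k]]
      arity <- OP_ARITY[[ins$op]]
      cands <- setdiff(config$allowed_ops[OP_ARITY[config$allowed_ops] == arity],
                       ins$op)
      # A power op may also "change op" to a different exponent.
      if (ins$op == "pow" && length(setdiff(config$allowed_exponents,
                                            ins$exponent))) {
        cands <- c(cands, "pow")
      }
      if (!length(cands)) return(NULL)
      op <- sample1(cands)
      if (op == "pow") {
        expo <- if (ins$op == "pow")
          sample1(setdiff(config$allowed_exponents, ins$exponent))
        else sample1(config$allowed_exponents)
        new_ins <- new_instruction("pow", ins$output, ins$inputs[1],
                                   exponent = expo)
      } else if (op == "gamma_transform") {
        g <- pick_gamma(program, config)
        if (is.null(g)) return(NULL)
        out$workspace <- g$workspace
        new_ins <- new_instruction("gamma_transform", ins$output,
                                   ins$inputs[1], bound_parameter = g$name)
      } else {
        inputs <- ins$inputs
        if (length(inputs) < OP_ARITY[[op]]) {
          inputs <- c(inputs, sample1(legal_arguments(program)))
        } else if (length(inputs) > OP_ARITY[[op]]) {
          inputs <- inputs[seq_len(OP_ARITY[[op]])]
        }
        new_ins <- new_instruction(op, ins$output, inputs)
      }
      out$instructions[[k]] <- new_ins
      out
    },
    change_arg = {
      if (n == 0L) return(NULL)
      k <- sample.int(n, 1L)
      ins <- program$instructions[[k]]
      # Slots: output (variables only) and each input (any legal argument).
      slots <- c("output", paste0("input", seq_along(ins$inputs)))
      gammas <- ws_gamma_parameters(program)
      if (!is.null(ins$bound_parameter) && length(gammas) > 1L) {
        slots <- c(slots, "gamma")
      }
      slot <- sample1(slots)
      if (slot == "output") {
        cands <- setdiff(ws_of_kind(program, "variable"), ins$output)
      } else if (slot == "gamma") {
        cands <- setdiff(gammas, ins$bound_parameter)
      } else {
        idx <- as.integer(sub("input", "", slot))
        cands <- setdiff(legal_arguments(program), ins$inputs[idx])
      }
      if (!length(cands)) return(NULL)
      pick <- sample1(cands)
      if (slot == "output") ins$output <- pick
      else if (slot == "gamma") ins$bound_parameter <- pick
      else ins$inputs[as.integer(sub("input", "", slot))] <- pick
      out$instructions[[k]] <- ins
      out
    },
    stop("unknown rule: ", rule))
}

#' Mutate a symbolic functional
#'
#' Chooses one channel uniformly among the mutable channels, draws a mutation
#' rule from the configured weights, and applies it.  Inapplicable draws are
#' resampled up to \code{max_retries}; if nothing applies the parent is
#' returned copied with attribute \code{noop = TRUE}.  The parent is never
#' modified; the child always satisfies \code{\link{validate_program}}.
#'
#' @param parent A valid \code{xc_functional}.
#' @param config An \code{\link{mutation_config}}.
#' @return The child functional, with attribute \code{provenance} recording
#'   the channel and rule applied.
#' @export
mutate_functional <- function(parent, config) {
  channel <- sample1(config$channels)
  prog <- parent$programs[[channel]]
  rules <- names(config$rule_weights)
  for (try in seq_len(config$max_retries)) {
    rule <- if (length(rules) == 1L) rules
            else sample(rules, 1L, prob = config$rule_weights)
    child_prog <- apply_rule(prog, rule, config)
    if (!is.null(child_prog)) {
      v <- validate_program(child_prog)
      if (length(v)) next  # defensive; rules should preserve validity
      child <- parent
      child$programs[[channel]] <- child_prog
      attr(child, "provenance") <- list(channel = channel, rule = rule)
      attr(child, "noop") <- FALSE
      return(child)
    }
  }
  child <- parent
  attr(child, "provenance") <- list(channel = channel, rule = NA_character_)
  attr(child, "noop") <- TRUE
  child
}
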