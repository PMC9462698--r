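# Workspace symbols and instructions: the machine representation of an
# enhancement factor.  A workspace declares features (inputs), parameters
# (scalars fitted to data) and variables (intermediates, all initialized to
# zero); the distinguished variable "F" holds the readout.

# Operation registry.  "mac" is the multiply-accumulate s = s + p*q, the only
# op whose output is also an effective input.  "gamma_transform" is the
# finite-domain building block s = gamma*p / (1 + gamma*p) with gamma a
# parameter bound to the instruction itself.
OP_TAGS <- c("add", "sub", "mul", "div", "mac", "pow", "gamma_transform")

OP_ARITY <- c(add = 2L, sub = 2L, mul = 2L, div = 2L, mac = 2L,
              pow = 1L, gamma_transform = 1L)

# Allowed exponents for the power op, with exact serialization labels.
POW_EXPONENTS <- c(2, 3, 4, 6, 1 / 2, 1 / 3)
POW_LABELS <- c("2", "3", "4", "6", "1/2", "1/3")

exponent_label <- function(exponent) {
  i <- which(abs(POW_EXPONENTS - exponent) < 1e-12)
  if (length(i) != 1L) stop("exponent must be one of 2, 3, 4, 6, 1/2, 1/3")
  POW_LABELS[[i]]
}

exponent_from_label <- function(label) {
  i <- match(label, POW_LABELS)
  if (is.na(i)) stop("unknown exponent label: ", label)
  POW_EXPONENTS[[i]]
}

#' Declare a workspace symbol
#'
#' @param name Identifier, unique within a workspace.
#' @param kind One of \code{"feature"}, \code{"parameter"}, \code{"variable"}.
#' @param gamma For parameters only: \code{TRUE} marks the parameter as a
#'   transform-bound gamma, usable only as the bound parameter of the
#'   finite-domain transform instruction (never as a free argument).
#' @return An \code{xc_symbol} object.
#' @export
ws_symbol <- function(name, kind = c("feature", "parameter", "variable"),
                      gamma = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (gamma && kind != "parameter") stop("only parameters can be gamma-bound")
  structure(list(name = name, kind = kind, gamma = isTRUE(gamma)),
            class = "xc_symbol")
}

#' @rdname ws_symbol
#' @export
ws_feature <- function(name) ws_symbol(name, "feature")

#' @rdname ws_symbol
#' @export
ws_parameter <- function(name, gamma = FALSE) ws_symbol(name, "parameter", gamma)

#' @rdname ws_symbol
#' @export
ws_variable <- function(name) ws_symbol(name, "variable")

#' Build an instruction
#'
#' @param op One of \code{add}, \code{sub}, \code{mul}, \code{div}, \code{mac}
#'   (\code{s = s + p*q}), \code{pow} (\code{s = p^n}), or
#'   \code{gamma_transform} (\code{s = gamma*p/(1 + gamma*p)}).
#' @param output Name of the output variable.
#' @param inputs Character vector of input symbol names (length = op arity).
#' @param exponent For \code{pow}: one of 2, 3, 4, 6, 1/2, 1/3.
#' @param bound_parameter For \code{gamma_transform}: name of the bound gamma
#'   parameter.
#' @return An \code{xc_instruction} object.
#' @export
new_instruction <- function(op, output, inputs, exponent = NULL,
                            bound_parameter = NULL) {
  if (!op %in% OP_TAGS) stop("unknown op: ", op)
  if (op == "pow") exponent_label(exponent) else exponent <- NULL
  if (op == "gamma_transform") {
    stopifnot(is.character(bound_parameter), length(bound_parameter) == 1L)
  } else {
    bound_parameter <- NULL
  }
  structure(list(op = op, output = output, inputs = as.character(inputs),
                 exponent = exponent, bound_parameter = bound_parameter),
            class = "xc_instruction")
}

# Terse constructors used throughout the package and tests.
i_add <- function(s, p, q) new_instruction("add", s, c(p, q))
i_sub <- function(s, p, q) new_instruction("sub", s, c(p, q))
i_mul <- function(s, p, q) new_instruction("mul", s, c(p, q))
i_div <- function(s, p, q) new_instruction("div", s, c(p, q))
i_mac <- function(s, p, q) new_instruction("mac", s, c(p, q))
i_pow <- function(s, p, n) new_instruction("pow", s, p, exponent = n)
i_transform <- function(s, p, gamma)
  new_instruction("gamma_transform", s, p, bound_parameter = gamma)

#' Create an instruction program
#'
#' @param workspace List of \code{\link{ws_symbol}} declarations.  Must contain
#'   a variable named \code{"F"}, the readout.
#' @param instructions List of \code{\link{new_instruction}} objects, executed
#'   in order.
#' @param max_instructions Cap on program length (search-space constraint).
#' @return An \code{xc_program}.
#' @export
new_program <- function(workspace, instructions = list(),
                        max_instructions = 20L) {
  prog <- structure(list(workspace = workspace,
                         instructions = instructions,
                         max_instructions = as.integer(max_instructions)),
                    class = "xc_program")
  prog
}

ws_names <- function(program) {
  vapply(program$workspace, function(s) s$name, character(1))
}

ws_kinds <- function(program) {
  k <- vapply(program$workspace, function(s) s$kind, character(1))
  names(k) <- ws_names(program)
  k
}

ws_of_kind <- function(program, kind, gamma = NA) {
  keep <- vapply(program$workspace, function(s) {
    s$kind == kind && (is.na(gamma) || identical(s$gamma, gamma))
  }, logical(1))
  vapply(program$workspace[keep], function(s) s$name, character(1))
}

# Parameters usable as free instruction arguments (non-gamma).
ws_free_parameters <- function(program) ws_of_kind(program, "parameter", FALSE)
ws_gamma_parameters <- function(program) ws_of_kind(program, "parameter", TRUE)

#' Validate an instruction program
#'
#' Total function returning all invariant violations: undeclared or duplicate
#' symbols, missing readout variable \code{F}, non-variable outputs, arity
#' mismatches, illegal exponents, non-parameter bound gammas, and programs
#' exceeding the instruction cap.
#'
#' @param program An \code{xc_program}.
#' @return Character vector of violations; empty when the program is valid.
#' @export
validate_program <- function(program) {
  v <- character(0)
  nm <- ws_names(program)
  if (anyDuplicated(nm)) {
    v <- c(v, paste0("workspace: duplicate symbol name(s): ",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  kinds <- ws_kinds(program)
  if (!("F" %in% nm) || kinds[["F"]] != "variable") {
    v <- c(v, "workspace: readout variable 'F' missing")
  }
  if (program$max_instructions < 1L) {
    v <- c(v, "max_instructions must be positive")
  }
  if (length(program$instructions) > program$max_instructions) {
    v <- c(v, sprintf("program has %d instructions, cap is %d",
                      length(program$instructions), program$max_instructions))
  }
  for (i in seq_along(program$instructions)) {
    ins <- program$instructions[[i]]
    tag <- function(msg) sprintf("instruction %d: %s", i, msg)
    if (!ins$op %in% OP_TAGS) {
      v <- c(v, tag(paste0("unknown op '", ins$op, "'")))
      next
    }
    if (length(ins$inputs) != OP_ARITY[[ins$op]]) {
      v <- c(v, tag(sprintf("op '%s' needs %d input(s), got %d",
                            ins$op, OP_ARITY[[ins$op]], length(ins$inputs))))
    }
    for (s in unique(c(ins$output, ins$inputs, ins$bound_parameter))) {
      if (!s %in% nm) v <- c(v, tag(paste0("symbol '", s, "' not declared")))
    }
    if (ins$output %in% nm && kinds[[ins$output]] != "variable") {
      v <- c(v, tag(paste0("output '", ins$output, "' is not a variable")))
    }
    if (ins$op == "pow") {
      ok <- !is.null(ins$exponent) &&
        any(abs(POW_EXPONENTS - ins$exponent) < 1e-12)
      if (!ok) v <- c(v, tag("exponent must be one of 2, 3, 4, 6, 1/2, 1/3"))
    }
    if (ins$op == "gamma_transform") {
      bp <- ins$bound_parameter
      if (is.null(bp)) {
        v <- c(v, tag("gamma_transform needs a bound parameter"))
      } else if (bp %in% nm && kinds[[bp]] != "parameter") {
        v <- c(v, tag(paste0("bound parameter '", bp, "' is not a parameter")))
      }
    }
  }
  v
}

assert_valid_program <- function(program) {
  v <- validate_program(program)
  if (length(v)) stop("invalid program:\n  ", paste(v, collapse = "\n  "))
  invisible(program)
}

#' @export
print.xc_program <- function(x, ...) {
  cat(sprintf("<xc_program: %d instruction(s), cap %d>\n",
              length(x$instructions), x$max_instructions))
  kinds <- ws_kinds(x)
  for (k in c("feature", "parameter", "variable")) {
    cat(sprintf("  %-10s %s\n", paste0(k, "s:"),
                paste(names(kinds)[kinds == k], collapse = " ")))
  }
  for (i in seq_along(x$instructions)) {
    cat(sprintf("  [%d] %s\n", i, instruction_text(x$instructions[[i]])))
  }
  invisible(x)
}

instruction_text <- function(ins) {
  a <- ins$inputs[1]
  b <- if (length(ins$inputs) > 1) ins$inputs[2] else NULL
  switch(ins$op,
    add = sprintf("%s <- %s + %s", ins$output, a, b),
    sub = sprintf("%s <- %s - %s", ins$output, a, b),
    mul = sprintf("%s <- %s * %s", ins$output, a, b),
    div = sprintf("%s <- %s / %s", ins$output, a, b),
    mac = sprintf("%s <- %s + %s * %s", ins$output, ins$output, a, b),
    pow = sprintf("%s <- %s^(%s)", ins$output, a, exponent_label(ins$exponent)),
    gamma_transform = sprintf("%s <- %s*%s / (1 + %s*%s)",
                              ins$output, ins$bound_parameter, a,
                              ins$bound_parameter, a))
}
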