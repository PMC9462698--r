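# Human-readable rendering: closed-form expression for the readout F obtained
# by deterministic forward substitution, with light zero-propagation so that
# untouched variables (which are identically zero) do not clutter the output.

render_step <- function(exprs, ins) {
  a <- exprs[[ins$inputs[1]]]
  b <- if (length(ins$inputs) > 1) exprs[[ins$inputs[2]]] else NULL
  z <- function(e) identical(e, "0")
  switch(ins$op,
    add = if (z(a)) b else if (z(b)) a else paste0("(", a, " + ", b, ")"),
    sub = if (z(b)) a else if (z(a)) paste0("(-", b, ")")
          else paste0("(", a, " - ", b, ")"),
    mul = if (z(a) || z(b)) "0" else paste0("(", a, " * ", b, ")"),
    div = if (z(a)) "0" else paste0("(", a, " / ", b, ")"),
    mac = {
      cur <- exprs[[ins$output]]
      term <- if (z(a) || z(b)) "0" else paste0("(", a, " * ", b, ")")
      if (z(term)) cur
      else if (z(cur)) term
      else paste0("(", cur, " + ", term, ")")
    },
    pow = if (z(a)) "0"
          else paste0("(", a, ")^(", exponent_label(ins$exponent), ")"),
    gamma_transform = {
      g <- exprs[[ins$bound_parameter]]
      if (z(a)) "0"
      else paste0("(", g, "*", a, " / (1 + ", g, "*", a, "))")
    })
}

#' Render a program as a closed-form expression
#'
#' Symbolic forward substitution through the instruction list yields a single
#' expression (in R syntax, parseable by \code{\link{evaluate_expression}}) for
#' the readout \code{F}.  Simplification is limited to deterministic zero
#' propagation; the empty program renders to \code{"0"}.
#'
#' @param program A valid \code{xc_program}.
#' @return A single character string.
#' @export
render_expression <- function(program) {
  assert_valid_program(program)
  kinds <- ws_kinds(program)
  exprs <- as.list(ifelse(kinds == "variable", "0", names(kinds)))
  names(exprs) <- names(kinds)
  for (ins in program$instructions) {
    exprs[[ins$output]] <- render_step(exprs, ins)
  }
  exprs[["F"]]
}

#' Numerically evaluate a rendered expression
#'
#' @param expr Expression string as produced by \code{\link{render_expression}}.
#' @param values Named list of feature vectors and parameter scalars.
#' @return Numeric vector.
#' @export
evaluate_expression <- function(expr, values) {
  eval(parse(text = expr)[[1]], envir = as.list(values),
       enclos = baseenv())
}
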