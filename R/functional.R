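# A symbolic functional is a triple of instruction programs, one per
# enhancement factor channel: exchange "x", same-spin correlation "c_ss",
# opposite-spin correlation "c_os".  Parameters with the same name in several
# programs denote one shared scalar.

CHANNELS <- c("x", "c_ss", "c_os")

#' Create a symbolic functional
#'
#' @param x,c_ss,c_os \code{xc_program}s for the exchange, same-spin and
#'   opposite-spin correlation enhancement factors.  Omitted channels default
#'   to the empty program (identically zero enhancement factor).
#' @return An \code{xc_functional}.
#' @export
new_functional <- function(x = NULL, c_ss = NULL, c_os = NULL) {
  progs <- list(x = x %||% minimal_program(),
                c_ss = c_ss %||% minimal_program(),
                c_os = c_os %||% minimal_program())
  structure(list(programs = progs), class = "xc_functional")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smallest legal program: just the readout variable, no instructions.
minimal_program <- function() {
  new_program(list(ws_variable("F")), list(), max_instructions = 20L)
}

#' Parameter names of a functional
#'
#' Union of the parameter symbols declared by the three programs, deduplicated
#' in a stable order (exchange first, then same-spin, then opposite-spin
#' correlation, each in workspace order).
#'
#' @param functional An \code{xc_functional}.
#' @return Character vector.
#' @export
functional_parameters <- function(functional) {
  nms <- unlist(lapply(CHANNELS, function(ch) {
    ws_of_kind(functional$programs[[ch]], "parameter")
  }), use.names = FALSE)
  unique(nms)
}

# Parameters that actually influence the output: those referenced (as free
# arguments or bound gammas) by instructions in the backward slice of F.
active_parameters <- function(functional) {
  nms <- unlist(lapply(CHANNELS, function(ch) {
    prog <- canonicalize(functional$programs[[ch]])
    kinds <- ws_kinds(prog)
    refs <- unlist(lapply(prog$instructions, function(ins) {
      c(ins$inputs, ins$bound_parameter)
    }), use.names = FALSE)
    refs[!is.na(match(refs, names(kinds))) & kinds[refs] == "parameter"]
  }), use.names = FALSE)
  unique(nms)
}

#' @export
print.xc_functional <- function(x, ...) {
  cat("<xc_functional>\n")
  for (ch in CHANNELS) {
    cat(sprintf("$%s: F = %s\n", ch, render_expression(x$programs[[ch]])))
  }
  invisible(x)
}

validate_functional <- function(functional) {
  unlist(lapply(CHANNELS, function(ch) {
    v <- validate_program(functional$programs[[ch]])
    if (length(v)) paste0("[", ch, "] ", v) else character(0)
  }), use.names = FALSE)
}

assert_valid_functional <- function(functional) {
  v <- validate_functional(functional)
  if (length(v)) stop("invalid functional:\n  ", paste(v, collapse = "\n  "))
  invisible(functional)
}
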