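# Lossless JSON serialization of programs and functionals.  Exponents are
# serialized by exact label ("1/2", "1/3") so round trips never lose
# precision.

program_to_list <- function(program) {
  list(
    workspace = lapply(program$workspace, function(s) {
      out <- list(name = s$name, kind = s$kind)
      if (isTRUE(s$gamma)) out$gamma <- TRUE
      out
    }),
    instructions = lapply(program$instructions, function(ins) {
      out <- list(op = ins$op, output = ins$output,
                  inputs = as.list(ins$inputs))
      if (!is.null(ins$exponent)) out$exponent <- exponent_label(ins$exponent)
      if (!is.null(ins$bound_parameter)) out$bound_parameter <- ins$bound_parameter
      out
    }),
    max_instructions = program$max_instructions
  )
}

program_from_list <- function(x) {
  ws <- lapply(x$workspace, function(s) {
    ws_symbol(s$name, s$kind, gamma = isTRUE(s$gamma))
  })
  ins <- lapply(x$instructions, function(i) {
    new_instruction(i$op, i$output, unlist(i$inputs),
                    exponent = if (!is.null(i$exponent))
                      exponent_from_label(i$exponent),
                    bound_parameter = i$bound_parameter)
  })
  new_program(ws, ins, max_instructions = x$max_instructions)
}

#' Serialize a program or functional to JSON
#'
#' @param program An \code{xc_program}.
#' @param functional An \code{xc_functional}.
#' @param params Optional named numeric vector of parameter values stored
#'   alongside the functional.
#' @return A JSON string.
#' @export
program_to_json <- function(program) {
  jsonlite::toJSON(program_to_list(program), auto_unbox = TRUE, digits = NA)
}

#' @rdname program_to_json
#' @export
program_from_json <- function(json) {
  program_from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
}

#' @rdname program_to_json
#' @export
functional_to_json <- function(functional, params = NULL) {
  x <- list(programs = lapply(functional$programs, program_to_list))
  if (!is.null(params)) x$params <- as.list(params)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname program_to_json
#' @export
functional_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fun <- new_functional(x = program_from_list(x$programs$x),
                        c_ss = program_from_list(x$programs$c_ss),
                        c_os = program_from_list(x$programs$c_os))
  params <- if (!is.null(x$params)) unlist(x$params) else NULL
  list(functional = fun, params = params)
}

#' Read/write a functional JSON file
#'
#' @param functional An \code{xc_functional}; \code{params} optional values.
#' @param path File path.
#' @export
write_functional <- function(functional, path, params = NULL) {
  writeLines(functional_to_json(functional, params), path)
  invisible(path)
}

#' @rdname write_functional
#' @export
read_functional <- function(path) {
  functional_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
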