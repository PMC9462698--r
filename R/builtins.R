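# Published enhancement factors, both as directly evaluable closed forms and
# as instruction-program encodings (the two representations cross-check each
# other in the test suite).

#' Coefficient tables shipped with the package
#'
#' Versioned JSON data files: the semilocal power-series coefficients of
#' omegaB97M-V (transcribed from its original publication) and the published
#' GAS22 closed form.
#'
#' @return Nested list mirroring the JSON file.
#' @export
wb97mv_coefficients <- function() {
  jsonlite::fromJSON(system.file("extdata", "wb97mv_coefficients.json",
                                 package = "xcevo"),
                     simplifyVector = TRUE)
}

#' @rdname wb97mv_coefficients
#' @export
gas22_coefficients <- function() {
  jsonlite::fromJSON(system.file("extdata", "gas22_coefficients.json",
                                 package = "xcevo"),
                     simplifyVector = TRUE)
}

# Term subsets (as "ij" labels for c_ij w^i u^j) selected per channel in
# omegaB97M-V; coefficients outside these subsets are rejected.
WB97MV_TERMS <- list(
  x = c("00", "10", "01"),
  c_ss = c("00", "10", "20", "43", "04"),
  c_os = c("00", "10", "20", "60", "21", "61")
)

#' B97-family enhancement factors (closed forms)
#'
#' \code{b97_enhancement} is \code{c0 + c1 u + c2 u^2} with
#' \code{u = gamma*x2/(1 + gamma*x2)}.  \code{eq5_enhancement} is the
#' re-parameterized equivalent family \code{c0^2 + c1 (c2 + u)^2};
#' \code{expand_to_b97} maps its coefficients onto the B97 ones
#' (\code{b0 = c0^2 + c1 c2^2}, \code{b1 = 2 c1 c2}, \code{b2 = c1}).
#'
#' @param x2 Squared reduced density gradient.
#' @param c0,c1,c2 Scalar coefficients.
#' @param gamma Transform parameter (>= 0).
#' @return Numeric vector (or for \code{expand_to_b97} a named vector
#'   \code{b0, b1, b2}).
#' @export
b97_enhancement <- function(x2, c0, c1, c2, gamma) {
  u <- u_transform(x2, gamma)
  c0 + c1 * u + c2 * u^2
}

#' @rdname b97_enhancement
#' @export
eq5_enhancement <- function(x2, c0, c1, c2, gamma) {
  u <- u_transform(x2, gamma)
  c0^2 + c1 * (c2 + u)^2
}

#' @rdname b97_enhancement
#' @export
expand_to_b97 <- function(c0, c1, c2) {
  c(b0 = c0^2 + c1 * c2^2, b1 = 2 * c1 * c2, b2 = c1)
}

#' omegaB97M-V power-series enhancement factor (closed form)
#'
#' \code{sum_ij c_ij w^i u^j} over the channel's fixed term subset.
#'
#' @param kind Channel: \code{"x"}, \code{"c_ss"} or \code{"c_os"}.
#' @param u Finite-domain transformed gradient feature in \code{[0, 1)}.
#' @param w Kinetic-energy-density feature in \code{[-1, 1]}.
#' @param coefficients Named vector of \code{c_ij} keyed by \code{"ij"}
#'   labels; defaults to the shipped table.  Labels outside the channel's
#'   subset are an error.
#' @return Numeric vector.
#' @export
wb97mv_enhancement <- function(kind = c("x", "c_ss", "c_os"), u, w,
                               coefficients = NULL) {
  kind <- match.arg(kind)
  if (is.null(coefficients)) {
    coefficients <- unlist(wb97mv_coefficients()$coefficients[[kind]])
  }
  allowed <- WB97MV_TERMS[[kind]]
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad)) {
    stop("coefficient(s) outside the ", kind, " term subset: ",
         paste(bad, collapse = ", "))
  }
  out <- 0 * (u + w)
  for (lab in names(coefficients)) {
    i <- as.integer(substr(lab, 1, 1))
    j <- as.integer(substr(lab, 2, 2))
    out <- out + coefficients[[lab]] * w^i * u^j
  }
  out
}

#' GAS22 enhancement factors (closed forms)
#'
#' The published forms: \code{F_x = 0.862 + 0.937 u + 0.318 w} (gamma =
#' 0.00384), \code{F_c_ss = u - 4.108 w - 5.242 w^2 - 1.766 u^6 +
#' 7.538 w^4 u^6} (gamma = 0.469), and \code{F_c_os = 0.805 + 7.989 w^2 -
#' 7.548 w^6 + 2.001 w^6 x^(3/2) - 1.761 w^2 x^(3/2)}.  The exponent of the
#' novel \code{x} term in the opposite-spin channel defaults to 3/2 and is
#' configurable through the coefficient table.
#'
#' @param kind Channel: \code{"x"}, \code{"c_ss"} or \code{"c_os"}.
#' @param x Reduced density gradient (needed for \code{c_os}); derived from
#'   \code{x2} when omitted.
#' @param x2 Squared reduced density gradient.
#' @param w Kinetic-energy-density feature.
#' @param coefs Coefficient table; defaults to the shipped
#'   \code{\link{gas22_coefficients}}.
#' @return Numeric vector.
#' @export
gas22_enhancement <- function(kind = c("x", "c_ss", "c_os"), x = NULL,
                              x2 = NULL, w = 0, coefs = NULL) {
  kind <- match.arg(kind)
  if (is.null(coefs)) coefs <- gas22_coefficients()
  if (is.null(x2)) {
    if (is.null(x)) stop("supply x or x2")
    x2 <- x^2
  }
  if (is.null(x)) x <- sqrt(x2)
  cc <- coefs$coefficients[[kind]]
  switch(kind,
    x = {
      u <- u_transform(x2, coefs$gamma$x)
      cc$c0 + cc$c_u * u + cc$c_w * w
    },
    c_ss = {
      u <- u_transform(x2, coefs$gamma$c_ss)
      cc$c_u * u + cc$c_w * w + cc$c_w2 * w^2 + cc$c_u6 * u^6 +
        cc$c_w4u6 * w^4 * u^6
    },
    c_os = {
      xp <- x^coefs$x_exponent
      cc$c0 + cc$c_w2 * w^2 + cc$c_w6 * w^6 + cc$c_w6x * w^6 * xp +
        cc$c_w2x * w^2 * xp
    })
}

# ---------------------------------------------------------------------------
# Instruction-program encodings

#' Program encoding of the B97 enhancement factor
#'
#' The canonical five-instruction encoding: finite-domain transform, linear
#' accumulate, square, quadratic accumulate, constant shift.  The workspace is
#' one feature (\code{x2}), four parameters (\code{c0}, \code{c1}, \code{c2}
#' free; \code{gamma0} bound to the transform) and three variables.
#'
#' @param max_instructions Instruction cap (default 6, the proof-of-principle
#'   search-space cap).
#' @return An \code{xc_program}.
#' @export
b97_program <- function(max_instructions = 6L) {
  new_program(
    workspace = list(ws_feature("x2"),
                     ws_parameter("c0"), ws_parameter("c1"),
                     ws_parameter("c2"), ws_parameter("gamma0", gamma = TRUE),
                     ws_variable("v0"), ws_variable("v1"), ws_variable("F")),
    instructions = list(
      i_transform("v0", "x2", "gamma0"),
      i_mac("F", "c1", "v0"),
      i_pow("v1", "v0", 2),
      i_mac("F", "c2", "v1"),
      i_add("F", "F", "c0")),
    max_instructions = max_instructions)
}

#' @rdname b97_program
#' @export
b97_functional <- function(c0 = 0.8094, c1 = 0.5073, c2 = 0.7481,
                           gamma = 0.004) {
  list(functional = new_functional(x = b97_program()),
       params = c(c0 = c0, c1 = c1, c2 = c2, gamma0 = gamma))
}

#' Program encoding of the re-parameterized B97-equivalent family
#'
#' Six instructions evaluating \code{c0^2 + c1 (c2 + u)^2}.
#'
#' @return An \code{xc_program}.
#' @export
eq5_program <- function() {
  new_program(
    workspace = list(ws_feature("x2"),
                     ws_parameter("c0"), ws_parameter("c1"),
                     ws_parameter("c2"), ws_parameter("gamma0", gamma = TRUE),
                     ws_variable("v0"), ws_variable("v1"), ws_variable("F")),
    instructions = list(
      i_transform("v0", "x2", "gamma0"),
      i_add("v0", "c2", "v0"),
      i_pow("v0", "v0", 2),
      i_mac("F", "c1", "v0"),
      i_pow("v1", "c0", 2),
      i_add("F", "F", "v1")),
    max_instructions = 6L)
}

# Build the instruction list for one power-series term c_ij w^i u^j.
# `usym` is the symbol holding u, `cpar` the coefficient parameter.
power_term_instructions <- function(i, j, cpar, usym) {
  pw <- function(out, sym, n) {
    if (n == 1) return(list(sym = sym, ins = list()))
    list(sym = out, ins = list(i_pow(out, sym, n)))
  }
  if (i == 0 && j == 0) return(list(i_add("F", "F", cpar)))
  ins <- list()
  parts <- character(0)
  if (i > 0) {
    p <- pw("t_w", "w", i)
    ins <- c(ins, p$ins); parts <- c(parts, p$sym)
  }
  if (j > 0) {
    p <- pw("t_u", usym, j)
    ins <- c(ins, p$ins); parts <- c(parts, p$sym)
  }
  if (length(parts) == 2) {
    ins <- c(ins, list(i_mul("t_w", parts[1], parts[2])))
    operand <- "t_w"
  } else {
    operand <- parts
  }
  c(ins, list(i_mac("F", cpar, operand)))
}

#' Program encoding of an omegaB97M-V enhancement factor
#'
#' Encodes the channel's power series \code{sum c_ij w^i u^j} in elementary
#' instructions.  With \code{on = "u"} the transformed gradient \code{u} is a
#' direct input feature (the exchange channel then needs only three
#' instructions); with \code{on = "x2"} the program opens with the
#' finite-domain transform using the channel's gamma parameter.
#'
#' @param kind Channel.
#' @param on Feature basis: \code{"x2"} (transform in-program) or \code{"u"}.
#' @param prefix Prefix for parameter names (used to keep channels of a full
#'   functional from sharing coefficients).
#' @return List with \code{program} and \code{params} (default values from
#'   the shipped table).
#' @export
wb97mv_program <- function(kind = c("x", "c_ss", "c_os"), on = c("x2", "u"),
                           prefix = "") {
  kind <- match.arg(kind)
  on <- match.arg(on)
  tab <- wb97mv_coefficients()
  cc <- unlist(tab$coefficients[[kind]])
  par <- function(lab) paste0(prefix, "c", lab)
  gpar <- paste0(prefix, "gamma")

  params <- setNames(as.numeric(cc), vapply(names(cc), par, character(1)))
  ws <- list(ws_feature("w"))
  ins <- list()
  if (on == "x2") {
    ws <- c(ws, list(ws_feature("x2")))
    usym <- "t_transform"
    ins <- list(i_transform(usym, "x2", gpar))
    params[[gpar]] <- tab$gamma[[kind]]
  } else {
    ws <- c(ws, list(ws_feature("u")))
    usym <- "u"
  }
  for (lab in names(cc)) {
    i <- as.integer(substr(lab, 1, 1))
    j <- as.integer(substr(lab, 2, 2))
    ins <- c(ins, power_term_instructions(i, j, par(lab), usym))
  }
  vars <- intersect(c("t_transform", "t_w", "t_u"),
                    unlist(lapply(ins, function(x) c(x$output, x$inputs))))
  ws <- c(ws,
          lapply(setdiff(names(params), gpar), ws_parameter),
          if (on == "x2") list(ws_parameter(gpar, gamma = TRUE)),
          lapply(vars, ws_variable),
          list(ws_variable("F")))
  list(program = new_program(ws, ins,
                             max_instructions = max(16L, length(ins))),
       params = params)
}

#' @rdname wb97mv_program
#' @export
wb97mv_functional <- function() {
  px <- wb97mv_program("x", on = "x2", prefix = "x_")
  pss <- wb97mv_program("c_ss", on = "x2", prefix = "ss_")
  pos <- wb97mv_program("c_os", on = "x2", prefix = "os_")
  list(functional = new_functional(x = px$program, c_ss = pss$program,
                                   c_os = pos$program),
       params = c(px$params, pss$params, pos$params))
}

#' Program encoding of the GAS22 enhancement factors
#'
#' @return List with \code{functional} and \code{params} holding the
#'   published coefficient values.
#' @export
gas22_functional <- function() {
  coefs <- gas22_coefficients()
  if (abs(coefs$x_exponent - 1.5) > 1e-12) {
    stop("the instruction encoding supports x_exponent = 3/2 only")
  }
  px <- new_program(
    workspace = list(ws_feature("x2"), ws_feature("w"),
                     ws_parameter("x_c0"), ws_parameter("x_cu"),
                     ws_parameter("x_cw"),
                     ws_parameter("x_gamma", gamma = TRUE),
                     ws_variable("v0"), ws_variable("F")),
    instructions = list(
      i_transform("v0", "x2", "x_gamma"),
      i_mac("F", "x_cu", "v0"),
      i_mac("F", "x_cw", "w"),
      i_add("F", "F", "x_c0")),
    max_instructions = 6L)
  pss <- new_program(
    workspace = list(ws_feature("x2"), ws_feature("w"),
                     ws_parameter("ss_cu"), ws_parameter("ss_cw"),
                     ws_parameter("ss_cw2"), ws_parameter("ss_cu6"),
                     ws_parameter("ss_cw4u6"),
                     ws_parameter("ss_gamma", gamma = TRUE),
                     ws_variable("v0"), ws_variable("v1"), ws_variable("F")),
    instructions = list(
      i_transform("v0", "x2", "ss_gamma"),
      i_mac("F", "ss_cu", "v0"),
      i_mac("F", "ss_cw", "w"),
      i_pow("v1", "w", 2),
      i_mac("F", "ss_cw2", "v1"),
      i_pow("v1", "v1", 2),
      i_pow("v0", "v0", 6),
      i_mac("F", "ss_cu6", "v0"),
      i_mul("v1", "v1", "v0"),
      i_mac("F", "ss_cw4u6", "v1")),
    max_instructions = 12L)
  pos <- new_program(
    workspace = list(ws_feature("x"), ws_feature("w"),
                     ws_parameter("os_c0"), ws_parameter("os_cw2"),
                     ws_parameter("os_cw6"), ws_parameter("os_cw6x"),
                     ws_parameter("os_cw2x"),
                     ws_variable("v0"), ws_variable("v1"), ws_variable("v2"),
                     ws_variable("F")),
    instructions = list(
      i_pow("v0", "w", 2),
      i_mac("F", "os_cw2", "v0"),
      i_pow("v1", "v0", 3),
      i_mac("F", "os_cw6", "v1"),
      i_pow("v2", "x", 1 / 2),
      i_mul("v2", "v2", "x"),
      i_mul("v1", "v1", "v2"),
      i_mac("F", "os_cw6x", "v1"),
      i_mul("v0", "v0", "v2"),
      i_mac("F", "os_cw2x", "v0"),
      i_add("F", "F", "os_c0")),
    max_instructions = 12L)
  cx <- coefs$coefficients$x
  css <- coefs$coefficients$c_ss
  cos_ <- coefs$coefficients$c_os
  list(functional = new_functional(x = px, c_ss = pss, c_os = pos),
       params = c(x_c0 = cx$c0, x_cu = cx$c_u, x_cw = cx$c_w,
                  x_gamma = coefs$gamma$x,
                  ss_cu = css$c_u, ss_cw = css$c_w, ss_cw2 = css$c_w2,
                  ss_cu6 = css$c_u6, ss_cw4u6 = css$c_w4u6,
                  ss_gamma = coefs$gamma$c_ss,
                  os_c0 = cos_$c0, os_cw2 = cos_$c_w2, os_cw6 = cos_$c_w6,
                  os_cw6x = cos_$c_w6x, os_cw2x = cos_$c_w2x))
}
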