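# Grid-point features of the electron density used by meta-GGA enhancement
# factors, all for the spin-unpolarized formalism.

#' Finite-domain transform of the squared reduced density gradient
#'
#' \code{u = gamma*x2 / (1 + gamma*x2)}, mapping \code{[0, Inf)} to
#' \code{[0, 1)} for \code{gamma > 0}.
#'
#' @param x2 Squared reduced density gradient (dimensionless, >= 0).
#' @param gamma Transform parameter (>= 0).
#' @return Numeric vector.
#' @export
u_transform <- function(x2, gamma) {
  g <- gamma * x2
  g / (1 + g)
}

#' Compute density features at grid points
#'
#' From the density \code{rho} and either the gradient norm \code{|grad rho|}
#' or the squared reduced gradient \code{x2} directly, derives the reduced
#' density gradient \code{x = 2^(1/3) |grad rho| / rho^(4/3)}, its
#' conventional rescaling \code{s = x / (2 (3 pi^2)^(1/3))}, the Wigner-Seitz
#' radius \code{rs = (3 / (4 pi rho))^(1/3)}, and (when \code{gamma} is given)
#' the finite-domain transform \code{u}.  The bounded kinetic-energy-density
#' feature \code{w} in \code{[-1, 1]} is taken as a direct input.
#'
#' @param rho Electron density (a.u.), strictly positive.
#' @param grad_norm Gradient norm \code{|grad rho|} (a.u.); alternative to
#'   \code{x2}.
#' @param x2 Squared reduced density gradient; alternative to
#'   \code{grad_norm}.
#' @param w Kinetic-energy-density feature in \code{[-1, 1]} (default 0).
#' @param gamma Optional transform parameter; when supplied, \code{u} is
#'   included.
#' @return Named list of feature vectors (class \code{xc_features}).
#' @export
compute_features <- function(rho, grad_norm = NULL, x2 = NULL, w = 0,
                             gamma = NULL) {
  if (any(rho <= 0)) stop("rho must be strictly positive")
  if (is.null(x2)) {
    if (is.null(grad_norm)) stop("supply either grad_norm or x2")
    x <- 2^(1 / 3) * abs(grad_norm) / rho^(4 / 3)
    x2 <- x^2
  } else {
    if (any(x2 < 0)) stop("x2 must be non-negative")
    x <- sqrt(x2)
  }
  n <- max(length(rho), length(x2))
  out <- list(rho = rep_len(rho, n), x = rep_len(x, n), x2 = rep_len(x2, n),
              s = rep_len(x / (2 * (3 * pi^2)^(1 / 3)), n),
              rs = rep_len((3 / (4 * pi * rho))^(1 / 3), n),
              w = rep_len(w, n))
  if (!is.null(gamma)) out$u <- u_transform(out$x2, gamma)
  structure(out, class = c("xc_features", "list"))
}

# Inverse maps used to lay out enhancement-factor diagnostic grids.
s_to_x <- function(s) 2 * (3 * pi^2)^(1 / 3) * s
rs_to_rho <- function(rs) 3 / (4 * pi * rs^3)

#' Optional adapter from kinetic energy density tau to the bounded feature w
#'
#' \code{w = (t - 1)/(t + 1)} with \code{t = tau_LDA / tau} and
#' \code{tau_LDA = (3/10) (3 pi^2)^(2/3) rho^(5/3)}.  Provided for
#' convenience; the package otherwise treats \code{w} as a direct input.
#'
#' @param rho Electron density (a.u.).
#' @param tau Kinetic energy density (a.u.), positive.
#' @return Numeric vector in \code{[-1, 1]}.
#' @export
w_from_tau <- function(rho, tau) {
  tau_lda <- (3 / 10) * (3 * pi^2)^(2 / 3) * rho^(5 / 3)
  t <- tau_lda / tau
  (t - 1) / (t + 1)
}

#' LDA energy densities (exchange plus a surrogate correlation split)
#'
#' Exchange is the full-range LDA form
#' \code{e_x = -(3/4) (3/pi)^(1/3) rho^(4/3)}.  The same-spin/opposite-spin
#' correlation split is a deliberately simple, non-physical analytic
#' surrogate, \code{e_c = -coef * rho^(4/3)}: the search and fitting machinery
#' only require a fixed, smooth, negative energy-density kernel, and any
#' provider with this signature can be plugged into
#' \code{\link{exc_semilocal}} in its place.
#'
#' @param rho Electron density (a.u.), strictly positive.
#' @param c_ss_coef,c_os_coef Surrogate correlation prefactors.
#' @return List with components \code{e_x}, \code{e_c_ss}, \code{e_c_os}.
#' @export
lda_energy_densities <- function(rho, c_ss_coef = 0.02, c_os_coef = 0.06) {
  if (any(rho <= 0)) stop("rho must be strictly positive")
  r43 <- rho^(4 / 3)
  list(e_x = LDA_X_COEF * r43,
       e_c_ss = -c_ss_coef * r43,
       e_c_os = -c_os_coef * r43)
}
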