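# Non-self-consistent semilocal exchange-correlation energies: quadrature of
# LDA energy densities scaled by the three enhancement factors on fixed grids.

#' Create a grid system
#'
#' A "system" is a molecule stand-in: per-point density features and
#' quadrature weights on which the semilocal XC energy is evaluated.
#'
#' @param label System identifier.
#' @param rho Per-point electron density (> 0).
#' @param x2 Per-point squared reduced density gradient (>= 0).
#' @param w Per-point kinetic-energy-density feature in \code{[-1, 1]}.
#' @param quad_weights Per-point quadrature weights (>= 0).
#' @return An \code{xc_grid_system}.
#' @export
new_grid_system <- function(label, rho, x2, w, quad_weights) {
  n <- length(rho)
  stopifnot(length(x2) == n, length(w) == n, length(quad_weights) == n,
            all(rho > 0), all(x2 >= 0), all(quad_weights >= 0))
  structure(list(label = label, rho = rho, x2 = x2, w = w,
                 quad_weights = quad_weights),
            class = "xc_grid_system")
}

system_features <- function(system) {
  f <- compute_features(system$rho, x2 = system$x2, w = system$w)
  unclass(f)
}

#' Semilocal XC energy of a system under a symbolic functional
#'
#' Discretized quadrature
#' \code{sum_p q_p (e_x F_x + e_c_ss F_c_ss + e_c_os F_c_os)} with the LDA
#' energy densities supplied by a pluggable provider.  An invalid program
#' evaluation (non-finite intermediate) yields \code{valid = FALSE} rather
#' than an error.
#'
#' @param system An \code{xc_grid_system}.
#' @param functional An \code{xc_functional}.
#' @param params Named numeric vector covering the functional's parameters.
#' @param lda Energy-density provider with the signature of
#'   \code{\link{lda_energy_densities}}.
#' @return List with \code{energy} (hartree) and \code{valid}.
#' @export
exc_semilocal <- function(system, functional, params,
                          lda = lda_energy_densities) {
  feats <- system_features(system)
  dens <- lda(system$rho)
  total <- 0
  dens_by_channel <- list(x = dens$e_x, c_ss = dens$e_c_ss,
                          c_os = dens$e_c_os)
  for (ch in CHANNELS) {
    res <- execute_program(functional$programs[[ch]], feats, params,
                           n = length(system$rho))
    if (!res$valid) return(list(energy = NA_real_, valid = FALSE))
    total <- total + sum(system$quad_weights * dens_by_channel[[ch]] *
                           res$values)
  }
  list(energy = total, valid = TRUE)
}

#' Combined XC enhancement factor
#'
#' The pointwise ratio of the semilocal XC energy density to its LDA value,
#' \code{F_xc = (e_x F_x + e_c_ss F_c_ss + e_c_os F_c_os) /
#' (e_x + e_c_ss + e_c_os)}, used to visualize how a functional deviates from
#' LDA across density regimes.
#'
#' @param features Named list with at least \code{rho}, \code{x2}, \code{w}
#'   (e.g. from \code{\link{compute_features}}).
#' @param functional An \code{xc_functional}.
#' @param params Named parameter values.
#' @param lda Energy-density provider.
#' @return List with \code{fxc} (numeric, \code{NA} where invalid) and
#'   \code{valid}.
#' @export
combined_fxc <- function(features, functional, params,
                         lda = lda_energy_densities) {
  n <- length(features$rho)
  feats <- unclass(compute_features(features$rho, x2 = features$x2,
                                    w = features$w))
  dens <- lda(feats$rho)
  num <- 0
  dens_by_channel <- list(x = dens$e_x, c_ss = dens$e_c_ss,
                          c_os = dens$e_c_os)
  for (ch in CHANNELS) {
    res <- execute_program(functional$programs[[ch]], feats, params, n = n)
    if (!res$valid) return(list(fxc = rep(NA_real_, n), valid = FALSE))
    num <- num + dens_by_channel[[ch]] * res$values
  }
  den <- dens$e_x + dens$e_c_ss + dens$e_c_os
  bad <- den == 0
  fxc <- ifelse(bad, NA_real_, num / den)
  list(fxc = fxc, valid = !any(bad))
}

#' Tabulate F_xc over a diagnostic grid
#'
#' Evaluates \code{\link{combined_fxc}} on a regular grid in the rescaled
#' gradient \code{s}, the Wigner-Seitz radius \code{rs} and the bonding
#' feature \code{w}, the conventional axes for comparing functionals.
#'
#' @param functional An \code{xc_functional}; \code{params} its values.
#' @param params Named parameter values.
#' @param s Grid of rescaled gradients (normal systems have s in [0, 3]).
#' @param rs Wigner-Seitz radii (> 0); large rs = low density.
#' @param w Bonding-character features (-1 weak, 0 metallic, 1 covalent).
#' @param lda Energy-density provider.
#' @return data.frame with columns \code{s}, \code{rs}, \code{w}, \code{fxc}.
#' @export
fxc_curves <- function(functional, params, s = seq(0, 3, length.out = 100),
                       rs = c(0.5, 1, 2, 3, 5), w = c(-1, 0, 1),
                       lda = lda_energy_densities) {
  grid <- expand.grid(s = s, rs = rs, w = w, KEEP.OUT.ATTRS = FALSE)
  x <- s_to_x(grid$s)
  feats <- list(rho = rs_to_rho(grid$rs), x2 = x^2, w = grid$w)
  res <- combined_fxc(feats, functional, params, lda = lda)
  grid$fxc <- res$fxc
  grid
}
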