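#' DPD pair-interaction parameters
#'
#' Bundles the reduced-unit interaction table of the model: the maximal
#' conservative repulsion \eqn{a_{ij}} by species pair, the friction
#' coefficient \eqn{\beta} shared by all pairs, thermal energy \eqn{k_B T},
#' timestep \eqn{\Delta t} and the integrator mixing parameter \eqn{\lambda}.
#' The random-force amplitude is always \eqn{\sqrt{2\beta k_B T/\Delta t}}
#' (fluctuation--dissipation); it is derived, never set.
#'
#' Defaults are the standard water/glycocalyx set: `a_ww = 25`,
#' `a_gw = 26.3`, `a_gg = 30` (glycocalyx--glycocalyx, including cross terms
#' between endothelial and red-blood-cell chains), `beta = 4.5`,
#' `kBT = 1`, `dt = 0.001` tau.
#'
#' @param a_ww,a_gw,a_gg conservative repulsion maxima (reduced force units).
#' @param beta pair friction coefficient (all pairs).
#' @param kBT thermal energy (reduced); the thermostat target.
#' @param dt integration timestep in tau.
#' @param lambda Groot--Warren velocity-prediction factor.
#' @param a_wall soft wall repulsion amplitude; defaults to `a_ww`.
#' @param exclude_12 if `TRUE`, directly bonded bead pairs are excluded from
#'   the non-bonded (conservative/dissipative/random) pair forces. Default
#'   `FALSE`: all pairs within the cutoff interact.
#' @param body_force uniform body force applied to free water beads
#'   (length-3, reduced force units); used to drive flow in the
#'   two-compartment model.
#'
#' @return An object of class `dpd_params`.
#' @examples
#' p <- dpd_params()
#' p$a["water", "eg_bead"]   # 26.3
#' @export
dpd_params <- function(a_ww = 25, a_gw = 26.3, a_gg = 30,
                       beta = 4.5, kBT = 1, dt = 0.001, lambda = 0.65,
                       a_wall = a_ww, exclude_12 = FALSE,
                       body_force = c(0, 0, 0)) {
  stopifnot(beta > 0, kBT > 0, dt > 0, length(body_force) == 3)
  a <- matrix(c(a_ww, a_gw, a_gw,
                a_gw, a_gg, a_gg,
                a_gw, a_gg, a_gg), 3, 3,
              dimnames = list(names(.SPECIES), names(.SPECIES)))
  structure(list(a = a, beta = beta, kBT = kBT, dt = dt, lambda = lambda,
                 a_wall = a_wall, exclude_12 = exclude_12,
                 body_force = as.numeric(body_force),
                 sigma = sqrt(2 * beta * kBT / dt)),
            class = "dpd_params")
}

#' @export
print.dpd_params <- function(x, ...) {
  cat("<dpd_params> reduced units\n")
  cat("  a_ww =", x$a[1, 1], " a_gw =", x$a[1, 2], " a_gg =", x$a[2, 2], "\n")
  cat("  beta =", x$beta, " kBT =", x$kBT, " dt =", x$dt,
      " lambda =", x$lambda, "\n")
  cat("  random amplitude sigma =", format(x$sigma), "\n")
  invisible(x)
}
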