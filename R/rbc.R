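#' Rigid-cylinder red-blood-cell geometry
#'
#' The propulsion estimates idealise the red cell as a rigid cylinder of
#' radius `R` and thickness `d`. The outline area is taken as
#' `A = pi R^2 d` following the source model; note that this expression has
#' volume (not area) dimensions -- it is kept as defined, and a warning
#' documents the discrepancy once per construction. The longitudinal moment
#' of inertia is `J_L = m R^2 / 2`.
#'
#' @param R radius.
#' @param d thickness.
#' @param mass cell mass.
#' @param quiet suppress the dimensional-consistency note.
#' @return An `rbc_geometry` list with derived `A` and `J_L`.
#' @export
rbc_geometry <- function(R, d, mass, quiet = FALSE) {
  stopifnot(R > 0, d > 0, mass > 0)
  if (!quiet)
    rlang::inform(
      "note: outline area A = pi R^2 d as defined in the source model has volume dimensions",
      .frequency = "once", .frequency_id = "glycodpd_area_note")
  structure(list(R = R, d = d, mass = mass,
                 A = pi * R^2 * d, J_L = mass * R^2 / 2),
            class = "rbc_geometry")
}

#' Longitudinal acceleration of the red cell
#'
#' Newtonian response to the wall shear stress induced by the moving brush:
#' \eqn{a_{RBC} = f_L A / m_{RBC}}.
#'
#' @param f_L wall shear stress (force / area units consistent with `geom`).
#' @param geom an [rbc_geometry()].
#' @return Acceleration (same unit system).
#' @export
rbc_acceleration <- function(f_L, geom) {
  stopifnot(inherits(geom, "rbc_geometry"))
  f_L * geom$A / geom$mass
}

#' Angular response of the red cell
#'
#' Torque balance about the longitudinal axis: the angular shear stress
#' `f_AN` acting on the outline produces a moment \eqn{M = R f_{AN} A} and
#' an angular acceleration \eqn{M / J_L} (`form = "torque"`, the default,
#' dimensionally consistent). The source model's printed rearrangement
#' \eqn{w_{AN} = (J_L/R) f_{AN} A} is exposed read-only for comparison
#' (`form = "printed"`); it is dimensionally inconsistent and never used in
#' derived quantities.
#'
#' @param f_AN angular wall shear stress.
#' @param geom an [rbc_geometry()].
#' @param form `"torque"` or `"printed"`.
#' @return Angular acceleration (torque form) or the printed expression's
#'   value.
#' @export
rbc_angular_response <- function(f_AN, geom, form = c("torque", "printed")) {
  form <- match.arg(form)
  stopifnot(inherits(geom, "rbc_geometry"))
  if (geom$J_L <= 0) abort("zero moment of inertia")
  if (form == "torque") geom$R * f_AN * geom$A / geom$J_L
  else geom$J_L / geom$R * f_AN * geom$A
}

# ---------------------------------------------------------------------------
# physical unit mapping

#' Reduced-to-physical unit map
#'
#' The physical anchoring of the reduced unit system: `r_c = 0.5` nm sets
#' the length scale (one heparan-sulfate-like chain of 60 beads at
#' `b0 = 0.5 r_c` then spans ~15 nm of contour), the time unit tau is of
#' order 0.01--0.1 microseconds (default 0.05), and `k_B T` at the chosen
#' temperature (default physiological, 310 K) sets energies. One reduced
#' force unit is `k_B T / r_c`, in the printed 1--10 pN range.
#'
#' @param r_c_nm cutoff radius in nm.
#' @param tau_us time unit in microseconds.
#' @param temperature_K absolute temperature.
#' @return A `unit_map` with derived force (pN), stress (pN/nm^2), velocity
#'   (nm/us) and bending-stiffness (pN nm) units.
#' @export
unit_map <- function(r_c_nm = 0.5, tau_us = 0.05, temperature_K = 310) {
  stopifnot(r_c_nm > 0, tau_us > 0, temperature_K > 0)
  kB_pN_nm <- 0.01380649  # pN nm / K
  kBT <- kB_pN_nm * temperature_K
  structure(list(
    r_c_nm = r_c_nm, tau_us = tau_us, temperature_K = temperature_K,
    kBT_pN_nm = kBT,
    force_pN = kBT / r_c_nm,
    stress_pN_nm2 = kBT / r_c_nm^3,
    velocity_nm_us = r_c_nm / tau_us,
    stiffness_pN_nm = kBT * r_c_nm),  # unit of k_E * b0
    class = "unit_map")
}

.unit_factor <- function(kind, map) {
  switch(kind,
         length = map$r_c_nm,
         time = map$tau_us,
         velocity = map$velocity_nm_us,
         force = map$force_pN,
         stress = map$stress_pN_nm2,
         energy = map$kBT_pN_nm,
         stiffness = map$stiffness_pN_nm,
         abort(paste0("unknown quantity kind '", kind, "'")))
}

#' Convert between reduced and physical units
#'
#' @param value numeric value(s).
#' @param kind one of `"length"` (nm), `"time"` (us), `"velocity"` (nm/us),
#'   `"force"` (pN), `"stress"` (pN/nm^2), `"energy"` (pN nm),
#'   `"stiffness"` (pN nm, for `k_E b0` bending stiffnesses).
#' @param map a [unit_map()].
#' @return Converted value(s).
#' @export
to_physical <- function(value, kind, map = unit_map()) {
  value * .unit_factor(kind, map)
}

#' @rdname to_physical
#' @export
to_reduced <- function(value, kind, map = unit_map()) {
  value / .unit_factor(kind, map)
}

#' Bending stiffness of the brush in physical units
#'
#' Maps the harmonic bending constant to the Euler-Bernoulli flexural
#' rigidity via `EI = k_E b0` and converts with the unit map; the baseline
#' constant (`k_E/2 = 231`, `b0 = 0.5 r_c`) gives ~490 pN nm at
#' physiological temperature.
#'
#' @param kE_half half the bending constant (as tabulated).
#' @param b0 equilibrium bond length (r_c).
#' @param map a [unit_map()].
#' @return Stiffness in pN nm.
#' @examples
#' eg_bending_stiffness()  # ~494 pN nm
#' @export
eg_bending_stiffness <- function(kE_half = 231, b0 = 0.5, map = unit_map()) {
  to_physical(2 * kE_half * b0, "stiffness", map)
}
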