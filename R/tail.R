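# Long-range tail corrections for 1/r^6 and 1/r^8 dispersion, barostat
# set-point logic and the simple property estimators. Tail integrals
# assume g(r) = 1 beyond the cutoff and the undamped -C_n/r^n form (the
# damping correction is negligible there by construction); they apply to
# homogeneous fluids only — slab systems refuse correction.

#' Tail-correction input
#'
#' @param densities named numeric: number density per atom type (1/A^3)
#' @param pairs data.frame with columns `key` (canonical type pair), `C6`
#'   (kcal/mol A^6), `C8` (kcal/mol A^8) and optionally `rd` (A)
#' @param r_c cutoff (A); must exceed every damping distance present
#' @param volume system volume (A^3); needed for the per-system energy
#' @param geometry `"homogeneous"` or `"slab"`; slab systems are refused
#'   (the homogeneous-fluid correction formula is not valid there)
#' @return object of class `"tail_input"`
#' @export
tail_input <- function(densities, pairs, r_c, volume = 1,
                       geometry = c("homogeneous", "slab")) {
  geometry <- match.arg(geometry)
  stopifnot(all(densities >= 0), r_c > 0, volume > 0)
  if (!is.null(pairs$rd) && any(r_c <= pairs$rd))
    stop("cutoff r_c must exceed every damping distance r_d")
  structure(list(densities = densities, pairs = pairs, r_c = r_c,
                 volume = volume, geometry = geometry),
            class = "tail_input")
}

tail_pair_iter <- function(input, f) {
  rho <- input$densities
  total <- 0
  for (i in seq_len(nrow(input$pairs))) {
    ts <- strsplit(input$pairs$key[i], "-", fixed = TRUE)[[1]]
    a <- ts[1]; b <- ts[2]
    if (is.na(rho[a]) || is.na(rho[b]))
      stop("missing density for type in pair ", input$pairs$key[i])
    mult <- if (a == b) 1 else 2  # ordered-pair double count for a != b
    total <- total + mult * f(rho[[a]], rho[[b]],
                              input$pairs$C6[i], input$pairs$C8[i])
  }
  total
}

#' Long-range tail correction to the energy
#'
#' \deqn{U_{tail} = -\sum_{(a,b)} 2\pi N_a \rho_b
#'       \left[\frac{C_6}{3 r_c^3} + \frac{C_8}{5 r_c^5}\right]}
#' summed over ordered type pairs (unordered pairs with \eqn{a \ne b}
#' count twice), with \eqn{N_a = \rho_a V}.
#'
#' @param input a [tail_input()]
#' @return energy correction (kcal/mol per system); negative for
#'   attractive dispersion
#' @export
tail_energy <- function(input) {
  stopifnot(inherits(input, "tail_input"))
  if (input$geometry == "slab")
    stop("homogeneous tail correction is invalid for slab systems")
  rc <- input$r_c
  -tail_pair_iter(input, function(ra, rb, C6, C8) {
    2 * pi * (ra * input$volume) * rb * (C6 / (3 * rc^3) + C8 / (5 * rc^5))
  })
}

#' Long-range tail correction to the pressure
#'
#' \deqn{P_{tail} = -\sum_{(a,b)} \frac{2\pi}{3} \rho_a \rho_b
#'       \left[\frac{6 C_6}{3 r_c^3} + \frac{8 C_8}{5 r_c^5}\right]}
#' converted to bar. A negative value means the truncated simulation
#' overestimates the pressure by its magnitude.
#'
#' @param input a [tail_input()]
#' @return pressure correction (bar)
#' @export
tail_pressure <- function(input) {
  stopifnot(inherits(input, "tail_input"))
  if (input$geometry == "slab")
    stop("homogeneous tail correction is invalid for slab systems")
  rc <- input$r_c
  -PRESS_CONV * tail_pair_iter(input, function(ra, rb, C6, C8) {
    (2 * pi / 3) * ra * rb * (6 * C6 / (3 * rc^3) + 8 * C8 / (5 * rc^5))
  })
}

#' Rescale an r^-8 pressure tail correction to another cutoff
#'
#' The 1/r^8 tail correction scales as \eqn{r_c^{-5}}, so a value known at
#' one cutoff transfers in closed form to another.
#'
#' @param value correction magnitude at `rc_from` (bar)
#' @param rc_from,rc_to cutoffs (any common length unit)
#' @return correction at `rc_to` (bar)
#' @examples
#' tail_pressure_rescale(32.2, 1.0, 1.3)  # ~8.7 bar
#' @export
tail_pressure_rescale <- function(value, rc_from, rc_to) {
  stopifnot(rc_from > 0, rc_to > 0)
  value * (rc_from / rc_to)^5
}

#' Barostat set-point for a truncated-dispersion run
#'
#' The truncated simulation must be held above the physical target so
#' that adding the attractive tail afterwards lands on the target:
#' set-point = target + |correction|.
#'
#' @param target_pressure desired final pressure (bar)
#' @param tail_correction_magnitude magnitude of the missing tail
#'   correction (bar)
#' @return barostat set-point (bar)
#' @examples
#' barostat_setpoint(1, 8.7)  # 9.7
#' @export
barostat_setpoint <- function(target_pressure, tail_correction_magnitude) {
  stopifnot(is.finite(target_pressure),
            is.finite(tail_correction_magnitude))
  target_pressure + abs(tail_correction_magnitude)
}

#' Heat of vaporization
#'
#' \eqn{\Delta H_{vap} = U_{gas} - U_{liquid} + RT}, with the average
#' potential energies per molecule in the gas and liquid phases.
#'
#' @param U_gas,U_liquid average potential energies (kcal/mol per
#'   molecule)
#' @param T_kelvin temperature (K), positive
#' @return kcal/mol
#' @export
heat_of_vaporization <- function(U_gas, U_liquid, T_kelvin) {
  stopifnot(is.finite(U_gas), is.finite(U_liquid))
  if (T_kelvin <= 0) stop("temperature must be positive")
  U_gas - U_liquid + R_GAS * T_kelvin
}

#' Isothermal compressibility by centered finite difference
#'
#' \eqn{\kappa_T = \frac{1}{\rho}\frac{\partial \rho}{\partial P}}
#' evaluated as \eqn{\frac{2}{\rho_1+\rho_2}\,
#' \frac{\rho_2-\rho_1}{P_2-P_1}} from two state points.
#'
#' @param rho1,rho2 densities at the two pressures (any common unit)
#' @param P1,P2 pressures (bar), distinct
#' @return compressibility (1/bar)
#' @export
isothermal_compressibility <- function(rho1, P1, rho2, P2) {
  if (P1 == P2) stop("the two pressures must differ")
  (2 / (rho1 + rho2)) * (rho2 - rho1) / (P2 - P1)
}

#' Boiling temperature from Trouton's rule
#'
#' \eqn{T_b = \Delta H_{vap} / \Delta S_{vap}} with
#' \eqn{\Delta S_{vap} \approx 85} J/(mol K).
#'
#' @param dHvap heat of vaporization (kcal/mol), positive
#' @param dSvap entropy of vaporization (J/(mol K))
#' @return boiling temperature (K)
#' @export
trouton_boiling_temperature <- function(dHvap, dSvap = 85) {
  if (dHvap <= 0) stop("heat of vaporization must be positive")
  dHvap * KCAL_TO_J / dSvap
}
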