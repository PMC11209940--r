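#' Force-field container
#'
#' Holds all parameters of the alkane energy expression: per-type partial
#' charges, harmonic bonds \eqn{k_r (r - r_e)^2}, harmonic angles
#' \eqn{k_\theta (\theta - \theta_e)^2}, cosine torsions
#' \eqn{A_t (1 + \cos(m\phi - \phi_0))}, and pair-specific noncovalent terms
#' \deqn{u_{ab}(r) = k_e q_a q_b / r + A_{ab} e^{-b_{ab} r}
#'       - C_{6,ab}/(r^6 + r_d^6) - C_{8,ab}/(r^8 + r_d^8).}
#' Parameters are pair-specific: no combining rules are applied, every type
#' pair carries its own repulsion and dispersion values. Dispersion
#' (\eqn{C_6}, \eqn{C_8}) is carried only by carbon-carbon pairs; the
#' damping distance \eqn{r_d} is a fixed configuration value (set from van
#' der Waals radii), never fitted.
#'
#' @param atom_types data.frame with columns `name`, `element`, `charge`
#'   (elementary charge units).
#' @param bonds data.frame with columns `key` (canonical "t1-t2"), `k`
#'   (kcal/mol/A^2), `r0` (A).
#' @param angles data.frame with columns `key` ("t1-t2-t3"), `k`
#'   (kcal/mol/rad^2), `theta0` (rad).
#' @param torsions data.frame with columns `key` ("t1-t2-t3-t4"), `A`
#'   (kcal/mol), `m` (multiplicity), `phi0` (rad).
#' @param pairs data.frame with columns `key` ("ta-tb"), `A` (kcal/mol),
#'   `b` (1/A), `C6` (kcal/mol A^6), `C8` (kcal/mol A^8), `rd` (A).
#' @param damping damping functional form tag; only `"rational"`
#'   (\eqn{-C_n/(r^n + r_d^n)}) is implemented.
#' @param check_neutrality optional list of topologies whose molecules must
#'   be charge neutral under `atom_types$charge` (within 1e-8 e).
#' @return object of class `"forcefield"`
#' @examples
#' ff <- alkane_ground_truth()
#' ff$pairs
#' @export
forcefield <- function(atom_types, bonds, angles, torsions, pairs,
                       damping = "rational", check_neutrality = NULL) {
  stopifnot(is.data.frame(atom_types),
            all(c("name", "element", "charge") %in% names(atom_types)))
  if (anyDuplicated(atom_types$name)) stop("duplicate atom type name")
  if (any(!is.finite(atom_types$charge))) stop("non-finite charge")
  if (!identical(damping, "rational"))
    stop("unknown damping form: ", damping)
  for (df in list(bonds, angles, torsions, pairs))
    stopifnot(is.data.frame(df), "key" %in% names(df))
  if (nrow(bonds) && (any(bonds$k <= 0) | any(bonds$r0 <= 0)))
    stop("bond parameters must satisfy k > 0, r0 > 0")
  if (nrow(angles) && (any(angles$k <= 0) | any(angles$theta0 <= 0) |
                       any(angles$theta0 >= pi)))
    stop("angle parameters must satisfy k > 0, 0 < theta0 < pi")
  if (nrow(pairs)) {
    if (any(pairs$b <= 0)) stop("repulsion exponent b must be positive")
    if (any(pairs$rd < 0)) stop("damping distance rd must be >= 0")
    el <- setNames(atom_types$element, atom_types$name)
    ts <- strsplit(pairs$key, "-", fixed = TRUE)
    carbon <- vapply(ts, function(t_) all(el[t_] == "C"), logical(1))
    if (any((pairs$C6 != 0 | pairs$C8 != 0) & !carbon))
      stop("dispersion (C6/C8) is allowed only between pairs of carbon atoms")
  }
  ff <- structure(list(
    atom_types = atom_types, bonds = bonds, angles = angles,
    torsions = torsions, pairs = pairs, kcoul = K_COULOMB,
    damping = damping
  ), class = "forcefield")
  if (!is.null(check_neutrality)) {
    for (top in check_neutrality) {
      q <- setNames(atom_types$charge, atom_types$name)[top$atoms$type]
      net <- tapply(q, top$atoms$mol, sum)
      if (any(abs(net) > 1e-8))
        stop("molecule not charge neutral: net charge ",
             format(max(abs(net))))
    }
  }
  ff
}

#' @export
print.forcefield <- function(x, ...) {
  cat("Force field:", nrow(x$atom_types), "atom types,",
      nrow(x$bonds), "bond,", nrow(x$angles), "angle,",
      nrow(x$torsions), "torsion,", nrow(x$pairs), "pair terms\n")
  cat("  charges (e): ",
      paste(sprintf("%s=%+.4f", x$atom_types$name, x$atom_types$charge),
            collapse = "  "), "\n", sep = "")
  cat("  dispersion damping:", x$damping, "\n")
  invisible(x)
}

ff_charges <- function(ff) setNames(ff$atom_types$charge, ff$atom_types$name)

# parameter lookup tables keyed by canonical keys
ff_lookup <- function(df, cols) {
  lapply(setNames(cols, cols), function(cc) setNames(df[[cc]], df$key))
}

#' Replace the per-type charges of a force field
#' @param ff a [forcefield()]
#' @param charges named numeric vector (names = type names, units e)
#' @return updated forcefield
#' @export
set_charges <- function(ff, charges) {
  idx <- match(ff$atom_types$name, names(charges))
  if (anyNA(idx)) stop("missing charge for type(s): ",
                       paste(ff$atom_types$name[is.na(idx)], collapse = ", "))
  ff$atom_types$charge <- as.numeric(charges[idx])
  ff
}
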