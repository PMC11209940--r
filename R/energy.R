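# Energy expression and analytic forces.
#
# Scalar term functions expose the one-dimensional energy/derivative pairs;
# the geometry kernels below map internal-coordinate derivatives (dE/dr,
# dE/dtheta, dE/dphi) to Cartesian forces by the chain rule. The same
# kernels back both force-field evaluation and the force-matching design
# matrix, so evaluation and fitting are consistent by construction.

#' Harmonic bond energy and radial derivative
#'
#' \eqn{E = k_r (r - r_e)^2} (no 1/2 prefactor: this convention is part of
#' the parameter definition, external parameters must be converted on
#' import).
#'
#' @param r bond length (A), must be positive
#' @param k force constant (kcal/mol/A^2)
#' @param r0 equilibrium length (A)
#' @return list with `energy` (kcal/mol) and `dEdr` (kcal/mol/A)
#' @export
bond_energy_force <- function(r, k, r0) {
  if (any(r <= 0)) stop("bond length must be positive")
  d <- r - r0
  list(energy = k * d^2, dEdr = 2 * k * d)
}

#' Harmonic angle energy and angular derivative
#'
#' \eqn{E = k_\theta (\theta - \theta_e)^2}.
#'
#' @param theta angle (rad), strictly inside (0, pi)
#' @param k force constant (kcal/mol/rad^2)
#' @param theta0 equilibrium angle (rad)
#' @return list with `energy` and `dEdtheta`
#' @export
angle_energy_force <- function(theta, k, theta0) {
  if (any(theta <= 0) || any(theta >= pi))
    stop("angle must be strictly between 0 and pi (gradient undefined at the poles)")
  d <- theta - theta0
  list(energy = k * d^2, dEdtheta = 2 * k * d)
}

#' Cosine torsion energy and dihedral derivative
#'
#' \eqn{E = A_t (1 + \cos(m\phi - \phi_0))}. For saturated alkanes the
#' multiplicity is 3 and the phase 0.
#'
#' @param phi dihedral (rad)
#' @param A barrier coefficient (kcal/mol)
#' @param m integer multiplicity
#' @param phi0 phase (rad)
#' @return list with `energy` and `dEdphi`
#' @export
torsion_energy_force <- function(phi, A, m = 3L, phi0 = 0) {
  list(energy = A * (1 + cos(m * phi - phi0)),
       dEdphi = -A * m * sin(m * phi - phi0))
}

#' Noncovalent pair energy and radial derivative
#'
#' Coulomb + exponential repulsion + short-range-damped C6/C8 dispersion:
#' \deqn{u(r) = k_e q_i q_j/r + A e^{-b r} - C_6/(r^6+r_d^6) - C_8/(r^8+r_d^8).}
#' The rational damping removes the unphysical short-range attraction of
#' the inverse power laws while preserving the \eqn{-C_n/r^n} asymptote.
#'
#' @param r distance (A); values below 0.1 A are rejected as unphysical
#'   overlap
#' @param qi,qj partial charges (e)
#' @param A,b,C6,C8,rd pair parameters (see [forcefield()])
#' @return list with `energy` and `dEdr`
#' @export
pair_energy_force <- function(r, qi, qj, A, b, C6, C8, rd) {
  if (any(r < 0.1)) stop("pair distance below 0.1 A: unphysical overlap")
  qq <- qi * qj
  d6 <- r^6 + rd^6
  d8 <- r^8 + rd^8
  e <- K_COULOMB * qq / r + A * exp(-b * r) - C6 / d6 - C8 / d8
  dEdr <- -K_COULOMB * qq / r^2 - A * b * exp(-b * r) +
    C6 * 6 * r^5 / d6^2 + C8 * 8 * r^7 / d8^2
  list(energy = e, dEdr = dEdr)
}

# ---- geometry kernels -------------------------------------------------

row_norm <- function(m) sqrt(rowSums(m * m))

# minimum image displacement (orthorhombic box or NULL)
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# bond geometry: lengths + unit vectors i->j
bond_geometry <- function(coords, bonds) {
  d <- coords[bonds[, 2], , drop = FALSE] - coords[bonds[, 1], , drop = FALSE]
  r <- row_norm(d)
  list(r = r, u = d / r)
}

# scatter bond forces: F = -dE/dr * dr/dx. dr/dx_j = u, dr/dx_i = -u.
scatter_bond_forces <- function(nat, bonds, geo, dEdr) {
  f <- matrix(0, nat, 3)
  g <- geo$u * dEdr
  for (k in 1:3) {
    f[, k] <- f[, k] + tabulate2(bonds[, 1], g[, k], nat) -
      tabulate2(bonds[, 2], g[, k], nat)
  }
  f
}

# sum `val` into bins `idx` of an n-vector (scatter-add)
tabulate2 <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# angle geometry: theta plus dtheta/dx for the three atoms
angle_geometry <- function(coords, angles) {
  i <- angles[, 1]; j <- angles[, 2]; k <- angles[, 3]
  a <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  b <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  ra <- row_norm(a); rb <- row_norm(b)
  ah <- a / ra; bh <- b / rb
  ct <- pmin(1, pmax(-1, rowSums(ah * bh)))
  theta <- acos(ct)
  st <- sqrt(pmax(1 - ct^2, 1e-24))
  # dtheta/dri = -(bh - ct*ah) / (ra * st); dtheta/drk symmetric
  gi <- -(bh - ct * ah) / (ra * st)
  gk <- -(ah - ct * bh) / (rb * st)
  gj <- -(gi + gk)
  list(theta = theta, gi = gi, gj = gj, gk = gk)
}

scatter_angle_forces <- function(nat, angles, geo, dEdtheta) {
  f <- matrix(0, nat, 3)
  for (k in 1:3) {
    f[, k] <- f[, k] -
      tabulate2(angles[, 1], geo$gi[, k] * dEdtheta, nat) -
      tabulate2(angles[, 2], geo$gj[, k] * dEdtheta, nat) -
      tabulate2(angles[, 3], geo$gk[, k] * dEdtheta, nat)
  }
  f
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# torsion geometry: phi plus dphi/dx (Blondel-Karplus form)
torsion_geometry <- function(coords, torsions) {
  i <- torsions[, 1]; j <- torsions[, 2]; k <- torsions[, 3]; l <- torsions[, 4]
  b1 <- coords[j, , drop = FALSE] - coords[i, , drop = FALSE]
  b2 <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  b3 <- coords[l, , drop = FALSE] - coords[k, , drop = FALSE]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  r2 <- row_norm(b2)
  phi <- atan2(rowSums(cross3(n1, n2) * (b2 / r2)), rowSums(n1 * n2))
  n1sq <- rowSums(n1 * n1); n2sq <- rowSums(n2 * n2)
  gi <- -n1 * (r2 / n1sq)
  gl <- n2 * (r2 / n2sq)
  c12 <- rowSums(b1 * b2) / r2^2
  c32 <- rowSums(b3 * b2) / r2^2
  gj <- gi * (-c12 - 1) + gl * c32
  gk <- gl * (-c32 - 1) + gi * c12
  list(phi = phi, gi = gi, gj = gj, gk = gk, gl = gl)
}

scatter_torsion_forces <- function(nat, torsions, geo, dEdphi) {
  f <- matrix(0, nat, 3)
  for (k in 1:3) {
    f[, k] <- f[, k] -
      tabulate2(torsions[, 1], geo$gi[, k] * dEdphi, nat) -
      tabulate2(torsions[, 2], geo$gj[, k] * dEdphi, nat) -
      tabulate2(torsions[, 3], geo$gk[, k] * dEdphi, nat) -
      tabulate2(torsions[, 4], geo$gl[, k] * dEdphi, nat)
  }
  f
}

# nonbonded pair geometry with optional minimum image + cutoff
pair_geometry <- function(coords, pairs, box = NULL, cutoff = NULL) {
  d <- coords[pairs[, 2], , drop = FALSE] - coords[pairs[, 1], , drop = FALSE]
  d <- min_image(d, box)
  r <- row_norm(d)
  keep <- if (is.null(cutoff)) seq_along(r) else which(r <= cutoff)
  list(pairs = pairs[keep, , drop = FALSE], r = r[keep],
       u = d[keep, , drop = FALSE] / r[keep])
}

scatter_pair_forces <- function(nat, pairs, geo, dEdr) {
  f <- matrix(0, nat, 3)
  g <- geo$u * dEdr
  for (k in 1:3) {
    f[, k] <- f[, k] + tabulate2(pairs[, 1], g[, k], nat) -
      tabulate2(pairs[, 2], g[, k], nat)
  }
  f
}

# ---- full evaluation --------------------------------------------------

#' Evaluate total energy and analytic forces
#'
#' Assembles the bonded and noncovalent terms of the energy expression on
#' one conformation and returns the total energy, the analytic forces
#' (negative Cartesian gradient), and a per-term breakdown. The minimum
#' image convention is applied when the conformation carries box vectors;
#' clusters are evaluated without periodicity.
#'
#' @param conf a [conformation()]
#' @param top matching [topology()]
#' @param ff a [forcefield()] supplying every needed parameter
#' @param cutoff optional nonbonded cutoff (A); `NULL` evaluates all pairs
#' @param pair_map optional precomputed [classify_pairs()] result
#' @return list with `energy`, `forces` (N x 3), and `breakdown` (named
#'   numeric: bond, angle, torsion, coulomb, repulsion, dispersion)
#' @examples
#' top <- make_alkane_topology("n-butane")
#' ff <- alkane_ground_truth()
#' conf <- ideal_geometry(top)
#' eval_forcefield(conf, top, ff)$energy
#' @export
eval_forcefield <- function(conf, top, ff, cutoff = NULL, pair_map = NULL) {
  stopifnot(inherits(conf, "conformation"), inherits(top, "topology"),
            inherits(ff, "forcefield"))
  coords <- conf$coords
  nat <- nrow(coords)
  if (nat != n_atoms(top))
    stop("conformation and topology atom counts differ")
  if (is.null(pair_map)) pair_map <- classify_pairs(top)
  f <- matrix(0, nat, 3)
  brk <- c(bond = 0, angle = 0, torsion = 0, coulomb = 0,
           repulsion = 0, dispersion = 0)

  if (nrow(top$bonds) > 0) {
    keys <- bond_type_keys(top)
    p <- ff$bonds[match(keys, ff$bonds$key), ]
    if (anyNA(p$k)) stop("missing bond parameters for type pair ",
                         keys[which(is.na(p$k))[1]])
    geo <- bond_geometry(coords, top$bonds)
    ev <- bond_energy_force(geo$r, p$k, p$r0)
    brk["bond"] <- sum(ev$energy)
    f <- f + scatter_bond_forces(nat, top$bonds, geo, ev$dEdr)
  }
  if (nrow(top$angles) > 0) {
    keys <- angle_type_keys(top)
    p <- ff$angles[match(keys, ff$angles$key), ]
    if (anyNA(p$k)) stop("missing angle parameters for type triple ",
                         keys[which(is.na(p$k))[1]])
    geo <- angle_geometry(coords, top$angles)
    ev <- angle_energy_force(geo$theta, p$k, p$theta0)
    brk["angle"] <- sum(ev$energy)
    f <- f + scatter_angle_forces(nat, top$angles, geo, ev$dEdtheta)
  }
  if (nrow(top$torsions) > 0) {
    keys <- torsion_type_keys(top)
    p <- ff$torsions[match(keys, ff$torsions$key), ]
    if (anyNA(p$A)) stop("missing torsion parameters for type quadruple ",
                         keys[which(is.na(p$A))[1]])
    geo <- torsion_geometry(coords, top$torsions)
    ev <- torsion_energy_force(geo$phi, p$A, p$m, p$phi0)
    brk["torsion"] <- sum(ev$energy)
    f <- f + scatter_torsion_forces(nat, top$torsions, geo, ev$dEdphi)
  }

  nb <- pair_map$nonbonded
  if (nrow(nb) > 0) {
    geo <- pair_geometry(coords, nb, conf$box, cutoff)
    if (nrow(geo$pairs) > 0) {
      ty <- top$atoms$type
      keys <- pair_key(ty[geo$pairs[, 1]], ty[geo$pairs[, 2]])
      p <- ff$pairs[match(keys, ff$pairs$key), ]
      if (anyNA(p$A)) stop("missing pair parameters for type pair ",
                           keys[which(is.na(p$A))[1]])
      q <- ff_charges(ff)
      qi <- q[ty[geo$pairs[, 1]]]; qj <- q[ty[geo$pairs[, 2]]]
      if (any(geo$r < 0.1)) stop("pair distance below 0.1 A: unphysical overlap")
      qq <- qi * qj
      ec <- K_COULOMB * qq / geo$r
      er <- p$A * exp(-p$b * geo$r)
      d6 <- geo$r^6 + p$rd^6; d8 <- geo$r^8 + p$rd^8
      ed <- -p$C6 / d6 - p$C8 / d8
      brk["coulomb"] <- sum(ec)
      brk["repulsion"] <- sum(er)
      brk["dispersion"] <- sum(ed)
      dEdr <- -ec / geo$r - p$A * p$b * exp(-p$b * geo$r) +
        p$C6 * 6 * geo$r^5 / d6^2 + p$C8 * 8 * geo$r^7 / d8^2
      f <- f + scatter_pair_forces(nat, geo$pairs, geo, dEdr)
    }
  }
  list(energy = sum(brk), forces = f, breakdown = brk)
}

#' Numerical forces by central finite differences
#'
#' Independent check of the analytic gradient: perturbs every coordinate by
#' +/- `h` and differences the total energy.
#'
#' @inheritParams eval_forcefield
#' @param h step (A)
#' @return N x 3 matrix of numerical forces
#' @export
numerical_forces <- function(conf, top, ff, h = 1e-6, cutoff = NULL) {
  pm <- classify_pairs(top)
  coords <- conf$coords
  f <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) for (k in 1:3) {
    cp <- coords; cp[i, k] <- cp[i, k] + h
    cm <- coords; cm[i, k] <- cm[i, k] - h
    ep <- eval_forcefield(conformation(cp, box = conf$box), top, ff,
                          cutoff = cutoff, pair_map = pm)$energy
    em <- eval_forcefield(conformation(cm, box = conf$box), top, ff,
                          cutoff = cutoff, pair_map = pm)$energy
    f[i, k] <- -(ep - em) / (2 * h)
  }
  f
}
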