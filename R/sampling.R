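# Conformational sampling: Langevin dynamics with the BAOAB splitting.
# Default settings: 1 fs time step, friction 1/(2.0 ps) (the gas-phase
# Langevin setting used for property calculations), deterministic for a
# given seed.

atom_masses <- function(top) {
  m <- ELEMENT_MASSES[top$atoms$element]
  if (anyNA(m)) stop("unknown element(s): ",
                     paste(unique(top$atoms$element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Sample conformations by Langevin dynamics
#'
#' BAOAB-splitting Langevin integrator at temperature `T_kelvin`. The
#' first `equil_frac` of the trajectory is discarded as equilibration and
#' frames are then saved every `stride` steps. Bitwise deterministic given
#' `seed`.
#'
#' @param ff [forcefield()] used for sampling
#' @param top [topology()]
#' @param T_kelvin thermostat temperature (K)
#' @param n_frames number of frames to return
#' @param seed RNG seed
#' @param start optional starting [conformation()]; defaults to
#'   [ideal_geometry()] for single-molecule alkane topologies
#' @param dt time step (ps)
#' @param friction Langevin friction (1/ps); the default corresponds to an
#'   inverse friction constant of 2.0 ps
#' @param stride steps between saved frames
#' @param equil_frac fraction of the total trajectory discarded before the
#'   first saved frame
#' @param cutoff optional nonbonded cutoff (A)
#' @return a [conformation_set()]; each frame carries the box of `start`
#' @export
sample_conformations <- function(ff, top, T_kelvin = 298, n_frames = 100,
                                 seed = 1, start = NULL, dt = 0.001,
                                 friction = 0.5, stride = 20,
                                 equil_frac = 0.2, cutoff = NULL) {
  if (is.null(start)) {
    if (top$n_molecules > 1)
      stop("multi-molecule sampling needs an explicit `start` conformation")
    start <- ideal_geometry(top, relax_ff = ff)
  }
  pm <- classify_pairs(top)
  nat <- n_atoms(top)
  m <- atom_masses(top)
  kT <- K_BOLTZ * T_kelvin
  ev0 <- eval_forcefield(start, top, ff, cutoff = cutoff, pair_map = pm)
  if (!is.finite(ev0$energy) || abs(ev0$energy) > 1e6)
    stop("unstable force field: non-finite or divergent energy at start")
  set.seed(seed)
  x <- start$coords
  v <- matrix(stats::rnorm(nat * 3), nat, 3) * sqrt(kT * ACC_CONV / m)
  f <- ev0$forces
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2)
  sig_v <- sqrt(kT * ACC_CONV / m)
  prod_steps <- n_frames * stride
  equil_steps <- ceiling(prod_steps * equil_frac / (1 - equil_frac))
  total <- equil_steps + prod_steps
  frames <- vector("list", n_frames)
  saved <- 0L
  for (step in seq_len(total)) {
    v <- v + (dt / 2) * ACC_CONV * f / m
    x <- x + (dt / 2) * v
    v <- c1 * v + c2 * sig_v * matrix(stats::rnorm(nat * 3), nat, 3)
    x <- x + (dt / 2) * v
    ev <- eval_forcefield(conformation(x, box = start$box), top, ff,
                          cutoff = cutoff, pair_map = pm)
    if (!is.finite(ev$energy) || abs(ev$energy) > 1e6)
      stop(sprintf("energy divergence at MD step %d", step))
    f <- ev$forces
    v <- v + (dt / 2) * ACC_CONV * f / m
    if (step > equil_steps && (step - equil_steps) %% stride == 0) {
      saved <- saved + 1L
      frames[[saved]] <- conformation(x, box = start$box,
                                      label = sprintf("T%g-step%d",
                                                      T_kelvin, step))
    }
  }
  conformation_set(frames[seq_len(saved)])
}

#' Kinetic temperature of a velocity set
#'
#' Equipartition estimate \eqn{T = \sum m v^2 / (3 N k_B)} (with the
#' internal unit conversion); used by the sampler's validation tests.
#'
#' @param v N x 3 velocity matrix (A/ps)
#' @param m length-N masses (amu)
#' @return temperature (K)
#' @export
kinetic_temperature <- function(v, m) {
  sum(m * rowSums(v^2)) / (ACC_CONV * K_BOLTZ * 3 * nrow(v))
}

#' Build a periodic liquid-like starting configuration
#'
#' Places `n_mol` randomly oriented copies of the molecule on a cubic
#' sub-lattice inside a periodic box sized from the target mass density.
#' Used to seed fixed-volume Langevin sampling of a small liquid system.
#'
#' @param top1 single-molecule alkane [topology()]
#' @param n_mol number of molecules
#' @param density target mass density (g/L)
#' @param seed RNG seed for orientations
#' @return list with `topology` (replicated) and `start` ([conformation()]
#'   with box)
#' @export
make_liquid_start <- function(top1, n_mol = 8, density = 620, seed = 1) {
  set.seed(seed)
  m_mol <- sum(ELEMENT_MASSES[top1$atoms$element])
  # g/L -> amu/A^3: 1 g/L = 1e-3 g/cm^3 = 1e-3/1.66054 amu/A^3
  rho <- density * 1e-3 / 1.66054
  vol <- n_mol * m_mol / rho
  box <- rep(vol^(1 / 3), 3)
  ncell <- ceiling(n_mol^(1 / 3))
  base <- ideal_geometry(top1)$coords
  base <- sweep(base, 2, colMeans(base))
  sites <- as.matrix(expand.grid(seq_len(ncell), seq_len(ncell),
                                 seq_len(ncell)))[seq_len(n_mol), , drop = FALSE]
  sites <- (sites - 0.5) / ncell * box[1]
  coords <- do.call(rbind, lapply(seq_len(n_mol), function(k) {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    sweep(base %*% q, 2, sites[k, ], "+")
  }))
  list(topology = replicate_topology(top1, n_mol),
       start = conformation(coords, box = box, label = "liquid-start"))
}

#' Extract a compact training cluster from a liquid frame
#'
#' Selects a seed molecule (deterministically from `seed`) and its
#' `n_molecules - 1` nearest neighbors by minimum intermolecular atom
#' distance (minimum image), then unwraps the selected molecules so the
#' cluster is whole (no periodic wrapping) and returns it as a finite
#' cluster conformation.
#'
#' @param frame a [conformation()] (periodic liquid frame)
#' @param top matching multi-molecule [topology()]
#' @param n_molecules cluster size (the reference-calculation cluster uses
#'   6 molecules)
#' @param seed RNG seed for the seed-molecule choice
#' @return list with `conformation` (finite cluster), `topology`
#'   (replicated single-molecule topology for the cluster) and `molecules`
#'   (indices selected)
#' @export
make_training_cluster <- function(frame, top, n_molecules = 6, seed = 1) {
  mols <- split(seq_len(n_atoms(top)), top$atoms$mol)
  if (length(mols) < n_molecules)
    stop(sprintf("frame has %d molecules; %d requested", length(mols),
                 n_molecules))
  set.seed(seed)
  seed_mol <- sample.int(length(mols), 1)
  box <- frame$box
  dmin <- vapply(seq_along(mols), function(mi) {
    if (mi == seed_mol) return(0)
    d <- frame$coords[rep(mols[[seed_mol]], each = length(mols[[mi]])), ] -
      frame$coords[rep(mols[[mi]], times = length(mols[[seed_mol]])), ]
    d <- min_image(d, box)
    min(sqrt(rowSums(d^2)))
  }, numeric(1))
  sel <- order(dmin)[seq_len(n_molecules)]
  sel <- sel[order(sel)]
  # unwrap: shift each selected molecule by the image closest to the seed
  # molecule's center
  ctr_seed <- colMeans(frame$coords[mols[[seed_mol]], , drop = FALSE])
  coords <- do.call(rbind, lapply(sel, function(mi) {
    xs <- frame$coords[mols[[mi]], , drop = FALSE]
    ctr <- colMeans(xs)
    shift <- if (is.null(box)) c(0, 0, 0) else
      -box * round((ctr - ctr_seed) / box)
    sweep(xs, 2, shift, "+")
  }))
  nat1 <- length(mols[[1]])
  top1 <- single_molecule_topology(top)
  list(conformation = conformation(coords, label = frame$label),
       topology = replicate_topology(top1, n_molecules),
       molecules = sel)
}

# first-molecule sub-topology of a replicated topology
single_molecule_topology <- function(top) {
  nat1 <- sum(top$atoms$mol == top$atoms$mol[1])
  top1 <- topology(top$atoms[seq_len(nat1), , drop = FALSE],
                   top$bonds[top$bonds[, 1] <= nat1 &
                               top$bonds[, 2] <= nat1, , drop = FALSE])
  attr(top1, "n_carbons") <- attr(top, "n_carbons")
  attr(top1, "cyclic") <- attr(top, "cyclic")
  top1
}
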