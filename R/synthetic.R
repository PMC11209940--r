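# Synthetic reference generator: a stand-in for quantum-chemistry training
# data. Conformations, per-atom forces and dimer dispersion energies are
# produced from a known ground-truth force field so that every fitting
# stage can be validated by exact parameter recovery.

#' Alkane ground-truth force field
#'
#' A complete, alkane-plausible parameter set used as the synthetic "truth"
#' behind mock reference forces and dispersion energies. Charges are
#' group-neutral (each CH3/CH2 group sums to zero), so every alkane built
#' by [make_alkane_topology()] is charge neutral. Dispersion C6/C8 sit only
#' on carbon-carbon pairs; damping distances come from van der Waals radii
#' and are never fitted.
#'
#' @return a [forcefield()]
#' @export
alkane_ground_truth <- function() {
  atom_types <- data.frame(
    name = c("C3", "C2", "HC"),
    element = c("C", "C", "H"),
    charge = c(-0.15, -0.10, 0.05)
  )
  bonds <- data.frame(
    key = c("C2-C2", "C2-C3", "C3-C3", "C2-HC", "C3-HC"),
    k = c(310, 300, 305, 330, 340),
    r0 = c(1.529, 1.531, 1.530, 1.095, 1.090)
  )
  deg <- pi / 180
  angles <- data.frame(
    key = c("C2-C2-C2", "C2-C2-C3", "C3-C2-C3",
            "HC-C2-HC", "HC-C3-HC", "C2-C2-HC", "C3-C2-HC", "C2-C3-HC",
            "C3-C3-HC"),
    k = c(62, 60, 59, 50, 48, 55, 54, 56, 57),
    theta0 = c(111.0, 111.5, 112.0, 107.8, 107.6, 110.0, 110.2, 110.5,
               110.7) * deg
  )
  torsions <- data.frame(
    key = c("C2-C2-C2-C2", "C2-C2-C2-C3", "C3-C2-C2-C3", "C2-C2-C3-C3"),
    A = c(1.40, 1.30, 1.35, 1.25),
    m = 3L, phi0 = 0
  )
  pairs <- data.frame(
    key = c("C2-C2", "C2-C3", "C3-C3", "C2-HC", "C3-HC", "HC-HC"),
    A = c(70000, 75000, 80000, 12000, 13000, 2650),
    b = c(3.60, 3.62, 3.64, 3.67, 3.69, 3.74),
    C6 = c(600, 620, 640, 0, 0, 0),
    C8 = c(5200, 5500, 5800, 0, 0, 0),
    rd = c(3.40, 3.40, 3.40, 3.00, 3.00, 2.60)
  )
  forcefield(atom_types, bonds, angles, torsions, pairs)
}

#' Build an alkane topology with the standard AFM atom typing
#'
#' Linear alkanes use three atom types: terminal carbons `C3`, secondary
#' carbons `C2` and a single hydrogen type `HC`. Cyclic alkanes need only
#' two types (`C2`, `HC`) since every carbon is secondary. Bonds, angles
#' and torsions are enumerated from the bond graph; torsions involving
#' hydrogen are not considered.
#'
#' Atoms are ordered carbon-by-carbon, each carbon followed by its
#' hydrogens, matching the geometry builders.
#'
#' @param species one of `"n-butane"`, `"n-pentane"`, `"n-octane"`,
#'   `"cyclopentane"`, `"cycloheptane"`, or `NULL` to use `n_carbons` /
#'   `cyclic` directly
#' @param n_carbons carbon count (>= 2 linear, >= 3 cyclic)
#' @param cyclic logical
#' @return a [topology()] with attributes `n_carbons` and `cyclic`
#' @examples
#' make_alkane_topology("cyclopentane")
#' @export
make_alkane_topology <- function(species = NULL, n_carbons = NULL,
                                 cyclic = FALSE) {
  if (!is.null(species)) {
    tab <- list("n-butane" = c(4, FALSE), "n-pentane" = c(5, FALSE),
                "n-octane" = c(8, FALSE), "cyclopentane" = c(5, TRUE),
                "cycloheptane" = c(7, TRUE))
    if (!species %in% names(tab)) stop("unknown species: ", species)
    n_carbons <- tab[[species]][1]
    cyclic <- as.logical(tab[[species]][2])
  }
  if (cyclic && n_carbons < 3) stop("cyclic alkanes need at least 3 carbons")
  if (!cyclic && n_carbons < 2) stop("linear alkanes need at least 2 carbons")

  atoms <- list(); bonds <- list()
  c_index <- integer(n_carbons)
  idx <- 0L
  for (ci in seq_len(n_carbons)) {
    terminal <- !cyclic && (ci == 1 || ci == n_carbons)
    ctype <- if (terminal) "C3" else "C2"
    nh <- if (terminal) 3L else 2L
    idx <- idx + 1L
    c_index[ci] <- idx
    atoms[[idx]] <- data.frame(type = ctype, element = "C", mol = 1L)
    for (h in seq_len(nh)) {
      idx <- idx + 1L
      atoms[[idx]] <- data.frame(type = "HC", element = "H", mol = 1L)
      bonds[[length(bonds) + 1L]] <- c(c_index[ci], idx)
    }
  }
  for (ci in seq_len(n_carbons - 1))
    bonds[[length(bonds) + 1L]] <- c(c_index[ci], c_index[ci + 1])
  if (cyclic)
    bonds[[length(bonds) + 1L]] <- c(c_index[n_carbons], c_index[1])

  top <- topology(do.call(rbind, atoms), do.call(rbind, bonds))
  attr(top, "n_carbons") <- n_carbons
  attr(top, "cyclic") <- cyclic
  top
}

# unit-normalize a length-3 vector
unit3 <- function(v) v / sqrt(sum(v * v))

# rotate rows of x about the axis through `origin` along unit vector `axis`
rotate_about_axis <- function(x, origin, axis, angle) {
  y <- sweep(x, 2, origin)
  k <- unit3(axis)
  cosa <- cos(angle); sina <- sin(angle)
  kxy <- cbind(k[2] * y[, 3] - k[3] * y[, 2],
               k[3] * y[, 1] - k[1] * y[, 3],
               k[1] * y[, 2] - k[2] * y[, 1])
  kdot <- as.numeric(y %*% k)
  sweep(y * cosa + kxy * sina + outer(kdot * (1 - cosa), k), 2, origin, "+")
}

# draw a random backbone conformer of a linear alkane: each interior C-C
# torsion is set to anti or gauche+/- (liquid alkanes are a mixture), by
# rotating the chain tail about the bond axis
sample_conformer <- function(coords, c_idx, p_gauche = 0.4) {
  n_c <- length(c_idx)
  if (n_c < 4) return(coords)
  for (ci in 2:(n_c - 2)) {
    state <- sample(c(0, 2 * pi / 3, -2 * pi / 3), 1,
                    prob = c(1 - p_gauche, p_gauche / 2, p_gauche / 2))
    if (state == 0) next
    a <- coords[c_idx[ci], ]; b <- coords[c_idx[ci + 1], ]
    tail_rows <- (c_idx[ci + 1] + 1):nrow(coords)
    coords[tail_rows, ] <- rotate_about_axis(coords[tail_rows, , drop = FALSE],
                                             b, b - a, state)
  }
  coords
}

# hydrogen directions for a CH2 carbon given unit vectors to its 2 heavy
# neighbors
ch2_h_dirs <- function(u1, u2, hch = 107.8 * pi / 180) {
  bis <- unit3(-(u1 + u2))
  perp <- unit3(c(u1[2] * u2[3] - u1[3] * u2[2],
                  u1[3] * u2[1] - u1[1] * u2[3],
                  u1[1] * u2[2] - u1[2] * u2[1]))
  h <- hch / 2
  list(bis * cos(h) + perp * sin(h), bis * cos(h) - perp * sin(h))
}

# three hydrogen directions for a CH3 carbon given the unit vector to its
# heavy neighbor; psi0 sets the azimuthal (stagger) offset
ch3_h_dirs <- function(u, psi0 = pi / 3) {
  a <- -u
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- unit3(c(a[2] * ref[3] - a[3] * ref[2],
               a[3] * ref[1] - a[1] * ref[3],
               a[1] * ref[2] - a[2] * ref[1]))
  q <- c(a[2] * p[3] - a[3] * p[2],
         a[3] * p[1] - a[1] * p[3],
         a[1] * p[2] - a[2] * p[1])
  t <- (180 - 109.47) * pi / 180
  lapply(0:2, function(k) {
    psi <- psi0 + k * 2 * pi / 3
    a * cos(t) + sin(t) * (p * cos(psi) + q * sin(psi))
  })
}

#' Idealized alkane geometry
#'
#' Builds coordinates for a single-molecule topology from
#' [make_alkane_topology()]: standard bond lengths (C-C 1.53, C-H 1.09 A),
#' a 112 degree backbone with all-anti torsions for linear species, and a
#' planar carbon ring for cyclic species. Cyclic geometries are relaxed
#' under `relax_ff` (analytic-gradient BFGS) to relieve the ring strain of
#' the planar start.
#'
#' @param top alkane [topology()] (single molecule)
#' @param relax_ff force field used to relax cyclic rings;
#'   [alkane_ground_truth()] by default. Set `NULL` to skip relaxation.
#' @return a [conformation()]
#' @export
ideal_geometry <- function(top, relax_ff = alkane_ground_truth()) {
  n_c <- attr(top, "n_carbons")
  cyclic <- attr(top, "cyclic")
  if (is.null(n_c)) stop("topology was not built by make_alkane_topology()")
  rcc <- 1.53; rch <- 1.09
  coords <- matrix(NA_real_, n_atoms(top), 3)
  is_c <- top$atoms$element == "C"
  c_idx <- which(is_c)

  if (!cyclic) {
    delta <- (pi - 112 * pi / 180) / 2
    cpos <- matrix(0, n_c, 3)
    dirs <- list(c(cos(delta), 0, sin(delta)), c(cos(delta), 0, -sin(delta)))
    for (ci in seq_len(n_c - 1))
      cpos[ci + 1, ] <- cpos[ci, ] + rcc * dirs[[1 + ci %% 2]]
  } else {
    rad <- rcc / (2 * sin(pi / n_c))
    ang <- 2 * pi * (seq_len(n_c) - 1) / n_c
    cpos <- cbind(rad * cos(ang), rad * sin(ang), 0)
  }
  coords[c_idx, ] <- cpos

  # hydrogens: rows between carbon ci's index and the next carbon
  for (ci in seq_len(n_c)) {
    me <- c_idx[ci]
    h_rows <- (me + 1):(if (ci < n_c) c_idx[ci + 1] - 1 else n_atoms(top))
    h_rows <- h_rows[!is_c[h_rows]]
    heavy <- if (cyclic) {
      c(c_idx[if (ci == 1) n_c else ci - 1], c_idx[if (ci == n_c) 1 else ci + 1])
    } else {
      c(if (ci > 1) c_idx[ci - 1], if (ci < n_c) c_idx[ci + 1])
    }
    u <- lapply(heavy, function(j) unit3(coords[j, ] - coords[me, ]))
    dirs <- if (length(u) == 2) ch2_h_dirs(u[[1]], u[[2]])
            else ch3_h_dirs(u[[1]], psi0 = pi / 3 + ci)
    for (k in seq_along(h_rows))
      coords[h_rows[k], ] <- coords[me, ] + rch * dirs[[k]]
  }
  conf <- conformation(coords, label = "ideal")
  if (cyclic && !is.null(relax_ff)) conf <- relax_geometry(conf, top, relax_ff)
  conf
}

#' Relax a conformation under a force field
#'
#' BFGS minimization of the total energy with analytic gradients.
#'
#' @inheritParams eval_forcefield
#' @param maxit iteration cap
#' @return relaxed [conformation()]
#' @export
relax_geometry <- function(conf, top, ff, maxit = 500) {
  pm <- classify_pairs(top)
  nat <- n_atoms(top)
  fn <- function(x) eval_forcefield(conformation(matrix(x, nat, 3)),
                                    top, ff, pair_map = pm)$energy
  gr <- function(x) -as.numeric(eval_forcefield(conformation(matrix(x, nat, 3)),
                                                top, ff, pair_map = pm)$forces)
  opt <- stats::optim(as.numeric(conf$coords), fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  conformation(matrix(opt$par, nat, 3), box = conf$box, label = conf$label)
}

# place n_mol copies of a molecule as a compact cluster: each new molecule
# gets a random orientation and is slid in from a random direction until
# its nearest-atom distance to the cluster reaches `contact` (bisection)
place_cluster <- function(base_coords, n_mol, contact_range = c(1.9, 3.2),
                          conformer = identity) {
  rand_rot <- function() {
    m <- matrix(stats::rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  draw_mol <- function() {
    x <- conformer(base_coords)
    sweep(x, 2, colMeans(x)) %*% rand_rot()
  }
  placed <- draw_mol()
  for (k in seq_len(n_mol - 1)) {
    mol <- draw_mol()
    dir <- unit3(stats::rnorm(3))
    contact <- stats::runif(1, contact_range[1], contact_range[2])
    mind <- function(s) {
      cand <- sweep(mol, 2, s * dir, "+")
      min(sqrt(pmax(outer(rowSums(placed^2), rowSums(cand^2), "+") -
                      2 * placed %*% t(cand), 0)))
    }
    lo <- 0; hi <- 40
    while (mind(hi) < contact) hi <- hi * 1.5
    for (it in 1:50) {
      mid <- (lo + hi) / 2
      if (mind(mid) < contact) lo <- mid else hi <- mid
    }
    placed <- rbind(placed, sweep(mol, 2, hi * dir, "+"))
  }
  placed
}

#' Generate training conformations from a ground-truth model
#'
#' `mode = "perturb"` draws Gaussian displacements around an idealized
#' geometry (for multi-molecule topologies, around a freshly placed compact
#' cluster per frame) with a displacement scale proportional to
#' \eqn{\sqrt{T}}; `mode = "md"` delegates to the Langevin sampler
#' ([sample_conformations()]) run under the ground-truth force field.
#' Deterministic given `seed`.
#'
#' @param top [topology()] (single- or multi-molecule alkane)
#' @param truth ground-truth [forcefield()]
#' @param T_kelvin temperature (K); scales the perturbation amplitude or
#'   the thermostat
#' @param n number of frames
#' @param seed RNG seed
#' @param mode `"perturb"` or `"md"`
#' @param sigma0 perturbation amplitude (A) at 298 K for `"perturb"`
#' @param conformers for linear alkanes in `"perturb"` mode, draw random
#'   anti/gauche backbone conformers per molecule (liquid alkanes are a
#'   conformer mixture); `FALSE` perturbs the all-anti geometry only
#' @param ... passed to [sample_conformations()] in `"md"` mode
#' @return a [conformation_set()]
#' @export
generate_conformations <- function(top, truth, T_kelvin = 298, n = 100,
                                   seed = 1, mode = c("perturb", "md"),
                                   sigma0 = 0.035, conformers = TRUE, ...) {
  mode <- match.arg(mode)
  if (mode == "md")
    return(sample_conformations(truth, top, T_kelvin = T_kelvin,
                                n_frames = n, seed = seed, ...))
  set.seed(seed)
  n_mol <- top$n_molecules
  nat <- n_atoms(top)
  sig <- sigma0 * sqrt(T_kelvin / 298)
  base_single <- NULL
  if (n_mol > 1) {
    nat1 <- nat / n_mol
    top1 <- topology(top$atoms[seq_len(nat1), , drop = FALSE],
                     top$bonds[top$bonds[, 1] <= nat1 &
                                 top$bonds[, 2] <= nat1, , drop = FALSE])
    attr(top1, "n_carbons") <- attr(top, "n_carbons")
    attr(top1, "cyclic") <- attr(top, "cyclic")
    base_single <- ideal_geometry(top1)$coords
  } else {
    base <- ideal_geometry(top)$coords
  }
  cyclic <- isTRUE(attr(top, "cyclic"))
  conformer <- function(x) {
    if (cyclic || !conformers) return(x)
    sample_conformer(x, which(top$atoms$element[seq_len(nrow(x))] == "C"))
  }
  frames <- lapply(seq_len(n), function(i) {
    x0 <- if (n_mol > 1) place_cluster(base_single, n_mol, conformer = conformer)
          else conformer(base)
    conformation(x0 + matrix(stats::rnorm(nat * 3, sd = sig), nat, 3),
                 label = sprintf("perturb-%d", i))
  })
  conformation_set(frames)
}

#' Attach mock quantum-reference forces to conformations
#'
#' Forces are the analytic forces of the ground-truth model, optionally
#' plus i.i.d. Gaussian noise of standard deviation `sigma`
#' (kcal/mol/A). Reproducible from `seed`.
#'
#' @param confs [conformation_set()]
#' @param top matching [topology()]
#' @param truth ground-truth [forcefield()]
#' @param sigma per-component noise SD (kcal/mol/A)
#' @param seed RNG seed for the noise
#' @return the conformation set with `forces` populated
#' @export
mock_reference_forces <- function(confs, top, truth, sigma = 0, seed = 1) {
  pm <- classify_pairs(top)
  if (sigma > 0) set.seed(seed)
  frames <- lapply(confs, function(cf) {
    f <- eval_forcefield(cf, top, truth, pair_map = pm)$forces
    if (sigma > 0) f <- f + matrix(stats::rnorm(length(f), sd = sigma),
                                   nrow(f), 3)
    cf$forces <- f
    cf
  })
  conformation_set(frames)
}

#' Generate dilute multi-molecule frames for dimer extraction
#'
#' Scatters `n_mol` randomly oriented copies of the molecule in a cubic
#' region large enough that many molecule pairs fall in the 5-12 A
#' dimer-extraction window. Frames are finite (no box).
#'
#' @param top single-molecule alkane [topology()]
#' @param n_frames frames to produce
#' @param n_mol molecules per frame
#' @param span cube edge (A) over which molecule centers are scattered
#' @param seed RNG seed
#' @return a [conformation_set()] over [replicate_topology()]'s ordering
#' @export
make_dilute_frames <- function(top, n_frames = 5, n_mol = 12, span = 30,
                               seed = 1) {
  set.seed(seed)
  base <- ideal_geometry(top)$coords
  base <- sweep(base, 2, colMeans(base))
  nat1 <- nrow(base)
  frames <- lapply(seq_len(n_frames), function(fi) {
    coords <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
      q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      sweep(base %*% q, 2, stats::runif(3, 0, span), "+")
    }))
    conformation(coords, label = sprintf("dilute-%d", fi))
  })
  conformation_set(frames)
}

#' Extract dimer records from multi-molecule frames
#'
#' Scans every molecule pair of every frame, computes the nearest-atom
#' distance by the brute-force double loop, and keeps pairs inside the
#' `window`. At most `n` records are returned, sampled deterministically
#' from `seed`; a warning reports frames contributing no pair.
#'
#' @param confs [conformation_set()] of multi-molecule frames
#' @param top matching multi-molecule [topology()]
#' @param window closed distance interval (A), default the 5-12 A
#'   dimer-extraction range
#' @param n maximum number of records
#' @param seed RNG seed for subsampling
#' @return object of class `"dimer_set"`: list of records with fields
#'   `coords1`, `coords2`, `types1`, `types2`, `elements1`, `elements2`,
#'   `distance`, `label`
#' @export
extract_dimers <- function(confs, top, window = c(5, 12), n = Inf, seed = 1) {
  if (window[1] >= window[2]) stop("invalid window: d_min must be < d_max")
  mols <- split(seq_len(n_atoms(top)), top$atoms$mol)
  if (length(mols) < 2) {
    warning("frame(s) with fewer than two molecules: no dimers extracted")
    return(structure(list(), class = "dimer_set"))
  }
  recs <- list()
  for (fi in seq_along(confs)) {
    coords <- confs[[fi]]$coords
    for (a in seq_len(length(mols) - 1)) for (b in (a + 1):length(mols)) {
      ia <- mols[[a]]; ib <- mols[[b]]
      d <- nearest_atom_distance_xy(coords[ia, , drop = FALSE],
                                    coords[ib, , drop = FALSE])
      if (d >= window[1] && d <= window[2]) {
        recs[[length(recs) + 1L]] <- list(
          coords1 = coords[ia, , drop = FALSE],
          coords2 = coords[ib, , drop = FALSE],
          types1 = top$atoms$type[ia], types2 = top$atoms$type[ib],
          elements1 = top$atoms$element[ia], elements2 = top$atoms$element[ib],
          distance = d, label = sprintf("frame%d-mol%d-mol%d", fi, a, b))
      }
    }
  }
  if (length(recs) > n) {
    set.seed(seed)
    recs <- recs[sort(sample.int(length(recs), n))]
  }
  structure(recs, class = "dimer_set")
}

#' @export
print.dimer_set <- function(x, ...) {
  cat("Dimer set:", length(x), "record(s)\n")
  if (length(x)) {
    d <- vapply(x, `[[`, numeric(1), "distance")
    cat(sprintf("  nearest-atom distance: %.2f - %.2f A\n", min(d), max(d)))
    if (!is.null(x[[1]]$energy))
      cat("  reference dispersion energies attached\n")
  }
  invisible(x)
}

#' Mock dimer dispersion energy
#'
#' The stand-in for a dimer dispersion reference energy: the sum over
#' intermolecular carbon-carbon pairs of the damped dispersion terms only,
#' evaluated under the ground truth, optionally with Gaussian noise.
#'
#' @param dimers `"dimer_set"` from [extract_dimers()]
#' @param truth ground-truth [forcefield()]
#' @param sigma_E energy noise SD (kcal/mol)
#' @param seed RNG seed for the noise
#' @return the dimer set with an `energy` field on each record
#' @export
mock_dispersion_energy <- function(dimers, truth, sigma_E = 0, seed = 1) {
  if (sigma_E > 0) set.seed(seed)
  lk <- ff_lookup(truth$pairs, c("C6", "C8", "rd"))
  recs <- lapply(dimers, function(rec) {
    e <- 0
    i_c <- which(rec$elements1 == "C"); j_c <- which(rec$elements2 == "C")
    for (i in i_c) for (j in j_c) {
      key <- pair_key(rec$types1[i], rec$types2[j])
      r <- sqrt(sum((rec$coords1[i, ] - rec$coords2[j, ])^2))
      e <- e - lk$C6[key] / (r^6 + lk$rd[key]^6) -
        lk$C8[key] / (r^8 + lk$rd[key]^8)
    }
    if (sigma_E > 0) e <- e + stats::rnorm(1, sd = sigma_E)
    rec$energy <- unname(e)
    rec
  })
  structure(recs, class = "dimer_set")
}
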