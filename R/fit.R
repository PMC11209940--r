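#' Two-pass force-matching fit
#'
#' The central fitting routine. Pass 1 solves the linear force-matching
#' system with all charge products as independent parameters (with soft
#' charge-neutrality constraint rows). Charge Matrix Decomposition then
#' extracts per-type charges from the fitted product matrix, and pass 2
#' re-solves the system with the charge products fixed at the CMD-derived
#' values (their Coulomb contribution subtracted from the reference
#' forces) to obtain the remaining non-Coulombic parameters. Dispersion
#' coefficients are frozen throughout (they are fitted separately to dimer
#' dispersion energies, see [fit_dispersion()]); repulsion exponents b and
#' damping distances r_d are taken from `init` and never fitted.
#'
#' For molecules with only two atom types the neutrality-constrained
#' products are automatically rank-1 consistent, CMD is exact and the two
#' passes agree; the second pass is still run for uniformity.
#'
#' @param confs training [conformation_set()] with reference forces
#' @param top matching [topology()]
#' @param init starting [forcefield()] supplying b, r_d, torsion
#'   multiplicity/phase, and the frozen C6/C8 (unless `dispersion` is
#'   given)
#' @param dispersion optional data.frame (key, C6, C8) from
#'   [fit_dispersion()] overriding `init`'s dispersion coefficients
#' @param charges optional named numeric (e): skip pass 1 and CMD, fit
#'   non-Coulombic parameters with these charges fixed (must be neutral
#'   per molecule within 1e-6 e)
#' @param constraint_weight weight of the neutrality rows (default
#'   `1e3 *` median force-row RMS)
#' @param rcond SVD truncation threshold
#' @return object of class `"fm_fit"` with components `forcefield`,
#'   `pass1`, `cmd`, `pass2`, `spec`, plus stored training references for
#'   [residuals()] / [predict()]
#' @examples
#' \donttest{
#' truth <- alkane_ground_truth()
#' top1 <- make_alkane_topology("n-pentane")
#' top <- replicate_topology(top1, 3)
#' confs <- generate_conformations(top, truth, n = 12, seed = 7)
#' confs <- mock_reference_forces(confs, top, truth)
#' fit <- fm_fit(confs, top, truth)
#' coef(fit$cmd)
#' }
#' @export
fm_fit <- function(confs, top, init, dispersion = NULL, charges = NULL,
                   constraint_weight = NULL, rcond = 1e-10) {
  stopifnot(inherits(top, "topology"), inherits(init, "forcefield"))
  fix_disp <- if (is.null(dispersion)) {
    el <- setNames(init$atom_types$element, init$atom_types$name)
    carbon <- vapply(strsplit(init$pairs$key, "-", fixed = TRUE),
                     function(t_) all(el[t_] == "C"), logical(1))
    data.frame(key = init$pairs$key[carbon], C6 = init$pairs$C6[carbon],
               C8 = init$pairs$C8[carbon])
  } else dispersion

  pass1 <- NULL; cmd <- NULL
  if (is.null(charges)) {
    spec1 <- build_parameter_spec(list(top), fix_dispersion = fix_disp)
    sys1 <- build_design_matrix(confs, top, spec1, init)
    sys1 <- add_neutrality_constraints(sys1, list(top),
                                       weight = constraint_weight)
    pass1 <- solve_svd(sys1, rcond = rcond)
    p1 <- coef(pass1)
    qq <- p1[grep("^qq:", names(p1))]
    names(qq) <- sub("^qq:", "", names(qq))
    types <- sort(unique(top$atoms$type))
    Q <- build_product_matrix(qq, types)
    elements <- setNames(top$atoms$element, top$atoms$type)[types]
    cmd <- cmd_decompose(Q, elements = elements)
    charges <- coef(cmd)
    # minimal-norm neutrality restoration, applied only when CMD charges
    # violate molecular neutrality beyond 1e-6 e
    charges <- renormalize_neutral(charges, top)
  } else {
    net <- check_molecular_neutrality(charges, top)
    if (max(abs(net)) > 1e-6)
      stop("supplied charges violate molecular neutrality by ",
           format(max(abs(net))), " e")
  }

  products <- products_from_charges(charges)
  spec2 <- build_parameter_spec(list(top), fix_charge_products = products,
                                fix_dispersion = fix_disp)
  sys2 <- build_design_matrix(confs, top, spec2, init)
  pass2 <- solve_svd(sys2, rcond = rcond)

  ff <- assemble_forcefield(coef(pass2), charges, top, init, fix_disp)
  structure(list(forcefield = ff, pass1 = pass1, cmd = cmd, pass2 = pass2,
                 spec = spec2, charges = charges, topology = top,
                 dispersion = fix_disp,
                 n_frames = length(confs)),
            class = "fm_fit")
}

check_molecular_neutrality <- function(charges, top) {
  q <- charges[top$atoms$type]
  tapply(q, top$atoms$mol, sum)
}

renormalize_neutral <- function(charges, top) {
  net <- check_molecular_neutrality(charges, top)
  if (max(abs(net)) <= 1e-6) return(charges)
  # minimal-norm shift over atoms: subtract the per-molecule mean, then
  # average the per-type corrections back to type charges
  warning("CMD charges violate molecular neutrality by ",
          format(max(abs(net))), " e; applying minimal-norm shift")
  counts <- table(top$atoms$type) / top$n_molecules
  shift <- sum(charges[names(counts)] * as.numeric(counts)) /
    sum(as.numeric(counts))
  charges - shift
}

assemble_forcefield <- function(p, charges, top, init, fix_disp) {
  types <- sort(unique(top$atoms$type))
  atom_types <- data.frame(
    name = types,
    element = setNames(top$atoms$element, top$atoms$type)[types],
    charge = as.numeric(charges[types]))
  getp <- function(name) unname(p[name])

  bk <- sort(unique(bond_type_keys(top)))
  bonds <- do.call(rbind, lapply(bk, function(k) {
    kk <- getp(paste0("bond_k:", k)); kre <- getp(paste0("bond_kre:", k))
    if (abs(kk) < 1e-8) {
      warning("bond force constant ~0 for ", k, "; r_e undefined, term dropped")
      return(NULL)
    }
    data.frame(key = k, k = kk, r0 = kre / kk)
  }))
  ak <- sort(unique(angle_type_keys(top)))
  angles <- do.call(rbind, lapply(ak, function(k) {
    kk <- getp(paste0("angle_k:", k)); kte <- getp(paste0("angle_kte:", k))
    if (abs(kk) < 1e-8) {
      warning("angle force constant ~0 for ", k, "; theta_e undefined, term dropped")
      return(NULL)
    }
    data.frame(key = k, k = kk, theta0 = kte / kk)
  }))
  tk <- sort(unique(torsion_type_keys(top)))
  torsions <- do.call(rbind, lapply(tk, function(k) {
    i <- match(k, init$torsions$key)
    data.frame(key = k, A = getp(paste0("tors_A:", k)),
               m = if (is.na(i)) 3L else init$torsions$m[i],
               phi0 = if (is.na(i)) 0 else init$torsions$phi0[i])
  }))
  pk <- grep("^A:", names(p), value = TRUE)
  pkeys <- sub("^A:", "", pk)
  ii <- match(pkeys, init$pairs$key)
  di <- match(pkeys, fix_disp$key)
  pairs <- data.frame(
    key = pkeys,
    A = unname(p[pk]),
    b = init$pairs$b[ii],
    C6 = ifelse(is.na(di), 0, fix_disp$C6[di]),
    C8 = ifelse(is.na(di), 0, fix_disp$C8[di]),
    rd = init$pairs$rd[ii])
  forcefield(atom_types, bonds, angles, torsions, pairs,
             damping = init$damping)
}

#' @export
print.fm_fit <- function(x, ...) {
  cat("Two-pass force-matching fit on", x$n_frames, "frame(s)\n")
  if (!is.null(x$pass1))
    cat(sprintf("  pass 1 (free charge products): residual RMS %.6g\n",
                x$pass1$residual_rms))
  if (!is.null(x$cmd))
    cat(sprintf("  CMD: lambda1 = %.6g, rank-1 error = %.3g\n",
                x$cmd$lambda1, x$cmd$reconstruction_error))
  cat(sprintf("  pass 2 (charges fixed): residual RMS %.6g, rank %d\n",
              x$pass2$residual_rms, x$pass2$rank))
  invisible(x)
}

#' @export
summary.fm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.fm_fit")
}

#' @export
print.summary.fm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCharges (e):\n"); print(round(x$fit$charges, 6))
  cat("\nPass-2 parameters:\n")
  print(round(coef(x$fit$pass2), 6))
  cat("\nSingular values (pass 2):\n")
  print(signif(x$fit$pass2$singular_values, 4))
  invisible(x)
}

#' Coefficients of a force-matching fit
#'
#' The pass-2 parameter vector augmented with the CMD charges
#' (`charge:<type>` entries).
#'
#' @param object an `"fm_fit"`
#' @param ... unused
#' @return named numeric vector
#' @export
coef.fm_fit <- function(object, ...) {
  c(coef(object$pass2),
    setNames(object$charges, paste0("charge:", names(object$charges))))
}

#' Predict forces (and energies) for new conformations
#'
#' @param object an `"fm_fit"`
#' @param newdata a [conformation_set()] or single [conformation()]
#' @param ... unused
#' @return list of evaluation results (see [eval_forcefield()]), one per
#'   frame
#' @export
predict.fm_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "conformation")) newdata <- conformation_set(list(newdata))
  pm <- classify_pairs(object$topology)
  lapply(newdata, eval_forcefield, top = object$topology,
         ff = object$forcefield, pair_map = pm)
}

#' Pass-2 force residuals
#' @param object an `"fm_fit"`
#' @param ... unused
#' @return numeric vector of reference-minus-model force components
#' @export
residuals.fm_fit <- function(object, ...) object$pass2$residuals

#' Sample conformations from a fitted model
#'
#' Convenience wrapper: Langevin sampling under the fitted force field.
#'
#' @param object an `"fm_fit"`
#' @param nsim number of frames
#' @param seed RNG seed
#' @param ... passed to [sample_conformations()]
#' @return a [conformation_set()]
#' @export
simulate.fm_fit <- function(object, nsim = 100, seed = 1, ...) {
  sample_conformations(object$forcefield, object$topology, n_frames = nsim,
                       seed = seed, ...)
}
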