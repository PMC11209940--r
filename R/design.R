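# Force-matching linear system: the model force is linear in every fitted
# parameter once the repulsion exponents b, the damping distances r_d and
# (in the second pass) the charge products are held fixed. Bonded terms
# stay linear through the reparameterization
#   bond:  dE/dr     = 2*[bond_k]*r     - 2*[bond_kre],   bond_kre  = k_r * r_e
#   angle: dE/dtheta = 2*[angle_k]*th   - 2*[angle_kte],  angle_kte = k_th * theta_e
# so each design column is the exact derivative of the model force vector
# with respect to one parameter.

#' Parameter specification for a force-matching fit
#'
#' Enumerates the fit parameters implied by one or more topologies: one
#' charge product per unordered type pair, one repulsion prefactor A per
#' type pair, C6/C8 only for carbon-carbon pairs, and composite bonded
#' entries (`bond_k`/`bond_kre`, `angle_k`/`angle_kte`, `tors_A`) per unique
#' type tuple occurring in the topologies. Repulsion exponents b and
#' damping distances r_d are never fit parameters.
#'
#' @param topologies list of [topology()] objects
#' @param fix_charge_products optional named numeric (`"ta-tb"` keys, e^2):
#'   treat charge products as fixed at these values (the second CMD pass)
#' @param fix_dispersion optional data.frame (key, C6, C8) freezing the
#'   dispersion coefficients (the usual case: dispersion is pre-fitted to
#'   dimer energies); `NULL` leaves C6/C8 free
#' @return data.frame of class `"parameter_spec"` with columns `name`
#'   (`"kind:key"`), `kind`, `key`, `fixed`, `value`
#' @export
build_parameter_spec <- function(topologies, fix_charge_products = NULL,
                                 fix_dispersion = NULL) {
  if (length(topologies) == 0) stop("at least one topology is required")
  stopifnot(all(vapply(topologies, inherits, logical(1), "topology")))
  types <- unique(do.call(rbind, lapply(topologies, function(t_)
    unique(t_$atoms[c("type", "element")]))))
  tn <- sort(types$type)
  el <- setNames(types$element, types$type)
  cmb <- cbind(rep(tn, times = seq_along(tn)),
               unlist(lapply(seq_along(tn), function(i) tn[seq_len(i)])))
  pkeys <- sort(unique(pair_key(cmb[, 1], cmb[, 2])))
  carbon <- vapply(strsplit(pkeys, "-", fixed = TRUE),
                   function(t_) all(el[t_] == "C"), logical(1))

  rows <- list()
  add <- function(kind, key, fixed = FALSE, value = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste0(kind, ":", key), kind = kind, key = key,
      fixed = fixed, value = value)
  }
  for (k in pkeys) {
    fx <- !is.null(fix_charge_products)
    add("qq", k, fixed = fx,
        value = if (fx) unname(fix_charge_products[k]) else NA_real_)
  }
  for (k in pkeys) add("A", k)
  for (k in pkeys[carbon]) {
    if (is.null(fix_dispersion)) {
      add("C6", k); add("C8", k)
    } else {
      i <- match(k, fix_dispersion$key)
      if (is.na(i)) stop("fix_dispersion is missing carbon pair ", k)
      add("C6", k, fixed = TRUE, value = fix_dispersion$C6[i])
      add("C8", k, fixed = TRUE, value = fix_dispersion$C8[i])
    }
  }
  bk <- sort(unique(unlist(lapply(topologies, bond_type_keys))))
  ak <- sort(unique(unlist(lapply(topologies, angle_type_keys))))
  tk <- sort(unique(unlist(lapply(topologies, torsion_type_keys))))
  for (k in bk) { add("bond_k", k); add("bond_kre", k) }
  for (k in ak) { add("angle_k", k); add("angle_kte", k) }
  for (k in tk) add("tors_A", k)
  spec <- do.call(rbind, rows)
  rownames(spec) <- NULL
  if (anyDuplicated(spec$name)) stop("duplicate parameter names")
  class(spec) <- c("parameter_spec", "data.frame")
  spec
}

#' A linear force-matching system
#'
#' @param L design matrix (rows = force components or constraint rows,
#'   columns = free parameters)
#' @param f reference vector
#' @param weights per-row weights (default 1)
#' @param provenance character vector describing each row
#' @return object of class `"linear_system"`
#' @export
linear_system <- function(L, f, weights = rep(1, length(f)),
                          provenance = rep("", length(f))) {
  L <- as.matrix(L)
  stopifnot(nrow(L) == length(f), all(is.finite(L)), all(is.finite(f)),
            length(weights) == length(f))
  structure(list(L = L, f = as.numeric(f), weights = as.numeric(weights),
                 provenance = provenance), class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  cat("Linear system:", nrow(x$L), "rows x", ncol(x$L), "columns\n")
  invisible(x)
}

# per-frame geometry + type-key cache used by the column builders
frame_context <- function(conf, top, pair_map) {
  ty <- top$atoms$type
  nb <- pair_map$nonbonded
  pg <- if (nrow(nb) > 0) pair_geometry(conf$coords, nb, conf$box) else NULL
  list(
    nat = n_atoms(top),
    bond_geo = if (nrow(top$bonds)) bond_geometry(conf$coords, top$bonds),
    bond_keys = bond_type_keys(top),
    angle_geo = if (nrow(top$angles)) angle_geometry(conf$coords, top$angles),
    angle_keys = angle_type_keys(top),
    tors_geo = if (nrow(top$torsions)) torsion_geometry(conf$coords, top$torsions),
    tors_keys = torsion_type_keys(top),
    pair_geo = pg,
    pair_keys = if (!is.null(pg)) pair_key(ty[pg$pairs[, 1]], ty[pg$pairs[, 2]])
  )
}

# design column (3N force components) for one parameter on one frame
design_column <- function(ctx, top, kind, key, init_ff) {
  nat <- ctx$nat
  zero <- matrix(0, nat, 3)
  col <- switch(kind,
    qq = , A = , C6 = , C8 = {
      if (is.null(ctx$pair_geo)) return(as.numeric(zero))
      sel <- ctx$pair_keys == key
      if (!any(sel)) return(as.numeric(zero))
      g <- list(pairs = ctx$pair_geo$pairs[sel, , drop = FALSE],
                r = ctx$pair_geo$r[sel],
                u = ctx$pair_geo$u[sel, , drop = FALSE])
      dEdr <- switch(kind,
        qq = -K_COULOMB / g$r^2,
        A = {
          b <- init_ff$pairs$b[match(key, init_ff$pairs$key)]
          if (is.na(b)) stop("missing repulsion exponent b for pair ", key)
          -b * exp(-b * g$r)
        },
        C6 = {
          rd <- init_ff$pairs$rd[match(key, init_ff$pairs$key)]
          6 * g$r^5 / (g$r^6 + rd^6)^2
        },
        C8 = {
          rd <- init_ff$pairs$rd[match(key, init_ff$pairs$key)]
          8 * g$r^7 / (g$r^8 + rd^8)^2
        })
      scatter_pair_forces(nat, g$pairs, g, dEdr)
    },
    bond_k = , bond_kre = {
      sel <- ctx$bond_keys == key
      if (!any(sel)) return(as.numeric(zero))
      bonds <- top$bonds[sel, , drop = FALSE]
      g <- list(r = ctx$bond_geo$r[sel], u = ctx$bond_geo$u[sel, , drop = FALSE])
      dEdr <- if (kind == "bond_k") 2 * g$r else rep(-2, length(g$r))
      scatter_bond_forces(nat, bonds, g, dEdr)
    },
    angle_k = , angle_kte = {
      sel <- ctx$angle_keys == key
      if (!any(sel)) return(as.numeric(zero))
      angles <- top$angles[sel, , drop = FALSE]
      g <- lapply(ctx$angle_geo, function(m)
        if (is.matrix(m)) m[sel, , drop = FALSE] else m[sel])
      dEdth <- if (kind == "angle_k") 2 * g$theta else rep(-2, length(g$theta))
      scatter_angle_forces(nat, angles, g, dEdth)
    },
    tors_A = {
      sel <- ctx$tors_keys == key
      if (!any(sel)) return(as.numeric(zero))
      tors <- top$torsions[sel, , drop = FALSE]
      g <- lapply(ctx$tors_geo, function(m)
        if (is.matrix(m)) m[sel, , drop = FALSE] else m[sel])
      i <- match(key, init_ff$torsions$key)
      m_ <- if (is.na(i)) 3L else init_ff$torsions$m[i]
      phi0 <- if (is.na(i)) 0 else init_ff$torsions$phi0[i]
      dEdphi <- -m_ * sin(m_ * g$phi - phi0)
      scatter_torsion_forces(nat, tors, g, dEdphi)
    },
    stop("unknown parameter kind: ", kind))
  as.numeric(col)
}

#' Assemble the force-matching design matrix
#'
#' Builds the linear system `L p = f` whose rows are the 3N Cartesian
#' force components of every training frame and whose columns are the
#' derivatives of the model force with respect to each free parameter.
#' Contributions of fixed parameters (frozen dispersion, fixed charge
#' products) are evaluated at their fixed values and subtracted from the
#' reference forces.
#'
#' @param confs [conformation_set()] carrying reference forces
#' @param top matching [topology()]
#' @param spec [build_parameter_spec()] output
#' @param init_ff [forcefield()] supplying the fixed non-linear quantities
#'   (repulsion exponents b, damping distances r_d, torsion multiplicity
#'   and phase)
#' @return a [linear_system()]
#' @export
build_design_matrix <- function(confs, top, spec, init_ff) {
  stopifnot(inherits(spec, "parameter_spec"))
  if (any(vapply(confs, function(cf) is.null(cf$forces), logical(1))))
    stop("every conformation must carry reference forces")
  pm <- classify_pairs(top)
  free <- spec[!spec$fixed, ]
  fixed <- spec[spec$fixed, ]
  nat <- n_atoms(top)
  blocks <- vector("list", length(confs))
  fvec <- vector("list", length(confs))
  prov <- vector("list", length(confs))
  for (fi in seq_along(confs)) {
    cf <- confs[[fi]]
    ctx <- frame_context(cf, top, pm)
    Lb <- matrix(0, 3 * nat, nrow(free))
    for (pj in seq_len(nrow(free)))
      Lb[, pj] <- design_column(ctx, top, free$kind[pj], free$key[pj], init_ff)
    target <- as.numeric(cf$forces)
    for (pj in seq_len(nrow(fixed)))
      target <- target - fixed$value[pj] *
        design_column(ctx, top, fixed$kind[pj], fixed$key[pj], init_ff)
    blocks[[fi]] <- Lb
    fvec[[fi]] <- target
    prov[[fi]] <- sprintf("frame%d:atom%d:%s", fi,
                          rep(seq_len(nat), 3),
                          rep(c("x", "y", "z"), each = nat))
  }
  L <- do.call(rbind, blocks)
  colnames(L) <- free$name
  linear_system(L, unlist(fvec), provenance = unlist(prov))
}

#' Append charge-neutrality constraint rows
#'
#' For every molecule species and every atom type A it contains, appends a
#' soft constraint row encoding \eqn{\sum_B n_B Q_{AB} = 0} (n_B = count of
#' type B in the molecule), with zero reference value, scaled by `weight`.
#' Together with the force rows these rows make the charge products of a
#' neutral molecule identifiable.
#'
#' @param sys a [linear_system()] whose columns include free `qq:` entries
#' @param topologies list of [topology()] objects defining the species
#' @param weight positive row weight; default `1e3` times the median
#'   root-mean-square of the existing force rows
#' @return augmented [linear_system()]
#' @export
add_neutrality_constraints <- function(sys, topologies, weight = NULL) {
  qq_cols <- grep("^qq:", colnames(sys$L))
  if (length(qq_cols) == 0)
    stop("no free charge-product columns in the system")
  if (is.null(weight))
    weight <- 1e3 * stats::median(sqrt(rowMeans(sys$L^2)))
  if (weight <= 0) stop("constraint weight must be positive")
  species <- unique(do.call(rbind, lapply(topologies, function(t_) {
    comp <- split(t_$atoms$type, t_$atoms$mol)
    do.call(rbind, lapply(unique(lapply(comp, function(x) sort(table(x)))),
                          function(tb) {
      data.frame(key = paste(names(tb), as.integer(tb), sep = "=",
                             collapse = ";"))
    }))
  })))$key
  rows <- list(); prov <- character(0)
  for (sp in species) {
    parts <- strsplit(strsplit(sp, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    counts <- setNames(as.numeric(vapply(parts, `[`, "", 2)),
                       vapply(parts, `[`, "", 1))
    for (A in names(counts)) {
      row <- numeric(ncol(sys$L))
      for (B in names(counts)) {
        cn <- paste0("qq:", pair_key(A, B))
        j <- match(cn, colnames(sys$L))
        if (is.na(j)) stop("missing charge-product column ", cn)
        row[j] <- row[j] + counts[[B]]
      }
      rows[[length(rows) + 1L]] <- row
      prov <- c(prov, sprintf("neutrality:%s:%s", sp, A))
    }
  }
  R <- do.call(rbind, rows)
  colnames(R) <- colnames(sys$L)
  linear_system(rbind(sys$L, R), c(sys$f, numeric(nrow(R))),
                weights = c(sys$weights, rep(weight, nrow(R))),
                provenance = c(sys$provenance, prov))
}

#' Minimum-norm least-squares solve by SVD
#'
#' Solves the (possibly rank-deficient) weighted least-squares problem by
#' singular value decomposition, truncating singular values below
#' `rcond` times the largest one, and returns the minimum-Euclidean-norm
#' solution with diagnostics.
#'
#' @param sys a [linear_system()]
#' @param rcond relative truncation threshold
#' @return object of class `"fm_solution"`: `coefficients` (named),
#'   `singular_values`, `rank`, `rcond`, `residual_rms` (over force rows,
#'   i.e. rows with unit weight), `residuals`, `std_scores` (coefficient /
#'   approximate standard error)
#' @export
solve_svd <- function(sys, rcond = 1e-10) {
  stopifnot(inherits(sys, "linear_system"))
  if (all(sys$L == 0)) stop("all-zero design matrix")
  W <- sys$weights
  Lw <- sys$L * W
  fw <- sys$f * W
  # column equilibration: parameters differ by orders of magnitude in
  # natural scale (bond force constants vs charge products), so truncation
  # relative to the raw largest singular value would discard physical
  # directions; normalize columns to unit norm, solve, unscale
  cs <- sqrt(colSums(Lw^2))
  cs[cs == 0] <- 1
  sv <- svd(sweep(Lw, 2, cs, "/"))
  keep <- sv$d > rcond * sv$d[1]
  rank <- sum(keep)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  p <- (sv$v %*% (dinv * crossprod(sv$u, fw))) / cs
  p <- setNames(as.numeric(p), colnames(sys$L))
  res <- sys$f - as.numeric(sys$L %*% p)
  force_rows <- W == 1
  rms <- sqrt(mean(res[force_rows]^2))
  # approximate per-parameter standard errors from the truncated
  # pseudoinverse covariance sigma^2 * V S^-2 V'
  sigma2 <- if (sum(force_rows) > length(p)) {
    sum(res[force_rows]^2) / (sum(force_rows) - rank)
  } else NA_real_
  se <- if (is.na(sigma2)) rep(NA_real_, length(p)) else
    sqrt(sigma2 * rowSums((sv$v * rep(dinv, each = nrow(sv$v)))^2)) / cs
  structure(list(coefficients = p, singular_values = sv$d, rank = rank,
                 rcond = rcond, residual_rms = rms, residuals = res,
                 std_scores = p / se, provenance = sys$provenance),
            class = "fm_solution")
}

#' @export
print.fm_solution <- function(x, ...) {
  cat("Force-matching SVD solution:", length(x$coefficients),
      "parameters, rank", x$rank, "\n")
  cat(sprintf("  residual RMS %.6g, condition %.3g\n", x$residual_rms,
              x$singular_values[1] / min(x$singular_values[x$singular_values > 0])))
  invisible(x)
}

#' @export
coef.fm_solution <- function(object, ...) object$coefficients

#' Grid scan of a shared repulsion-exponent scale factor
#'
#' The repulsion exponent b enters the model nonlinearly and is therefore
#' never part of the linear solve; this outer scan refits the linear
#' system for each candidate scaling of all b values and reports the
#' factor minimizing the force residual.
#'
#' @param confs training [conformation_set()] with forces
#' @param top [topology()]
#' @param init_ff starting [forcefield()]
#' @param factors candidate multipliers applied to every pair's b
#' @param ... passed to [fm_fit()]
#' @return list with `factor` (best multiplier), `residuals` (named by
#'   factor), `fit` (the winning [fm_fit()])
#' @export
scan_repulsion_b <- function(confs, top, init_ff,
                             factors = seq(0.9, 1.1, by = 0.05), ...) {
  fits <- lapply(factors, function(fac) {
    ff <- init_ff
    ff$pairs$b <- ff$pairs$b * fac
    fm_fit(confs, top, ff, ...)
  })
  res <- vapply(fits, function(f) f$pass2$residual_rms, numeric(1))
  best <- which.min(res)
  list(factor = factors[best], residuals = setNames(res, factors),
       fit = fits[[best]])
}
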