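# Dispersion fitting: C6/C8 coefficients against dimer dispersion
# energies. Dispersion references are energies (not forces), so the fit is
# energy-based and performed once, before and independently of the
# force-matching iterations; the fitted coefficients are then frozen.

nearest_atom_distance_xy <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(min(d2), 0))
}

#' Nearest-atom distance between the two monomers of a dimer
#'
#' Minimum over all intermolecular atom pairs of the Euclidean distance.
#'
#' @param dimer a record from [extract_dimers()] (fields `coords1`,
#'   `coords2`)
#' @return distance in Angstrom
#' @export
nearest_atom_distance <- function(dimer) {
  if (nrow(dimer$coords1) == 0 || nrow(dimer$coords2) == 0)
    stop("empty monomer")
  d <- nearest_atom_distance_xy(dimer$coords1, dimer$coords2)
  if (d < 0.1) stop("overlapping atoms (nearest distance below 0.1 A)")
  d
}

#' Filter dimer records by nearest-atom distance
#'
#' Keeps records whose nearest-atom distance lies in the closed interval
#' \[`d_min`, `d_max`\] (default 5-12 A: shorter separations are excluded
#' because exchange-dispersion, which the model does not represent, is not
#' negligible there; the window guarantees the fitted terms pick up the
#' correct asymptotics).
#'
#' @param dimers a `"dimer_set"`
#' @param d_min,d_max window bounds (A)
#' @return filtered `"dimer_set"`; kept/discarded counts are reported via
#'   `message()`
#' @export
filter_dimers <- function(dimers, d_min = 5, d_max = 12) {
  if (d_min >= d_max) stop("d_min must be smaller than d_max")
  d <- vapply(dimers, nearest_atom_distance, numeric(1))
  keep <- d >= d_min & d <= d_max
  message(sprintf("filter_dimers: kept %d, discarded %d", sum(keep),
                  sum(!keep)))
  structure(unclass(dimers)[keep], class = "dimer_set")
}

# energy design row for one dimer: derivative of the model dispersion
# energy w.r.t. each C6/C8 coefficient (columns ordered per `coef_keys`)
dispersion_basis_row <- function(rec, coef_keys, rd_map) {
  row <- numeric(length(coef_keys))
  names(row) <- coef_keys
  i_c <- which(rec$elements1 == "C"); j_c <- which(rec$elements2 == "C")
  for (i in i_c) for (j in j_c) {
    key <- pair_key(rec$types1[i], rec$types2[j])
    rd <- rd_map[key]
    if (is.na(rd)) stop("missing damping distance for pair ", key)
    r <- sqrt(sum((rec$coords1[i, ] - rec$coords2[j, ])^2))
    k6 <- paste0("C6:", key); k8 <- paste0("C8:", key)
    row[k6] <- row[k6] - 1 / (r^6 + rd^6)
    row[k8] <- row[k8] - 1 / (r^8 + rd^8)
  }
  row
}

#' Fit C6/C8 dispersion coefficients to dimer energies
#'
#' Linear least squares of the reference dispersion energies on the damped
#' \eqn{-1/(r^6+r_d^6)} and \eqn{-1/(r^8+r_d^8)} basis summed over
#' intermolecular carbon-carbon pairs. One shared coefficient per carbon
#' type pair across all source molecules (records from different species
#' may be combined in one call); solved by the SVD engine. Damping is
#' active during the fit with the production damping distances, so fitted
#' coefficients and damping are self-consistent.
#'
#' @param dimers `"dimer_set"` with `energy` fields (see
#'   [mock_dispersion_energy()])
#' @param rd_map named numeric: damping distance per carbon pair key
#'   (e.g. `c("C2-C2" = 3.4)`)
#' @param rcond SVD truncation threshold (relative)
#' @return list with `coefficients` (data.frame key/C6/C8), `fit` (the
#'   [solve_svd()] report) and `warnings` from [stability_check()]
#' @export
fit_dispersion <- function(dimers, rd_map, rcond = 1e-10) {
  if (length(dimers) == 0) stop("no dimer records to fit")
  if (any(vapply(dimers, function(r) is.null(r$energy), logical(1))))
    stop("dimer records carry no reference energies")
  keys <- sort(unique(unlist(lapply(dimers, function(rec) {
    i_c <- rec$types1[rec$elements1 == "C"]
    j_c <- rec$types2[rec$elements2 == "C"]
    as.vector(outer(i_c, j_c, pair_key))
  }))))
  coef_keys <- c(paste0("C6:", keys), paste0("C8:", keys))
  if (length(dimers) < 2 * length(coef_keys))
    stop(sprintf(paste0("under-determined dispersion fit: %d records for %d",
                        " coefficients; need at least %d"),
                 length(dimers), length(coef_keys), 2 * length(coef_keys)))
  L <- t(vapply(dimers, dispersion_basis_row, numeric(length(coef_keys)),
                coef_keys = coef_keys, rd_map = rd_map))
  e_ref <- vapply(dimers, `[[`, numeric(1), "energy")
  sys <- linear_system(L, e_ref,
                       provenance = vapply(dimers, `[[`, character(1), "label"))
  fit <- solve_svd(sys, rcond = rcond)
  p <- coef(fit)
  coefficients <- data.frame(
    key = keys,
    C6 = unname(p[paste0("C6:", keys)]),
    C8 = unname(p[paste0("C8:", keys)])
  )
  list(coefficients = coefficients, fit = fit,
       warnings = stability_check(coefficients))
}

#' Check fitted dispersion coefficients for stability
#'
#' A negative (repulsive) C6 or C8 signals an unstable model — the same
#' pathology that ruled out a C10 term — and is flagged with the offending
#' pair and value.
#'
#' @param coefficients data.frame with columns `key`, `C6`, `C8`
#' @return character vector of warnings (empty when all coefficients are
#'   attractive)
#' @export
stability_check <- function(coefficients) {
  w <- character(0)
  for (i in seq_len(nrow(coefficients))) {
    for (cn in c("C6", "C8")) {
      v <- coefficients[[cn]][i]
      if (v < 0)
        w <- c(w, sprintf("repulsive %s = %.6g for pair %s: unstable model",
                          cn, v, coefficients$key[i]))
    }
  }
  w
}
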