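#' Molecular topology
#'
#' A topology lists the atoms of one or more molecules together with their
#' atom types and the bonded terms (bonds, angles, torsions) enumerated from
#' the covalent bond graph. Torsions whose terminal atom is a hydrogen are
#' never included: only heavy-atom (carbon backbone) torsions are modeled.
#'
#' @param atoms data.frame with columns `type` (atom type label), `element`
#'   (chemical element symbol) and `mol` (1-based molecule id). Atoms are
#'   implicitly numbered 1..n in row order.
#' @param bonds integer matrix with two columns, one covalent bond per row.
#' @param angles optional integer matrix with three columns (i-j-k, j is the
#'   apex). Enumerated from `bonds` when `NULL`.
#' @param torsions optional integer matrix with four columns. Enumerated
#'   from `bonds` when `NULL`, omitting any torsion that involves hydrogen.
#' @return An object of class `"topology"`.
#' @examples
#' top <- make_alkane_topology("n-butane")
#' top$n_molecules
#' @export
topology <- function(atoms, bonds, angles = NULL, torsions = NULL) {
  stopifnot(is.data.frame(atoms), all(c("type", "element", "mol") %in% names(atoms)))
  n <- nrow(atoms)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && (any(bonds < 1) || any(bonds > n)))
    stop("bond index out of range")
  if (nrow(bonds) > 0) {
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond")
    # canonical order, uniqueness
    bonds <- matrix(t(apply(bonds, 1, sort)), ncol = 2)
    if (anyDuplicated(paste(bonds[, 1], bonds[, 2]))) stop("duplicate bond")
    if (any(atoms$mol[bonds[, 1]] != atoms$mol[bonds[, 2]]))
      stop("bond crossing molecule boundary")
  }

  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }

  if (is.null(angles)) angles <- enumerate_angles(adj)
  if (is.null(torsions)) {
    torsions <- enumerate_torsions(adj)
    if (nrow(torsions) > 0) {
      keep <- atoms$element[torsions[, 1]] != "H" &
        atoms$element[torsions[, 2]] != "H" &
        atoms$element[torsions[, 3]] != "H" &
        atoms$element[torsions[, 4]] != "H"
      torsions <- torsions[keep, , drop = FALSE]
    }
  }
  angles <- matrix(as.integer(angles), ncol = 3)
  torsions <- matrix(as.integer(torsions), ncol = 4)

  structure(list(
    atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
    n_molecules = length(unique(atoms$mol)), adjacency = adj
  ), class = "topology")
}

enumerate_angles <- function(adj) {
  out <- list()
  for (j in seq_along(adj)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (c_ in seq_len(ncol(cmb)))
        out[[length(out) + 1L]] <- c(cmb[1, c_], j, cmb[2, c_])
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 3))
  do.call(rbind, out)
}

enumerate_torsions <- function(adj) {
  out <- list()
  n <- length(adj)
  for (j in seq_len(n)) for (k in adj[[j]]) {
    if (j >= k) next  # central bond j-k once
    for (i in adj[[j]]) for (l in adj[[k]]) {
      if (i == k || l == j || i == l) next
      out[[length(out) + 1L]] <- c(i, j, k, l)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 4))
  do.call(rbind, out)
}

#' @export
print.topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms in", x$n_molecules, "molecule(s)\n")
  cat("  types:", paste(sort(unique(x$atoms$type)), collapse = ", "), "\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " torsions:", nrow(x$torsions), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a [topology()]
#' @return integer atom count
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Classify atom pairs into excluded and nonbonded sets
#'
#' Pairs separated by one (1-2) or two (1-3) covalent bonds are excluded
#' from noncovalent interactions; pairs separated by more than two bonds
#' (1-4 and beyond) or belonging to different molecules interact at full
#' strength — no 1-4 scaling is applied.
#'
#' @param top a [topology()]
#' @return list with integer matrices `nonbonded` and `excluded`, each with
#'   columns `i < j`.
#' @examples
#' cp <- classify_pairs(make_alkane_topology("n-butane"))
#' nrow(cp$nonbonded)
#' @export
classify_pairs <- function(top) {
  stopifnot(inherits(top, "topology"))
  n <- n_atoms(top)
  mol <- top$atoms$mol
  # graph distances up to 2 via BFS depth-2; also check per-molecule
  # connectivity with a full BFS from each molecule's first atom
  adj <- top$adjacency
  for (m in unique(mol)) {
    members <- which(mol == m)
    seen <- rep(FALSE, n)
    queue <- members[1]; seen[queue] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen[members]))
      stop(sprintf("molecule %s is not a connected bond graph", m))
  }
  excl <- list()
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    near <- setdiff(unique(c(one, two)), i)
    near <- near[near > i]
    if (length(near) > 0) excl[[length(excl) + 1L]] <- cbind(i, near)
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else matrix(integer(0), ncol = 2)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  allp <- cbind(ut[, "row"], ut[, "col"])
  key <- function(m_) paste(m_[, 1], m_[, 2])
  nb <- allp[!(key(allp) %in% key(excluded)), , drop = FALSE]
  dimnames(excluded) <- NULL; dimnames(nb) <- NULL
  list(nonbonded = nb, excluded = excluded)
}

# canonical keys for parameter lookup -----------------------------------

pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
}

triple_key <- function(a, b, c_) {
  ifelse(a <= c_, paste(a, b, c_, sep = "-"), paste(c_, b, a, sep = "-"))
}

quad_key <- function(a, b, c_, d) {
  fw <- paste(a, b, c_, d, sep = "-")
  bw <- paste(d, c_, b, a, sep = "-")
  ifelse(fw <= bw, fw, bw)
}

# type keys for every bonded term of a topology
bond_type_keys <- function(top) {
  ty <- top$atoms$type
  if (nrow(top$bonds) == 0) return(character(0))
  pair_key(ty[top$bonds[, 1]], ty[top$bonds[, 2]])
}

angle_type_keys <- function(top) {
  ty <- top$atoms$type
  if (nrow(top$angles) == 0) return(character(0))
  triple_key(ty[top$angles[, 1]], ty[top$angles[, 2]], ty[top$angles[, 3]])
}

torsion_type_keys <- function(top) {
  ty <- top$atoms$type
  if (nrow(top$torsions) == 0) return(character(0))
  quad_key(ty[top$torsions[, 1]], ty[top$torsions[, 2]],
           ty[top$torsions[, 3]], ty[top$torsions[, 4]])
}

#' Replicate a single-molecule topology
#'
#' Builds an n-copy topology (e.g. a 6-molecule training cluster) from a
#' one-molecule template; atom indices are offset per copy and molecule ids
#' run 1..n.
#'
#' @param top single-molecule [topology()]
#' @param n number of copies
#' @return a [topology()] with `n` molecules
#' @export
replicate_topology <- function(top, n) {
  stopifnot(inherits(top, "topology"), n >= 1)
  na <- n_atoms(top)
  atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
    a <- top$atoms
    a$mol <- k
    a
  }))
  rownames(atoms) <- NULL
  off <- rep((seq_len(n) - 1L) * na, each = nrow(top$bonds))
  bonds <- top$bonds[rep(seq_len(nrow(top$bonds)), n), , drop = FALSE] + off
  out <- topology(atoms, bonds)
  attr(out, "n_carbons") <- attr(top, "n_carbons")
  attr(out, "cyclic") <- attr(top, "cyclic")
  out
}
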