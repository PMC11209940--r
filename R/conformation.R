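#' A single conformation (frame)
#'
#' @param coords N x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param forces optional N x 3 matrix of reference forces
#'   (kcal/mol/Angstrom).
#' @param box optional length-3 numeric of orthorhombic box edges (Angstrom);
#'   `NULL` for finite clusters (no periodicity).
#' @param label frame label carried through i/o round trips.
#' @param energy optional scalar reference energy (kcal/mol).
#' @return object of class `"conformation"`
#' @export
conformation <- function(coords, forces = NULL, box = NULL, label = "",
                         energy = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (!identical(dim(forces), dim(coords)))
      stop("force array shape does not match coordinates")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3, all(box > 0))
  }
  structure(list(coords = coords, forces = forces, box = box,
                 label = as.character(label), energy = energy),
            class = "conformation")
}

#' A set of conformations
#' @param frames list of [conformation()] objects
#' @return object of class `"conformation_set"` (a list)
#' @export
conformation_set <- function(frames) {
  stopifnot(all(vapply(frames, inherits, logical(1), "conformation")))
  structure(frames, class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  na <- if (length(x)) nrow(x[[1]]$coords) else 0
  hasf <- length(x) && !is.null(x[[1]]$forces)
  cat("Conformation set:", length(x), "frame(s),", na, "atoms",
      if (hasf) "(with reference forces)" else "", "\n")
  invisible(x)
}

#' @export
`[.conformation_set` <- function(x, i) conformation_set(unclass(x)[i])

#' Combine conformation sets
#' @param ... conformation_set objects
#' @return pooled conformation_set
#' @export
c.conformation_set <- function(...) {
  conformation_set(unlist(lapply(list(...), unclass), recursive = FALSE))
}
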