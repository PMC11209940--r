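#' Radial distribution function
#'
#' Shell-normalized pair-distance histogram with ideal-gas normalization
#' at the frame's density, averaged over frames. By default only
#' intermolecular pairs are counted (the liquid-structure diagnostic used
#' for AFM convergence).
#'
#' @param confs [conformation_set()] of periodic frames (each needs a box)
#' @param top matching [topology()]
#' @param sel_a,sel_b atom selectors: an atom type label (e.g. `"C2"`) or
#'   an element symbol (e.g. `"C"`)
#' @param r_max histogram range (A); must not exceed half the smallest box
#'   edge
#' @param n_bins number of bins
#' @param intermolecular count only pairs in different molecules
#' @return object of class `"rdf"`: `edges`, `r` (bin centers), `g`,
#'   `pair` (label), `n_frames`
#' @export
compute_rdf <- function(confs, top, sel_a = "C", sel_b = "C", r_max = 6,
                        n_bins = 60, intermolecular = TRUE) {
  stopifnot(length(confs) >= 1)
  pick <- function(sel) {
    hit <- top$atoms$type == sel | top$atoms$element == sel
    if (!any(hit)) stop("selector matches no atoms: ", sel)
    which(hit)
  }
  ia <- pick(sel_a); ib <- pick(sel_b)
  edges <- seq(0, r_max, length.out = n_bins + 1)
  shell <- 4 / 3 * pi * diff(edges^3)
  acc <- numeric(n_bins)
  for (cf in confs) {
    if (is.null(cf$box)) stop("RDF requires periodic frames (box present)")
    if (r_max > min(cf$box) / 2)
      stop("r_max exceeds half the smallest box edge")
    pr <- expand.grid(i = ia, j = ib)
    pr <- pr[pr$i < pr$j | (identical(ia, ib) == FALSE & pr$i != pr$j), ]
    # unordered pairs once: for identical selections keep i < j, for
    # different selections keep i != j but drop the duplicated mirror
    if (identical(sort(ia), sort(ib))) {
      pr <- pr[pr$i < pr$j, ]
    } else {
      pr <- pr[pr$i != pr$j, ]
      key <- pmin(pr$i, pr$j) * 1e6 + pmax(pr$i, pr$j)
      pr <- pr[!duplicated(key), ]
    }
    if (intermolecular)
      pr <- pr[top$atoms$mol[pr$i] != top$atoms$mol[pr$j], ]
    if (nrow(pr) == 0) stop("no eligible pairs for RDF selectors")
    d <- min_image(cf$coords[pr$j, , drop = FALSE] -
                     cf$coords[pr$i, , drop = FALSE], cf$box)
    r <- sqrt(rowSums(d^2))
    h <- graphics::hist(r[r < r_max], breaks = edges, plot = FALSE)$counts
    vol <- prod(cf$box)
    acc <- acc + h / (nrow(pr) * shell / vol)
  }
  structure(list(edges = edges, r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = acc / length(confs),
                 pair = paste(sel_a, sel_b, sep = "-"),
                 n_frames = length(confs)), class = "rdf")
}

#' @export
print.rdf <- function(x, ...) {
  cat("RDF", x$pair, "over", x$n_frames, "frame(s),",
      length(x$g), "bins to", max(x$edges), "A\n")
  invisible(x)
}

#' @export
plot.rdf <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (A)", ylab = "g(r)",
                 main = paste("RDF", x$pair), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Distance between two RDFs
#'
#' Maximum absolute difference of g(r) over bins; the AFM convergence
#' metric (generations are converged when the tracked RDFs stop changing).
#'
#' @param a,b `"rdf"` objects on identical binning
#' @return non-negative scalar
#' @export
rdf_distance <- function(a, b) {
  stopifnot(inherits(a, "rdf"), inherits(b, "rdf"))
  if (!isTRUE(all.equal(a$edges, b$edges)))
    stop("RDFs have mismatched binning")
  max(abs(a$g - b$g))
}
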