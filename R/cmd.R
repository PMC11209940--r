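# Charge Matrix Decomposition (CMD): per-type partial charges from the
# symmetric matrix of fitted charge products via its dominant eigenpair.
# With more than two atom types the independently fitted products Q_AB
# generally violate the rank-1 consistency Q_AB * Q_CD = Q_AC * Q_BD, so no
# exact charge set exists; the dominant eigenpair gives the best rank-1
# approximation in the Frobenius norm (Eckart-Young), and q_A =
# sqrt(lambda_1) v_A are the optimal charges.

#' Build the symmetric charge-product matrix
#'
#' @param products named numeric vector of fitted charge products keyed by
#'   canonical type pair (`"A-B"`, units e^2); one entry per unordered pair
#' @param types character vector of type labels (matrix order)
#' @return T x T symmetric matrix of class `"charge_product_matrix"` with
#'   dimnames `types`
#' @export
build_product_matrix <- function(products, types) {
  T_ <- length(types)
  Q <- matrix(NA_real_, T_, T_, dimnames = list(types, types))
  for (i in seq_len(T_)) for (j in i:T_) {
    key <- pair_key(types[i], types[j])
    v <- products[key]
    if (is.na(v)) stop("missing charge product for pair ", key)
    Q[i, j] <- Q[j, i] <- unname(v)
  }
  structure(Q, class = c("charge_product_matrix", "matrix", "array"))
}

check_symmetric <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || !isTRUE(all.equal(Q, t(Q),
                                                    tolerance = 1e-12)))
    stop("charge-product matrix must be symmetric")
}

#' Charge Matrix Decomposition
#'
#' Eigendecomposes the real symmetric charge-product matrix. If the
#' largest eigenvalue \eqn{\lambda_1} is positive, the per-type charges are
#' \eqn{q_A = \sqrt{\lambda_1}\, v_A} with the eigenvector sign chosen so
#' the anchor type carries a non-negative charge; if no positive
#' eigenvalue exists (imaginary charges), all charges are zero. The anchor
#' is hydrogen when present, otherwise the least electronegative element
#' (Pauling scale), ties broken by type label order.
#'
#' @param Q symmetric matrix with type labels as dimnames (see
#'   [build_product_matrix()])
#' @param elements named character: element per type; needed to pick the
#'   anchor unless `sign_anchor` is given
#' @param sign_anchor optional type label to anchor the sign rule
#' @return object of class `"cmd_charges"`: `charges` (named, e),
#'   `lambda1`, `eigenvalues`, `reconstruction_error` (Frobenius norm of
#'   \eqn{Q - \lambda_1 v v^T}), `anchor`
#' @examples
#' q <- c(HC = 0.05, C2 = -0.1)
#' Q <- outer(q, q)
#' coef(cmd_decompose(Q, elements = c(HC = "H", C2 = "C")))
#' @export
cmd_decompose <- function(Q, elements = NULL, sign_anchor = NULL) {
  check_symmetric(Q)
  types <- rownames(Q)
  if (is.null(types)) stop("Q must carry type labels as dimnames")
  if (is.null(sign_anchor)) {
    if (is.null(elements)) stop("need `elements` to choose the sign anchor")
    el <- elements[types]
    sign_anchor <- if (any(el == "H")) {
      sort(types[el == "H"])[1]
    } else {
      en <- PAULING_EN[el]
      sort(types[which(en == min(en, na.rm = TRUE))])[1]
    }
  }
  ei <- eigen(Q, symmetric = TRUE)
  lambda1 <- ei$values[1]
  if (lambda1 <= 0) {
    charges <- setNames(numeric(length(types)), types)
    return(structure(list(charges = charges, lambda1 = lambda1,
                          eigenvalues = ei$values,
                          reconstruction_error = norm(Q, "F"),
                          anchor = sign_anchor), class = "cmd_charges"))
  }
  # degeneracy of lambda_1: pick the eigenvector with the largest
  # |component| on the anchor type
  deg <- which(abs(ei$values - lambda1) <= 1e-12 * max(1, abs(lambda1)))
  ai <- match(sign_anchor, types)
  if (is.na(ai)) stop("anchor type not in matrix: ", sign_anchor)
  if (length(deg) > 1) {
    warning("degenerate dominant eigenvalue; choosing eigenvector with ",
            "largest anchor component")
    pick <- deg[which.max(abs(ei$vectors[ai, deg]))]
  } else pick <- 1L
  v <- ei$vectors[, pick]
  if (v[ai] < 0) v <- -v
  charges <- setNames(sqrt(lambda1) * v, types)
  recon <- lambda1 * tcrossprod(v)
  structure(list(charges = charges, lambda1 = lambda1,
                 eigenvalues = ei$values,
                 reconstruction_error = norm(Q - recon, "F"),
                 anchor = sign_anchor), class = "cmd_charges")
}

#' @export
print.cmd_charges <- function(x, ...) {
  cat("CMD charge assignment (anchor ", x$anchor, "):\n", sep = "")
  print(round(x$charges, 6))
  cat(sprintf("  lambda1 = %.6g, rank-1 Frobenius error = %.3g\n",
              x$lambda1, x$reconstruction_error))
  invisible(x)
}

#' @export
coef.cmd_charges <- function(object, ...) object$charges

#' Charge products implied by a charge assignment
#'
#' The outer product \eqn{Q'_{AB} = q_A q_B}; by construction these
#' products satisfy the rank-1 consistency identity
#' \eqn{Q'_{AB} Q'_{CD} = Q'_{AC} Q'_{BD}} exactly.
#'
#' @param assignment a `"cmd_charges"` object or a named numeric vector of
#'   charges
#' @return named numeric vector of products keyed by canonical type pair
#' @export
products_from_charges <- function(assignment) {
  q <- if (inherits(assignment, "cmd_charges")) assignment$charges
       else assignment
  types <- names(q)
  out <- numeric(0)
  for (i in seq_along(types)) for (j in i:length(types)) {
    out[pair_key(types[i], types[j])] <- q[[i]] * q[[j]]
  }
  out
}

#' Rank-1 consistency defect of a charge-product matrix
#'
#' The maximum over index quadruples of
#' \eqn{|Q_{AB} Q_{CD} - Q_{AC} Q_{BD}|}; zero iff the products are
#' consistent with a single charge vector (up to sign).
#'
#' @param Q symmetric charge-product matrix
#' @return non-negative scalar
#' @export
consistency_defect <- function(Q) {
  check_symmetric(Q)
  T_ <- nrow(Q)
  worst <- 0
  for (a in 1:T_) for (b in 1:T_) for (c_ in 1:T_) for (d in 1:T_) {
    worst <- max(worst, abs(Q[a, b] * Q[c_, d] - Q[a, c_] * Q[b, d]))
  }
  worst
}
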