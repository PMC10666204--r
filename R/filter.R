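# Generalized Laplacian smoothing filter.  With self-looped adjacency
# At = I + A, degree Dt = diag(rowSums(At)) and L = Dt - At, the symmetric
# normalized Laplacian Lsym = Dt^(-1/2) L Dt^(-1/2) has spectrum in [0, 2);
# the filter H = I - alpha * Lsym attenuates high-frequency (neighbour-
# inconsistent) feature components, and repeated application smooths
# attributes along the graph.

#' Build the Laplacian smoothing filter H = I - alpha * Lsym
#'
#' @param A binary symmetric adjacency matrix (zero diagonal), typically
#'   from [build_adjacency()].
#' @param alpha smoothing strength in \[0, 1\] (default 2/3).
#' @param laplacian_sign `"minus"` (default) builds the standard Laplacian
#'   `Dt - At`; `"plus"` builds `Dt + At`, an anti-smoothing variant kept
#'   only for replication experiments.
#' @return sparse symmetric n x n operator (class from the Matrix package)
#'   with the gene dimnames of `A`.
#' @details Self-loops guarantee every degree is at least 1, so the
#'   normalization is always defined, including for isolated nodes (an
#'   isolated node gets `H[i, i] = 1` and is passed through unchanged).
#' @export
build_filter <- function(A, alpha = 2 / 3, laplacian_sign = c("minus", "plus")) {
  laplacian_sign <- match.arg(laplacian_sign)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  n <- nrow(A)
  stopifnot(n == ncol(A))
  At <- Matrix::Diagonal(n) + A
  dt <- Matrix::rowSums(At)
  Dm12 <- Matrix::Diagonal(n, x = 1 / sqrt(dt))
  L <- if (laplacian_sign == "minus") Matrix::Diagonal(n, x = dt) - At
       else Matrix::Diagonal(n, x = dt) + At
  Lsym <- Dm12 %*% L %*% Dm12
  H <- Matrix::Diagonal(n) - alpha * Lsym
  H <- Matrix::forceSymmetric(H)
  dimnames(H) <- dimnames(A)
  H
}

#' Apply the smoothing filter t times: Xs = H^t X
#'
#' Performed as `t` successive sparse multiplications; `t = 0` returns `X`
#' unchanged.  The result carries `alpha`/`t` provenance attributes.
#'
#' @param H operator from [build_filter()].
#' @param X attribute matrix (genes x features), rows aligned with `H`.
#' @param t non-negative integer stack count (default 2).
#' @return dense base matrix of the same shape as `X`.
#' @export
apply_filter <- function(H, X, t = 2L) {
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer")
  if (nrow(X) != nrow(H)) stop("shape mismatch: H is ", nrow(H), " x ", ncol(H),
                               " but X has ", nrow(X), " rows")
  Xs <- as.matrix(X)
  for (k in seq_len(t)) Xs <- as.matrix(H %*% Xs)
  dimnames(Xs) <- dimnames(X)
  structure(Xs, alpha = attr(H, "alpha"), t = t)
}
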