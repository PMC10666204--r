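# Self-supervised pretraining of the linear encoder.  The pretext task:
# encode smoothed attributes with Z = Xs %*% W (min-max scaled to [0,1] per
# column), rank all unordered gene pairs by cosine similarity, call the top
# k "positive" and the bottom k "negative", and train W so that positive
# pairs approach similarity 1 and negative pairs similarity 0 under a
# binary cross-entropy on the similarities themselves.  The pair sets are
# re-selected as the embedding evolves.

#' Encode node embeddings with the linear encoder
#'
#' `Z = Xs %*% W`, followed by per-column min-max scaling to \[0, 1\]
#' (a constant column scales to all zeros).  Scaling is part of the encoder
#' definition: it keeps `Z` non-negative so that pair cosine similarities
#' land in \[0, 1\] and can serve directly as probabilities in the
#' self-supervised loss.
#'
#' @param Xs smoothed feature matrix (genes x d).
#' @param W encoder weight matrix (d x e).
#' @return embedding matrix (genes x e) with entries in \[0, 1\].
#' @export
encode <- function(Xs, W) {
  Z0 <- Xs %*% W
  if (!all(is.finite(Z0))) {
    bad <- which(!apply(is.finite(Z0), 2L, all))
    stop("non-finite embedding values in column(s) ", paste(bad, collapse = ", "))
  }
  Z <- minmax_scale(Z0)$scaled
  dimnames(Z) <- list(rownames(Xs), NULL)
  Z
}

#' Pairwise cosine similarity of embedding rows
#'
#' `S[i, j] = <z_i, z_j> / (|z_i| |z_j|)`; with non-negative embeddings the
#' result lies in \[0, 1\].  All-zero rows get similarity 0 to everything
#' (including themselves); nonzero rows get an exact unit diagonal.
#'
#' @param Z embedding matrix (genes x e), entries >= 0.
#' @return symmetric n x n similarity matrix.
#' @export
cosine_similarity_matrix <- function(Z) {
  rn <- sqrt(rowSums(Z^2))
  nz <- rn > 0
  if (any(!nz)) message(sum(!nz), " all-zero embedding row(s): similarity set to 0")
  Zn <- Z
  Zn[nz, ] <- Z[nz, , drop = FALSE] / rn[nz]
  Zn[!nz, ] <- 0
  S <- tcrossprod(Zn)
  S <- clamp(S, 0, 1)
  diag(S) <- as.numeric(nz)
  S
}

# All unordered non-self pairs (i < j) of n nodes, in lexicographic order.
all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Select the self-supervision training pairs
#'
#' Sorts all unordered non-self pairs by similarity (descending, ties broken
#' lexicographically by `(i, j)` for determinism); the top `k` pairs become
#' positives and the bottom `k` negatives.  The two windows must not
#' overlap, which bounds `2k` by the number of distinct pairs.
#'
#' @param S similarity matrix from [cosine_similarity_matrix()].
#' @param k number of positive (= negative) pairs.
#' @return list of class `pair_set`: `positives`, `negatives` (two-column
#'   index matrices, `i < j`) and `k`.
#' @export
select_training_pairs <- function(S, k) {
  n <- nrow(S)
  pairs <- all_pairs(n)
  total <- nrow(pairs)
  if (k < 1L) stop("k must be >= 1")
  if (2L * k > total)
    stop(sprintf("k = %d too large: only %d unordered pairs exist (need 2k <= %d)",
                 k, total, total))
  s <- S[pairs]
  ord <- order(-s, pairs[, 1L], pairs[, 2L])
  pos <- pairs[ord[seq_len(k)], , drop = FALSE]
  neg <- pairs[ord[seq.int(total - k + 1L, total)], , drop = FALSE]
  structure(list(positives = pos, negatives = neg, k = k), class = "pair_set")
}

#' Self-supervised cross-entropy loss on pair similarities
#'
#' Sum over the `2k` selected pairs of the binary cross-entropy with the
#' pair similarity as the predicted probability: positives contribute
#' `-log(s)`, negatives `-log(1 - s)`.  Similarities are clamped to
#' `[eps, 1 - eps]` so the loss stays finite.
#'
#' @param S similarity matrix.
#' @param pairs a `pair_set` from [select_training_pairs()].
#' @param eps clamp width (default 1e-15).
#' @return scalar loss (>= 0).
#' @export
ssl_loss <- function(S, pairs, eps = 1e-15) {
  sp <- clamp(S[pairs$positives], eps, 1 - eps)
  sn <- clamp(S[pairs$negatives], eps, 1 - eps)
  -sum(log(sp)) - sum(log(1 - sn))
}

# Forward pass pieces shared by pretrain(): returns the scaled embedding,
# row norms and the scaling record needed for the backward pass.
ssl_forward <- function(Xs, W) {
  Z0 <- Xs %*% W
  sc <- minmax_scale(Z0)
  Z <- sc$scaled
  rn <- sqrt(rowSums(Z^2))
  list(Z = Z, rn = rn, range = sc$range)
}

#' Pretrain the linear encoder on the pair pretext task
#'
#' Runs Adam on the encoder weights `W`.  Each epoch: encode, build the
#' cosine similarity matrix, re-select the positive/negative pair sets
#' every `reselect_every` epochs, and take one full-batch gradient step on
#' the pair cross-entropy.  The per-column min-max scaling constants are
#' treated as fixed within each step.  Deterministic given `seed`.
#'
#' @param Xs smoothed feature matrix (genes x d).
#' @param embed_dim embedding width `e` (default 2048).
#' @param k number of positive pairs; default `10 * n`, capped at the
#'   feasible maximum.
#' @param epochs gradient steps (default 100); `epochs = 0` returns the
#'   freshly initialized encoder and its embedding.
#' @param learning_rate Adam step size (default 0.001).
#' @param reselect_every epochs between pair re-selections (default 1).
#' @param seed RNG seed for the weight initialization.
#' @return list with `W` (d x e), `Z` (final scaled embedding), and `trace`
#'   (data.frame epoch / loss / k).
#' @export
pretrain <- function(Xs, embed_dim = 2048L, k = NULL, epochs = 100L,
                     learning_rate = 0.001, reselect_every = 1L, seed = 1L) {
  n <- nrow(Xs)
  d <- ncol(Xs)
  stopifnot(embed_dim >= 1L, epochs >= 0L, reselect_every >= 1L, n >= 2L)
  total_pairs <- n * (n - 1) / 2
  if (is.null(k)) k <- min(10L * n, floor(total_pairs / 2))
  if (2 * k > total_pairs)
    stop("k too large for ", n, " genes: need 2k <= ", total_pairs)

  set.seed(as.integer(seed))
  # symmetric uniform initialization scaled by 1/sqrt(d)
  W <- matrix(stats::runif(d * embed_dim, -1, 1) / sqrt(d), d, embed_dim)

  if (epochs == 0L) {
    fw <- ssl_forward(Xs, W)
    return(list(W = W, Z = structure(fw$Z, dimnames = list(rownames(Xs), NULL)),
                trace = data.frame(epoch = integer(0), loss = numeric(0),
                                   k = integer(0))))
  }

  st <- adam_init(list(W = W))
  pairs <- NULL
  trace <- data.frame(epoch = seq_len(epochs), loss = NA_real_, k = k)
  eps <- 1e-15

  for (ep in seq_len(epochs)) {
    fw <- ssl_forward(Xs, W)
    Z <- fw$Z
    rn <- fw$rn
    if (is.null(pairs) || (ep - 1L) %% reselect_every == 0L) {
      S <- cosine_similarity_matrix(Z)
      pairs <- select_training_pairs(S, k)
    }
    I <- c(pairs$positives[, 1L], pairs$negatives[, 1L])
    J <- c(pairs$positives[, 2L], pairs$negatives[, 2L])
    y <- rep(c(1, 0), times = c(pairs$k, pairs$k))

    ok <- rn[I] > 0 & rn[J] > 0
    Uh <- Z[I, , drop = FALSE] / pmax(rn[I], eps)
    Vh <- Z[J, , drop = FALSE] / pmax(rn[J], eps)
    s_raw <- rowSums(Uh * Vh)
    s_raw[!ok] <- 0
    s <- clamp(s_raw, eps, 1 - eps)
    loss <- -sum(y * log(s) + (1 - y) * log(1 - s))
    if (!is.finite(loss))
      stop(sprintf("non-finite SSL loss at epoch %d (k = %d, mean s = %.3g)",
                   ep, pairs$k, mean(s)))
    trace$loss[ep] <- loss

    # dL/ds with a wider clamp than the loss (keeps single-step gradients
    # bounded); zero where the similarity is undefined (zero row)
    sg <- clamp(s_raw, 1e-7, 1 - 1e-7)
    g <- -(y / sg) + (1 - y) / (1 - sg)
    g[!ok] <- 0
    # cosine backward: ds/du = (vh - s*uh)/|u|
    GU <- (Vh - s * Uh) * (g / pmax(rn[I], eps))
    GV <- (Uh - s * Vh) * (g / pmax(rn[J], eps))
    agg <- rowsum(rbind(GU, GV), group = c(I, J))
    dZ <- matrix(0, n, ncol(Z))
    dZ[as.integer(rownames(agg)), ] <- agg
    # through the (stop-gradient) min-max scaling: divide by the column range
    rngsafe <- ifelse(fw$range > 0, fw$range, Inf)
    dZ0 <- sweep(dZ, 2L, rngsafe, "/")
    gradW <- crossprod(Xs, dZ0)

    upd <- adam_step(list(W = W), list(W = gradW), st, lr = learning_rate)
    W <- upd$params$W
    st <- upd$state
  }

  fw <- ssl_forward(Xs, W)
  list(W = W,
       Z = structure(fw$Z, dimnames = list(rownames(Xs), NULL)),
       trace = trace)
}
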