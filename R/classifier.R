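# Multi-label deep classifier: embeddings -> phenotype-term probabilities.
# Each hidden layer is affine -> batch normalization -> LeakyReLU; the
# output layer is affine -> sigmoid, one unit per phenotype term.  Training
# minimizes the multi-label binary cross-entropy (mean over gene-term pairs
# in a batch) with Adam.  Batch-norm keeps running statistics so inference
# is batch-independent.

#' Classifier configuration
#'
#' @param hidden_sizes widths of the hidden layers (default `c(1024, 512,
#'   512)`; the architecture fixes three hidden layers by default but any
#'   length is accepted).
#' @param leaky_slope LeakyReLU negative slope (default 0.01).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate initial Adam step size (default 0.001).
#' @param epochs maximum training epochs (default 200).
#' @param patience early-stopping patience on the validation loss, in
#'   epochs (default 20); set `val_fraction = 0` to disable early stopping.
#' @param val_fraction fraction of training genes held out for validation
#'   (default 0.1).
#' @param seed RNG seed for initialization, batching and the validation
#'   split.
#' @export
classifier_config <- function(hidden_sizes = c(1024L, 512L, 512L),
                              leaky_slope = 0.01, batch_size = 128L,
                              learning_rate = 0.001, epochs = 200L,
                              patience = 20L, val_fraction = 0.1, seed = 1L) {
  stopifnot(all(hidden_sizes >= 1L), batch_size >= 1L, learning_rate > 0,
            epochs >= 0L, val_fraction >= 0, val_fraction < 1)
  list(hidden_sizes = as.integer(hidden_sizes), leaky_slope = leaky_slope,
       batch_size = as.integer(batch_size), learning_rate = learning_rate,
       epochs = as.integer(epochs), patience = as.integer(patience),
       val_fraction = val_fraction, seed = as.integer(seed))
}

mlp_init <- function(d_in, hidden, q, seed) {
  set.seed(as.integer(seed))
  dims <- c(d_in, hidden)
  params <- list()
  for (l in seq_along(hidden)) {
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
      dims[l], dims[l + 1L])
    params[[paste0("gamma", l)]] <- rep(1, dims[l + 1L])
    params[[paste0("beta", l)]] <- rep(0, dims[l + 1L])
  }
  params$Wo <- matrix(stats::rnorm(dims[length(dims)] * q,
                                   sd = sqrt(1 / dims[length(dims)])),
                      dims[length(dims)], q)
  params$bo <- rep(0, q)
  running <- list()
  for (l in seq_along(hidden)) {
    running[[paste0("mu", l)]] <- rep(0, dims[l + 1L])
    running[[paste0("var", l)]] <- rep(1, dims[l + 1L])
  }
  list(params = params, running = running, n_hidden = length(hidden))
}

# Forward pass.  training = TRUE uses batch statistics (and returns a cache
# for the backward pass plus updated running stats); training = FALSE uses
# the running statistics, so predictions do not depend on batch composition.
mlp_forward <- function(model, X, slope, training = FALSE, momentum = 0.9) {
  p <- model$params
  bn_eps <- 1e-5
  cache <- list(X0 = X)
  H <- X
  for (l in seq_len(model$n_hidden)) {
    A <- H %*% p[[paste0("W", l)]]
    if (training) {
      mu <- colMeans(A)
      v <- colMeans(sweep(A, 2L, mu, "-")^2)
      model$running[[paste0("mu", l)]] <-
        momentum * model$running[[paste0("mu", l)]] + (1 - momentum) * mu
      model$running[[paste0("var", l)]] <-
        momentum * model$running[[paste0("var", l)]] + (1 - momentum) * v
    } else {
      mu <- model$running[[paste0("mu", l)]]
      v <- model$running[[paste0("var", l)]]
    }
    xhat <- sweep(sweep(A, 2L, mu, "-"), 2L, sqrt(v + bn_eps), "/")
    Y <- sweep(sweep(xhat, 2L, p[[paste0("gamma", l)]], "*"),
               2L, p[[paste0("beta", l)]], "+")
    Hn <- ifelse(Y > 0, Y, slope * Y)
    if (training) {
      cache[[paste0("H", l - 1L)]] <- H
      cache[[paste0("xhat", l)]] <- xhat
      cache[[paste0("invstd", l)]] <- 1 / sqrt(v + bn_eps)
      cache[[paste0("Y", l)]] <- Y
    }
    H <- Hn
  }
  logits <- sweep(H %*% p$Wo, 2L, p$bo, "+")
  P <- 1 / (1 + exp(-logits))
  if (training) cache$Hlast <- H
  list(P = P, cache = cache, model = model)
}

bce_mean <- function(P, Y, eps = 1e-12) {
  Pc <- clamp(P, eps, 1 - eps)
  -mean(Y * log(Pc) + (1 - Y) * log(1 - Pc))
}

mlp_backward <- function(model, fw, Y, slope) {
  p <- model$params
  cache <- fw$cache
  nb <- nrow(Y)
  q <- ncol(Y)
  grads <- list()
  dlogits <- (fw$P - Y) / (nb * q)
  grads$Wo <- crossprod(cache$Hlast, dlogits)
  grads$bo <- colSums(dlogits)
  dH <- tcrossprod(dlogits, p$Wo)
  for (l in rev(seq_len(model$n_hidden))) {
    Yl <- cache[[paste0("Y", l)]]
    dY <- dH * ifelse(Yl > 0, 1, slope)
    xhat <- cache[[paste0("xhat", l)]]
    grads[[paste0("gamma", l)]] <- colSums(dY * xhat)
    grads[[paste0("beta", l)]] <- colSums(dY)
    dxhat <- sweep(dY, 2L, p[[paste0("gamma", l)]], "*")
    invstd <- cache[[paste0("invstd", l)]]
    # batch-norm backward (biased batch variance)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dA <- sweep(dxhat - matrix(m1, nb, length(m1), byrow = TRUE) -
                  xhat * matrix(m2, nb, length(m2), byrow = TRUE),
                2L, invstd, "*")
    Hprev <- cache[[paste0("H", l - 1L)]]
    grads[[paste0("W", l)]] <- crossprod(Hprev, dA)
    dH <- tcrossprod(dA, p[[paste0("W", l)]])
  }
  grads
}

#' Train the multi-label phenotype classifier
#'
#' @param Z embedding matrix (genes x e), rows named by gene.
#' @param Y binary label matrix (genes x terms), rows aligned with `Z`.
#' @param cfg a [classifier_config()].
#' @param train_idx integer indices of the training genes (default: all).
#' @return trained model of class `pheno_mlp` (weights, running batch-norm
#'   statistics, config, per-epoch loss trace).
#' @details A fraction `val_fraction` of the training genes is held out to
#'   monitor the validation loss; training stops after `patience` epochs
#'   without improvement and the best weights are restored.  Terms with no
#'   positive gene in the training fold trigger a warning but still train
#'   (as all-negative columns).
#' @export
train_classifier <- function(Z, Y, cfg = classifier_config(),
                             train_idx = seq_len(nrow(Z))) {
  stopifnot(nrow(Z) == nrow(Y), all(train_idx >= 1L), all(train_idx <= nrow(Z)))
  Zt <- as.matrix(Z)[train_idx, , drop = FALSE]
  Yt <- as.matrix(Y)[train_idx, , drop = FALSE]
  if (!all(is.finite(Zt))) stop("non-finite values in the embedding matrix")
  zero_pos <- colSums(Yt) == 0
  if (any(zero_pos))
    warning(sum(zero_pos), " term(s) have no positive gene in the training fold")

  set.seed(cfg$seed)
  n <- nrow(Zt)
  n_val <- if (cfg$val_fraction > 0) max(1L, floor(cfg$val_fraction * n)) else 0L
  use_val <- n_val > 0L && n - n_val >= 2L
  perm <- sample.int(n)
  val <- if (use_val) perm[seq_len(n_val)] else integer(0)
  tr <- setdiff(perm, val)

  model <- mlp_init(ncol(Zt), cfg$hidden_sizes, ncol(Yt), seed = cfg$seed + 1L)
  st <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, running = model$running)
  bad_epochs <- 0L
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      fw <- mlp_forward(model, Zt[b, , drop = FALSE], cfg$leaky_slope,
                        training = TRUE)
      model <- fw$model
      loss <- bce_mean(fw$P, Yt[b, , drop = FALSE])
      if (!is.finite(loss)) stop("non-finite classifier loss at epoch ", ep)
      ep_loss <- ep_loss + loss * length(b)
      grads <- mlp_backward(model, fw, Yt[b, , drop = FALSE], cfg$leaky_slope)
      upd <- adam_step(model$params, grads, st, lr = cfg$learning_rate)
      model$params <- upd$params
      st <- upd$state
    }
    ep_loss <- ep_loss / length(tr)
    vl <- NA_real_
    if (use_val) {
      pv <- mlp_forward(model, Zt[val, , drop = FALSE], cfg$leaky_slope)$P
      vl <- bce_mean(pv, Yt[val, , drop = FALSE])
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = model$params, running = model$running)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
    }
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = ep_loss,
                                     val_loss = vl))
    if (use_val && bad_epochs >= cfg$patience) break
  }
  if (use_val && is.finite(best$loss)) {
    model$params <- best$params
    model$running <- best$running
  }
  structure(list(params = model$params, running = model$running,
                 n_hidden = model$n_hidden, cfg = cfg, d_in = ncol(Zt),
                 q = ncol(Yt), terms = colnames(Y), trace = trace),
            class = "pheno_mlp")
}

#' @export
print.pheno_mlp <- function(x, ...) {
  cat(sprintf("<pheno_mlp> %d -> %s -> %d terms (%d epochs trained)\n",
              x$d_in, paste(x$cfg$hidden_sizes, collapse = "/"), x$q,
              nrow(x$trace)))
  invisible(x)
}

#' Predict phenotype-term scores
#'
#' Inference uses the running batch-norm statistics, so the score of a gene
#' does not depend on which other genes are in the batch.
#'
#' @param object a trained `pheno_mlp`.
#' @param Z embedding matrix (genes x e).
#' @param ... unused.
#' @return matrix of scores in (0, 1), genes x terms.
#' @export
predict.pheno_mlp <- function(object, Z, ...) {
  Z <- as.matrix(Z)
  if (ncol(Z) != object$d_in)
    stop("embedding width ", ncol(Z), " does not match model input ", object$d_in)
  model <- list(params = object$params, running = object$running,
                n_hidden = object$n_hidden)
  P <- mlp_forward(model, Z, object$cfg$leaky_slope, training = FALSE)$P
  dimnames(P) <- list(rownames(Z), object$terms)
  P
}
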