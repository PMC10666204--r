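# Independent brute-force oracles and small fixture builders used across
# the suite.  Each oracle is deliberately written in the most naive way
# possible, without sharing code with the implementation it checks.

# Transitive ancestor closure by repeated one-step expansion over an edge
# list (child, parent), until a fixed point.
oracle_closure <- function(terms, edges) {
  out <- as.list(stats::setNames(terms, terms))
  repeat {
    changed <- FALSE
    for (t in names(out)) {
      cur <- out[[t]]
      step <- unique(c(cur, edges[edges[, 1] %in% cur, 2]))
      if (length(step) > length(cur)) {
        out[[t]] <- step
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(out, sort)
}

# Average precision by explicit enumeration of every distinct score cutoff:
# AP = sum over cutoffs (descending) of precision * (recall increment).
oracle_ap <- function(scores, labels) {
  P <- sum(labels)
  if (P == 0) return(NA_real_)
  cuts <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (cut in cuts) {
    pred <- scores >= cut
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    ap <- ap + prec * (rec - r_prev)
    r_prev <- rec
  }
  ap
}

# Fmax by explicit loop over an arbitrary threshold vector.
oracle_fmax <- function(scores, labels, taus = seq(0, 1, 0.01)) {
  if (sum(labels) == 0) return(NA_real_)
  best <- 0
  for (tau in taus) {
    pred <- scores >= tau
    if (!any(pred)) next
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(labels)
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    if (f > best) best <- f
  }
  best
}

# Pair selection by repeated extraction: scan all remaining pairs for the
# maximum similarity (lexicographically first on ties) k times for the
# positives, then the minimum (lexicographically last on ties) k times for
# the negatives.
oracle_select_pairs <- function(S, k) {
  n <- nrow(S)
  pool <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    cbind(i, seq.int(i + 1, n))))
  sims <- S[pool]
  pick <- function(mode) {
    chosen <- matrix(0L, 0, 2)
    alive <- rep(TRUE, nrow(pool))
    for (step in seq_len(k)) {
      idx <- which(alive)
      val <- if (mode == "max") max(sims[idx]) else min(sims[idx])
      cand <- idx[sims[idx] == val]
      ord <- order(pool[cand, 1], pool[cand, 2])
      sel <- if (mode == "max") cand[ord[1]] else cand[ord[length(ord)]]
      chosen <- rbind(chosen, pool[sel, , drop = FALSE])
      alive[sel] <- FALSE
    }
    chosen
  }
  list(positives = pick("max"), negatives = pick("min"))
}

# Random DAG on `n` terms t1..tn: each term may take is_a parents only among
# lower-numbered terms, which guarantees acyclicity.
random_dag <- function(n, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  terms <- paste0("t", seq_len(n))
  edges <- NULL
  for (i in seq(2, n)) {
    par <- which(stats::runif(i - 1) < p_edge)
    if (length(par) > 0)
      edges <- rbind(edges, cbind(terms[i], terms[par]))
  }
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  list(terms = terms, edges = edges,
       dag = ontology_dag(terms, edges))
}

# Erdos-Renyi adjacency as a dense base matrix (the tests convert when a
# sparse operator is needed).
random_adjacency <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(stats::runif(length(up)) < p)
  A <- A + t(A)
  dimnames(A) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  A
}

write_tmp_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

# Small diamond ontology: d is_a b, d is_a c, b is_a a, c is_a a.
diamond_dag <- function() {
  ontology_dag(c("a", "b", "c", "d"),
               rbind(c("b", "a"), c("c", "a"), c("d", "b"), c("d", "c")))
}
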