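# CAFA-style evaluation: per-term and micro-averaged AUPR (as average
# precision) and Fmax over a fixed threshold grid, reported overall and per
# term-size group; 5-fold CV and temporal split construction.

#' Area under the precision-recall curve for one term
#'
#' Computed as average precision: each distinct score value defines a
#' cutoff (predict positive when score >= cutoff); the AUPR is the sum over
#' cutoffs of `precision * delta-recall`.  Tied scores therefore enter and
#' leave the prediction set as a block, which makes the value independent
#' of the within-tie ordering.  No trapezoidal interpolation is used (it is
#' optimistic for PR curves).
#'
#' @param scores numeric score vector.
#' @param labels binary label vector of the same length.
#' @return AUPR in \[0, 1\], or `NA_real_` when there is no positive label
#'   (the metric is undefined, never silently 0).
#' @export
term_aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  ends <- cumsum(rle(s)$lengths)      # last index of each tied block
  cumtp <- cumsum(l)[ends]
  prec <- cumtp / ends
  dtp <- diff(c(0, cumtp))
  sum(prec * dtp) / P
}

# F1 over a fixed threshold grid; prediction rule is score >= tau.
# Thresholds with no predicted positive are skipped (precision undefined).
fmax_grid <- function(scores, labels, step = 0.01) {
  if (sum(labels) == 0L) return(NA_real_)
  taus <- seq(0, 1, by = step)
  best <- 0
  for (tau in taus) {
    pred <- scores >= tau
    npred <- sum(pred)
    if (npred == 0L) next
    tp <- sum(pred & labels == 1)
    prec <- tp / npred
    rec <- tp / sum(labels)
    if (prec + rec > 0) best <- max(best, 2 * prec * rec / (prec + rec))
  }
  best
}

# Shared-threshold macro Fmax: at each grid threshold, average the per-term
# F1 over evaluable terms, then maximize over the grid.
fmax_macro_shared <- function(P, Y, step = 0.01) {
  evaluable <- which(colSums(Y) > 0)
  if (length(evaluable) == 0L) return(NA_real_)
  taus <- seq(0, 1, by = step)
  best <- 0
  for (tau in taus) {
    f1s <- vapply(evaluable, function(j) {
      pred <- P[, j] >= tau
      tp <- sum(pred & Y[, j] == 1)
      if (sum(pred) == 0L) return(0)
      prec <- tp / sum(pred)
      rec <- tp / sum(Y[, j])
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1))
    best <- max(best, mean(f1s))
  }
  best
}

# Metrics for one scope (a set of term columns).  Macro: unweighted mean of
# per-term AUPR / max-F1 over terms with at least one positive.  Micro:
# flatten the evaluable columns and score the flat vector.
scope_metrics <- function(P, Y, cols, step, macro_shared = FALSE) {
  Ps <- P[, cols, drop = FALSE]
  Ys <- Y[, cols, drop = FALSE]
  evaluable <- which(colSums(Ys) > 0)
  if (length(evaluable) == 0L)
    return(list(M_aupr = NA_real_, M_fmax = NA_real_,
                m_aupr = NA_real_, m_fmax = NA_real_, n_terms = 0L))
  auprs <- vapply(evaluable, function(j) term_aupr(Ps[, j], Ys[, j]), numeric(1))
  if (macro_shared) {
    Mf <- fmax_macro_shared(Ps[, evaluable, drop = FALSE],
                            Ys[, evaluable, drop = FALSE], step)
  } else {
    Mf <- mean(vapply(evaluable, function(j) fmax_grid(Ps[, j], Ys[, j], step),
                      numeric(1)))
  }
  flatP <- as.vector(Ps[, evaluable, drop = FALSE])
  flatY <- as.vector(Ys[, evaluable, drop = FALSE])
  list(M_aupr = mean(auprs),
       M_fmax = Mf,
       m_aupr = term_aupr(flatP, flatY),
       m_fmax = fmax_grid(flatP, flatY, step),
       n_terms = length(evaluable))
}

#' Evaluate a prediction matrix against binary labels
#'
#' Reports macro- and micro-averaged AUPR and Fmax overall (`All`) and for
#' each term-size group present in `groups`.  Terms with no positive label
#' in `Y` are excluded from the macro averages and from the micro
#' flattening of their scope.
#'
#' @param P score matrix (genes x terms), entries in \[0, 1\].
#' @param Y binary label matrix of the same shape (matching colnames).
#' @param groups named character vector term -> group label (from
#'   [filter_terms_by_count()]); terms absent from `groups` only count in
#'   the `All` scope.
#' @param step Fmax threshold-grid step (default 0.01, i.e. grid
#'   0, 0.01, ..., 1).
#' @param macro_shared use one shared threshold (maximizing the mean F1)
#'   for the macro Fmax instead of per-term optimal thresholds?
#' @return `eval_report`: list with `scopes` (named list of metric lists),
#'   `term_aupr` (per-term table), `threshold_step`.
#' @export
evaluate_predictions <- function(P, Y, groups = NULL, step = 0.01,
                                 macro_shared = FALSE) {
  stopifnot(all(dim(P) == dim(Y)))
  if (!is.null(colnames(P)) && !is.null(colnames(Y)) &&
      !identical(colnames(P), colnames(Y)))
    stop("P and Y column names disagree")
  terms <- colnames(Y) %||% as.character(seq_len(ncol(Y)))
  scopes <- list(All = scope_metrics(P, Y, seq_len(ncol(Y)), step, macro_shared))
  if (!is.null(groups)) {
    for (gl in c("11-30", "31-100", "101-300", ">300")) {
      cols <- which(terms %in% names(groups)[groups == gl])
      if (length(cols) > 0L)
        scopes[[gl]] <- scope_metrics(P, Y, cols, step, macro_shared)
    }
  }
  ta <- vapply(seq_len(ncol(Y)), function(j) term_aupr(P[, j], Y[, j]), numeric(1))
  structure(list(scopes = scopes,
                 term_aupr = stats::setNames(ta, terms),
                 threshold_step = step),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (nm in names(x$scopes)) {
    s <- x$scopes[[nm]]
    cat(sprintf("  %-8s (%d terms)  M-aupr %.3f  M-Fmax %.3f  m-aupr %.3f  m-Fmax %.3f\n",
                nm, s$n_terms, s$M_aupr, s$M_fmax, s$m_aupr, s$m_fmax))
  }
  invisible(x)
}

#' Serialize an eval report to JSON
#' @param report an `eval_report`.
#' @param path output path; when `NULL`, the JSON string is returned.
#' @param extra named list merged into the top level (e.g. a config
#'   fingerprint).
#' @export
write_eval_report <- function(report, path = NULL, extra = list()) {
  obj <- c(list(scopes = report$scopes, threshold_step = report$threshold_step),
           extra)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                         na = "null")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Build a k-fold cross-validation plan
#'
#' Genes are shuffled with `seed` and dealt round-robin into `folds` folds,
#' which therefore partition the gene set with sizes differing by at most
#' one.
#'
#' @param index a [gene_index()] (or character vector of gene ids).
#' @param folds number of folds (default 5).
#' @param seed shuffle seed.
#' @return `split_plan` with `kind = "cv"` and `fold`, a named integer
#'   vector gene -> fold id in `1..folds`.
#' @export
make_cv_splits <- function(index, folds = 5L, seed = 1L) {
  genes <- as.character(index)
  n <- length(genes)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many genes as folds")
  set.seed(as.integer(seed))
  perm <- sample(genes)
  fold <- stats::setNames(rep(seq_len(folds), length.out = n), perm)[genes]
  structure(list(kind = "cv", fold = fold, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Build a temporal (CAFA2-style) split from two annotation snapshots
#'
#' Test genes are those with no annotation at the earlier snapshot `t0`
#' that have accumulated at least one term by `t1`; training genes are
#' those annotated at `t0` (trained on their `t0` labels, evaluated never).
#' Genes annotated at neither time are excluded.
#'
#' @param annotations_t0,annotations_t1 propagated/filtered
#'   [annot_table()]s over a shared term universe.
#' @return `split_plan` with `kind = "temporal"`, `train` and `test` gene
#'   id vectors.
#' @export
make_temporal_split <- function(annotations_t0, annotations_t1) {
  stopifnot(inherits(annotations_t0, "annot_table"),
            inherits(annotations_t1, "annot_table"))
  n0 <- annotations_t0$genes[lengths(annotations_t0$assignments) > 0L]
  n1 <- annotations_t1$genes[lengths(annotations_t1$assignments) > 0L]
  test <- setdiff(n1, n0)
  train <- n0
  if (length(test) == 0L)
    stop("empty temporal test set: no gene gains its first annotation between snapshots")
  structure(list(kind = "temporal", train = train, test = test),
            class = "split_plan")
}
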