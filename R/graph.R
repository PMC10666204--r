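# Gene attributed network construction: scored PPI edge list -> binary
# symmetric adjacency; GO annotations -> binary attribute matrix; PCA
# reduction of the attribute space.

#' Create a gene index
#'
#' Fixes the row order used by every matrix in the pipeline.
#' @param ids character vector of unique gene identifiers.
#' @return character vector of class `gene_index` (order preserved).
#' @export
gene_index <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("gene identifiers must be unique")
  structure(ids, class = "gene_index")
}

#' Read a scored edge-list TSV
#'
#' Headerless `gene_a<TAB>gene_b<TAB>score`.  STRING exports carry integer
#' combined scores in 0-1000; pass `string_scale = TRUE` to divide by 1000
#' so the core operations only ever see scores in \[0, 1\].
#' @param path file path.
#' @param string_scale divide scores by 1000?
#' @export
read_edge_list <- function(path, string_scale = FALSE) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("gene_a", "gene_b", "score"),
                          colClasses = c("character", "character", "numeric"))
  if (string_scale) df$score <- df$score / 1000
  df
}

#' Build the binary adjacency matrix from a scored edge list
#'
#' An edge is set (symmetrically) whenever some input edge between the pair
#' has score >= `threshold`; equivalently, duplicate edges are resolved by
#' their maximum score.  Self-edges in the input are ignored.  Genes in the
#' index that appear in no retained edge become isolated nodes.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `score`
#'   (scores in \[0, 1\]).
#' @param index a [gene_index()].
#' @param threshold retain edges with score not below this value
#'   (default 0.3).
#' @return sparse symmetric binary `Matrix` with zero diagonal and
#'   `dimnames` equal to the index.
#' @export
build_adjacency <- function(edges, index, threshold = 0.3) {
  stopifnot(is.data.frame(edges), inherits(index, "gene_index"))
  n <- length(index)
  if (nrow(edges) > 0L) {
    if (any(!is.finite(edges$score)) || any(edges$score < 0 | edges$score > 1))
      stop("edge scores must lie in [0, 1]; rescale raw STRING scores first")
    unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), index)
    if (length(unknown) > 0L)
      stop("edge endpoints not in gene index: ", paste(unknown, collapse = ", "))
  }
  i <- match(edges$gene_a, index)
  j <- match(edges$gene_b, index)
  keep <- i != j & edges$score >= threshold
  A <- Matrix::sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                            x = 1, dims = c(n, n),
                            dimnames = list(as.character(index), as.character(index)))
  A <- methods::as(Matrix::drop0(sign(A)), "generalMatrix")
  A
}

#' Binary GO-indicator attribute matrix
#'
#' Columns are the lexicographically sorted union of terms in the table;
#' `X[i, j] = 1` iff gene `i` carries term `j`.  Genes in the index without
#' any annotation keep an all-zero row (a message reports how many).
#'
#' @param go_annotations a (propagated) [annot_table()] of GO terms.
#' @param index a [gene_index()].
#' @return binary base matrix with `rownames` = index, `colnames` = terms.
#' @export
build_go_attributes <- function(go_annotations, index) {
  stopifnot(inherits(go_annotations, "annot_table"), inherits(index, "gene_index"))
  vocab <- sort(unique(unlist(go_annotations$assignments, use.names = FALSE)))
  X <- matrix(0, nrow = length(index), ncol = length(vocab),
              dimnames = list(as.character(index), vocab))
  present <- intersect(as.character(index), go_annotations$genes)
  for (g in present) X[g, go_annotations$assignments[[g]]] <- 1
  empty <- length(index) - length(present)
  if (empty > 0L)
    message(empty, " gene(s) without GO annotations keep all-zero attribute rows")
  X
}

#' Reduce attribute dimensionality with PCA
#'
#' Centered (unscaled) PCA fit on all rows: pretraining is transductive over
#' the full gene universe, so the projection may see every gene.  Output
#' width is `min(d, rank)`; components are ordered by decreasing explained
#' variance, and each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the result deterministic.
#'
#' @param X raw binary attribute matrix (genes x terms).
#' @param d requested number of components (default 1000).
#' @return score matrix (genes x width) with attributes
#'   `explained_variance` (per component) and `total_variance`.
#' @export
reduce_dimensions_pca <- function(X, d = 1000L) {
  if (d < 1L) stop("d must be >= 1")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tol <- max(dim(X)) * .Machine$double.eps
  rank <- sum(p$sdev > p$sdev[1L] * sqrt(tol))
  width <- min(d, rank)
  if (d > rank)
    warning(sprintf("requested %d components but centered rank is %d; returning %d",
                    d, rank, width))
  scores <- p$x[, seq_len(width), drop = FALSE]
  load <- p$rotation[, seq_len(width), drop = FALSE]
  for (k in seq_len(width)) {
    top <- which.max(abs(load[, k]))
    if (load[top, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- rownames(X)
  structure(scores,
            explained_variance = p$sdev[seq_len(width)]^2,
            total_variance = sum(p$sdev^2))
}

#' Write a matrix with a JSON header sidecar
#'
#' The matrix itself goes to `<path>` as TSV (row names in the first
#' column); metadata (row ids, column vocabulary, form flag) goes to
#' `<path>.json`.
#' @param M matrix with dimnames.
#' @param path output path.
#' @param form `"raw"`, `"reduced"`, `"smoothed"` or `"embedding"`.
#' @param extra named list merged into the JSON header.
#' @export
write_matrix_tsv <- function(M, path, form = "raw", extra = list()) {
  utils::write.table(as.matrix(M), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  hdr <- c(list(rows = rownames(M), cols = colnames(M), form = form), extra)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
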