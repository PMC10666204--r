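# Seeded synthetic benchmark generator.  The method's premise is that
# functionally related genes (i) interact more often, (ii) share functional
# annotations and (iii) produce similar phenotypes.  The minimal generative
# model with that co-dependence is a stochastic block model whose blocks
# also drive binary attribute activation and multi-label phenotype
# annotation, so the generator ties topology, attributes and labels to a
# shared latent block assignment.

#' Specification of a synthetic benchmark dataset
#'
#' Defaults define the package's standard benchmark: 300 genes in 3 equal
#' blocks, assortative topology (within-block edge probability 0.2 vs 0.02
#' across blocks), 60 block-correlated binary attributes (activation 0.30
#' in the owning block vs 0.15 elsewhere - individually weak, collectively
#' informative, like sparse functional annotations), 20 phenotype terms
#' each linked to a subset of blocks (annotation probability 0.6 in linked
#' blocks, 0.05 elsewhere), 2% label noise, seed 17.  Attribute signal is
#' deliberately weaker than label signal so that graph topology carries
#' information the attributes alone do not.
#'
#' @param n genes. @param blocks number of blocks (>= 2).
#' @param p_in,p_out within/cross-block edge probabilities.
#' @param m_attr number of binary attribute columns.
#' @param attr_on,attr_off attribute activation probability in the owning /
#'   other blocks.
#' @param q_terms number of phenotype terms.
#' @param rho_on,rho_off annotation probability in linked / unlinked blocks.
#' @param flip label-noise flip rate per cell.
#' @param seed RNG seed; the same spec always yields the same dataset.
#' @export
synthetic_spec <- function(n = 300L, blocks = 3L, p_in = 0.2, p_out = 0.02,
                           m_attr = 60L, attr_on = 0.30, attr_off = 0.15,
                           q_terms = 20L, rho_on = 0.6,
                           rho_off = 0.05, flip = 0.02, seed = 17L) {
  probs <- c(p_in, p_out, attr_on, attr_off, rho_on, rho_off, flip)
  stopifnot(blocks >= 2L, n >= blocks, all(probs >= 0 & probs <= 1),
            m_attr >= 1L, q_terms >= 1L)
  structure(list(n = as.integer(n), blocks = as.integer(blocks),
                 p_in = p_in, p_out = p_out, m_attr = as.integer(m_attr),
                 attr_on = attr_on, attr_off = attr_off,
                 q_terms = as.integer(q_terms), rho_on = rho_on,
                 rho_off = rho_off, flip = flip, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Equal-sized (up to remainder) block assignment, named by gene id.
assign_blocks <- function(spec) {
  b <- rep(seq_len(spec$blocks), length.out = spec$n)
  b <- sort(b)
  stats::setNames(b, sprintf("g%03d", seq_len(spec$n)))
}

#' Sample the stochastic-block-model interaction graph
#'
#' Each within-block pair receives an edge with probability `p_in`, each
#' cross-block pair with `p_out`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `A` (sparse symmetric binary adjacency, gene dimnames)
#'   and `blocks` (named block assignment).
#' @export
generate_graph <- function(spec) {
  set.seed(spec$seed)
  blocks <- assign_blocks(spec)
  genes <- names(blocks)
  n <- spec$n
  pr <- all_pairs(n)
  same <- blocks[pr[, 1L]] == blocks[pr[, 2L]]
  p <- ifelse(same, spec$p_in, spec$p_out)
  on <- stats::runif(nrow(pr)) < p
  A <- Matrix::sparseMatrix(i = c(pr[on, 1L], pr[on, 2L]),
                            j = c(pr[on, 2L], pr[on, 1L]),
                            x = 1, dims = c(n, n),
                            dimnames = list(genes, genes))
  list(A = methods::as(A, "generalMatrix"), blocks = blocks)
}

#' Sample block-correlated binary attributes
#'
#' Attribute columns are assigned owner blocks round-robin; a gene activates
#' an attribute with probability `attr_on` when its block owns it and
#' `attr_off` otherwise, so every column carries (weak) block information.
#'
#' @param spec a [synthetic_spec()].
#' @param blocks named block assignment from [generate_graph()].
#' @return binary matrix (genes x `m_attr`) with columns `A001`, ...
#' @export
generate_attributes <- function(spec, blocks) {
  set.seed(spec$seed + 1L)
  owner <- rep(seq_len(spec$blocks), length.out = spec$m_attr)
  p <- ifelse(outer(blocks, owner, "=="), spec$attr_on, spec$attr_off)
  X <- matrix(as.numeric(stats::runif(length(p)) < p), nrow = spec$n,
              dimnames = list(names(blocks), sprintf("A%03d", seq_len(spec$m_attr))))
  X
}

#' Sample block-linked multi-label phenotype annotations
#'
#' Term `t` is linked to a block subset (one or two blocks, cycling so all
#' subsets occur); a gene is annotated with probability `rho_on` when its
#' block is linked and `rho_off` otherwise, then each cell is flipped with
#' the noise rate.  A column left with zero positives is resampled once;
#' a second failure is an error.
#'
#' @param spec a [synthetic_spec()].
#' @param blocks named block assignment.
#' @param snapshots also return `(t0, t1)` annotation snapshots in which a
#'   seeded 10% of genes have all annotations hidden at `t0`?
#' @return list with `Y` (binary genes x terms matrix, columns `P01`...),
#'   `links` (list term -> linked blocks), and when `snapshots = TRUE`,
#'   `t0`/`t1` ([annot_table()]s) plus `hidden` (the gene ids hidden at t0).
#' @export
generate_labels <- function(spec, blocks, snapshots = FALSE) {
  set.seed(spec$seed + 2L)
  B <- spec$blocks
  genes <- names(blocks)
  terms <- sprintf("P%02d", seq_len(spec$q_terms))
  links <- lapply(seq_len(spec$q_terms), function(t) {
    base <- (t - 1L) %% B + 1L
    if (t %% 3L == 0L) sort(unique(c(base, base %% B + 1L))) else base
  })
  names(links) <- terms
  sample_col <- function(t) {
    p <- ifelse(blocks %in% links[[t]], spec$rho_on, spec$rho_off)
    y <- as.numeric(stats::runif(spec$n) < p)
    if (spec$flip > 0) {
      fl <- stats::runif(spec$n) < spec$flip
      y[fl] <- 1 - y[fl]
    }
    y
  }
  Y <- vapply(seq_len(spec$q_terms), sample_col, numeric(spec$n))
  for (t in which(colSums(Y) == 0)) {
    Y[, t] <- sample_col(t)
    if (sum(Y[, t]) == 0)
      stop("term ", terms[t], " has zero positives after one resample; ",
           "raise rho_on/rho_off")
  }
  dimnames(Y) <- list(genes, terms)
  out <- list(Y = Y, links = links)
  if (snapshots) {
    hidden <- sample(genes, size = max(1L, round(0.1 * spec$n)))
    Y0 <- Y
    Y0[hidden, ] <- 0
    out$t0 <- labels_to_annot(Y0)
    out$t1 <- labels_to_annot(Y)
    out$hidden <- sort(intersect(hidden, out$t1$genes))
  }
  out
}

# Binary label matrix -> annot_table (genes with all-zero rows dropped,
# matching how annotation files carry only annotated genes).
labels_to_annot <- function(Y) {
  rows <- which(rowSums(Y) > 0)
  assignments <- lapply(rows, function(i) colnames(Y)[Y[i, ] == 1])
  names(assignments) <- rownames(Y)[rows]
  annot_table(assignments, propagated = TRUE)
}

#' Generate a complete synthetic benchmark dataset
#'
#' @param spec a [synthetic_spec()].
#' @param snapshots include the two-snapshot annotation pair for temporal
#'   validation?
#' @return list of class `synthetic_dataset`: `genes` ([gene_index()]),
#'   `A` (adjacency), `X` (raw binary attributes), `Y` (label matrix),
#'   `blocks`, `groups` (term-size group labels computed from the label
#'   counts), `links`, `spec`, and optionally `t0`/`t1`/`hidden`.
#' @export
simulate_dataset <- function(spec = synthetic_spec(), snapshots = FALSE) {
  g <- generate_graph(spec)
  X <- generate_attributes(spec, g$blocks)
  lab <- generate_labels(spec, g$blocks, snapshots = snapshots)
  counts <- colSums(lab$Y)
  grp <- as.character(term_group_label(counts))
  names(grp) <- colnames(lab$Y)
  grp <- grp[!is.na(grp)]
  structure(c(list(genes = gene_index(names(g$blocks)), A = g$A, X = X,
                   Y = lab$Y, blocks = g$blocks, groups = grp,
                   links = lab$links, spec = spec),
              lab[intersect(names(lab), c("t0", "t1", "hidden"))]),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes, %d blocks, %d edges, %d attrs, %d terms\n",
              x$spec$n, x$spec$blocks, Matrix::nnzero(x$A) / 2, ncol(x$X),
              ncol(x$Y)))
  invisible(x)
}

#' Write a synthetic dataset as standard text fixtures
#'
#' Emits the formats the real readers consume: `edges.tsv` (scored edge
#' list, score 1.0), `gene2go.tsv` and `gene2pheno.tsv` (two-column
#' annotation TSVs), a flat `terms.obo` in which every phenotype term is_a
#' a single root, and `blocks.tsv` for reference.
#'
#' @param dataset from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset_fixtures <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ij <- Matrix::which(dataset$A == 1, arr.ind = TRUE)
  ij <- ij[ij[, 1L] < ij[, 2L], , drop = FALSE]
  utils::write.table(
    data.frame(a = rownames(dataset$A)[ij[, 1L]],
               b = rownames(dataset$A)[ij[, 2L]], score = 1),
    file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_annotation_tsv(labels_to_annot(dataset$X), file.path(dir, "gene2go.tsv"))
  write_annotation_tsv(labels_to_annot(dataset$Y), file.path(dir, "gene2pheno.tsv"))
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: P00", "name: phenotype root")
  for (t in colnames(dataset$Y))
    obo <- c(obo, "", "[Term]", paste0("id: ", t),
             paste0("name: synthetic term ", t), "is_a: P00 ! phenotype root")
  writeLines(obo, file.path(dir, "terms.obo"))
  utils::write.table(
    data.frame(gene = names(dataset$blocks), block = dataset$blocks),
    file.path(dir, "blocks.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
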