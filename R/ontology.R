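# Ontology ingestion, true-path-rule propagation, branch restriction and
# term-count filtering.  Terms live in a DAG of is_a relations; annotating a
# gene with a term implies annotation with every ancestor of that term.

#' Construct an ontology DAG
#'
#' @param term_ids character vector of term accessions.
#' @param parent_edges two-column character matrix or data.frame of
#'   child -> parent `is_a` pairs (may have zero rows).
#' @return An object of class `onto_dag` with elements `terms` (sorted
#'   accessions), `parents` (named list, child -> character vector of
#'   parents) and `roots` (terms with no parent).
#' @details Validates that every edge endpoint is a known term and that the
#'   graph is acyclic; a cycle aborts with the offending terms listed.
#' @export
ontology_dag <- function(term_ids, parent_edges = NULL) {
  terms <- sort(unique(as.character(term_ids)))
  if (is.null(parent_edges) || NROW(parent_edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(parent_edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("parent_edges must have two columns (child, parent)")
    unknown <- setdiff(c(edges), terms)
    if (length(unknown) > 0L)
      stop("edge endpoints not in term_ids: ", paste(unknown, collapse = ", "))
  }
  parents <- split(edges[, 2L], factor(edges[, 1L], levels = terms))
  parents <- lapply(parents, unique)
  cyc <- find_cycle(terms, parents)
  if (!is.null(cyc))
    stop("ontology contains an is_a cycle: ", paste(cyc, collapse = " -> "))
  roots <- terms[vapply(parents[terms], length, 1L) == 0L]
  structure(list(terms = terms, parents = parents, roots = roots),
            class = "onto_dag")
}

#' @export
print.onto_dag <- function(x, ...) {
  cat(sprintf("<onto_dag> %d terms, %d is_a edges, %d root(s)\n",
              length(x$terms), sum(lengths(x$parents)), length(x$roots)))
  invisible(x)
}

# Iterative depth-first search over child->parent edges; returns the terms on
# the first cycle found, or NULL.
find_cycle <- function(terms, parents) {
  color <- stats::setNames(integer(length(terms)), terms)  # 0 white 1 grey 2 black
  for (start in terms) {
    if (color[start] != 0L) next
    stack <- list(list(node = start, i = 0L))
    color[start] <- 1L
    path <- start
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      kids <- parents[[top$node]] %||% character(0)
      if (top$i < length(kids)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- kids[top$i + 1L]
        if (color[nxt] == 1L) {
          at <- match(nxt, path)
          return(c(path[at:length(path)], nxt))
        }
        if (color[nxt] == 0L) {
          color[nxt] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
          path <- c(path, nxt)
        }
      } else {
        color[top$node] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      }
    }
  }
  NULL
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas, keeping `id:`, `alt_id:`, `is_a:` and
#' `is_obsolete:` lines.  Obsolete terms are dropped (together with edges
#' touching them); `alt_id` accessions are mapped to their canonical id when
#' they appear as `is_a` targets.  Trailing `! comment` text on `is_a` lines
#' is ignored.
#'
#' @param path path to an OBO 1.2 file.
#' @return An [ontology_dag()] of the non-obsolete terms.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$id))
      stop(sprintf("malformed [Term] stanza starting at line %d: missing id", cur$line))
    cur
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      s <- flush(cur); if (!is.null(s)) stanzas[[length(stanzas) + 1L]] <- s
      cur <- NULL
      if (line == "[Term]") {
        in_term <- TRUE
        cur <- list(line = ln, alt = character(0), isa = character(0),
                    obsolete = FALSE)
      } else in_term <- FALSE
      next
    }
    if (!in_term) next
    if (!grepl(":", line, fixed = TRUE))
      stop(sprintf("malformed OBO line %d: '%s' (expected tag: value)", ln, line))
    tag <- sub(":.*$", "", line)
    val <- trimws(sub("^[^:]+:", "", line))
    if (tag == "id") cur$id <- val
    else if (tag == "alt_id") cur$alt <- c(cur$alt, val)
    else if (tag == "is_a") cur$isa <- c(cur$isa, trimws(sub("!.*$", "", val)))
    else if (tag == "is_obsolete" && tolower(val) == "true") cur$obsolete <- TRUE
  }
  s <- flush(cur); if (!is.null(s)) stanzas[[length(stanzas) + 1L]] <- s
  if (length(stanzas) == 0L) stop("no [Term] stanzas found in ", path)

  ids <- vapply(stanzas, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  obsolete <- vapply(stanzas, `[[`, FALSE, "obsolete")
  alt_map <- stats::setNames(
    rep(ids, vapply(stanzas, function(s) length(s$alt), 1L)),
    unlist(lapply(stanzas, `[[`, "alt")))

  keep <- !obsolete
  live <- ids[keep]
  edges <- do.call(rbind, lapply(stanzas[keep], function(s) {
    if (length(s$isa) == 0L) return(NULL)
    cbind(s$id, s$isa)
  }))
  if (!is.null(edges)) {
    # resolve alt ids, then drop edges into obsolete or unknown-but-obsolete terms
    hit <- edges[, 2L] %in% names(alt_map)
    edges[hit, 2L] <- alt_map[edges[hit, 2L]]
    unknown <- setdiff(edges[, 2L], ids)
    if (length(unknown) > 0L)
      stop("is_a targets not defined in file: ", paste(unique(unknown), collapse = ", "))
    edges <- edges[edges[, 2L] %in% live & edges[, 1L] %in% live, , drop = FALSE]
  }
  ontology_dag(live, edges)
}

# Memoized ancestor closure (excluding self) for every term, computed by
# dynamic programming over the child->parent recursion.
dag_ancestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- dag$parents[[t]] %||% character(0)
    out <- ps
    for (p in ps) out <- c(out, anc(p))
    out <- unique(out)
    memo[[t]] <- out
    out
  }
  stats::setNames(lapply(dag$terms, anc), dag$terms)
}

#' Descendants of a term (excluding the term itself)
#' @param dag an [ontology_dag()].
#' @param term a term accession in `dag`.
#' @export
dag_descendants <- function(dag, term) {
  if (!term %in% dag$terms) stop("term not in ontology: ", term)
  kids <- split(rep(names(dag$parents), lengths(dag$parents)),
                unlist(dag$parents, use.names = FALSE))
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(kids[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, term))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Construct a gene-annotation table
#'
#' @param assignments named list: gene id -> character vector of term
#'   accessions.
#' @param propagated has the true-path-rule closure already been applied?
#' @return An object of class `annot_table` with elements `genes` (ordered
#'   gene ids), `assignments` and the `propagated` flag.
#' @export
annot_table <- function(assignments, propagated = FALSE) {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  assignments <- lapply(assignments, function(x) sort(unique(as.character(x))))
  structure(list(genes = names(assignments), assignments = assignments,
                 propagated = isTRUE(propagated)),
            class = "annot_table")
}

#' @export
print.annot_table <- function(x, ...) {
  cat(sprintf("<annot_table> %d genes, %d annotations, %d distinct terms%s\n",
              length(x$genes), sum(lengths(x$assignments)),
              length(unique(unlist(x$assignments, use.names = FALSE))),
              if (x$propagated) ", propagated" else ""))
  invisible(x)
}

#' Read a two-column gene/term annotation TSV
#'
#' Headerless, `gene<TAB>term`; lines starting with `#` are skipped.
#' @param path file path.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character",
                          col.names = c("gene", "term"))
  annot_table(split(df$term, df$gene))
}

#' Read a GAF 2.x gene-annotation file
#'
#' Accepts GAF 2.1/2.2.  Rows whose qualifier contains `NOT` are skipped;
#' evidence codes are not filtered.  Gene identifiers are taken from the
#' DB Object ID column by default (`id_col = 2`); pass `id_col = 3` for the
#' DB Object Symbol.
#' @param path file path.
#' @param id_col GAF column carrying the gene identifier (2 or 3).
#' @export
read_gaf <- function(path, id_col = 2L) {
  stopifnot(id_col %in% c(2L, 3L))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) stop("no annotation rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 5L)
  if (length(bad) > 0L)
    stop("GAF row with fewer than 5 columns at data line ", bad[1L])
  qual <- vapply(parts, `[[`, "", 4L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  genes <- vapply(parts, `[[`, "", id_col)[keep]
  terms <- vapply(parts, `[[`, "", 5L)[keep]
  annot_table(split(terms, genes))
}

#' Propagate annotations by the true-path-rule
#'
#' Replaces each gene's term set with its closure under the ancestor
#' relation of `dag` (original terms retained).
#'
#' @param table an unpropagated [annot_table()].
#' @param dag the companion [ontology_dag()].
#' @export
propagate_annotations <- function(table, dag) {
  stopifnot(inherits(table, "annot_table"), inherits(dag, "onto_dag"))
  if (table$propagated) stop("annotation table is already propagated")
  used <- unique(unlist(table$assignments, use.names = FALSE))
  unknown <- setdiff(used, dag$terms)
  if (length(unknown) > 0L)
    stop("annotations to unknown terms: ", paste(unknown, collapse = ", "))
  anc <- dag_ancestors(dag)
  closed <- lapply(table$assignments, function(ts)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE)))))
  annot_table(closed, propagated = TRUE)
}

#' Restrict annotations to one ontology branch
#'
#' Keeps only terms that are `branch_root` or one of its descendants; genes
#' left with empty term sets are dropped.  By default the branch root itself
#' is excluded from the retained label space, since after propagation it
#' annotates every remaining gene and carries no signal.
#'
#' @param table a propagated [annot_table()].
#' @param dag the companion [ontology_dag()].
#' @param branch_root term accession of the branch to keep.
#' @param include_root keep `branch_root` itself as a label? Default `FALSE`.
#' @export
restrict_to_branch <- function(table, dag, branch_root, include_root = FALSE) {
  stopifnot(inherits(table, "annot_table"), inherits(dag, "onto_dag"))
  if (!branch_root %in% dag$terms)
    stop("branch_root not in ontology: ", branch_root)
  if (!table$propagated) stop("restrict_to_branch requires a propagated table")
  keep <- dag_descendants(dag, branch_root)
  if (include_root) keep <- c(branch_root, keep)
  res <- lapply(table$assignments, intersect, y = keep)
  res <- res[lengths(res) > 0L]
  if (length(res) == 0L) stop("no gene retains any annotation in branch ", branch_root)
  annot_table(res, propagated = TRUE)
}

# Group label for a term annotating `count` genes; counts of 10 or fewer
# have no group (they are removed by the count filter).
term_group_label <- function(count) {
  cut(count, breaks = c(10, 30, 100, 300, Inf),
      labels = c("11-30", "31-100", "101-300", ">300"),
      right = TRUE)
}

#' Remove rarely annotated terms and group the survivors by count
#'
#' Terms annotating fewer than `min_genes` genes are removed and surviving
#' terms are binned by annotated-gene count into the groups `11-30`,
#' `31-100`, `101-300` and `>300`.  Filtering is single-pass: counts are
#' computed once, before any removal, so dropping a term (which can orphan
#' genes) never changes another term's count.
#'
#' @param table a propagated, branch-restricted [annot_table()].
#' @param min_genes minimum annotated-gene count to keep a term (default 11,
#'   i.e. terms with 10 or fewer annotations are removed).
#' @return list with elements `table` (filtered [annot_table()]), `groups`
#'   (named character vector term -> group label) and `counts` (the
#'   annotated-gene counts at filter time).
#' @export
filter_terms_by_count <- function(table, min_genes = 11L) {
  stopifnot(inherits(table, "annot_table"), min_genes >= 1L)
  counts <- table(unlist(table$assignments, use.names = FALSE))
  keep <- names(counts)[counts >= min_genes]
  if (length(keep) == 0L) stop("empty label space: every term has fewer than ",
                               min_genes, " annotated genes")
  res <- lapply(table$assignments, intersect, y = keep)
  res <- res[lengths(res) > 0L]
  kept_counts <- as.integer(counts[keep])
  grp <- as.character(term_group_label(kept_counts))
  names(grp) <- keep
  grp <- grp[!is.na(grp)]  # counts <= 10 (possible when min_genes < 11) have no group
  list(table = annot_table(res, propagated = TRUE),
       groups = grp,
       counts = stats::setNames(kept_counts, keep))
}

#' Write an annotation table as a two-column TSV
#' @param table an [annot_table()].
#' @param path output path.
#' @export
write_annotation_tsv <- function(table, path) {
  df <- data.frame(
    gene = rep(table$genes, lengths(table$assignments)),
    term = unlist(table$assignments, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write term groups as a JSON sidecar
#' @param groups named character vector, term -> group label.
#' @param path output path.
#' @export
write_term_groups_json <- function(groups, path) {
  jsonlite::write_json(as.list(groups), path, auto_unbox = TRUE)
  invisible(path)
}
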