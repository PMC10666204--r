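# Ontology parsing, true-path-rule propagation, branch restriction and
# term-count filtering.

test_that("parse_obo reads terms, edges, alt_ids, and drops obsolete terms", {
  path <- write_tmp_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: All", "",
    "[Term]", "id: HP:0000002", "name: child", "alt_id: HP:0009999",
    "is_a: HP:0000001 ! All", "",
    "[Term]", "id: HP:0000003", "name: gone", "is_obsolete: true", "",
    "[Term]", "id: HP:0000004", "is_a: HP:0009999 ! via alt id"))
  dag <- parse_obo(path)
  expect_setequal(dag$terms, c("HP:0000001", "HP:0000002", "HP:0000004"))
  expect_equal(dag$roots, "HP:0000001")
  expect_false("HP:0000003" %in% dag$terms)
  # alt_id resolved to its canonical accession
  expect_equal(dag$parents[["HP:0000004"]], "HP:0000002")
  expect_equal(sum(lengths(dag$parents)), 2L)
})

test_that("parse_obo rejects cycles and malformed stanzas", {
  cyc <- write_tmp_obo(c(
    "[Term]", "id: A", "is_a: B", "",
    "[Term]", "id: B", "is_a: A"))
  expect_error(parse_obo(cyc), "cycle")
  bad <- write_tmp_obo(c("[Term]", "id: A", "", "[Term]", "name-without-colon"))
  expect_error(parse_obo(bad), "line")
  noid <- write_tmp_obo(c("[Term]", "name: x"))
  expect_error(parse_obo(noid), "missing id")
})

test_that("propagation closes annotations over chains and diamonds", {
  chain <- ontology_dag(c("a", "b", "c"), rbind(c("c", "b"), c("b", "a")))
  tab <- annot_table(list(g1 = "c", g2 = "a"))
  out <- propagate_annotations(tab, chain)
  expect_true(out$propagated)
  expect_equal(out$assignments$g1, c("a", "b", "c"))
  expect_equal(out$assignments$g2, "a")  # root has no ancestors

  out2 <- propagate_annotations(annot_table(list(g = "d")), diamond_dag())
  expect_equal(out2$assignments$g, c("a", "b", "c", "d"))
})

test_that("propagation agrees with the transitive-closure oracle on random DAGs", {
  for (seed in 1:50) {
    rd <- random_dag(n = sample(4:15, 1), p_edge = 0.35, seed = seed)
    genes <- lapply(1:3, function(i) sample(rd$terms, sample(1:3, 1)))
    names(genes) <- paste0("g", 1:3)
    got <- propagate_annotations(annot_table(genes), rd$dag)
    want <- oracle_closure(rd$terms, rd$edges)
    for (g in names(genes)) {
      expect_equal(got$assignments[[g]],
                   sort(unique(unlist(want[genes[[g]]]))),
                   info = paste("seed", seed, "gene", g))
    }
  }
})

test_that("propagation is idempotent and never shrinks term sets", {
  rd <- random_dag(12, seed = 99)
  genes <- list(g1 = rd$terms[c(3, 7)], g2 = rd$terms[12], g3 = rd$terms[1])
  tab <- annot_table(genes)
  once <- propagate_annotations(tab, rd$dag)
  expect_error(propagate_annotations(once, rd$dag), "already propagated")
  # closure of a closed set is itself
  redo <- annot_table(once$assignments)
  twice <- propagate_annotations(redo, rd$dag)
  expect_identical(twice$assignments, once$assignments)
  for (g in names(genes))
    expect_gte(length(once$assignments[[g]]), length(genes[[g]]))
})

test_that("propagation rejects annotations to unknown terms", {
  dag <- ontology_dag(c("a", "b"), rbind(c("b", "a")))
  expect_error(propagate_annotations(annot_table(list(g = c("b", "zz"))), dag),
               "zz")
})

test_that("branch restriction keeps one branch, drops orphans, handles leaves", {
  # two roots R1, R2 with one child each; x under R1, y under R2
  dag <- ontology_dag(c("R1", "R2", "x", "y"),
                      rbind(c("x", "R1"), c("y", "R2")))
  tab <- propagate_annotations(annot_table(list(g1 = "x", g2 = "y")), dag)
  r1 <- restrict_to_branch(tab, dag, "R1")
  expect_equal(r1$genes, "g1")
  expect_equal(r1$assignments$g1, "x")  # R2-branch terms and root removed
  # gene annotated only in the other branch is dropped
  expect_false("g2" %in% r1$genes)
  # root itself excluded by default, included on request
  r1r <- restrict_to_branch(tab, dag, "R1", include_root = TRUE)
  expect_setequal(r1r$assignments$g1, c("R1", "x"))
  # restriction to a leaf keeps only that leaf
  leaf <- restrict_to_branch(tab, dag, "x", include_root = TRUE)
  expect_equal(leaf$assignments$g1, "x")
  expect_error(restrict_to_branch(tab, dag, "nope"), "not in ontology")
})

test_that("descendant sets match a DAG-traversal oracle", {
  rd <- random_dag(12, seed = 7)
  anc <- oracle_closure(rd$terms, rd$edges)
  for (t in rd$terms) {
    want <- sort(setdiff(rd$terms[vapply(anc, function(a) t %in% a, TRUE)], t))
    expect_equal(dag_descendants(rd$dag, t), want, info = t)
  }
})

test_that("term-count filter removes <=10 and bins survivors at the boundaries", {
  # one term per target count; counts 10 and below must vanish
  counts <- c(t10 = 10, t11 = 11, t30 = 30, t31 = 31, t100 = 100,
              t101 = 101, t300 = 300, t301 = 301)
  genes <- paste0("g", seq_len(301))
  assignments <- stats::setNames(
    lapply(genes, function(g) character(0)), genes)
  for (tm in names(counts)) {
    for (g in genes[seq_len(counts[[tm]])])
      assignments[[g]] <- c(assignments[[g]], tm)
  }
  res <- filter_terms_by_count(annot_table(assignments, propagated = TRUE))
  expect_false("t10" %in% names(res$groups))
  expect_equal(unname(res$groups[c("t11", "t30")]), c("11-30", "11-30"))
  expect_equal(unname(res$groups[c("t31", "t100")]), c("31-100", "31-100"))
  expect_equal(unname(res$groups[c("t101", "t300")]), c("101-300", "101-300"))
  expect_equal(unname(res$groups["t301"]), ">300")
  # group labels partition the survivors; counts at filter time all >= 11
  expect_setequal(names(res$groups), names(counts)[counts >= 11])
  expect_true(all(res$counts >= 11))
  # no annotation to a removed term survives
  expect_false(any(vapply(res$table$assignments, function(x) "t10" %in% x, TRUE)))
})

test_that("term-count filter errors when the label space empties", {
  tab <- annot_table(list(g1 = "t1", g2 = "t1"), propagated = TRUE)
  expect_error(filter_terms_by_count(tab, min_genes = 11), "empty label space")
  ok <- filter_terms_by_count(tab, min_genes = 2)
  expect_equal(ok$counts, c(t1 = 2L))
})

test_that("annotation TSV and GAF readers build equivalent tables", {
  tsv <- tempfile()
  writeLines(c("g1\tT1", "g1\tT2", "g2\tT2"), tsv)
  tab <- read_annotation_tsv(tsv)
  expect_equal(tab$assignments, list(g1 = c("T1", "T2"), g2 = "T2"))

  gaf <- tempfile()
  writeLines(c(
    "!gaf-version: 2.2",
    "DB\tg1\tG1SYM\t\tT1\tREF\tIEA\t\tP\t\t\tprotein\ttaxon:9606",
    "DB\tg1\tG1SYM\tNOT\tT3\tREF\tIEA\t\tP\t\t\tprotein\ttaxon:9606",
    "DB\tg2\tG2SYM\tNOT|colocalizes_with\tT2\tREF\tIDA\t\tP\t\t\tprotein\ttaxon:9606",
    "DB\tg2\tG2SYM\tinvolved_in\tT2\tREF\tIDA\t\tP\t\t\tprotein\ttaxon:9606"),
    gaf)
  gtab <- read_gaf(gaf)
  # NOT-qualified rows skipped, others kept regardless of evidence code
  expect_equal(gtab$assignments, list(g1 = "T1", g2 = "T2"))
})
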