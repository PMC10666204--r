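# AUPR / Fmax metrics, CV and temporal split construction.

test_that("term_aupr handles perfect, worst-rank and undefined cases", {
  expect_equal(term_aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # single positive ranked last among 4: precision at its rank = 1/4
  expect_equal(term_aupr(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 0.25)
  expect_true(is.na(term_aupr(c(0.5, 0.2), c(0, 0))))
})

test_that("term_aupr equals the threshold-enumeration oracle on random vectors", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding -> ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    expect_equal(term_aupr(scores, labels), oracle_ap(scores, labels),
                 tolerance = 1e-12, info = paste("case", i))
  }
})

test_that("tied blocks are averaged, not order-dependent", {
  # scores all equal: AP must equal prevalence regardless of label order
  expect_equal(term_aupr(rep(0.5, 8), c(1, 0, 1, 0, 0, 0, 1, 0)), 3 / 8)
  expect_equal(term_aupr(rep(0.5, 8), c(0, 0, 0, 0, 1, 1, 1, 0)), 3 / 8)
})

test_that("macro metrics average per-term values; P = Y gives all ones", {
  Y <- cbind(a = c(1, 0, 1, 0), b = c(0, 1, 0, 0))
  rep0 <- evaluate_predictions(Y, Y)
  s <- rep0$scopes$All
  expect_equal(c(s$M_aupr, s$M_fmax, s$m_aupr, s$m_fmax), rep(1, 4))
  # two terms with per-term AUPR 1.0 and 0.5 average to 0.75
  P <- cbind(a = c(0.9, 0.1, 0.8, 0.2),        # perfect -> 1.0
             b = c(0.9, 0.8, 0.1, 0.2))        # single positive at rank 2 -> 0.5
  r <- evaluate_predictions(P, Y)
  expect_equal(r$scopes$All$M_aupr, 0.75)
})

test_that("macro and micro Fmax match grid-exhaustive oracles on random fixtures", {
  set.seed(77)
  for (i in 1:5) {
    n <- 30
    q <- 5
    P <- matrix(round(runif(n * q), 2), n, q)   # scores exactly on the grid
    Y <- matrix(rbinom(n * q, 1, 0.3), n, q)
    Y[1, colSums(Y) == 0] <- 1
    r <- evaluate_predictions(P, Y)
    want_M <- mean(vapply(1:q, function(j) oracle_fmax(P[, j], Y[, j]), 0))
    expect_equal(r$scopes$All$M_fmax, want_M, tolerance = 1e-12)
    expect_equal(r$scopes$All$m_fmax, oracle_fmax(as.vector(P), as.vector(Y)),
                 tolerance = 1e-12)
    expect_equal(r$scopes$All$m_aupr, oracle_ap(as.vector(P), as.vector(Y)),
                 tolerance = 1e-12)
    # scores on the grid: the grid Fmax attains the continuous supremum
    all_taus <- sort(unique(c(as.vector(P), 0, 1)))
    expect_equal(r$scopes$All$m_fmax,
                 oracle_fmax(as.vector(P), as.vector(Y), taus = all_taus),
                 tolerance = 1e-12)
  }
})

test_that("flat micro metrics with constant scores give the closed-form F1", {
  # all scores equal, prevalence rho: best F = 2*rho/(1+rho)
  n <- 50
  Y <- matrix(rbinom(n * 2, 1, 0.3), n, 2)
  rho <- mean(Y)
  P <- matrix(0.5, n, 2)
  r <- evaluate_predictions(P, Y)
  expect_equal(r$scopes$All$m_fmax, 2 * rho / (1 + rho), tolerance = 1e-12)
})

test_that("macro and micro coincide for a single term", {
  set.seed(3)
  P <- matrix(runif(30), ncol = 1)
  Y <- matrix(rbinom(30, 1, 0.4), ncol = 1)
  r <- evaluate_predictions(P, Y)
  expect_equal(r$scopes$All$M_aupr, r$scopes$All$m_aupr)
  expect_equal(r$scopes$All$M_fmax, r$scopes$All$m_fmax)
})

test_that("group scopes use only their terms; zero-positive terms are excluded", {
  set.seed(13)
  P <- matrix(runif(40 * 3), 40, 3, dimnames = list(NULL, c("t1", "t2", "t3")))
  Y <- cbind(t1 = rbinom(40, 1, 0.5), t2 = rbinom(40, 1, 0.3), t3 = 0)
  groups <- c(t1 = "11-30", t2 = ">300")
  r <- evaluate_predictions(P, Y, groups)
  expect_named(r$scopes, c("All", "11-30", ">300"))
  expect_equal(r$scopes[["11-30"]]$M_aupr, term_aupr(P[, 1], Y[, 1]))
  expect_equal(r$scopes$All$n_terms, 2L)   # t3 undefined, excluded
  expect_true(is.na(r$term_aupr[["t3"]]))
  # all reported metrics in [0, 1]
  vals <- unlist(lapply(r$scopes, function(s)
    c(s$M_aupr, s$M_fmax, s$m_aupr, s$m_fmax)))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("metrics are invariant to simultaneous row permutation", {
  set.seed(21)
  P <- matrix(runif(25 * 4), 25, 4)
  Y <- matrix(rbinom(100, 1, 0.3), 25, 4)
  Y[1, colSums(Y) == 0] <- 1
  perm <- sample(25)
  a <- evaluate_predictions(P, Y)$scopes$All
  b <- evaluate_predictions(P[perm, ], Y[perm, ])$scopes$All
  expect_equal(a, b)
})

test_that("shared-threshold macro Fmax is an alternative, never above per-term", {
  set.seed(9)
  P <- matrix(runif(60), 20, 3)
  Y <- matrix(rbinom(60, 1, 0.4), 20, 3)
  Y[1, colSums(Y) == 0] <- 1
  per_term <- evaluate_predictions(P, Y)$scopes$All$M_fmax
  shared <- evaluate_predictions(P, Y, macro_shared = TRUE)$scopes$All$M_fmax
  expect_lte(shared, per_term + 1e-12)
})

test_that("cv splits partition the genes deterministically", {
  genes <- paste0("g", 1:10)
  sp <- make_cv_splits(genes, folds = 5, seed = 1)
  expect_equal(sort(unique(sp$fold)), 1:5)
  expect_equal(unname(table(sp$fold)), rep(2L, 5), ignore_attr = TRUE)
  expect_setequal(names(sp$fold), genes)
  # same seed identical, different seed different (n = 100)
  g2 <- paste0("g", 1:100)
  expect_identical(make_cv_splits(g2, 5, seed = 3)$fold,
                   make_cv_splits(g2, 5, seed = 3)$fold)
  expect_false(identical(make_cv_splits(g2, 5, seed = 3)$fold,
                         make_cv_splits(g2, 5, seed = 4)$fold))
  expect_error(make_cv_splits(genes, folds = 11), "at least")
})

test_that("temporal split selects first-annotation gainers", {
  t0 <- annot_table(list(g1 = "t1", g2 = c("t1", "t2")), propagated = TRUE)
  t1 <- annot_table(list(g1 = "t1", g2 = c("t1", "t2"),
                         g3 = c("t1", "t2")), propagated = TRUE)
  sp <- make_temporal_split(t0, t1)
  expect_equal(sp$test, "g3")              # zero at t0, two terms at t1
  expect_setequal(sp$train, c("g1", "g2")) # annotated at t0
  # gene absent from both snapshots is nowhere
  expect_false("g4" %in% c(sp$train, sp$test))
  # no gainers -> error
  expect_error(make_temporal_split(t1, t1), "empty temporal test set")
})
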