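chain_edges <- data.frame(parent = "root", child = "t")
diamond_edges <- data.frame(parent = c("root", "root", "a", "b"),
                            child = c("a", "b", "t", "t"))
sibling_edges <- data.frame(parent = c("root", "root"),
                            child = c("ta", "tb"))

test_that("DAG contributions decay along the chain and take the max over paths", {
  d <- build_disease_dag("x", list(x = "t"), chain_edges, delta = 0.5)
  expect_equal(d$contribution[c("t", "root")], c(t = 1, root = 0.5))
  expect_equal(d$semantic_value, 1.5)

  r <- build_disease_dag("y", list(y = "root"), chain_edges, delta = 0.5)
  expect_equal(r$contribution, c(root = 1))
  expect_equal(r$semantic_value, 1)

  dd <- build_disease_dag("z", list(z = "t"), diamond_edges, delta = 0.5)
  expect_equal(dd$contribution[c("t", "a", "b", "root")],
               c(t = 1, a = 0.5, b = 0.5, root = 0.25))
  expect_equal(dd$semantic_value, 2.25)
  # conservation: semantic value is the sum of the contribution map
  expect_equal(dd$semantic_value, sum(dd$contribution))
})

test_that("multiple tree positions merge into one DAG keeping max contributions", {
  edges <- data.frame(parent = c("root", "root", "ta1", "ta2"),
                      child = c("ta1", "ta2", "leaf1", "leaf2"))
  d <- build_disease_dag("a", list(a = c("leaf1", "ta2")), edges, delta = 0.5)
  # ta2 is an own term (1), not just an ancestor of nothing; root via ta2: 0.5
  expect_equal(d$contribution[["ta2"]], 1)
  expect_equal(d$contribution[["root"]], 0.5)
  expect_false("leaf2" %in% d$nodes)
  expect_error(build_disease_dag("q", list(a = "leaf1"), edges), "no MeSH")
  cyc <- data.frame(parent = c("x", "y"), child = c("y", "x"))
  expect_error(build_disease_dag("a", list(a = "x"), cyc), "cyclic")
})

test_that("semantic similarity is 1 on itself, 1/3 for siblings, 0 when disjoint", {
  da <- build_disease_dag("x", list(x = "ta"), sibling_edges)
  db <- build_disease_dag("y", list(y = "tb"), sibling_edges)
  expect_identical(semantic_similarity(da, da), 1)
  expect_equal(semantic_similarity(da, db), 1 / 3)
  expect_equal(semantic_similarity(da, db), semantic_similarity(db, da))
  other <- build_disease_dag("w", list(w = "u"),
                             data.frame(parent = "v", child = "u"))
  expect_equal(semantic_similarity(da, other), 0)
  expect_error(semantic_similarity(da, build_disease_dag("y", list(y = "tb"),
                                                         sibling_edges,
                                                         delta = 0.3)),
               "delta")
})

test_that("a shared ancestor never decreases similarity", {
  # without the common root the two leaves are disjoint
  da0 <- build_disease_dag("x", list(x = "ta"),
                           data.frame(parent = "pa", child = "ta"))
  db0 <- build_disease_dag("y", list(y = "tb"),
                           data.frame(parent = "pb", child = "tb"))
  base <- semantic_similarity(da0, db0)
  shared <- data.frame(parent = c("root", "root", "pa", "pb"),
                       child = c("pa", "pb", "ta", "tb"))
  da1 <- build_disease_dag("x", list(x = "ta"), shared)
  db1 <- build_disease_dag("y", list(y = "tb"), shared)
  expect_gte(semantic_similarity(da1, db1), base)
})

test_that("contributions agree with the shortest-path oracle on random DAGs", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    edges <- random_term_dag(n)
    leaf <- sample(unique(edges$child), 1)
    delta <- sample(c(0.3, 0.5, 0.8), 1)
    dag <- build_disease_dag("dz", list(dz = leaf), edges, delta = delta)
    oracle <- dag_contribution_oracle(dag, edges)
    expect_equal(dag$contribution[names(oracle)], oracle,
                 tolerance = 1e-12)
    expect_true(all(dag$contribution > 0 & dag$contribution <= 1))
    expect_gte(dag$semantic_value, 1)
  }
})

test_that("the similarity matrix is symmetric with unit diagonal and warns on unmapped diseases", {
  mapping <- list(a = "ta", b = "tb", c = "root")
  s1 <- semantic_similarity_matrix(c("a", "b", "c"), mapping, sibling_edges)
  expect_equal(dim(s1), c(3L, 3L))
  expect_equal(diag(s1), c(a = 1, b = 1, c = 1))
  expect_equal(s1, t(s1))
  expect_equal(s1["a", "b"], 1 / 3)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_warning(
    s1b <- semantic_similarity_matrix(c("a", "nope"), mapping, sibling_edges),
    "without MeSH mapping")
  expect_equal(rownames(s1b), "a")
  expect_equal(semantic_similarity_matrix("a", mapping, sibling_edges),
               matrix(1, dimnames = list("a", "a")))
})
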