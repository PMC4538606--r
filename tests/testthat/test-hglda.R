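test_that("hypergeometric tail matches enumeration oracle and boundary cases", {
  expect_equal(hypergeometric_tail_pvalue(10, 4, 5, 0), 1)
  expect_equal(hypergeometric_tail_pvalue(10, 4, 5, 2), 186 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_tail_pvalue(10, 4, 5, 4), 6 / 252,
               tolerance = 1e-12)
  expect_equal(brute_force_hypergeom(10, 4, 5, 2), 186 / 252)
  # strict-tail option shifts by one support point
  expect_equal(hypergeometric_tail_pvalue(10, 4, 5, 2, tail = "gt"),
               hypergeometric_tail_pvalue(10, 4, 5, 3), tolerance = 1e-12)
  expect_error(hypergeometric_tail_pvalue(10, 11, 5, 2), "exceed N")
  expect_error(hypergeometric_tail_pvalue(10, 4, 5, 5), "min\\(M, L\\)")
  expect_error(hypergeometric_tail_pvalue(10, 4.5, 5, 2), "integers")
})

test_that("tail P-value is strictly decreasing in x and symmetric in M and L", {
  grid <- expand.grid(N = c(8, 11), M = c(3, 5, 7), L = c(2, 6))
  for (k in seq_len(nrow(grid))) {
    N <- grid$N[k]; M <- grid$M[k]; L <- grid$L[k]
    xs <- max(0, M + L - N):min(M, L)  # the support, where decrease is strict
    p <- hypergeometric_tail_pvalue(N, M, L, xs)
    expect_true(all(diff(p) < 0), info = sprintf("N=%d M=%d L=%d", N, M, L))
    expect_equal(p, hypergeometric_tail_pvalue(N, L, M, xs),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches hand cases and the step-up oracle", {
  expect_equal(bh_adjust(0.005), 0.005)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.03, 0.002)), c(0.03, 0.004))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # order-preserving up to ties
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

make_sets <- function(lnc_edges, dis_edges) {
  list(lnc_mir = association_set(lnc_edges$l, lnc_edges$m, "lncrna", "mirna"),
       mir_dis = association_set(dis_edges$m, dis_edges$d, "mirna", "disease"))
}

test_that("score_all_pairs covers the cross-product with the pooled miRNA universe", {
  s <- make_sets(
    data.frame(l = c("l1", "l1", "l2"), m = c("m1", "m2", "m3")),
    data.frame(m = c("m1", "m4"), d = c("d1", "d2")))
  sc <- score_all_pairs(s$lnc_mir, s$mir_dis)
  expect_equal(nrow(sc), 2L * 2L)
  expect_equal(unique(sc$N), 4L)  # union {m1..m4}
  row <- sc[sc$lncrna == "l1" & sc$disease == "d1", ]
  expect_equal(row$x, 1L)
  expect_equal(row$M, 2L)
  expect_equal(row$L, 1L)
  expect_equal(row$pvalue, hypergeometric_tail_pvalue(4, 2, 1, 1),
               tolerance = 1e-12)
  expect_equal(sc$fdr, bh_adjust(sc$pvalue))
  # a lncRNA sharing nothing with a disease gets x = 0, p = 1
  row2 <- sc[sc$lncrna == "l2" & sc$disease == "d1", ]
  expect_equal(row2$x, 0L)
  expect_equal(row2$pvalue, 1)
})

test_that("a planted enriched pair attains the minimum P-value", {
  fx <- generate_bipartite_fixture(fixture_spec(
    seed = 11, planted_pairs = data.frame(lncrna = 3, disease = 5,
                                          n_shared = 10)))
  sc <- score_all_pairs(fx$lnc_mir, fx$mir_dis)
  expect_equal(nrow(sc),
               length(entities_of_class(fx$lnc_mir, "lncrna")) *
                 length(entities_of_class(fx$mir_dis, "disease")))
  top <- sc[which.min(sc$pvalue), ]
  expect_equal(top$lncrna, "lnc003")
  expect_equal(top$disease, "disease005")
  # spot-check one small-parameter row against the enumeration oracle
  small <- sc[sc$x <= 2 & sc$L <= 5 & sc$M <= 5 & sc$N <= 12, ]
  if (nrow(small) > 0) {
    r <- small[1L, ]
    expect_equal(r$pvalue, brute_force_hypergeom(r$N, r$M, r$L, r$x),
                 tolerance = 1e-12)
  }
})

test_that("significance calls use a strict FDR threshold with deterministic order", {
  sc <- data.frame(lncrna = c("a", "b", "c"), disease = "d",
                   x = c(5L, 1L, 0L), M = 5L, L = 5L, N = 20L,
                   pvalue = c(1e-4, 0.04, 0.9),
                   fdr = c(0.01, 0.05, 0.2))
  sig <- significant_pairs(sc, fdr_threshold = 0.05)
  expect_equal(nrow(sig), 1L)  # 0.05 itself excluded
  expect_equal(sig$lncrna, "a")
  expect_equal(nrow(significant_pairs(sc[0, ])), 0L)
  sc$fdr <- 1
  expect_equal(nrow(significant_pairs(sc)), 0L)
})

test_that("per-disease ranks follow pvalue order with documented tie-breaks", {
  sc <- data.frame(lncrna = c("l1", "l2", "l3", "l4"),
                   disease = "d1",
                   x = c(4L, 2L, 1L, 2L), M = 5L, L = 5L, N = 20L,
                   pvalue = c(0.001, 0.3, 0.7, 0.3),
                   fdr = c(0.004, 0.4, 0.7, 0.4))
  expect_equal(rank_for_disease(sc, "d1", "l1"), 1L)
  expect_equal(rank_for_disease(sc, "d1", "l3"), 4L)
  # tie at p = 0.3: equal x, lexicographic label decides
  expect_equal(rank_for_disease(sc, "d1", "l2"), 2L)
  expect_equal(rank_for_disease(sc, "d1", "l4"), 3L)
  expect_error(rank_for_disease(sc, "d1", "l9"), "not present")
  expect_error(rank_for_disease(sc, "d9", "l1"), "not present")
})
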