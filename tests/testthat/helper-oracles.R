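# Independent reference implementations and small fixture builders shared
# across tests.  These never call the code paths they are used to check.

# Textbook BH step-up: q(i) = min_{j >= i} m * p(j) / j on the sorted
# vector, clipped to 1, mapped back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Random symmetric base similarity matrix with unit diagonal.
random_base_matrix <- function(n, labels = sprintf("e%02d", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}

# Shortest-path contribution oracle: in the ancestor DAG, a node's
# contribution is delta^k where k is the shortest directed edge distance
# from the node down to any of the disease's own terms (max over children
# of a geometric decay is dominated by the shortest path).
dag_contribution_oracle <- function(dag, term_edges) {
  g <- igraph::graph_from_data_frame(term_edges[, c("parent", "child")],
                                     directed = TRUE)
  own <- dag$nodes[dag$contribution[dag$nodes] == 1]
  sub <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name, dag$nodes))
  d <- igraph::distances(sub, v = dag$nodes, to = own, mode = "out")
  dag$delta^apply(d, 1L, min)
}

# Random acyclic parent->child edge list over n terms: edges only from
# lower-indexed to higher-indexed terms, so acyclic by construction.
random_term_dag <- function(n, p_edge = 0.35) {
  terms <- sprintf("t%02d", seq_len(n))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < p_edge) { from <- c(from, i); to <- c(to, j) }
    }
  }
  # guarantee every non-root term has a parent so closures are non-trivial
  for (j in 2:n) {
    if (!j %in% to) { from <- c(from, sample.int(j - 1, 1)); to <- c(to, j) }
  }
  data.frame(parent = terms[from], child = terms[to],
             stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
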