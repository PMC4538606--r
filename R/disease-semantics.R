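#' Build a disease's MeSH ancestor DAG with semantic contributions
#'
#' A disease is located at one or more MeSH terms; its DAG is those terms
#' plus all of their ancestors in the term hierarchy.  Each node carries a
#' semantic contribution to the disease: the disease's own term(s)
#' contribute 1, and an ancestor contributes `delta` times the largest
#' contribution among its children inside the DAG, so contributions decay
#' with distance from the disease and a node reached along several paths
#' keeps the maximum.  The DAG's semantic value (DV) is the sum of all
#' node contributions.  Multiple tree positions of one disease are merged
#' into a single DAG.
#'
#' @param disease disease label (normalized internally).
#' @param mapping named list from disease to character vector of MeSH
#'   terms, as returned by [read_disease_dag_inputs()].
#' @param term_edges data frame with columns `parent`, `child` over MeSH
#'   terms (acyclic).
#' @param delta semantic contribution decay factor in (0, 1); 0.5 by
#'   default, the customary value for this DAG-based similarity.
#' @return object of class `disease_dag`: list with `disease`, `nodes`,
#'   `contribution` (named numeric, own terms = 1), `semantic_value`,
#'   `delta`.
#' @examples
#' mapping <- list(a = "t")
#' edges <- data.frame(parent = "root", child = "t")
#' build_disease_dag("a", mapping, edges)$semantic_value  # 1.5
#' @export
build_disease_dag <- function(disease, mapping, term_edges, delta = 0.5) {
  stopifnot(is.list(mapping), is.data.frame(term_edges),
            all(c("parent", "child") %in% names(term_edges)),
            delta > 0, delta < 1)
  disease <- normalize_label(disease)
  own <- mapping[[disease]]
  if (is.null(own) || length(own) == 0L) {
    stop(sprintf("disease '%s' has no MeSH term mapping", disease))
  }
  own <- normalize_label(own)
  assert_acyclic(term_edges)

  parents_of <- split(term_edges$parent, term_edges$child)
  children_of <- split(term_edges$child, term_edges$parent)

  # ancestor closure of all own terms
  nodes <- character(0)
  frontier <- unique(own)
  while (length(frontier) > 0L) {
    nodes <- c(nodes, frontier)
    frontier <- setdiff(unique(unlist(parents_of[frontier],
                                      use.names = FALSE)), nodes)
  }
  nodes <- sort(unique(nodes))

  contrib <- rep(NA_real_, length(nodes))
  names(contrib) <- nodes
  contrib[own] <- 1
  # ancestors in as many passes as the DAG is deep; each pass resolves
  # nodes all of whose in-DAG children are resolved
  todo <- nodes[is.na(contrib)]
  while (length(todo) > 0L) {
    progressed <- FALSE
    for (t in todo) {
      ch <- intersect(children_of[[t]], nodes)
      if (length(ch) > 0L && !anyNA(contrib[ch])) {
        contrib[[t]] <- delta * max(contrib[ch])
        progressed <- TRUE
      }
    }
    todo <- nodes[is.na(contrib)]
    if (!progressed && length(todo) > 0L) {
      stop("term graph inconsistency while computing contributions")
    }
  }

  res <- list(disease = disease, nodes = nodes, contribution = contrib,
              semantic_value = sum(contrib), delta = delta)
  class(res) <- "disease_dag"
  res
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag '%s': %d nodes, DV = %.4g (delta = %g)\n",
              x$disease, length(x$nodes), x$semantic_value, x$delta))
  invisible(x)
}

#' Semantic similarity of two diseases from their DAGs
#'
#' The shared-ancestor similarity: the contributions both DAGs assign to
#' their common nodes, summed and normalized by the two semantic values,
#' `(sum_t [Da(t) + Db(t)]) / (DVa + DVb)` over shared nodes `t`.
#' Identical DAGs give 1; DAGs with no shared node give 0.
#'
#' @param dag_a,dag_b `disease_dag` objects built with the same `delta`.
#' @return similarity in `[0, 1]`.
#' @export
semantic_similarity <- function(dag_a, dag_b) {
  stopifnot(inherits(dag_a, "disease_dag"), inherits(dag_b, "disease_dag"))
  if (!isTRUE(all.equal(dag_a$delta, dag_b$delta))) {
    stop("DAGs were built with different delta values")
  }
  shared <- intersect(dag_a$nodes, dag_b$nodes)
  if (length(shared) == 0L) return(0)
  (sum(dag_a$contribution[shared]) + sum(dag_b$contribution[shared])) /
    (dag_a$semantic_value + dag_b$semantic_value)
}

#' Pairwise disease semantic similarity matrix (S1)
#'
#' Builds the DAG of every mappable disease and fills the symmetric
#' semantic similarity matrix with unit diagonal.  Diseases without a MeSH
#' mapping are excluded with a warning (rather than kept as zero rows,
#' which would silently deflate downstream group similarities).
#'
#' @param diseases character vector of disease labels.
#' @inheritParams build_disease_dag
#' @return symmetric numeric matrix with the kept diseases as dimnames.
#' @export
semantic_similarity_matrix <- function(diseases, mapping, term_edges,
                                       delta = 0.5) {
  diseases <- sort(unique(normalize_label(diseases)))
  mapped <- vapply(diseases,
                   function(d) !is.null(mapping[[d]]) && length(mapping[[d]]) > 0L,
                   logical(1))
  if (any(!mapped)) {
    warning(sprintf("%d disease(s) without MeSH mapping excluded: %s",
                    sum(!mapped),
                    paste(diseases[!mapped], collapse = ", ")))
  }
  diseases <- diseases[mapped]
  if (length(diseases) == 0L) stop("no disease has a MeSH mapping")
  dags <- lapply(diseases, build_disease_dag, mapping = mapping,
                 term_edges = term_edges, delta = delta)
  n <- length(diseases)
  s1 <- diag(1, n)
  dimnames(s1) <- list(diseases, diseases)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        s1[i, j] <- s1[j, i] <- semantic_similarity(dags[[i]], dags[[j]])
      }
    }
  }
  s1
}
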