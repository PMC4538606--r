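#' Best match of an element against a group
#'
#' The element-to-group similarity used throughout the functional
#' similarity cascade: the maximum base similarity between `element` and
#' any member of `group`.
#'
#' @param element entity label present in `base`.
#' @param group non-empty character vector of entity labels in `base`.
#' @param base symmetric similarity matrix with entity dimnames.
#' @return maximum similarity in `[0, 1]`.
#' @export
element_group_similarity <- function(element, group, base) {
  stopifnot(is.matrix(base), !is.null(rownames(base)))
  if (length(group) == 0L) stop("group must be non-empty")
  element <- normalize_label(element)
  group <- normalize_label(group)
  if (!element %in% rownames(base)) {
    stop(sprintf("element '%s' not in base similarity matrix", element))
  }
  if (!all(group %in% colnames(base))) {
    stop("group contains entities absent from the base similarity matrix")
  }
  max(base[element, group])
}

#' Best-match-average similarity of two groups
#'
#' Group-to-group similarity: each member of one group is matched to its
#' best counterpart in the other group, and the best-match scores from
#' both directions are averaged,
#' `(sum_a S(a, Gv) + sum_b S(b, Gu)) / (|Gu| + |Gv|)`.
#' Symmetric; identical groups give 1 when `base` has unit diagonal.  An
#' empty group makes the similarity undefined and `NA` is returned (not
#' 0).
#'
#' @param group_u,group_v character vectors of entity labels in `base`.
#' @param base symmetric similarity matrix with entity dimnames.
#' @return similarity in `[0, 1]`, or `NA_real_` if a group is empty.
#' @examples
#' base <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("d1", "d2"), c("d1", "d2")))
#' group_group_similarity(c("d1", "d2"), "d1", base)  # (1 + 0.4 + 1)/3 = 0.8
#' @export
group_group_similarity <- function(group_u, group_v, base) {
  stopifnot(is.matrix(base), !is.null(rownames(base)))
  if (length(group_u) == 0L || length(group_v) == 0L) return(NA_real_)
  group_u <- normalize_label(group_u)
  group_v <- normalize_label(group_v)
  if (!all(c(group_u, group_v) %in% rownames(base))) {
    stop("groups contain entities absent from the base similarity matrix")
  }
  sub <- base[group_u, group_v, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
    (length(group_u) + length(group_v))
}

#' miRNA functional similarity matrix (S2)
#'
#' Functional similarity of two miRNAs as the best-match-average semantic
#' similarity of their associated disease groups over the disease
#' similarity matrix `s1`.  Diseases missing from `s1` are dropped from
#' the groups (with a logged count); miRNAs whose group becomes empty are
#' excluded from the output.
#'
#' @param mir_dis `association_set` between `"mirna"` and `"disease"`.
#' @param s1 disease semantic similarity matrix from
#'   [semantic_similarity_matrix()].
#' @return symmetric similarity matrix over the kept miRNAs, unit diagonal.
#' @export
mirna_functional_similarity <- function(mir_dis, s1) {
  groups <- annotation_groups(mir_dis, entity_class = "mirna",
                              annotation_class = "disease", base = s1)
  group_similarity_matrix(groups, s1)
}

#' lncRNA functional similarity matrix (FS)
#'
#' Functional similarity of two lncRNAs as the best-match-average
#' similarity of their interacting miRNA groups over the miRNA functional
#' similarity matrix `s2` — the final step of the cascade.  lncRNAs with
#' no miRNA partner present in `s2` are excluded: the method is undefined
#' for lncRNAs without known miRNA interaction partners.
#'
#' @param lnc_mir `association_set` between `"lncrna"` and `"mirna"`.
#' @param s2 miRNA functional similarity matrix from
#'   [mirna_functional_similarity()].
#' @return symmetric similarity matrix over the kept lncRNAs, unit
#'   diagonal.
#' @export
lncrna_functional_similarity <- function(lnc_mir, s2) {
  groups <- annotation_groups(lnc_mir, entity_class = "lncrna",
                              annotation_class = "mirna", base = s2)
  group_similarity_matrix(groups, s2)
}

# Annotation groups of each entity, restricted to annotations present in
# the base matrix; entities left with empty groups are excluded.
annotation_groups <- function(assoc, entity_class, annotation_class, base) {
  stopifnot(inherits(assoc, "association_set"), is.matrix(base))
  side <- side_of_class(assoc, entity_class)
  raw <- neighbor_list(assoc, side)
  known <- rownames(base)
  groups <- lapply(raw, intersect, y = known)
  n_dropped <- sum(lengths(raw) - lengths(groups))
  if (n_dropped > 0L) {
    message(sprintf("dropped %d %s annotation(s) absent from the base similarity matrix",
                    n_dropped, annotation_class))
  }
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning(sprintf("excluded %d %s(s) with no %s annotation in the base matrix",
                    sum(empty), entity_class, annotation_class))
  }
  groups <- groups[!empty]
  if (length(groups) == 0L) {
    stop(sprintf("no eligible %s: every annotation group is empty", entity_class))
  }
  groups[order(names(groups))]
}

# Pairwise best-match-average matrix over annotation groups.  Diagonal is
# forced to exactly 1 (the formula gives 1 for identical groups; forcing
# avoids float drift).
group_similarity_matrix <- function(groups, base) {
  nms <- names(groups)
  n <- length(nms)
  out <- diag(1, n)
  dimnames(out) <- list(nms, nms)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        out[i, j] <- out[j, i] <-
          group_group_similarity(groups[[i]], groups[[j]], base)
      }
    }
  }
  out
}

#' Write a similarity matrix as long-format TSV
#'
#' One row per unordered entity pair (including the diagonal), columns
#' `entity_a`, `entity_b`, `value` — the interchange format for the S1, S2
#' and FS matrices.
#'
#' @param mat symmetric similarity matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_long <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            identical(rownames(mat), colnames(mat)))
  idx <- which(upper.tri(mat, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(entity_a = rownames(mat)[idx[, 1L]],
                    entity_b = colnames(mat)[idx[, 2L]],
                    value = mat[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$entity_a, out$entity_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format similarity TSV back into a matrix
#'
#' @param path TSV written by [write_similarity_long()].
#' @return symmetric numeric matrix with unit-filled missing diagonal.
#' @export
read_similarity_long <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric"))
  ents <- sort(unique(c(tab$entity_a, tab$entity_b)))
  m <- matrix(0, length(ents), length(ents), dimnames = list(ents, ents))
  m[cbind(tab$entity_a, tab$entity_b)] <- tab$value
  m[cbind(tab$entity_b, tab$entity_a)] <- tab$value
  m
}
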