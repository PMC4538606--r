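#' Upper-tail hypergeometric P-value for shared-partner enrichment
#'
#' Probability of observing at least `x` shared miRNAs when `L` miRNAs
#' (the disease's partners) are drawn without replacement from a universe
#' of `N` miRNAs of which `M` (the lncRNA's partners) count as successes:
#' `P(X >= x)` with `X ~ Hypergeometric(N, M, L)`.  Evaluated through
#' [stats::phyper()], which works in log space and is stable for the
#' universe sizes met here (up to a few thousand miRNAs).
#'
#' All arguments are recycled to a common length, so the function is
#' vectorized over pairs.
#'
#' @param N total miRNA universe size.
#' @param M number of miRNAs interacting with the lncRNA.
#' @param L number of miRNAs associated with the disease.
#' @param x number of miRNAs shared by both.
#' @param tail `"ge"` (default) for the inclusive tail `P(X >= x)`, the
#'   standard enrichment convention under which `x = 0` gives exactly 1;
#'   `"gt"` for the strict tail `P(X > x)`.
#' @return numeric vector of P-values in `[0, 1]`.
#' @examples
#' hypergeometric_tail_pvalue(10, 4, 5, 2)  # 186/252
#' hypergeometric_tail_pvalue(10, 4, 5, 0)  # exactly 1
#' @export
hypergeometric_tail_pvalue <- function(N, M, L, x, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  n <- max(length(N), length(M), length(L), length(x))
  N <- rep_len(as.numeric(N), n); M <- rep_len(as.numeric(M), n)
  L <- rep_len(as.numeric(L), n); x <- rep_len(as.numeric(x), n)
  if (any(N < 0 | M < 0 | L < 0 | x < 0) ||
      any(N != round(N) | M != round(M) | L != round(L) | x != round(x))) {
    stop("N, M, L, x must be nonnegative integers")
  }
  if (any(M > N) || any(L > N)) stop("M and L must not exceed N")
  if (any(x > pmin(M, L))) stop("x must not exceed min(M, L)")
  q <- if (tail == "ge") x - 1 else x
  stats::phyper(q, m = M, n = N - M, k = L, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up false discovery rate adjustment (via [stats::p.adjust()]),
#' returned in the original input order and clipped to 1.
#'
#' @param pvalues numeric vector of raw P-values in `[0, 1]`.
#' @return numeric vector of BH-adjusted P-values, same length and order.
#' @examples
#' bh_adjust(c(0.03, 0.002))  # c(0.03, 0.004)
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("all P-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Score every lncRNA-disease pair by shared-miRNA enrichment
#'
#' The core prediction step: for each lncRNA in the lncRNA-miRNA
#' interaction set crossed with each disease in the miRNA-disease
#' association set, counts the shared miRNA partners and computes the
#' hypergeometric tail P-value, then adjusts all P-values jointly by
#' Benjamini-Hochberg.  The miRNA universe `N` is the union of miRNAs
#' appearing in either input set.  Pairs whose lncRNA or disease has no
#' miRNA partner in the other set get `x = 0` and hence P-value 1; they are
#' kept so the score table always covers the full cross-product.
#'
#' @param lnc_mir `association_set` between `"lncrna"` and `"mirna"`.
#' @param mir_dis `association_set` between `"mirna"` and `"disease"`.
#' @param tail tail convention, see [hypergeometric_tail_pvalue()].
#' @return a data frame with one row per (lncRNA, disease) pair and columns
#'   `lncrna`, `disease`, `x`, `M`, `L`, `N`, `pvalue`, `fdr`, ordered by
#'   lncRNA then disease.
#' @examples
#' lm <- association_set(c("l1", "l1"), c("m1", "m2"), "lncrna", "mirna")
#' md <- association_set(c("m1", "m2"), c("d1", "d1"), "mirna", "disease")
#' score_all_pairs(lm, md)
#' @export
score_all_pairs <- function(lnc_mir, mir_dis, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  stopifnot(inherits(lnc_mir, "association_set"),
            inherits(mir_dis, "association_set"))
  mir_in_lnc <- entities_of_class(lnc_mir, "mirna")
  mir_in_dis <- entities_of_class(mir_dis, "mirna")
  universe <- sort(union(mir_in_lnc, mir_in_dis))
  if (length(universe) == 0L) stop("empty miRNA universe: no miRNAs in either input")
  lncs <- entities_of_class(lnc_mir, "lncrna")
  diss <- entities_of_class(mir_dis, "disease")

  A <- incidence_matrix(lnc_mir, "lncrna", lncs, universe)
  B <- incidence_matrix(mir_dis, "disease", diss, universe)
  X <- A %*% t(B)                       # shared-miRNA counts, lncRNA x disease
  M <- rowSums(A)
  L <- rowSums(B)
  N <- length(universe)

  nl <- length(lncs); nd <- length(diss)
  out <- data.frame(
    lncrna = rep(lncs, each = nd),
    disease = rep(diss, times = nl),
    x = as.integer(t(X)),
    M = as.integer(rep(M, each = nd)),
    L = as.integer(rep(L, times = nl)),
    N = N,
    stringsAsFactors = FALSE
  )
  out$pvalue <- hypergeometric_tail_pvalue(out$N, out$M, out$L, out$x,
                                           tail = tail)
  out$fdr <- bh_adjust(out$pvalue)
  out
}

# 0/1 incidence matrix of `rows` (entities of class `row_class`) against the
# miRNA universe columns.
incidence_matrix <- function(assoc, row_class, rows, universe) {
  side <- side_of_class(assoc, row_class)
  other <- if (side == "left") "right" else "left"
  m <- matrix(0, nrow = length(rows), ncol = length(universe),
              dimnames = list(rows, universe))
  ri <- match(assoc$edges[[side]], rows)
  ci <- match(assoc$edges[[other]], universe)
  ok <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[ok], ci[ok])] <- 1
  m
}

#' Extract significant pairs at an FDR threshold
#'
#' @param scores a pair-score data frame from [score_all_pairs()].
#' @param fdr_threshold call a pair significant when `fdr` is strictly
#'   below this value (default 0.05).
#' @return the significant rows sorted by `fdr`, then `pvalue`, then
#'   labels (deterministic order).
#' @export
significant_pairs <- function(scores, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(scores), "fdr" %in% names(scores),
            fdr_threshold > 0, fdr_threshold < 1)
  hit <- scores[scores$fdr < fdr_threshold, , drop = FALSE]
  hit <- hit[order(hit$fdr, hit$pvalue, hit$lncrna, hit$disease), ,
             drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Rank of a lncRNA in a disease's prediction list
#'
#' Position (1-based) of `lncrna` among all lncRNAs scored for `disease`,
#' ordered by ascending P-value with ties broken by larger shared count
#' `x` and then lexicographic lncRNA label, so the ranking is
#' deterministic.
#'
#' @param scores a pair-score data frame from [score_all_pairs()].
#' @param disease,lncrna the queried pair (labels normalized internally).
#' @return integer rank, 1 = top prediction.
#' @export
rank_for_disease <- function(scores, disease, lncrna) {
  disease <- normalize_label(disease)
  lncrna <- normalize_label(lncrna)
  sub <- scores[scores$disease == disease, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("disease '%s' not present in scores", disease))
  if (!lncrna %in% sub$lncrna) {
    stop(sprintf("pair (%s, %s) not present in scores", lncrna, disease))
  }
  ord <- order(sub$pvalue, -sub$x, sub$lncrna)
  match(lncrna, sub$lncrna[ord])
}
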