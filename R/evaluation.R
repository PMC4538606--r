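#' Leave-one-out ranking evaluation of pair scores
#'
#' Evaluates a pair-score table against a gold standard of experimentally
#' verified lncRNA-disease associations.  Each verified pair is treated in
#' turn as the test sample and ranked, by ascending P-value, against the
#' candidate pairs — all scored pairs without verification evidence (the
#' other gold pairs are excluded from the candidate pool, since they do
#' have evidence).  Because the scoring model uses no gold information,
#' leaving a pair out does not change its score, so the loop reduces to
#' ranking each positive once against the fixed candidate pool; the result
#' is identical to a literal per-fold rerun.
#'
#' Ranks are midranks: a test score tied with `k` candidate scores gets
#' half of `k` counted below it, the standard Mann-Whitney convention.
#' TPR at a rank threshold is the fraction of test pairs at or above it,
#' FPR the fraction of candidates; the AUC is the trapezoidal area under
#' the TPR-FPR curve.
#'
#' @param scores pair-score data frame from [score_all_pairs()].
#' @param gold `association_set` of verified lncRNA-disease pairs; every
#'   gold pair must be present in `scores` (use [filter_to_universe()]
#'   first).
#' @param per_disease if `TRUE`, rank each test pair only against the
#'   candidate pairs of its own disease (sensitivity analysis); AUC is then
#'   the mean per-pair concordance and no pooled ROC curve is returned.
#' @return object of class `loocv_result`: a list with `test_pairs` (data
#'   frame `lncrna`, `disease`, `pvalue`, `rank`, `n_candidates`), `roc`
#'   (data frame `fpr`, `tpr`, from (0,0) to (1,1); `NULL` in per-disease
#'   mode) and `auc`.
#' @export
loocv <- function(scores, gold, per_disease = FALSE) {
  stopifnot(is.data.frame(scores),
            all(c("lncrna", "disease", "pvalue") %in% names(scores)),
            inherits(gold, "association_set"))
  lside <- side_of_class(gold, "lncrna")
  dside <- side_of_class(gold, "disease")
  gkey <- paste(gold$edges[[lside]], gold$edges[[dside]], sep = "\r")
  skey <- paste(scores$lncrna, scores$disease, sep = "\r")
  missing <- setdiff(gkey, skey)
  if (length(missing) > 0L) {
    stop(sprintf("gold pairs missing from scores: %s",
                 paste(gsub("\r", " / ", missing), collapse = "; ")))
  }
  is_test <- skey %in% gkey

  if (per_disease) {
    test <- scores[is_test, , drop = FALSE]
    ranks <- numeric(nrow(test))
    ncand <- integer(nrow(test))
    conc <- numeric(nrow(test))
    for (i in seq_len(nrow(test))) {
      cand <- scores$pvalue[!is_test & scores$disease == test$disease[i]]
      ranks[i] <- midrank(test$pvalue[i], cand)
      ncand[i] <- length(cand)
      conc[i] <- if (length(cand) == 0L) NA_real_ else
        (sum(cand > test$pvalue[i]) + 0.5 * sum(cand == test$pvalue[i])) /
        length(cand)
    }
    res <- list(
      test_pairs = data.frame(lncrna = test$lncrna, disease = test$disease,
                              pvalue = test$pvalue, rank = ranks,
                              n_candidates = ncand,
                              stringsAsFactors = FALSE),
      roc = NULL,
      auc = mean(conc, na.rm = TRUE)
    )
    class(res) <- "loocv_result"
    return(res)
  }

  test_p <- scores$pvalue[is_test]
  cand_p <- scores$pvalue[!is_test]
  if (length(cand_p) == 0L) stop("no candidate pairs: every scored pair is in the gold standard")
  sc <- sort(cand_p)
  less <- findInterval(test_p, sc, left.open = TRUE)
  ties <- findInterval(test_p, sc) - less
  ranks <- 1 + less + 0.5 * ties

  roc <- roc_points(test_p, cand_p)
  res <- list(
    test_pairs = data.frame(lncrna = scores$lncrna[is_test],
                            disease = scores$disease[is_test],
                            pvalue = test_p, rank = ranks,
                            n_candidates = length(cand_p),
                            stringsAsFactors = FALSE),
    roc = roc,
    auc = trapezoid_auc(roc$fpr, roc$tpr)
  )
  class(res) <- "loocv_result"
  res
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("loocv_result: %d test pairs, %s candidates, AUC = %.4f\n",
              nrow(x$test_pairs),
              paste(unique(x$test_pairs$n_candidates), collapse = "/"),
              x$auc))
  invisible(x)
}

# ROC points at every distinct score threshold (scores: lower = better).
roc_points <- function(test_scores, candidate_scores) {
  thr <- sort(unique(c(test_scores, candidate_scores)))
  st <- sort(test_scores)
  sc <- sort(candidate_scores)
  tpr <- findInterval(thr, st) / length(st)
  fpr <- findInterval(thr, sc) / length(sc)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(fpr, tpr) {
  n <- length(fpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-n]) / 2)
}

#' AUC from test-pair ranks
#'
#' Converts 1-based ranks of test pairs among `n_candidates` candidate
#' pairs into the area under the ROC curve: the Mann-Whitney U statistic
#' normalized by `n_test * n_candidates`.  A test pair ranked `r` beats
#' `n_candidates - (r - 1)` candidates; midranks (fractional, from tied
#' scores) are supported and implement the ties-count-one-half convention.
#'
#' @param ranks numeric vector of ranks in `[1, n_candidates + 1]`.
#' @param n_candidates number of candidate pairs each rank was computed
#'   against.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_from_ranks(c(1, 3), 4)  # (4 + 2) / 8 = 0.75
#' @export
auc_from_ranks <- function(ranks, n_candidates) {
  stopifnot(n_candidates >= 1, length(ranks) >= 1,
            all(ranks >= 1), all(ranks <= n_candidates + 1))
  mean((n_candidates - (ranks - 1)) / n_candidates)
}

# Midrank of one score among candidate scores (ties count half).
midrank <- function(score, candidates) {
  1 + sum(candidates < score) + 0.5 * sum(candidates == score)
}
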