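#' Run the shared-miRNA enrichment prediction pipeline
#'
#' End-to-end prediction: reads the lncRNA-miRNA interaction and
#' miRNA-disease association tables, merges miRNA genomic copies, scores
#' every lncRNA-disease pair and writes the full score table
#' (`scores.tsv`) plus the FDR-significant prediction list
#' (`significant.tsv`) into `out_dir`.  Progress counts go to `message()`
#' so data streams stay clean.
#'
#' @param lnc_mir_path,mir_dis_path TSV inputs (see
#'   [read_association_table()]).
#' @param out_dir output directory, created if needed.
#' @param fdr_threshold significance cutoff (strict `<`), default 0.05.
#' @param tail tail convention, see [hypergeometric_tail_pvalue()].
#' @param merge_copies merge miRNA genomic copies before scoring
#'   (default `TRUE`).
#' @param lnc_mir_columns,mir_dis_columns column selectors passed through
#'   to the readers.
#' @param aliases optional alias data frame passed to the readers.
#' @return invisibly, a list with the score data frame, the significant
#'   subset and the paths written.
#' @export
run_hglda <- function(lnc_mir_path, mir_dis_path, out_dir,
                      fdr_threshold = 0.05, tail = "ge",
                      merge_copies = TRUE,
                      lnc_mir_columns = c(1L, 2L),
                      mir_dis_columns = c(1L, 2L),
                      aliases = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lnc_mir <- read_association_table(lnc_mir_path, "lncrna", "mirna",
                                    columns = lnc_mir_columns,
                                    aliases = aliases)
  mir_dis <- read_association_table(mir_dis_path, "mirna", "disease",
                                    columns = mir_dis_columns,
                                    aliases = aliases)
  if (merge_copies) {
    lnc_mir <- merge_mirna_copies(lnc_mir)
    mir_dis <- merge_mirna_copies(mir_dis)
  }
  scores <- score_all_pairs(lnc_mir, mir_dis, tail = tail)
  sig <- significant_pairs(scores, fdr_threshold = fdr_threshold)
  message(sprintf("N = %d miRNAs, %d lncRNAs x %d diseases = %d pairs, %d significant at FDR < %g",
                  scores$N[1L], length(unique(scores$lncrna)),
                  length(unique(scores$disease)), nrow(scores), nrow(sig),
                  fdr_threshold))
  score_path <- file.path(out_dir, "scores.tsv")
  sig_path <- file.path(out_dir, "significant.tsv")
  utils::write.table(scores, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sig, sig_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(scores = scores, significant = sig,
                 paths = c(scores = score_path, significant = sig_path)))
}

#' Run the functional-similarity cascade
#'
#' Computes and writes the three similarity matrices in long TSV format:
#' disease semantic similarity (`s1.tsv`) from the MeSH inputs, miRNA
#' functional similarity (`s2.tsv`) from S1 and the miRNA-disease
#' associations, and lncRNA functional similarity (`fs.tsv`) from S2 and
#' the lncRNA-miRNA interactions.
#'
#' @param mir_dis_path,lnc_mir_path association TSV inputs.
#' @param mesh_mapping_path,mesh_edges_path disease-DAG TSV inputs (see
#'   [read_disease_dag_inputs()]).
#' @param out_dir output directory, created if needed.
#' @param delta semantic decay factor, see [build_disease_dag()].
#' @param merge_copies merge miRNA genomic copies first (default `TRUE`).
#' @return invisibly, a list with matrices `s1`, `s2`, `fs` and the paths
#'   written.
#' @export
run_lfscm <- function(mir_dis_path, lnc_mir_path, mesh_mapping_path,
                      mesh_edges_path, out_dir, delta = 0.5,
                      merge_copies = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mir_dis <- read_association_table(mir_dis_path, "mirna", "disease")
  lnc_mir <- read_association_table(lnc_mir_path, "lncrna", "mirna")
  if (merge_copies) {
    mir_dis <- merge_mirna_copies(mir_dis)
    lnc_mir <- merge_mirna_copies(lnc_mir)
  }
  dag_in <- read_disease_dag_inputs(mesh_mapping_path, mesh_edges_path)
  s1 <- semantic_similarity_matrix(entities_of_class(mir_dis, "disease"),
                                   dag_in$mapping, dag_in$edges,
                                   delta = delta)
  s2 <- mirna_functional_similarity(mir_dis, s1)
  fs <- lncrna_functional_similarity(lnc_mir, s2)
  message(sprintf("S1: %d diseases; S2: %d miRNAs; FS: %d lncRNAs",
                  nrow(s1), nrow(s2), nrow(fs)))
  paths <- c(s1 = file.path(out_dir, "s1.tsv"),
             s2 = file.path(out_dir, "s2.tsv"),
             fs = file.path(out_dir, "fs.tsv"))
  write_similarity_long(s1, paths[["s1"]])
  write_similarity_long(s2, paths[["s2"]])
  write_similarity_long(fs, paths[["fs"]])
  invisible(list(s1 = s1, s2 = s2, fs = fs, paths = paths))
}

#' Run the leave-one-out evaluation
#'
#' Reads a pair-score TSV (as written by [run_hglda()]) and a gold
#' standard TSV, restricts the gold set to the scored universe, runs
#' [loocv()] and writes per-pair ranks (`ranks.tsv`), ROC points
#' (`roc.tsv`) and the AUC (`auc.txt`, single line).
#'
#' @param scores_path pair-score TSV with columns `lncrna`, `disease`,
#'   `pvalue`.
#' @param gold_path gold-standard TSV, columns lncRNA then disease.
#' @param out_dir output directory, created if needed.
#' @param per_disease rank within each disease instead of globally.
#' @return invisibly, the `loocv_result`.
#' @export
run_evaluate <- function(scores_path, gold_path, out_dir,
                         per_disease = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scores <- utils::read.delim(scores_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  stopifnot(all(c("lncrna", "disease", "pvalue") %in% names(scores)))
  gold <- read_association_table(gold_path, "lncrna", "disease")
  gold <- filter_to_universe(gold, diseases = unique(scores$disease),
                             lncrnas = unique(scores$lncrna))
  if (n_edges(gold) == 0L) stop("no gold pair falls inside the scored universe")
  res <- loocv(scores, gold, per_disease = per_disease)
  message(sprintf("LOOCV: %d test pairs, AUC = %.4f",
                  nrow(res$test_pairs), res$auc))
  utils::write.table(res$test_pairs, file.path(out_dir, "ranks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$roc)) {
    utils::write.table(res$roc, file.path(out_dir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(format(res$auc, digits = 10), file.path(out_dir, "auc.txt"))
  invisible(res)
}

#' Write a synthetic fixture to disk
#'
#' Materializes a [fixture_spec()] as the three association TSVs plus the
#' two disease-DAG TSVs in `out_dir`, ready to be consumed by
#' [run_hglda()], [run_lfscm()] and [run_evaluate()].
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a named character vector of the paths written.
#' @export
run_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- generate_bipartite_fixture(spec)
  dg <- generate_dag_fixture(spec)
  paths <- c(lnc_mir = file.path(out_dir, "lnc_mir.tsv"),
             mir_dis = file.path(out_dir, "mir_dis.tsv"),
             gold = file.path(out_dir, "gold.tsv"),
             mesh_mapping = file.path(out_dir, "mesh_mapping.tsv"),
             mesh_edges = file.path(out_dir, "mesh_edges.tsv"))
  write_association_table(fx$lnc_mir, paths[["lnc_mir"]])
  write_association_table(fx$mir_dis, paths[["mir_dis"]])
  write_association_table(fx$gold, paths[["gold"]])
  utils::write.table(dg$mapping, paths[["mesh_mapping"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dg$edges, paths[["mesh_edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(sprintf("fixture (seed %d): %d lnc-mir, %d mir-dis, %d gold edges",
                  spec$seed, n_edges(fx$lnc_mir), n_edges(fx$mir_dis),
                  n_edges(fx$gold)))
  invisible(paths)
}
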