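#' Read a tab-separated association table
#'
#' Reads a header-bearing TSV of pairwise associations into an
#' [association_set()].  Rows that repeat the same pair — e.g. the same
#' association reported with different supporting evidence — collapse to a
#' single edge.  The column layout is configurable because source databases
#' differ: `columns` may be column names or 1-based indices, and extra
#' columns (evidence text, PubMed ids, ...) are ignored.
#'
#' @param path path to a TSV file with a header row.
#' @param left_class,right_class entity-class names for the two columns.
#' @param columns length-2 vector of column names or indices giving the
#'   left and right entity columns (default: the first two columns).
#' @param aliases optional data frame with columns `alias` and `canonical`
#'   mapping residual entity-name synonyms (applied after normalization).
#' @param provenance source tag recorded on the result (default: the file
#'   name).
#' @return an `association_set`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("mirna\tdisease", "m1\td1", "m1\td1", "m2\td1"), tf)
#' read_association_table(tf, "mirna", "disease")
#' @export
read_association_table <- function(path, left_class, right_class,
                                   columns = c(1L, 2L), aliases = NULL,
                                   provenance = basename(path)) {
  if (!file.exists(path)) stop(sprintf("association table not found: %s", path))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  stopifnot(length(columns) == 2L)
  if (is.character(columns)) {
    missing_cols <- setdiff(columns, names(tab))
    if (length(missing_cols) > 0L) {
      stop(sprintf("columns %s not found in %s (has: %s)",
                   paste(missing_cols, collapse = ", "), path,
                   paste(names(tab), collapse = ", ")))
    }
  } else if (max(columns) > ncol(tab)) {
    stop(sprintf("%s has %d columns, need column %d", path, ncol(tab),
                 max(columns)))
  }
  if (nrow(tab) == 0L) stop(sprintf("no associations in %s", path))
  left <- tab[[columns[[1L]]]]
  right <- tab[[columns[[2L]]]]
  if (!is.null(aliases)) {
    stopifnot(all(c("alias", "canonical") %in% names(aliases)))
    left <- apply_aliases(left, aliases)
    right <- apply_aliases(right, aliases)
  }
  association_set(left, right, left_class, right_class,
                  provenance = provenance)
}

apply_aliases <- function(labels, aliases) {
  labels <- normalize_label(labels)
  from <- normalize_label(aliases$alias)
  to <- normalize_label(aliases$canonical)
  hit <- match(labels, from)
  labels[!is.na(hit)] <- to[hit[!is.na(hit)]]
  labels
}

#' Write an association set as TSV
#'
#' Long two-column TSV with a header naming the entity classes; reading it
#' back with [read_association_table()] reproduces the identical edge set.
#'
#' @param x an `association_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  stopifnot(inherits(x, "association_set"))
  out <- x$edges
  names(out) <- c(x$left_class, x$right_class)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Merge genomic miRNA copies producing the same mature miRNA
#'
#' Several miRNA genes occur as multiple genomic copies whose names carry a
#' trailing copy index (e.g. `hsa-mir-125b-1` and `hsa-mir-125b-2`) yet
#' produce the same mature miRNA.  This renames copy-suffixed labels on the
#' miRNA side to their common stem and collapses the resulting duplicate
#' edges.  The default pattern strips a trailing `-<digit>` only when the
#' remaining stem itself ends in the numeric part of a mature miRNA name
#' (so `hsa-mir-7-1` becomes `hsa-mir-7` but `hsa-mir-21` and `hsa-mir-1`
#' are left alone).
#'
#' @param assoc an `association_set` with `"mirna"` on one side.
#' @param pattern regular expression whose first capture group is the stem;
#'   labels not matching are untouched.  Set to `NULL` to disable merging.
#' @return a new `association_set` with merged miRNA labels.
#' @examples
#' a <- association_set(c("hsa-mir-125b-1", "hsa-mir-125b-2"),
#'                      c("d1", "d1"), "mirna", "disease")
#' n_edges(merge_mirna_copies(a))  # 1
#' @export
merge_mirna_copies <- function(assoc,
                               pattern = "^(.*[0-9][a-z]*)-[1-9]$") {
  stopifnot(inherits(assoc, "association_set"))
  if (is.null(pattern)) return(assoc)
  side <- side_of_class(assoc, "mirna")
  lab <- assoc$edges[[side]]
  hit <- grepl(pattern, lab)
  lab[hit] <- sub(pattern, "\\1", lab[hit])
  edges <- assoc$edges
  edges[[side]] <- lab
  association_set(edges$left, edges$right, assoc$left_class,
                  assoc$right_class, provenance = assoc$provenance)
}

#' Restrict a gold-standard set to a disease and lncRNA universe
#'
#' Gold-standard lncRNA-disease associations whose disease or lncRNA does
#' not occur in the datasets used for scoring cannot be ranked and are
#' removed before evaluation.
#'
#' @param gold an `association_set` between `"lncrna"` and `"disease"`.
#' @param diseases,lncrnas character vectors of admissible labels
#'   (normalized internally).
#' @return the filtered `association_set` (possibly with zero edges).
#' @export
filter_to_universe <- function(gold, diseases, lncrnas) {
  stopifnot(inherits(gold, "association_set"))
  lside <- side_of_class(gold, "lncrna")
  dside <- side_of_class(gold, "disease")
  diseases <- normalize_label(diseases)
  lncrnas <- normalize_label(lncrnas)
  keep <- gold$edges[[dside]] %in% diseases &
    gold$edges[[lside]] %in% lncrnas
  out <- gold
  out$edges <- gold$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Read disease-to-MeSH mapping and MeSH term DAG inputs
#'
#' Two TSV inputs describe the disease ontology side: a disease-to-term
#' mapping (a disease may map to several MeSH tree positions) and a
#' parent-to-child edge list over MeSH terms.  The edge list must be
#' acyclic; a cycle is reported with one offending cycle named.
#'
#' @param mapping_path TSV with header, columns disease and term.
#' @param edges_path TSV with header, columns parent and child.
#' @return a list with `mapping` (named list: disease to character vector of
#'   terms) and `edges` (data frame with columns `parent`, `child`).
#' @export
read_disease_dag_inputs <- function(mapping_path, edges_path) {
  for (p in c(mapping_path, edges_path)) {
    if (!file.exists(p)) stop(sprintf("DAG input not found: %s", p))
  }
  map_tab <- utils::read.delim(mapping_path, sep = "\t", header = TRUE,
                               quote = "", colClasses = "character",
                               check.names = FALSE)
  edge_tab <- utils::read.delim(edges_path, sep = "\t", header = TRUE,
                                quote = "", colClasses = "character",
                                check.names = FALSE)
  stopifnot(ncol(map_tab) >= 2L, ncol(edge_tab) >= 2L)
  mapping_df <- data.frame(disease = normalize_label(map_tab[[1L]]),
                           term = normalize_label(map_tab[[2L]]),
                           stringsAsFactors = FALSE)
  edges <- data.frame(parent = normalize_label(edge_tab[[1L]]),
                      child = normalize_label(edge_tab[[2L]]),
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$parent, edges$child, sep = "\r")), ,
                 drop = FALSE]
  assert_acyclic(edges)
  mapping <- lapply(split(mapping_df$term, mapping_df$disease),
                    function(v) sort(unique(v)))
  list(mapping = mapping, edges = edges)
}

# Errors with one concrete cycle if the parent->child edge list is cyclic.
assert_acyclic <- function(edges) {
  if (nrow(edges) == 0L) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     directed = TRUE)
  if (igraph::is_dag(g)) return(invisible(TRUE))
  cyc <- find_one_cycle(edges)
  stop(sprintf("term graph is cyclic: %s", paste(cyc, collapse = " -> ")))
}

find_one_cycle <- function(edges) {
  children <- split(edges$child, edges$parent)
  # walk from any node on a cycle until a node repeats
  indeg <- table(factor(edges$child,
                        levels = unique(c(edges$parent, edges$child))))
  nodes <- names(indeg)
  deg <- as.integer(indeg)
  names(deg) <- nodes
  queue <- nodes[deg == 0L]
  alive <- rep(TRUE, length(nodes))
  names(alive) <- nodes
  while (length(queue) > 0L) {
    n <- queue[[1L]]; queue <- queue[-1L]
    alive[[n]] <- FALSE
    for (ch in children[[n]]) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  start <- nodes[alive][1L]
  path <- start
  cur <- start
  repeat {
    nxt <- intersect(children[[cur]], nodes[alive])[1L]
    if (nxt %in% path) {
      return(c(path[seq(match(nxt, path), length(path))], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}
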