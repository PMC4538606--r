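#' Specification for a synthetic fixture
#'
#' Describes a seeded synthetic dataset: random bipartite lncRNA-miRNA and
#' miRNA-disease networks at a background edge density, with optional
#' planted lncRNA-disease pairs that are wired to a common set of miRNAs
#' (shared-neighbour enrichment), plus a rooted MeSH-like term tree for
#' the semantic-similarity side.  Defaults are the recovery study
#' conditions used throughout the package's tests: 50 miRNAs, background
#' density 0.05, plants sharing 10 miRNAs.
#'
#' @param seed integer seed driving a single local pseudo-random stream;
#'   the global RNG state is left untouched.
#' @param n_mirna,n_disease,n_lncrna entity counts (positive).
#' @param background_density independent edge probability in (0, 1).
#' @param planted_pairs data frame with columns `lncrna`, `disease`,
#'   `n_shared` (labels as 1-based entity indices or full labels), or
#'   `NULL` for none.
#' @param dag_depth,dag_branching shape of the synthetic term tree.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_mirna = 50L, n_disease = 15L,
                         n_lncrna = 20L, background_density = 0.05,
                         planted_pairs = NULL, dag_depth = 3L,
                         dag_branching = 2L) {
  stopifnot(n_mirna >= 1L, n_disease >= 1L, n_lncrna >= 1L,
            background_density > 0, background_density < 1,
            dag_depth >= 1L, dag_branching >= 1L)
  if (!is.null(planted_pairs)) {
    stopifnot(is.data.frame(planted_pairs),
              all(c("lncrna", "disease", "n_shared") %in% names(planted_pairs)))
    if (any(planted_pairs$n_shared > n_mirna)) {
      stop("planted n_shared exceeds n_mirna")
    }
  }
  spec <- list(seed = as.integer(seed), n_mirna = as.integer(n_mirna),
               n_disease = as.integer(n_disease),
               n_lncrna = as.integer(n_lncrna),
               background_density = background_density,
               planted_pairs = planted_pairs,
               dag_depth = as.integer(dag_depth),
               dag_branching = as.integer(dag_branching))
  class(spec) <- "fixture_spec"
  spec
}

# Run code under a local seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fixture_name <- function(prefix, i) sprintf("%s%03d", prefix, i)

resolve_plant_label <- function(x, prefix, n) {
  if (is.numeric(x)) {
    stopifnot(all(x >= 1), all(x <= n))
    return(fixture_name(prefix, as.integer(x)))
  }
  normalize_label(x)
}

#' Generate a seeded bipartite fixture with planted enrichment
#'
#' Draws the two association networks independently at the background
#' density, then, for each planted pair, samples `n_shared` miRNAs and
#' wires them to both the planted lncRNA and the planted disease (edges
#' are only ever added, so the planted pair shares at least `n_shared`
#' miRNAs).  Planted pairs are emitted as the gold standard.  Everything
#' is reproducible bit-for-bit from the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `lnc_mir`, `mir_dis`, `gold` association sets.
#' @examples
#' fx <- generate_bipartite_fixture(fixture_spec(
#'   seed = 7, planted_pairs = data.frame(lncrna = 1, disease = 1, n_shared = 10)))
#' n_edges(fx$gold)  # 1
#' @export
generate_bipartite_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  mirnas <- fixture_name("mir", seq_len(spec$n_mirna))
  diseases <- fixture_name("disease", seq_len(spec$n_disease))
  lncrnas <- fixture_name("lnc", seq_len(spec$n_lncrna))

  with_local_seed(spec$seed, {
    lm <- expand.grid(left = lncrnas, right = mirnas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lm <- lm[stats::runif(nrow(lm)) < spec$background_density, , drop = FALSE]
    md <- expand.grid(left = mirnas, right = diseases,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    md <- md[stats::runif(nrow(md)) < spec$background_density, , drop = FALSE]

    gold_l <- character(0); gold_d <- character(0)
    if (!is.null(spec$planted_pairs)) {
      for (k in seq_len(nrow(spec$planted_pairs))) {
        pl <- resolve_plant_label(spec$planted_pairs$lncrna[k], "lnc",
                                  spec$n_lncrna)
        pd <- resolve_plant_label(spec$planted_pairs$disease[k], "disease",
                                  spec$n_disease)
        ns <- spec$planted_pairs$n_shared[k]
        shared <- sample(mirnas, ns)
        lm <- rbind(lm, data.frame(left = pl, right = shared,
                                   stringsAsFactors = FALSE))
        md <- rbind(md, data.frame(left = shared, right = pd,
                                   stringsAsFactors = FALSE))
        gold_l <- c(gold_l, pl); gold_d <- c(gold_d, pd)
      }
    }
    if (nrow(lm) == 0L || nrow(md) == 0L) {
      stop("fixture draw produced an empty network; increase density or sizes")
    }
    list(
      lnc_mir = association_set(lm$left, lm$right, "lncrna", "mirna",
                                provenance = sprintf("fixture seed %d", spec$seed)),
      mir_dis = association_set(md$left, md$right, "mirna", "disease",
                                provenance = sprintf("fixture seed %d", spec$seed)),
      gold = if (length(gold_l) > 0L) {
        association_set(gold_l, gold_d, "lncrna", "disease",
                        provenance = "planted pairs")
      } else {
        empty <- association_set("x", "y", "lncrna", "disease")
        empty$edges <- empty$edges[0L, , drop = FALSE]
        empty
      }
    )
  })
}

#' Generate a rooted term-tree fixture with disease mappings
#'
#' Builds a complete rooted tree of the spec's depth and branching factor
#' (a valid DAG by construction) and maps each disease to one leaf term,
#' chosen uniformly from the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `mapping` (data frame `disease`, `term`) and `edges`
#'   (data frame `parent`, `child`).
#' @export
generate_dag_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  parent <- character(0); child <- character(0)
  level_nodes <- "root"
  for (d in seq_len(spec$dag_depth)) {
    nxt <- character(0)
    for (p in level_nodes) {
      kids <- paste0(p, ".", seq_len(spec$dag_branching))
      parent <- c(parent, rep(p, length(kids)))
      child <- c(child, kids)
      nxt <- c(nxt, kids)
    }
    level_nodes <- nxt
  }
  leaves <- level_nodes
  diseases <- fixture_name("disease", seq_len(spec$n_disease))
  terms <- with_local_seed(spec$seed + 1L,
                           sample(leaves, spec$n_disease, replace = TRUE))
  list(mapping = data.frame(disease = diseases, term = terms,
                            stringsAsFactors = FALSE),
       edges = data.frame(parent = parent, child = child,
                          stringsAsFactors = FALSE))
}

#' Brute-force hypergeometric tail probability by draw enumeration
#'
#' Reference oracle: enumerates every one of the `choose(N, L)` ways to
#' draw `L` miRNAs from the universe of `N` (of which the first `M` count
#' as the lncRNA's partners) and returns the fraction of draws with at
#' least `x` successes.  Only feasible for tiny `N`; intended for tests.
#'
#' @param N,M,L,x hypergeometric parameters (scalars, `N <= 12`).
#' @return `P(X >= x)` as an exact enumeration fraction.
#' @examples
#' brute_force_hypergeom(10, 4, 5, 2)  # 186/252
#' @export
brute_force_hypergeom <- function(N, M, L, x) {
  stopifnot(N <= 12, N >= 0, M >= 0, L >= 0, x >= 0, M <= N, L <= N,
            x <= min(M, L))
  if (L == 0L) return(as.numeric(x <= 0))
  draws <- utils::combn(N, L)
  successes <- colSums(draws <= M)
  mean(successes >= x)
}

#' Brute-force best-match-average group similarity
#'
#' Reference oracle: plain double loop computing each element's best match
#' in the opposite group and averaging over both groups.  Intended for
#' tests on small groups.
#'
#' @param group_u,group_v character vectors (each of length at most 6).
#' @param base similarity matrix with dimnames.
#' @return best-match-average similarity.
#' @export
brute_force_bma <- function(group_u, group_v, base) {
  stopifnot(length(group_u) >= 1, length(group_v) >= 1,
            length(group_u) <= 6, length(group_v) <= 6)
  total <- 0
  for (a in group_u) {
    best <- -Inf
    for (b in group_v) best <- max(best, base[a, b])
    total <- total + best
  }
  for (b in group_v) {
    best <- -Inf
    for (a in group_u) best <- max(best, base[a, b])
    total <- total + best
  }
  total / (length(group_u) + length(group_v))
}

#' Brute-force AUC by concordant-pair counting
#'
#' Reference oracle: Mann-Whitney concordance over all (test, candidate)
#' score pairs, where a lower score is better and ties count one half.
#' Intended for tests on small score sets.
#'
#' @param test_scores,candidate_scores numeric vectors (each of length at
#'   most 50).
#' @return AUC in `[0, 1]`.
#' @examples
#' brute_force_auc(c(0.01, 0.5), c(0.1, 0.9))  # 0.75
#' @export
brute_force_auc <- function(test_scores, candidate_scores) {
  stopifnot(length(test_scores) >= 1, length(candidate_scores) >= 1,
            length(test_scores) <= 50, length(candidate_scores) <= 50)
  conc <- 0
  for (t in test_scores) {
    for (c in candidate_scores) {
      if (t < c) conc <- conc + 1
      else if (t == c) conc <- conc + 0.5
    }
  }
  conc / (length(test_scores) * length(candidate_scores))
}
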