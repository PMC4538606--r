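#' Normalize an entity label
#'
#' Labels from different source databases are reconciled by trimming
#' surrounding whitespace, case-folding to lower case, and collapsing
#' internal runs of whitespace to a single space.  Equality of entities is
#' always on the normalized label.
#'
#' @param x character vector of raw labels.
#' @return character vector of normalized labels.
#' @examples
#' normalize_label(c("  Breast  Cancer ", "breast cancer"))
#' @export
normalize_label <- function(x) {
  gsub("[[:space:]]+", " ", trimws(tolower(as.character(x))))
}

#' Construct a bipartite association set
#'
#' An `association_set` is a deduplicated bipartite edge set between two
#' named entity classes (e.g. `"mirna"` and `"disease"`), the container used
#' for every network in this package.  Labels are normalized with
#' [normalize_label()] and duplicate edges collapse to one.
#'
#' @param left,right character vectors of equal length: the edge endpoints.
#' @param left_class,right_class entity-class names, e.g. `"lncrna"`,
#'   `"mirna"`, `"disease"`.
#' @param provenance free-text source tag carried along for logging.
#' @return an object of class `association_set` with fields `edges`
#'   (two-column character data frame), `left_class`, `right_class`,
#'   `provenance`.
#' @examples
#' a <- association_set(c("m1", "m1", "m2"), c("d1", "d1", "d1"),
#'                      "mirna", "disease")
#' n_edges(a)  # 2: the duplicate (m1, d1) collapsed
#' @export
association_set <- function(left, right, left_class, right_class,
                            provenance = "") {
  stopifnot(length(left) == length(right),
            is.character(left_class), length(left_class) == 1L,
            is.character(right_class), length(right_class) == 1L)
  left <- normalize_label(left)
  right <- normalize_label(right)
  if (any(!nzchar(left)) || any(!nzchar(right))) {
    stop("association_set: empty entity label after normalization")
  }
  keep <- !duplicated(paste(left, right, sep = "\r"))
  obj <- list(
    edges = data.frame(left = left[keep], right = right[keep],
                       stringsAsFactors = FALSE),
    left_class = left_class,
    right_class = right_class,
    provenance = provenance
  )
  class(obj) <- "association_set"
  obj
}

#' @export
print.association_set <- function(x, ...) {
  cat(sprintf("association_set: %s-%s, %d edges (%d x %d entities)%s\n",
              x$left_class, x$right_class, nrow(x$edges),
              length(unique(x$edges$left)), length(unique(x$edges$right)),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Number of edges in an association set
#' @param x an `association_set`.
#' @return integer edge count.
#' @export
n_edges <- function(x) {
  stopifnot(inherits(x, "association_set"))
  nrow(x$edges)
}

#' Entities on one side of an association set
#'
#' @param x an `association_set`.
#' @param side `"left"` or `"right"`.
#' @return sorted character vector of unique entity labels on that side.
#' @export
entities <- function(x, side = c("left", "right")) {
  stopifnot(inherits(x, "association_set"))
  side <- match.arg(side)
  sort(unique(x$edges[[side]]))
}

#' Entities of a given class in an association set
#'
#' Looks up which side carries `class` and returns its entities; errors if
#' neither side matches.
#'
#' @param x an `association_set`.
#' @param class entity-class name.
#' @return sorted character vector of unique labels.
#' @export
entities_of_class <- function(x, class) {
  entities(x, side_of_class(x, class))
}

side_of_class <- function(x, class) {
  stopifnot(inherits(x, "association_set"))
  if (identical(x$left_class, class)) return("left")
  if (identical(x$right_class, class)) return("right")
  stop(sprintf("association set %s-%s has no side of class '%s'",
               x$left_class, x$right_class, class))
}

#' Neighbors of an entity in an association set
#'
#' @param x an `association_set`.
#' @param entity entity label (normalized internally).
#' @param side which side `entity` lives on: `"left"` or `"right"`.
#' @return sorted character vector of the entity's partners on the opposite
#'   side (empty if the entity has no edges).
#' @examples
#' a <- association_set(c("m1", "m2"), c("d1", "d1"), "mirna", "disease")
#' neighbors(a, "d1", side = "right")  # c("m1", "m2")
#' @export
neighbors <- function(x, entity, side = c("left", "right")) {
  stopifnot(inherits(x, "association_set"))
  side <- match.arg(side)
  entity <- normalize_label(entity)
  other <- if (side == "left") "right" else "left"
  sort(unique(x$edges[[other]][x$edges[[side]] == entity]))
}

#' Adjacency (neighbor) list for one side of an association set
#'
#' @param x an `association_set`.
#' @param side `"left"` or `"right"`.
#' @return named list mapping each entity on `side` to the sorted character
#'   vector of its partners.
#' @export
neighbor_list <- function(x, side = c("left", "right")) {
  stopifnot(inherits(x, "association_set"))
  side <- match.arg(side)
  other <- if (side == "left") "right" else "left"
  sp <- split(x$edges[[other]], x$edges[[side]])
  lapply(sp, function(v) sort(unique(v)))
}
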