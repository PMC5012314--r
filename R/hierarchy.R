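# Nested hierarchical grouping of group identifiers.
#
# The hierarchy is a forest: each class has at most one parent, so the
# classes form properly nested sets over the group identifiers (the leaf
# level). A sister subtree is summarised by the smallest class that covers
# every group in it; if no class does, no result is produced and the token
# "UNCLASSIFIED" is reported so batch totals stay auditable.

#' The token reported when no hierarchy class covers a group set
#' @export
UNCLASSIFIED <- "UNCLASSIFIED"

#' Parse a hierarchy configuration
#'
#' One `child<TAB>parent` pair per line; `#` starts a comment; blank lines
#' are ignored. Chains compose transitively (e.g. Animalia -> Opisthokonta,
#' Opisthokonta -> Eukaryota). Class names may not contain tabs or hyphens
#' (the hyphen is the leaf-label delimiter).
#'
#' @param lines Character vector of configuration lines.
#' @return An object of class `"sister_hierarchy"` wrapping the child ->
#'   parent map.
#' @examples
#' h <- parse_hierarchy(c("Animalia\tOpisthokonta",
#'                        "Fungi\tOpisthokonta",
#'                        "Opisthokonta\tEukaryota",
#'                        "Plantae\tEukaryota"))
#' classify_groups(c("Animalia", "Fungi"), h)$label
#' @export
parse_hierarchy <- function(lines) {
  parent <- character(0)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L) {
      stop(sprintf("malformed hierarchy line %d: '%s' (expected child<TAB>parent)",
                   i, trimws(lines[i])), call. = FALSE)
    }
    if (any(grepl("-", parts, fixed = TRUE))) {
      stop(sprintf("hierarchy line %d: class names may not contain '-'", i),
           call. = FALSE)
    }
    child <- parts[1L]; par <- parts[2L]
    if (child == par) {
      stop(sprintf("hierarchy line %d: class '%s' cannot be its own parent", i, child),
           call. = FALSE)
    }
    if (child %in% names(parent) && parent[[child]] != par) {
      stop(sprintf("class '%s' is listed with two parents ('%s' and '%s'): the hierarchy must be properly nested",
                   child, parent[[child]], par), call. = FALSE)
    }
    parent[child] <- par
  }
  # cycle check: walk up from every class; a chain longer than the map
  # revisits a class.
  for (cl in names(parent)) {
    seen <- character(0)
    x <- cl
    while (x %in% names(parent)) {
      if (x %in% seen) {
        stop(sprintf("hierarchy contains a cycle involving '%s'", x), call. = FALSE)
      }
      seen <- c(seen, x)
      x <- parent[[x]]
    }
  }
  structure(list(parent_of = parent), class = "sister_hierarchy")
}

#' Read a hierarchy configuration file
#'
#' @param path Path to a UTF-8 text file in the [parse_hierarchy()] format.
#' @return A `"sister_hierarchy"` object.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  parse_hierarchy(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' An empty hierarchy (only exact group identity classifies)
#' @return A `"sister_hierarchy"` with no classes.
#' @export
empty_hierarchy <- function() parse_hierarchy(character(0))

#' @export
print.sister_hierarchy <- function(x, ...) {
  p <- x$parent_of
  cat(sprintf("hierarchy with %d child->parent relation(s)\n", length(p)))
  if (length(p)) {
    for (i in seq_along(p)) cat(sprintf("  %s -> %s\n", names(p)[i], p[[i]]))
  }
  invisible(x)
}

#' Ancestor classes of a class, nearest first (excluding the class itself)
#'
#' @param hierarchy A `"sister_hierarchy"` (or `NULL` for none).
#' @param class A class or group name.
#' @return Character vector of ancestors, possibly empty.
#' @export
class_ancestors <- function(hierarchy, class) {
  if (is.null(hierarchy)) return(character(0))
  stopifnot(inherits(hierarchy, "sister_hierarchy"))
  p <- hierarchy$parent_of
  out <- character(0)
  x <- class
  while (x %in% names(p)) {
    x <- p[[x]]
    out <- c(out, x)
  }
  out
}

#' @keywords internal
#' @noRd
.is_ancestor_class <- function(hierarchy, a, b) {
  a %in% class_ancestors(hierarchy, b)
}

#' Top-level class a label rolls up to
#'
#' @inheritParams class_ancestors
#' @param class A class or group name.
#' @return The root of the class's chain (the class itself when it has no
#'   parent).
#' @export
top_class <- function(hierarchy, class) {
  anc <- class_ancestors(hierarchy, class)
  if (length(anc)) anc[length(anc)] else class
}

#' Smallest hierarchical class covering a set of group identifiers
#'
#' A single identifier classifies as itself (depth 0), hierarchy or not.
#' Several identifiers classify as the minimal class that is an
#' ancestor-or-self of each of them; when no such class exists the result is
#' [UNCLASSIFIED] and no label is produced.
#'
#' @param groups Non-empty character vector of group identifiers.
#' @param hierarchy A `"sister_hierarchy"` or `NULL`.
#' @return A list of class `"sister_classification"` with fields `label`
#'   (class name or `UNCLASSIFIED`) and `depth` (rank distance from the
#'   group level; `NA` when unclassified).
#' @export
classify_groups <- function(groups, hierarchy = NULL) {
  groups <- unique(as.character(groups))
  if (!length(groups)) stop("`groups` must be non-empty", call. = FALSE)
  mk <- function(label, depth) {
    structure(list(label = label, depth = depth), class = "sister_classification")
  }
  if (length(groups) == 1L) return(mk(groups, 0L))
  if (is.null(hierarchy)) return(mk(UNCLASSIFIED, NA_integer_))
  stopifnot(inherits(hierarchy, "sister_hierarchy"))
  chains <- lapply(groups, function(g) c(g, class_ancestors(hierarchy, g)))
  common <- Reduce(intersect, chains)   # keeps the order of chains[[1]]
  if (!length(common)) return(mk(UNCLASSIFIED, NA_integer_))
  lab <- common[1L]                     # nearest to the group level = smallest
  mk(lab, match(lab, chains[[1L]]) - 1L)
}

#' @export
print.sister_classification <- function(x, ...) {
  cat(sprintf("classification: %s (depth %s)\n", x$label,
              ifelse(is.na(x$depth), "NA", x$depth)))
  invisible(x)
}

#' Combine the two sister candidates when they fall in the same group
#'
#' Two alternative sisters are mutually exclusive rooting hypotheses; when
#' both carry the same classification label, or one label is an ancestor of
#' the other, they are reported as a single combined result: its label is
#' the more general of the two, its leaf set the full complement of the
#' target, and its support the annotation on the split separating the target
#' from everything else (the label on the target subtree's root node when
#' numeric, else the label on the other side of that same unrooted edge,
#' else missing). Candidates labelled [UNCLASSIFIED] are never combined.
#'
#' @param tree The tree the candidates came from.
#' @param target The `"target_clade"` of that tree.
#' @param c1,c2 `"sister_candidate"` objects carrying a `label` field (see
#'   [classify_groups()]).
#' @param hierarchy A `"sister_hierarchy"` or `NULL`.
#' @return A list of one combined candidate, or of the two originals
#'   unchanged.
#' @export
combine_candidates <- function(tree, target, c1, c2, hierarchy = NULL) {
  stopifnot(inherits(c1, "sister_candidate"), inherits(c2, "sister_candidate"))
  l1 <- c1$label; l2 <- c2$label
  if (is.null(l1) || is.null(l2)) {
    stop("candidates must carry a classification `label` before combining",
         call. = FALSE)
  }
  lab <- NULL
  if (!identical(l1, UNCLASSIFIED) && !identical(l2, UNCLASSIFIED)) {
    if (identical(l1, l2)) lab <- l1
    else if (!is.null(hierarchy)) {
      if (.is_ancestor_class(hierarchy, l1, l2)) lab <- l1
      else if (.is_ancestor_class(hierarchy, l2, l1)) lab <- l2
    }
  }
  if (is.null(lab)) return(list(c1, c2))
  tree <- ape::reorder.phylo(tree, "cladewise")
  comb <- structure(list(leaves = sort(union(c1$leaves, c2$leaves)),
                         groups = unique(c(c1$groups, c2$groups)),
                         support = .split_support(tree, target$leaves),
                         ordinal = "S1+S2",
                         label = lab),
                    class = "sister_candidate")
  list(comb)
}
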