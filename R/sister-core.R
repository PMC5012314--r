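# Locating the target clade and extracting its possible sisters.
#
# The root of a gene tree is treated as arbitrary: a set of leaves is a
# clade when it forms one side of a bipartition of the unrooted topology.
# Rerooting is only ever "virtual" -- the input tree object is never
# mutated; all reasoning happens on the bipartition set of the given tree.

#' Describe which leaves to search for
#'
#' @param pattern The search string. In `"prefix"` mode a leaf matches when
#'   its label starts with `pattern`; in `"regex"` mode when it matches the
#'   regular expression.
#' @param mode `"prefix"` (default) or `"regex"`.
#' @return An object of class `"target_spec"`.
#' @examples
#' target_spec("Bacteroidetes-")
#' target_spec(".*-Salinibacter_.*", mode = "regex")
#' @export
target_spec <- function(pattern, mode = c("prefix", "regex")) {
  mode <- match.arg(mode)
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) || !nzchar(pattern)) {
    stop("`pattern` must be a single non-empty string", call. = FALSE)
  }
  if (mode == "regex") {
    ok <- tryCatch({grepl(pattern, "x"); TRUE}, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop(sprintf("invalid regular expression: '%s'", pattern), call. = FALSE)
  }
  structure(list(pattern = pattern, mode = mode), class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("target spec: %s match on '%s'\n", x$mode, x$pattern))
  invisible(x)
}

#' @keywords internal
#' @noRd
.as_target_spec <- function(spec) {
  if (inherits(spec, "target_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1L) return(target_spec(spec))
  stop("`spec` must be a target_spec or a single prefix string", call. = FALSE)
}

#' Leaves matching a target specification
#'
#' @param tree A `phylo` object.
#' @param spec A [target_spec()] (a bare string is taken as a prefix).
#' @return Character vector of matching leaf labels (possibly empty).
#' @export
match_target_leaves <- function(tree, spec) {
  stopifnot(inherits(tree, "phylo"))
  spec <- .as_target_spec(spec)
  labs <- tree$tip.label
  hit <- if (spec$mode == "prefix") startsWith(labs, spec$pattern)
         else grepl(spec$pattern, labs)
  labs[hit]
}

#' Locate the target clade, allowing virtual rerooting
#'
#' Succeeds when `targets` is a clade of the given rooting, a single leaf,
#' or one side of a bipartition of the unrooted topology (i.e. some rerooting
#' would make it a clade). The certificate is the tree node `v` whose
#' subtree's leaf set equals either `targets` (cases `"root_child"` /
#' `"internal"`) or its complement (case `"whole_minus_rest"`, the virtual
#' rerooting case). The input tree is never modified.
#'
#' @param tree A `phylo` object.
#' @param targets Non-empty character vector of leaf labels, a proper subset
#'   of the tree's leaves.
#' @return An object of class `"target_clade"` (fields `leaves`, `node`,
#'   `complement`, `case`, `n_leaves`), or `NULL` when the targets are not
#'   monophyletic under any rooting.
#' @export
find_target_clade <- function(tree, targets) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  labs <- tree$tip.label
  n <- length(labs)
  targets <- unique(as.character(targets))
  if (!length(targets)) {
    stop("target clade cannot be found: no target leaves given", call. = FALSE)
  }
  unknown <- setdiff(targets, labs)
  if (length(unknown)) {
    stop(sprintf("target leaves not in tree: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  k <- length(targets)
  if (k == n) {
    stop("every leaf is a target: the sister set is empty", call. = FALSE)
  }

  below <- .tips_below(tree)
  root <- .root_node(tree)
  is_t <- labs %in% targets
  nt <- lengths(below)
  ntg <- vapply(below, function(ix) sum(is_t[ix]), integer(1))
  nodes <- setdiff(seq_len(n + tree$Nnode), root)

  res <- function(v, complement, case) {
    structure(list(leaves = sort(targets), node = v, complement = complement,
                   case = case, n_leaves = n),
              class = "target_clade")
  }

  direct <- nodes[nt[nodes] == k & ntg[nodes] == k]
  if (length(direct)) {
    v <- direct[1L]
    tag <- if (.parent_of(tree, v) == root) "root_child" else "internal"
    return(res(v, FALSE, tag))
  }
  comp <- nodes[nt[nodes] == n - k & ntg[nodes] == 0L]
  if (length(comp)) {
    return(res(comp[1L], TRUE, "whole_minus_rest"))
  }
  NULL
}

#' @export
print.target_clade <- function(x, ...) {
  cat(sprintf("target clade: %d leaf/leaves, case %s\n  {%s}\n",
              length(x$leaves), x$case, paste(x$leaves, collapse = ",")))
  invisible(x)
}

#' Extract the possible sister subtrees of a located target clade
#'
#' Because the root is arbitrary, a target clade has up to two alternative
#' sisters, one per possible rooting of the edge leading to it. When the
#' target is a child of a degree-2 root, the sisters are the two subtrees of
#' the other root child; otherwise the sibling subtree is the first sister
#' and the rest of the phylogeny (the tree as if rerooted at the target's
#' parent) is the second. A trifurcating root -- the standard unrooted
#' encoding -- is handled identically; at a true polytomy every adjacent
#' non-target subtree is returned as a candidate.
#'
#' @param tree The same `phylo` object given to [find_target_clade()].
#' @param target A `"target_clade"` object.
#' @return A list of `"sister_candidate"` objects (fields `leaves`, `groups`,
#'   `support`, `ordinal`). Supports are `NA` here; fill them with
#'   [association_support()].
#' @export
extract_sisters <- function(tree, target) {
  stopifnot(inherits(tree, "phylo"), inherits(target, "target_clade"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  labs <- tree$tip.label
  n <- length(labs)
  if (length(target$leaves) == n) {
    stop("every leaf is a target: the sister set is empty", call. = FALSE)
  }
  below <- .tips_below(tree)
  root <- .root_node(tree)
  v <- target$node
  clade_of <- function(node) sort(labs[below[[node]]])

  if (target$complement) {
    # virtual rerooting case: the non-target side IS the subtree under v;
    # the sisters are v's child subtrees (v itself when v is a leaf).
    sets <- if (v <= n) list(labs[v])
            else lapply(.children(tree, v), clade_of)
  } else {
    p <- .parent_of(tree, v)
    root_kids <- .children(tree, root)
    if (p == root && length(root_kids) == 2L) {
      u <- setdiff(root_kids, v)
      sets <- if (u <= n) list(labs[u])
              else lapply(.children(tree, u), clade_of)
    } else if (p == root) {
      # trifurcating root = unrooted encoding (two candidates);
      # larger root polytomies yield one candidate per adjacent subtree.
      sets <- lapply(setdiff(root_kids, v), clade_of)
    } else {
      sets <- lapply(setdiff(.children(tree, p), v), clade_of)
      rest <- sort(setdiff(labs, labs[below[[p]]]))
      sets <- c(sets, list(rest))
    }
  }
  sets <- Filter(length, sets)
  lapply(seq_along(sets), function(i) {
    lv <- sets[[i]]
    structure(list(leaves = lv,
                   groups = unname(vapply(lv, function(x) parse_leaf_label(x)$group_id, "")),
                   support = NA_real_,
                   ordinal = paste0("S", i)),
              class = "sister_candidate")
  })
}

#' @export
print.sister_candidate <- function(x, ...) {
  lab <- if (!is.null(x$label)) paste0(" label=", x$label) else ""
  cat(sprintf("sister %s: %d leaf/leaves%s support=%s\n  {%s}\n",
              x$ordinal, length(x$leaves), lab,
              ifelse(is.na(x$support), "NA", format(x$support)),
              paste(x$leaves, collapse = ",")))
  invisible(x)
}

# Support annotated on the unrooted edge separating `side` from the rest.
# Preference order: the node whose subtree equals `side`, then the node
# whose subtree equals the complement (the two can only coexist as the two
# children of a degree-2 root, where they annotate the same unrooted edge;
# a conflict between two numeric labels there is reported).
#' @keywords internal
#' @noRd
.split_support <- function(tree, side) {
  labs <- tree$tip.label
  n <- length(labs)
  k <- length(side)
  if (n - k < 1L || k < 1L) return(NA_real_)
  below <- .tips_below(tree)
  root <- .root_node(tree)
  in_a <- labs %in% side
  nt <- lengths(below)
  na_b <- vapply(below, function(ix) sum(in_a[ix]), integer(1))
  nodes <- setdiff(seq_len(n + tree$Nnode), root)
  v_a <- nodes[nt[nodes] == k & na_b[nodes] == k]
  v_b <- nodes[nt[nodes] == n - k & na_b[nodes] == 0L]
  l_a <- if (length(v_a)) .as_support(.node_annotation(tree, v_a[1L])) else NA_real_
  l_b <- if (length(v_b)) .as_support(.node_annotation(tree, v_b[1L])) else NA_real_
  if (!is.na(l_a) && !is.na(l_b) && l_a != l_b) {
    warning(sprintf("conflicting support labels (%s vs %s) on the two sides of one unrooted edge; using the side uniting target and sister",
                    format(l_a), format(l_b)), call. = FALSE)
  }
  if (!is.na(l_a)) l_a else l_b
}

#' Branch support for a target-sister association
#'
#' The support for pairing `target` with `sister` is the annotation on the
#' unrooted edge separating (target union sister) from all remaining leaves:
#' when that union is a clade of the given rooting, the label on the clade's
#' root node; otherwise the label on the root of the complement subtree.
#' The value is missing (`NA`) when the separating split is trivial (the
#' remainder is a single leaf or empty, e.g. after a polytomy junction or
#' for a single-sister tree) or when the relevant node carries no numeric
#' label.
#'
#' @param tree The tree given to [find_target_clade()].
#' @param target A `"target_clade"`.
#' @param sister A `"sister_candidate"` from [extract_sisters()].
#' @return A single numeric support, or `NA_real_`.
#' @export
association_support <- function(tree, target, sister) {
  stopifnot(inherits(tree, "phylo"), inherits(target, "target_clade"),
            inherits(sister, "sister_candidate"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  a <- union(target$leaves, sister$leaves)
  if (length(tree$tip.label) - length(a) < 2L) return(NA_real_)
  .split_support(tree, a)
}
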