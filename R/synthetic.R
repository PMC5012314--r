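# Synthetic group-labelled gene trees with planted sister scenarios.
#
# Random binary topologies are grown by iterative random leaf attachment;
# leaf groups are drawn uniformly from an alphabet; every internal node
# except the root carries a support drawn uniformly on [0,1] and rounded to
# three decimals (PhyML-style local supports, exact under a
# serialise->parse round trip). One integer seed drives all randomness;
# the draw order is fixed (topology attachments, then groups, then
# supports, then -- for planted scenarios -- the rerooting edge), so a
# given seed always regenerates the identical newick text.

# Random binary topology on n leaves by iterative random leaf attachment.
# Returns parent/children arrays; leaves are 1..n, internals n+1..2n-1,
# root is n+1. Draw order: one uniform edge choice per added leaf (n-2
# draws).
#' @keywords internal
#' @noRd
.random_attachment_topology <- function(n) {
  stopifnot(n >= 2L)
  maxn <- 2L * n
  parent <- integer(maxn)
  children <- vector("list", maxn)
  root <- n + 1L
  children[[root]] <- c(1L, 2L)
  parent[1L] <- root; parent[2L] <- root
  nxt <- n + 2L
  attachable <- c(1L, 2L)   # nodes with an edge above them
  for (leaf in seq.int(3L, length.out = max(0L, n - 2L))) {
    x <- attachable[sample.int(length(attachable), 1L)]
    m <- nxt; nxt <- nxt + 1L
    p <- parent[x]
    children[[p]][children[[p]] == x] <- m
    parent[m] <- p
    parent[x] <- m
    parent[leaf] <- m
    children[[m]] <- c(x, leaf)
    attachable <- c(attachable, m, leaf)
  }
  list(parent = parent, children = children, root = root, n = n)
}

# Newick text for a topology. `labels` indexed by leaf id; `supports` is a
# function(node_id) -> label text for non-root internal nodes ("" to omit).
#' @keywords internal
#' @noRd
.topology_newick <- function(topo, labels, supports, label_root = "") {
  n <- topo$n
  rec <- function(v) {
    if (v <= n) return(labels[v])
    inner <- paste(vapply(topo$children[[v]], rec, ""), collapse = ",")
    lab <- if (v == topo$root) label_root else supports(v)
    paste0("(", inner, ")", lab)
  }
  rec(topo$root)
}

# Random labelled subtree as newick (no trailing ';'); all internal nodes,
# including the subtree's own root, carry 3-decimal supports. Draw order:
# attachments, then groups (when `groups` has several), then supports in
# internal-node-id order.
#' @keywords internal
#' @noRd
.random_subtree_newick <- function(k, groups, stem) {
  grp <- if (length(groups) == 1L) rep(groups, k) else sample(groups, k, replace = TRUE)
  labs <- paste0(grp, "-", stem, seq_len(k))
  if (k == 1L) return(labs)
  topo <- .random_attachment_topology(k)
  n_int <- k - 1L
  sup <- round(stats::runif(n_int), 3)
  names(sup) <- as.character(seq.int(k + 1L, k + n_int))
  .topology_newick(topo, labs, function(v) .fmt_support(sup[[as.character(v)]]),
                   label_root = .fmt_support(sup[[as.character(k + 1L)]]))
}

#' Generate a random group-labelled gene tree
#'
#' Binary topology by iterative random leaf attachment; one group drawn
#' uniformly per leaf; a support on every internal node except the root
#' (the two root children share one value, since both annotate the same
#' unrooted edge). Deterministic per seed: the same call yields
#' byte-identical newick text.
#'
#' @param n_leaves Number of leaves (at least 2).
#' @param groups Character vector of group identifiers to draw from.
#' @param seed Integer seed.
#' @return A `phylo` object with tip labels `"<group>-leaf<i>"`.
#' @export
generate_labeled_tree <- function(n_leaves, groups, seed) {
  if (n_leaves < 2L) stop("`n_leaves` must be at least 2", call. = FALSE)
  if (!length(groups)) stop("`groups` must be non-empty", call. = FALSE)
  .with_seed(seed, {
    topo <- .random_attachment_topology(n_leaves)
    grp <- sample(groups, n_leaves, replace = TRUE)
    labs <- paste0(grp, "-leaf", seq_len(n_leaves))
    ids <- setdiff(seq.int(n_leaves + 1L, 2L * n_leaves - 1L), topo$root)
    sup <- round(stats::runif(length(ids)), 3)
    names(sup) <- as.character(ids)
    # both children of the degree-2 root annotate the same unrooted edge:
    # give them one value (PhyML-style duplication) so the support
    # semantics of the unrooted view are consistent.
    rk <- topo$children[[topo$root]]
    rk <- rk[rk > n_leaves]
    if (length(rk) == 2L) sup[as.character(rk[2L])] <- sup[[as.character(rk[1L])]]
    txt <- paste0(.topology_newick(topo, labs,
                                   function(v) .fmt_support(sup[[as.character(v)]])),
                  ";")
    parse_newick(txt)
  })
}

#' Reroot a tree on the edge subtending a given leaf set
#'
#' `tips` must be one side of a bipartition of the unrooted topology.
#' Support labels keep describing the same unrooted edges
#' (`ape::root(..., edgelabel = TRUE)` semantics). Rerooting on the current
#' root edge returns an equivalent tree.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of leaf labels forming one split side.
#' @return The rerooted tree.
#' @export
reroot_on_split <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (!length(tips) || !all(tips %in% labs) || length(tips) >= length(labs)) {
    stop("`tips` must be a proper non-empty subset of the leaves", call. = FALSE)
  }
  # rooting on the current root edge is a no-op (ape::root mishandles it)
  tree <- ape::reorder.phylo(tree, "cladewise")
  root <- .root_node(tree)
  kids <- .children(tree, root)
  if (length(kids) == 2L) {
    below <- .tips_below(tree)
    for (k in kids) {
      if (setequal(labs[below[[k]]], tips)) return(tree)
    }
    # both root children annotate the same unrooted edge; when only one
    # carries the label, duplicate it so it survives the label shifting
    # ape performs when the old root vanishes.
    n <- length(labs)
    if (all(kids > n) && !is.null(tree$node.label)) {
      l1 <- .node_annotation(tree, kids[1L])
      l2 <- .node_annotation(tree, kids[2L])
      if (is.na(l2) && !is.na(l1)) tree$node.label[kids[2L] - n] <- l1
      if (is.na(l1) && !is.na(l2)) tree$node.label[kids[1L] - n] <- l2
    }
  }
  out <- tryCatch(
    ape::root(tree, outgroup = tips, resolve.root = TRUE, edgelabel = TRUE),
    error = function(e) {
      stop(sprintf("cannot reroot on {%s}: %s", paste(tips, collapse = ","),
                   conditionMessage(e)), call. = FALSE)
    })
  ape::reorder.phylo(out, "cladewise")
}

# All candidate rooting sides of the unrooted topology (one side per
# unrooted edge, pendant edges included), in a deterministic order.
#' @keywords internal
#' @noRd
.rooting_sides <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  below <- .tips_below(tree)
  root <- .root_node(tree)
  first_leaf <- sort(labs)[1L]
  sides <- list(); keys <- character(0)
  for (v in setdiff(seq_len(n + tree$Nnode), root)) {
    side <- sort(labs[below[[v]]])
    canon <- if (first_leaf %in% side) side else sort(setdiff(labs, side))
    key <- paste(canon, collapse = "\r")
    if (key %in% keys) next
    keys <- c(keys, key)
    sides[[length(sides) + 1L]] <- side
  }
  sides
}

#' Generate a tree with a planted monophyletic target and known sister
#'
#' Builds `((T,S)support, R)`: a monophyletic target clade `T` (uniformly
#' `target_group`), an adjacent sister clade `S` (uniformly
#' `sister_group`), the certifying edge carrying `sister_support`, and a
#' random remainder `R` over `background_groups`. The tree is then rerooted
#' on a uniformly chosen edge of the unrooted topology, so recovering the
#' plant requires rooting-invariant detection. The planted support sits on
#' a non-trivial split (hence is recoverable) whenever the remainder has at
#' least two leaves.
#'
#' @param n_leaves Total leaves; at least `target_size + 1`.
#' @param target_group,target_size Group identifier and leaf count of the
#'   planted target clade.
#' @param sister_group Group identifier of the planted sister clade.
#' @param sister_support Support on the target-sister edge; drawn as a
#'   3-decimal uniform value when `NULL`.
#' @param sister_size Leaf count of the sister clade; when `NULL`, drawn
#'   uniformly so that the remainder keeps at least 2 leaves (at least 1
#'   when sizes force it).
#' @param background_groups Alphabet for the remainder (the target and
#'   sister groups are excluded from it).
#' @param seed Integer seed.
#' @return A list with `tree` (a `phylo`) and `truth` (class
#'   `"planted_truth"`: seed, n_leaves, target_group, target_size,
#'   planted_sister_group, planted_sister_size, planted_support --
#'   `NA` when the certifying split is trivial and the support therefore
#'   unrecoverable).
#' @export
plant_sister_scenario <- function(n_leaves = 24L,
                                  target_group = "Bacteroidetes",
                                  target_size = 2L,
                                  sister_group = "Euryarchaeota",
                                  sister_support = NULL,
                                  sister_size = NULL,
                                  background_groups = c("Chlorobi",
                                                        "Gammaproteobacteria",
                                                        "Actinobacteria",
                                                        "Firmicutes",
                                                        "Crenarchaeota"),
                                  seed) {
  if (target_size < 1L) stop("`target_size` must be at least 1", call. = FALSE)
  if (n_leaves < target_size + 1L) {
    stop("`n_leaves` must leave room for at least one non-target leaf", call. = FALSE)
  }
  if (identical(target_group, sister_group)) {
    stop("target and sister groups must differ", call. = FALSE)
  }
  .with_seed(seed, {
    if (is.null(sister_support)) sister_support <- round(stats::runif(1L), 3)
    max_s <- n_leaves - target_size - 1L   # leave >=1 remainder when possible
    if (n_leaves == target_size + 1L) {
      sister_size <- 1L
    } else if (is.null(sister_size)) {
      pick_max <- if (max_s >= 3L) max_s - 2L else max_s  # prefer remainder >= 2
      sister_size <- sample.int(max(pick_max, 1L), 1L)
    }
    if (sister_size < 1L || target_size + sister_size > n_leaves) {
      stop("impossible target/sister sizes for `n_leaves`", call. = FALSE)
    }
    rest_n <- n_leaves - target_size - sister_size
    bg <- setdiff(background_groups, c(target_group, sister_group))
    if (rest_n > 0L && !length(bg)) {
      stop("background group alphabet is empty after excluding the target and sister groups",
           call. = FALSE)
    }

    tsub <- .random_subtree_newick(target_size, target_group, "t")
    ssub <- .random_subtree_newick(sister_size, sister_group, "s")
    txt <- if (rest_n == 0L) {
      paste0("(", tsub, ",", ssub, ");")
    } else {
      core <- paste0("(", tsub, ",", ssub, ")", .fmt_support(sister_support))
      rsub <- .random_subtree_newick(rest_n, bg, "r")
      # at a degree-2 root both child labels annotate the same unrooted
      # edge; duplicate the certifying support on the remainder's top node
      # (the PhyML convention), so any rerooting retains it.
      rsub <- sub(")[0-9.]+$", paste0(")", .fmt_support(sister_support)), rsub)
      paste0("(", core, ",", rsub, ");")
    }
    tr <- parse_newick(txt)
    sides <- .rooting_sides(tr)
    tr2 <- reroot_on_split(tr, sides[[sample.int(length(sides), 1L)]])
    truth <- structure(list(seed = seed, n_leaves = n_leaves,
                            target_group = target_group,
                            target_size = target_size,
                            planted_sister_group = sister_group,
                            planted_sister_size = sister_size,
                            planted_support = if (rest_n >= 2L) sister_support else NA_real_),
                       class = "planted_truth")
    list(tree = tr2, truth = truth)
  })
}

#' Scramble the planted target leaves across the tree
#'
#' Negative control: swaps each target-group leaf label with a uniformly
#' chosen non-target leaf label, usually destroying every split that
#' certifies target monophyly (whether one survives must be checked against
#' the bipartition set).
#'
#' @param tree A `phylo` object.
#' @param target_group Group identifier of the leaves to displace.
#' @param seed Integer seed.
#' @return The tree with permuted leaf labels (topology unchanged).
#' @export
scramble_target_leaves <- function(tree, target_group, seed) {
  stopifnot(inherits(tree, "phylo"))
  .with_seed(seed, {
    labs <- tree$tip.label
    grp <- vapply(labs, function(x) parse_leaf_label(x)$group_id, "")
    tgt <- which(grp == target_group)
    oth <- which(grp != target_group)
    for (i in tgt) {
      j <- oth[sample.int(length(oth), 1L)]
      tmp <- labs[i]; labs[i] <- labs[j]; labs[j] <- tmp
      grp <- vapply(labs, function(x) parse_leaf_label(x)$group_id, "")
      oth <- which(grp != target_group)
    }
    tree$tip.label <- labs
    tree
  })
}

#' Write a set of planted-scenario fixtures to disk
#'
#' Emits `tree_0001.nwk`, ... plus `truth.tsv` (tree_id, target_group,
#' target_size, planted_sister_group, planted_sister_size, planted_support,
#' n_leaves, scrambled). Per-tree seeds are drawn from `seed`, so the whole
#' set is deterministic.
#'
#' @param dir Output directory (created if needed).
#' @param n_trees Number of trees.
#' @param seed Integer master seed.
#' @param n_leaves_range Inclusive range the per-tree leaf count is drawn
#'   from.
#' @param scramble_fraction Fraction of trees whose target leaves are
#'   scrambled after planting (negative controls).
#' @param ... Further arguments passed to [plant_sister_scenario()].
#' @return Invisibly, the truth table data frame.
#' @export
write_fixture_set <- function(dir, n_trees, seed, n_leaves_range = c(12L, 32L),
                              scramble_fraction = 0, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- .with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max, 2L * n_trees),
    sizes = sample(seq.int(n_leaves_range[1L], n_leaves_range[2L]),
                   n_trees, replace = TRUE),
    scramble = stats::runif(n_trees) < scramble_fraction
  ))
  rows <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    sc <- plant_sister_scenario(n_leaves = draws$sizes[i],
                                seed = draws$seeds[i], ...)
    tree <- sc$tree
    if (draws$scramble[i]) {
      tree <- scramble_target_leaves(tree, sc$truth$target_group,
                                     seed = draws$seeds[n_trees + i])
    }
    id <- sprintf("tree_%04d", i)
    write_newick(tree, file.path(dir, paste0(id, ".nwk")))
    rows[[i]] <- data.frame(tree_id = id,
                            target_group = sc$truth$target_group,
                            target_size = sc$truth$target_size,
                            planted_sister_group = sc$truth$planted_sister_group,
                            planted_sister_size = sc$truth$planted_sister_size,
                            planted_support = sc$truth$planted_support,
                            n_leaves = sc$truth$n_leaves,
                            scrambled = draws$scramble[i],
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}
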