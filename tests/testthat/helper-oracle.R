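# Independent brute-force oracle: bipartitions by undirected flood fill,
# one edge at a time. Deliberately a different algorithm from the package's
# postorder accumulation so the two can check each other.

# all split sides (trivial ones included), as a list of sorted label vectors;
# for each edge the side containing the child endpoint
brute_all_sides <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  e <- tree$edge
  m <- nrow(e)
  nn <- n + tree$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(m)) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  sides <- vector("list", m)
  for (k in seq_len(m)) {
    a <- e[k, 1]; b <- e[k, 2]
    seen <- rep(FALSE, nn)
    seen[b] <- TRUE
    queue <- b
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!seen[w] && !(v == b && w == a) && !(v == a && w == b)) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    sides[[k]] <- sort(labs[which(seen[seq_len(n)])])
  }
  sides
}

# non-trivial unrooted splits, deduplicated, canonicalised to the side with
# the alphabetically first leaf
brute_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  sides <- brute_all_sides(tree)
  out <- character(0)
  for (s in sides) {
    if (length(s) < 2 || n - length(s) < 2) next
    canon <- if (labs[1] %in% s) s else setdiff(labs, s)
    out <- c(out, paste(sort(canon), collapse = "\r"))
  }
  unique(out)
}

split_keys <- function(splits) {
  vapply(splits, function(s) paste(s$side_a, collapse = "\r"), "")
}

# monophyly in the unrooted sense: some edge separates exactly `targets`
brute_monophyletic <- function(tree, targets) {
  labs <- tree$tip.label
  targets <- sort(targets)
  for (s in brute_all_sides(tree)) {
    if (identical(s, targets) || identical(sort(setdiff(labs, s)), targets)) {
      return(TRUE)
    }
  }
  FALSE
}

# random rooted tree with group-prefixed labels, via ape (independent of the
# package's own generator)
random_grouped_tree <- function(n, groups = LETTERS[1:4]) {
  tr <- ape::rtree(n, br = NULL)
  tr$tip.label <- paste0(sample(groups, n, replace = TRUE), "-t", seq_len(n))
  tr$node.label <- c("", sprintf("%.3f", stats::runif(tr$Nnode - 1L)))
  tr
}

candidate_key <- function(tree, target, cands) {
  sort(vapply(cands, function(s) {
    paste(paste(s$leaves, collapse = ","),
          format(association_support(tree, target, s)), sep = "|")
  }, ""))
}
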