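# Internal helpers shared across modules. All operate on ape "phylo" objects;
# node numbering convention: tips 1..n, internal nodes n+1..n+Nnode.

#' @keywords internal
#' @noRd
.root_node <- function(tree) {
  e <- tree$edge
  setdiff(unique(e[, 1L]), e[, 2L])[1L]
}

# Tip indices below every node (tips map to themselves). Postorder edge
# traversal guarantees children are accumulated before their parent.
#' @keywords internal
#' @noRd
.tips_below <- function(tree) {
  n <- length(tree$tip.label)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  eg <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eg))) {
    p <- eg[k, 1L]
    below[[p]] <- c(below[[p]], below[[eg[k, 2L]]])
  }
  below
}

# Children of `node` in newick (cladewise) order; tree must already be in
# cladewise order.
#' @keywords internal
#' @noRd
.children <- function(tree, node) {
  e <- tree$edge
  e[e[, 1L] == node, 2L]
}

#' @keywords internal
#' @noRd
.parent_of <- function(tree, node) {
  e <- tree$edge
  hit <- match(node, e[, 2L])
  if (is.na(hit)) NA_integer_ else e[hit, 1L]
}

# Raw internal-node annotation, NA for tips / absent / empty labels.
#' @keywords internal
#' @noRd
.node_annotation <- function(tree, node) {
  n <- length(tree$tip.label)
  if (is.na(node) || node <= n) return(NA_character_)
  lb <- tree$node.label
  if (is.null(lb)) return(NA_character_)
  v <- lb[node - n]
  if (is.na(v) || !nzchar(v)) NA_character_ else v
}

# Numeric reading of an annotation; non-numeric labels are "missing support".
#' @keywords internal
#' @noRd
.as_support <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = .GlobalEnv)
      else suppressWarnings(rm(list = ".Random.seed", envir = .GlobalEnv))
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Support formatting that survives a serialize->parse round trip for the
# 3-decimal supports the generator draws, and stays compact for user values.
#' @keywords internal
#' @noRd
.fmt_support <- function(x) {
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}
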