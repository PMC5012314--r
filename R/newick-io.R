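# newick input/output with the group-labelled-leaf convention.
#
# Trees are plain ape "phylo" objects: tip.label holds the leaf names,
# node.label the internal-node annotations (branch supports when numeric,
# conventionally attached to the edge above the node), edge.length the
# optional branch lengths. Parsing and serialisation are delegated to ape;
# this layer adds quoted-label handling, position-aware syntax errors,
# first-tree-only semantics for multi-tree files, and label validation.

# Replace single-quoted newick labels by safe placeholder tokens so ape's
# reader (which does not understand quoting) sees plain labels. '' inside a
# quoted label is an escaped quote.
#' @keywords internal
#' @noRd
.shield_quotes <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  out <- character(0)
  map <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "'") {
      j <- i + 1L
      buf <- character(0)
      repeat {
        if (j > n) stop(sprintf("malformed newick: unterminated quote opened at character %d", i),
                        call. = FALSE)
        if (chars[j] == "'") {
          if (j < n && chars[j + 1L] == "'") {   # escaped quote
            buf <- c(buf, "'")
            j <- j + 2L
          } else break
        } else {
          buf <- c(buf, chars[j])
          j <- j + 1L
        }
      }
      tok <- sprintf("xQUOTEDx%dx", length(map) + 1L)
      map[tok] <- paste(buf, collapse = "")
      out <- c(out, tok)
      i <- j + 1L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  list(text = paste(out, collapse = ""), map = map)
}

#' @keywords internal
#' @noRd
.unshield <- function(labels, map) {
  if (!length(map) || is.null(labels)) return(labels)
  for (tok in names(map)) labels[labels == tok] <- map[[tok]]
  labels
}

#' @keywords internal
#' @noRd
.validate_tree <- function(tree) {
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("tree has empty leaf labels", call. = FALSE)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup)) {
    stop(sprintf("duplicated leaf label(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch length(s)", call. = FALSE)
  }
  invisible(tree)
}

#' Parse a newick string into a phylogenetic tree
#'
#' Reads a single newick tree. Internal node labels are kept verbatim in
#' `node.label`; when numeric they are interpreted downstream as branch
#' supports for the edge above the node (the PhyML/RAxML convention).
#' Single-quoted labels and multifurcations are accepted. If the string
#' contains more than one `;`-terminated tree, only the first is read and a
#' warning is raised.
#'
#' @param text A length-one character vector holding a newick description.
#' @return An [ape::read.tree()]-style `phylo` object.
#' @seealso [read_newick()] for reading from a file, [write_newick()].
#' @examples
#' tr <- parse_newick("((A-x,A-y)0.95,(B-z,C-w)0.80);")
#' tr$node.label
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single character string", call. = FALSE)
  }
  raw <- trimws(text)
  if (!nzchar(raw)) stop("empty newick input", call. = FALSE)

  sh <- .shield_quotes(raw)
  s <- sh$text
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed newick: unmatched ')' at character %d", i),
             call. = FALSE)
      }
    }
  }
  semis <- which(chars == ";")
  if (!length(semis)) {
    if (depth > 0L) {
      stop(sprintf("malformed newick: %d unclosed '(' at end of input", depth),
           call. = FALSE)
    }
    stop("malformed newick: missing terminating ';'", call. = FALSE)
  }
  if (depth > 0L && semis[1L] == length(chars)) {
    stop(sprintf("malformed newick: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  }
  first <- substr(s, 1L, semis[1L])
  if (nzchar(trimws(substr(s, semis[1L] + 1L, nchar(s))))) {
    warning("input contains more than one tree; only the first was read",
            call. = FALSE)
  }
  opar <- sum(strsplit(first, "", fixed = TRUE)[[1L]] == "(")
  cpar <- sum(strsplit(first, "", fixed = TRUE)[[1L]] == ")")
  if (opar != cpar) {
    stop(sprintf("malformed newick: unbalanced parentheses before ';' at character %d",
                 semis[1L]), call. = FALSE)
  }

  tr <- tryCatch(suppressWarnings(ape::read.tree(text = first)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed newick: could not parse tree", call. = FALSE)
  }
  tr$tip.label <- .unshield(tr$tip.label, sh$map)
  tr$node.label <- .unshield(tr$node.label, sh$map)
  .validate_tree(tr)
  ape::reorder.phylo(tr, "cladewise")
}

#' Read a newick tree file
#'
#' @param path Path to a file holding one newick tree. Files holding several
#'   trees yield the first with a warning.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parse_newick(txt)
}

#' Serialise a tree to newick
#'
#' Writes topology, leaf labels, internal-node annotations and branch lengths
#' such that the output re-parses to an identical tree. Labels containing
#' newick metacharacters are single-quoted.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the newick string is also written
#'   there (with a trailing newline).
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tr <- tree
  needs_quote <- function(x) grepl("[][ \t(),:;']", x)
  quote_lab <- function(x) paste0("'", gsub("'", "''", x, fixed = TRUE), "'")

  map <- character(0)
  shield <- function(labs) {
    if (is.null(labs)) return(labs)
    bad <- which(!is.na(labs) & needs_quote(labs))
    for (i in bad) {
      tok <- sprintf("xQOUTx%dx", length(map) + 1L)
      map[tok] <<- quote_lab(labs[i])
      labs[i] <- tok
    }
    labs
  }
  tr$tip.label <- shield(tr$tip.label)
  tr$node.label <- shield(tr$node.label)

  s <- ape::write.tree(tr)
  s <- gsub(":NaN", "", s, fixed = TRUE)   # edges with no length stay lengthless
  for (tok in names(map)) s <- sub(tok, map[[tok]], s, fixed = TRUE)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Split a leaf label into group identifier and remainder
#'
#' Leaf names follow the convention `"<group>-<rest>"`: everything before the
#' FIRST hyphen is the group identifier (so the identifier itself is
#' hyphen-free), everything after it belongs to the remainder and may contain
#' further hyphens.
#'
#' @param label A single leaf label.
#' @return A list with elements `group_id` and `remainder`.
#' @examples
#' parse_leaf_label("Bacteroidetes-Salinibacter_ruber_Phy001XKJS")$group_id
#' @export
parse_leaf_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(label)) {
    stop("`label` must be a single non-empty string", call. = FALSE)
  }
  pos <- regexpr("-", label, fixed = TRUE)
  if (pos < 1L || pos == 1L) {
    stop(sprintf("leaf label '%s' violates the naming convention: expected '<group>-<name>' with a non-empty group identifier",
                 label), call. = FALSE)
  }
  list(group_id = substr(label, 1L, pos - 1L),
       remainder = substr(label, pos + 1L, nchar(label)))
}

#' Group identifiers of all leaves of a tree
#'
#' @param tree A `phylo` object whose tips follow the `"<group>-<rest>"`
#'   convention.
#' @return A character vector of group identifiers named by leaf label.
#' @export
leaf_groups <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  out <- vapply(tree$tip.label, function(x) parse_leaf_label(x)$group_id, "")
  out
}

#' Non-trivial bipartitions of the unrooted topology
#'
#' Each internal edge of the unrooted view of `tree` splits the leaves into
#' two sets. The two edges incident to a degree-2 root describe the same
#' unrooted edge and are merged; trivial splits (one side a single leaf) are
#' excluded. The result is invariant under rerooting of the same topology.
#'
#' @param tree A `phylo` object with at least 2 leaves.
#' @return A list of class `"sister_splits"`: each element a list with sorted
#'   character vectors `side_a` (the side holding the alphabetically first
#'   leaf) and `side_b`.
#' @export
unrooted_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 2L) stop("tree must have at least two leaves", call. = FALSE)
  below <- .tips_below(tree)
  root <- .root_node(tree)
  internal <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  first_leaf <- sort(labs)[1L]
  out <- list()
  keys <- character(0)
  for (v in internal) {
    side <- sort(labs[below[[v]]])
    if (length(side) < 2L || n - length(side) < 2L) next
    canon <- if (first_leaf %in% side) side else sort(setdiff(labs, side))
    key <- paste(canon, collapse = "\r")
    if (key %in% keys) next
    keys <- c(keys, key)
    out[[length(out) + 1L]] <- list(side_a = canon,
                                    side_b = sort(setdiff(labs, canon)))
  }
  structure(out, keys = keys, class = "sister_splits")
}

#' @export
print.sister_splits <- function(x, ...) {
  cat(sprintf("%d non-trivial unrooted split(s)\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  {%s} | {%s}\n",
                paste(x[[i]]$side_a, collapse = ","),
                paste(x[[i]]$side_b, collapse = ",")))
  }
  invisible(x)
}
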