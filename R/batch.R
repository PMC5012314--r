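# Batch driver: relabelling, per-tree processing, TSV reports, summaries.
#
# Every tree is processed independently; no failure in one file affects
# another, and output row order always follows input order, so a parallel
# run is byte-identical to a serial one.

REPORT_STATUSES <- c("OK", "NOT_MONOPHYLETIC", "NO_TARGET", "NO_SISTER", "PARSE_ERROR")

REPORT_COLUMNS <- c("tree_id", "status", "n_target_leaves",
                    "s1_label", "s1_support", "s1_size",
                    "s2_label", "s2_support", "s2_size",
                    "combined", "exclusive")

#' Prepend group identifiers to every leaf label
#'
#' Each leaf label becomes `"<group>-<old label>"`. Labels already carrying
#' a prefix are prefixed again verbatim (no deduplication). The topology is
#' unchanged.
#'
#' @param tree A `phylo` object.
#' @param mapping Either a named character vector (names = current leaf
#'   labels, values = group identifiers) or a two-column data frame
#'   (leaf, group).
#' @return The relabelled tree.
#' @export
relabel_leaves <- function(tree, mapping) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(mapping)) {
    stopifnot(ncol(mapping) >= 2L)
    mapping <- stats::setNames(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  }
  if (!is.character(mapping) || is.null(names(mapping))) {
    stop("`mapping` must be a named character vector or two-column data frame",
         call. = FALSE)
  }
  miss <- setdiff(tree$tip.label, names(mapping))
  if (length(miss)) {
    stop(sprintf("no group mapping for %d leaf/leaves: %s",
                 length(miss), paste(miss, collapse = ", ")), call. = FALSE)
  }
  grp <- unname(mapping[tree$tip.label])
  bad <- grp[grepl("-", grp, fixed = TRUE)]
  if (length(bad)) {
    stop(sprintf("group identifiers may not contain '-': %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  tree$tip.label <- paste0(grp, "-", tree$tip.label)
  tree
}

#' Read a leaf-to-group relabelling table
#'
#' @param path Two-column tab-separated file (leaf, group), no header;
#'   `#` comments allowed.
#' @return A named character vector usable by [relabel_leaves()].
#' @export
read_relabel_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("relabel table must have two tab-separated columns", call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

#' @keywords internal
#' @noRd
.empty_report <- function(tree_id, status, n_target = 0L, message = NULL) {
  structure(list(tree_id = tree_id, status = status,
                 n_target_leaves = as.integer(n_target),
                 candidates = list(), combined = FALSE, exclusive = FALSE,
                 message = message),
            class = "tree_report")
}

#' Run the full per-tree analysis on an already-parsed tree
#'
#' Pipeline: match the target leaves, locate the target clade (virtual
#' rerooting), extract the candidate sisters, attach association supports,
#' classify each candidate against the hierarchy, and optionally combine
#' the two candidates when they fall in the same hierarchical group. Every
#' failure mode is captured as a status; nothing is raised.
#'
#' @param tree A `phylo` object.
#' @param spec A [target_spec()] or prefix string.
#' @param hierarchy A `"sister_hierarchy"` or `NULL`.
#' @param combine Combine same-group candidates? Default `TRUE`.
#' @param tree_id Identifier recorded in the report.
#' @return A `"tree_report"`: `tree_id`, `status` (one of OK,
#'   NOT_MONOPHYLETIC, NO_TARGET, NO_SISTER, PARSE_ERROR),
#'   `n_target_leaves`, `candidates` (each with `label`, `support`,
#'   `leaves`), `combined`, `exclusive`.
#' @export
analyze_tree <- function(tree, spec, hierarchy = NULL, combine = TRUE,
                         tree_id = "tree") {
  spec <- .as_target_spec(spec)
  targets <- match_target_leaves(tree, spec)
  if (!length(targets)) return(.empty_report(tree_id, "NO_TARGET"))
  if (length(targets) == length(tree$tip.label)) {
    return(.empty_report(tree_id, "NO_SISTER", n_target = length(targets)))
  }
  tc <- find_target_clade(tree, targets)
  if (is.null(tc)) {
    return(.empty_report(tree_id, "NOT_MONOPHYLETIC", n_target = length(targets)))
  }
  cands <- extract_sisters(tree, tc)
  cands <- lapply(cands, function(s) {
    s$support <- association_support(tree, tc, s)
    s$label <- classify_groups(unique(s$groups), hierarchy)$label
    s
  })
  combined <- FALSE
  if (combine && length(cands) == 2L) {
    res <- combine_candidates(tree, tc, cands[[1L]], cands[[2L]], hierarchy)
    if (length(res) == 1L) {
      cands <- res
      combined <- TRUE
    }
  }
  tops <- vapply(cands, function(s) {
    if (identical(s$label, UNCLASSIFIED)) NA_character_
    else top_class(hierarchy, s$label)
  }, "")
  exclusive <- !anyNA(tops) && length(unique(tops)) == 1L
  structure(list(tree_id = tree_id, status = "OK",
                 n_target_leaves = length(targets),
                 candidates = cands, combined = combined,
                 exclusive = exclusive, message = NULL),
            class = "tree_report")
}

#' Process one newick file into a report row
#'
#' File-level wrapper around [analyze_tree()]: parse failures and
#' labelling-convention violations become status `PARSE_ERROR` (with the
#' condition message recorded) instead of errors, so phylome-scale batches
#' never stop mid-run.
#'
#' @param path Path to a newick file (tree id = file stem).
#' @param spec A [target_spec()] or prefix string.
#' @param hierarchy A `"sister_hierarchy"` or `NULL`.
#' @param relabel Optional named character vector for [relabel_leaves()].
#' @param combine Combine same-group candidates? Default `TRUE`.
#' @return A `"tree_report"`.
#' @export
process_tree <- function(path, spec, hierarchy = NULL, relabel = NULL,
                         combine = TRUE) {
  tree_id <- sub("\\.[^.]*$", "", basename(path))
  out <- tryCatch({
    tree <- read_newick(path)
    if (!is.null(relabel)) tree <- relabel_leaves(tree, relabel)
    analyze_tree(tree, spec, hierarchy, combine = combine, tree_id = tree_id)
  }, error = function(e) {
    .empty_report(tree_id, "PARSE_ERROR", message = conditionMessage(e))
  })
  out
}

#' @export
print.tree_report <- function(x, ...) {
  cat(sprintf("tree %s: %s (%d target leaf/leaves)\n",
              x$tree_id, x$status, x$n_target_leaves))
  for (s in x$candidates) print(s)
  invisible(x)
}

#' Process a batch of tree files
#'
#' One report per input file, in input order regardless of `jobs` (parallel
#' workers only change wall time, never output). Output is deterministic
#' for fixed inputs.
#'
#' @param paths Character vector of newick files (at least one).
#' @inheritParams process_tree
#' @param jobs Number of worker processes (forked; `1` = serial).
#' @return A list of `"tree_report"` objects, class `"tree_report_set"`.
#' @export
run_batch <- function(paths, spec, hierarchy = NULL, relabel = NULL,
                      combine = TRUE, jobs = 1L) {
  paths <- as.character(paths)
  if (!length(paths)) stop("no input tree files", call. = FALSE)
  spec <- .as_target_spec(spec)
  fun <- function(p) process_tree(p, spec, hierarchy, relabel, combine)
  reps <- if (jobs > 1L) parallel::mclapply(paths, fun, mc.cores = jobs)
          else lapply(paths, fun)
  structure(reps, class = "tree_report_set")
}

#' Tabulate reports into the fixed-column report table
#'
#' Columns: tree_id, status, n_target_leaves, s1_label, s1_support,
#' s1_size, s2_label, s2_support, s2_size, combined, exclusive. A missing
#' support is `NA`; an absent candidate leaves its fields `NA` (written as
#' empty fields by [write_report_tsv()]). At a polytomy junction more than
#' two candidates can exist; only the first two fit the fixed columns and a
#' warning is raised (the full list stays on the report objects).
#'
#' @param reports A `"tree_report_set"` or list of `"tree_report"`s.
#' @return A data frame with one row per report.
#' @export
report_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    cand <- r$candidates
    if (length(cand) > 2L) {
      warning(sprintf("tree %s: %d sister candidates at a polytomy junction; only the first two are tabulated",
                      r$tree_id, length(cand)), call. = FALSE)
    }
    data.frame(tree_id = r$tree_id,
               status = r$status,
               n_target_leaves = r$n_target_leaves,
               s1_label = if (length(cand) >= 1L) cand[[1L]]$label else NA_character_,
               s1_support = if (length(cand) >= 1L) cand[[1L]]$support else NA_real_,
               s1_size = if (length(cand) >= 1L) length(cand[[1L]]$leaves) else NA_integer_,
               s2_label = if (length(cand) >= 2L) cand[[2L]]$label else NA_character_,
               s2_support = if (length(cand) >= 2L) cand[[2L]]$support else NA_real_,
               s2_size = if (length(cand) >= 2L) length(cand[[2L]]$leaves) else NA_integer_,
               combined = r$combined,
               exclusive = r$exclusive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[REPORT_COLUMNS]
}

#' Write the report table as TSV
#'
#' Present-but-missing supports are written as `NA`; fields of an absent
#' candidate are written empty. Byte-identical for identical inputs.
#'
#' @param reports A report set, list of reports, or a [report_table()]
#'   data frame.
#' @param file Output path or connection (`""` = stdout).
#' @return The formatted table, invisibly.
#' @export
write_report_tsv <- function(reports, file = "") {
  df <- if (is.data.frame(reports)) reports else report_table(reports)
  fmt <- df
  num <- function(x) {   # element-wise: a row's bytes never depend on other rows
    vapply(x, function(v)
      if (is.na(v)) NA_character_ else format(v, digits = 15, trim = TRUE), "")
  }
  has_cand <- !is.na(df$s1_label)
  has_c2 <- !is.na(df$s2_label)
  fmt$s1_support <- ifelse(has_cand, ifelse(is.na(df$s1_support), "NA", num(df$s1_support)), "")
  fmt$s2_support <- ifelse(has_c2, ifelse(is.na(df$s2_support), "NA", num(df$s2_support)), "")
  fmt$s1_label <- ifelse(has_cand, df$s1_label, "")
  fmt$s2_label <- ifelse(has_c2, df$s2_label, "")
  fmt$s1_size <- ifelse(has_cand, num(df$s1_size), "")
  fmt$s2_size <- ifelse(has_c2, num(df$s2_size), "")
  fmt$combined <- ifelse(df$combined, "TRUE", "FALSE")
  fmt$exclusive <- ifelse(df$exclusive, "TRUE", "FALSE")
  utils::write.table(fmt, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(fmt)
}

#' Summarise a batch of reports
#'
#' Per sister label: total number of occurrences (a tree with two distinct
#' candidates counts towards both labels), occurrences with association
#' support at or above `support_threshold`, and occurrences in trees whose
#' sister association is exclusive (every candidate rolls up to one
#' top-level class). Status tallies cover all reports.
#'
#' @param reports A `"tree_report_set"` or list of `"tree_report"`s.
#' @param support_threshold Numeric support cutoff (default 0.9, the usual
#'   PhyML local-support screening value).
#' @return An object of class `"sister_summary"`: `labels` (data frame
#'   label/total/supported/exclusive, by decreasing total), `status` (data
#'   frame status/count over all five statuses), `support_threshold`.
#' @export
summarize_reports <- function(reports, support_threshold = 0.9) {
  status <- vapply(reports, function(r) r$status, "")
  st <- table(factor(status, levels = REPORT_STATUSES))
  lab <- character(0); sup <- numeric(0); exc <- logical(0)
  for (r in reports) {
    if (r$status != "OK") next
    for (s in r$candidates) {
      lab <- c(lab, s$label)
      sup <- c(sup, s$support)
      exc <- c(exc, r$exclusive)
    }
  }
  if (length(lab)) {
    labs <- sort(unique(lab))
    df <- data.frame(label = labs,
                     total = vapply(labs, function(l) sum(lab == l), 0L),
                     supported = vapply(labs, function(l)
                       sum(lab == l & !is.na(sup) & sup >= support_threshold), 0L),
                     exclusive = vapply(labs, function(l) sum(lab == l & exc), 0L),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$total, df$label), ]
    rownames(df) <- NULL
  } else {
    df <- data.frame(label = character(0), total = integer(0),
                     supported = integer(0), exclusive = integer(0),
                     stringsAsFactors = FALSE)
  }
  structure(list(labels = df,
                 status = data.frame(status = names(st),
                                     count = as.integer(st),
                                     stringsAsFactors = FALSE),
                 support_threshold = support_threshold),
            class = "sister_summary")
}

#' @export
print.sister_summary <- function(x, ...) {
  cat(sprintf("sister-association summary (support threshold %.3g)\n",
              x$support_threshold))
  cat("status tallies:\n")
  print(x$status, row.names = FALSE)
  cat("sister labels:\n")
  if (nrow(x$labels)) print(x$labels, row.names = FALSE) else cat("  (none)\n")
  invisible(x)
}

#' Write a summary as TSV
#'
#' @param summary A `"sister_summary"`.
#' @param file Output path or connection.
#' @return The summary, invisibly.
#' @export
write_summary_tsv <- function(summary, file = "") {
  stopifnot(inherits(summary, "sister_summary"))
  con <- if (is.character(file) && nzchar(file)) file(file, open = "wt") else file
  opened <- is.character(file) && nzchar(file)
  if (opened) on.exit(close(con))
  utils::write.table(summary$status, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary$labels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(summary)
}
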