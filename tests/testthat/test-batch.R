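write_tree_file <- function(text, dir, name) {
  p <- file.path(dir, name)
  writeLines(text, p)
  p
}

test_that("relabelling prepends group identifiers", {
  tr <- parse_newick("(Salinibacter_x,(Halobacterium_y,Ecoli_z));")
  map <- c(Salinibacter_x = "Bacteroidetes",
           Halobacterium_y = "Euryarchaeota",
           Ecoli_z = "Gammaproteobacteria")
  out <- relabel_leaves(tr, map)
  expect_setequal(out$tip.label,
                  c("Bacteroidetes-Salinibacter_x", "Euryarchaeota-Halobacterium_y",
                    "Gammaproteobacteria-Ecoli_z"))
  # already-prefixed labels are prefixed again verbatim
  out2 <- relabel_leaves(out, stats::setNames(rep("X", 3), out$tip.label))
  expect_true(all(startsWith(out2$tip.label, "X-")))
  expect_error(relabel_leaves(tr, c(Salinibacter_x = "B")), "Halobacterium_y")
  expect_error(relabel_leaves(tr, character(0)), "mapping")
})

test_that("per-tree processing composes the full pipeline", {
  d <- withr::local_tempdir()
  p <- write_tree_file("(((B-x,B-y)0.95,(C-z,C-q)0.85)0.90,(D-w,E-v)0.70);",
                       d, "phylo1.nwk")
  rep <- suppressWarnings(process_tree(p, "B-"))
  expect_equal(rep$status, "OK")
  expect_equal(rep$tree_id, "phylo1")
  expect_equal(rep$n_target_leaves, 2L)
  expect_length(rep$candidates, 2L)
  expect_equal(rep$candidates[[1]]$label, "C")
  expect_equal(rep$candidates[[1]]$support, 0.90)
  expect_length(rep$candidates[[1]]$leaves, 2L)
  expect_equal(rep$candidates[[2]]$label, UNCLASSIFIED)  # mixed D,E, no hierarchy
  expect_equal(rep$candidates[[2]]$support, 0.85)
  expect_false(rep$combined)
  expect_false(rep$exclusive)
})

test_that("every failure mode becomes a status, never an error", {
  d <- withr::local_tempdir()
  p_ok <- write_tree_file("((B-x,B-y)0.9,(C-z,C-q)0.9);", d, "ok.nwk")
  p_nm <- write_tree_file("((B-x,C-z),(B-y,D-w));", d, "nonmono.nwk")
  p_nt <- write_tree_file("((A-x,A-y),(C-z,D-w));", d, "notarget.nwk")
  p_ns <- write_tree_file("(B-x,(B-y,B-z));", d, "nosister.nwk")
  p_pe <- write_tree_file("((B-x,B-y", d, "garbled.nwk")
  p_nc <- write_tree_file("((B-x,By),(Cz,Dw));", d, "nohyphen.nwk")

  reps <- run_batch(c(p_ok, p_nm, p_nt, p_ns, p_pe, p_nc), "B-")
  expect_equal(vapply(reps, `[[`, "", "status"),
               c("OK", "NOT_MONOPHYLETIC", "NO_TARGET", "NO_SISTER",
                 "PARSE_ERROR", "PARSE_ERROR"))
  for (r in reps) if (r$status != "OK") expect_length(r$candidates, 0L)
  expect_match(reps[[5]]$message, "unclosed")
})

test_that("batch output is deterministic, order-preserving and independent", {
  d <- withr::local_tempdir()
  paths <- vapply(1:8, function(i) {
    sc <- plant_sister_scenario(n_leaves = 10 + i, seed = 100 + i)
    write_newick(sc$tree, file.path(d, sprintf("t%02d.nwk", i)))
    file.path(d, sprintf("t%02d.nwk", i))
  }, "")
  f1 <- file.path(d, "r1.tsv"); f2 <- file.path(d, "r2.tsv")
  reps <- run_batch(paths, "Bacteroidetes-")
  write_report_tsv(reps, f1)
  write_report_tsv(run_batch(paths, "Bacteroidetes-"), f2)
  expect_identical(readLines(f1), readLines(f2))

  df <- report_table(reps)
  expect_equal(df$tree_id, sub("\\.nwk$", "", basename(paths)))
  expect_equal(names(df),
               c("tree_id", "status", "n_target_leaves", "s1_label", "s1_support",
                 "s1_size", "s2_label", "s2_support", "s2_size", "combined",
                 "exclusive"))

  # a tree processed alone yields the identical row
  solo <- report_table(list(process_tree(paths[3], "Bacteroidetes-")))
  expect_equal(solo, df[3, ], ignore_attr = TRUE)
})

test_that("TSV encodes missing supports as NA and absent candidates as empty", {
  d <- withr::local_tempdir()
  p1 <- write_tree_file("((B-x,B-y)0.95,C-z);", d, "single.nwk")   # lone sister, no support
  p2 <- write_tree_file("((B-x,C-z),(B-y,D-w));", d, "nm.nwk")
  f <- file.path(d, "out.tsv")
  write_report_tsv(run_batch(c(p1, p2), "B-"), f)
  lines <- readLines(f)
  expect_equal(length(lines), 3L)
  row1 <- strsplit(lines[2], "\t")[[1]]
  expect_equal(row1[4:6], c("C", "NA", "1"))      # present candidate, missing support
  row2 <- strsplit(lines[3], "\t")[[1]]
  expect_equal(row2[2], "NOT_MONOPHYLETIC")
  expect_equal(row2[4:9], rep("", 6))             # absent candidates -> empty fields
})

test_that("summaries count labels, thresholds and exclusivity", {
  d <- withr::local_tempdir()
  paths <- character(0)
  for (i in 1:10) {
    sup <- ifelse(i <= 4, 0.95, 0.5)   # support on the target clade's edge
    paths <- c(paths, write_tree_file(
      sprintf("(((B-x,B-y)%s,(Eury-a%d,Eury-b%d)0.8)0.9,(Eury-c%d,(Eury-d%d,Eury-e%d)0.7)0.9);",
              sup, i, i, i, i, i),
      d, sprintf("s%02d.nwk", i)))
  }
  reps <- run_batch(paths, "B-")
  sm <- summarize_reports(reps, support_threshold = 0.90)
  expect_equal(sm$status$count[sm$status$status == "OK"], 10L)
  expect_equal(sum(sm$status$count), 10L)
  lab <- sm$labels
  expect_equal(lab$label, "Eury")                 # both sisters Eury -> combined
  expect_equal(lab$total, 10L)
  expect_equal(lab$supported, 4L)
  expect_equal(lab$exclusive, 10L)
  expect_true(all(vapply(reps, `[[`, TRUE, "combined")))
})

test_that("raising the support threshold never raises a supported count", {
  set.seed(31)
  d <- withr::local_tempdir()
  paths <- vapply(1:20, function(i) {
    sc <- plant_sister_scenario(n_leaves = sample(8:20, 1), seed = 300 + i)
    p <- file.path(d, sprintf("m%02d.nwk", i))
    write_newick(sc$tree, p)
    p
  }, "")
  reps <- run_batch(paths, "Bacteroidetes-")
  thresholds <- seq(0, 1, by = 0.1)
  prev <- NULL
  for (th in thresholds) {
    sm <- summarize_reports(reps, support_threshold = th)
    cur <- stats::setNames(sm$labels$supported, sm$labels$label)
    if (!is.null(prev)) {
      expect_true(all(cur[names(prev)] <= prev))
    }
    expect_true(all(sm$labels$supported <= sm$labels$total))
    prev <- cur
  }
})

test_that("two-stage search: narrowed reruns cover only non-monophyletic trees", {
  d <- withr::local_tempdir()
  paths <- character(0)
  # trees where strain M8/M13 copies of group B are split apart
  for (i in 1:4) {
    paths <- c(paths, write_tree_file(
      sprintf("((B-M8_g%d,(C-c%d,C-d%d)0.9)0.8,(B-M13_g%d,(D-e%d,D-f%d)0.7)0.8);",
              i, i, i, i, i, i),
      d, sprintf("two%d.nwk", i)))
  }
  # and trees where B is intact
  for (i in 5:8) {
    paths <- c(paths, write_tree_file(
      sprintf("((B-M8_g%d,B-M13_g%d)0.9,(C-c%d,D-d%d)0.8);", i, i, i, i),
      d, sprintf("one%d.nwk", i)))
  }
  stage1 <- run_batch(paths, "B-")
  st <- vapply(stage1, `[[`, "", "status")
  ok_ids <- vapply(stage1, `[[`, "", "tree_id")[st == "OK"]
  redo <- paths[st == "NOT_MONOPHYLETIC"]
  expect_length(redo, 4L)
  stage2 <- run_batch(redo, "B-M8")
  expect_true(all(vapply(stage2, `[[`, "", "status") == "OK"))
  expect_length(intersect(vapply(stage2, `[[`, "", "tree_id"), ok_ids), 0L)
})

test_that("parallel execution yields byte-identical output", {
  skip_on_os("windows")
  d <- withr::local_tempdir()
  paths <- vapply(1:6, function(i) {
    sc <- plant_sister_scenario(n_leaves = 12, seed = 700 + i)
    p <- file.path(d, sprintf("p%d.nwk", i))
    write_newick(sc$tree, p)
    p
  }, "")
  f1 <- file.path(d, "serial.tsv"); f2 <- file.path(d, "parallel.tsv")
  write_report_tsv(run_batch(paths, "Bacteroidetes-", jobs = 1), f1)
  write_report_tsv(run_batch(paths, "Bacteroidetes-", jobs = 2), f2)
  expect_identical(readLines(f1), readLines(f2))
})
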