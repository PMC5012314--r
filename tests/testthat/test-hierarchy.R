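example_h <- function() {
  parse_hierarchy(c("Animalia\tOpisthokonta",
                    "Fungi\tOpisthokonta",
                    "Opisthokonta\tEukaryota",
                    "Plantae\tEukaryota"))
}

test_that("hierarchy files parse, with comments and blank lines", {
  h <- parse_hierarchy(c("# kingdoms", "", "Animalia\tOpisthokonta",
                         "Fungi\tOpisthokonta  # opisthokonts",
                         "Opisthokonta\tEukaryota"))
  expect_equal(class_ancestors(h, "Animalia"), c("Opisthokonta", "Eukaryota"))
  expect_length(empty_hierarchy()$parent_of, 0L)
})

test_that("improper nesting, cycles and malformed lines are rejected", {
  expect_error(parse_hierarchy(c("X\tA", "X\tB")), "two parents")
  expect_error(parse_hierarchy(c("A\tB", "B\tC", "C\tA")), "cycle")
  expect_error(parse_hierarchy("A B"), "line 1")
  expect_error(parse_hierarchy(c("A\tB", "oops")), "line 2")
  expect_error(parse_hierarchy("A-x\tB"), "'-'")
  expect_error(parse_hierarchy("A\tA"), "own parent")
})

test_that("classification finds the smallest covering class", {
  h <- example_h()
  expect_equal(classify_groups("Fungi")$label, "Fungi")
  expect_equal(classify_groups("Fungi", h)$depth, 0L)
  expect_equal(classify_groups(c("Animalia", "Fungi"), h)$label, "Opisthokonta")
  expect_equal(classify_groups(c("Animalia", "Fungi"), h)$depth, 1L)
  expect_equal(classify_groups(c("Animalia", "Plantae"), h)$label, "Eukaryota")
  expect_equal(classify_groups(c("Animalia", "Fungi", "Plantae"), h)$label, "Eukaryota")
  expect_equal(classify_groups(c("Animalia", "Euryarchaeota"), h)$label, UNCLASSIFIED)
  expect_equal(classify_groups(c("Animalia", "Animalia"), h)$label, "Animalia")
  # a class name itself can occur as a "group"
  expect_equal(classify_groups(c("Opisthokonta", "Fungi"), h)$label, "Opisthokonta")
})

test_that("single identifiers classify as themselves regardless of hierarchy", {
  h <- example_h()
  for (g in c("Animalia", "Euryarchaeota", "Zzz")) {
    expect_equal(classify_groups(g, h)$label, g)
    expect_equal(classify_groups(g, NULL)$label, g)
  }
})

test_that("classification is minimal: no proper descendant also covers", {
  set.seed(5)
  for (rep in 1:20) {
    # random properly nested forest over <= 20 classes
    classes <- paste0("C", 1:sample(5:20, 1))
    parents <- character(0)
    for (i in seq_along(classes)[-1]) {
      if (stats::runif(1) < 0.7) parents[classes[i]] <- classes[sample(i - 1, 1)]
    }
    h <- parse_hierarchy(sprintf("%s\t%s", names(parents), parents))
    leaves <- sample(classes, min(4, length(classes)))
    cl <- classify_groups(leaves, h)
    if (identical(cl$label, UNCLASSIFIED)) {
      # no single class covers all picked groups
      for (c0 in classes) {
        covers <- all(vapply(leaves, function(g)
          c0 %in% c(g, class_ancestors(h, g)), TRUE))
        expect_false(covers)
      }
    } else {
      # the label covers, and no proper descendant of it covers
      expect_true(all(vapply(leaves, function(g)
        cl$label %in% c(g, class_ancestors(h, g)), TRUE)))
      desc <- classes[vapply(classes, function(c0)
        cl$label %in% class_ancestors(h, c0), TRUE)]
      for (d in desc) {
        covers <- all(vapply(leaves, function(g)
          d %in% c(g, class_ancestors(h, g)), TRUE))
        expect_false(covers)
      }
    }
  }
})

test_that("adding a class only turns UNCLASSIFIED into a label", {
  h <- example_h()
  expect_equal(classify_groups(c("Animalia", "Euryarchaeota"), h)$label, UNCLASSIFIED)
  h2 <- parse_hierarchy(c("Animalia\tOpisthokonta", "Fungi\tOpisthokonta",
                          "Opisthokonta\tEukaryota", "Plantae\tEukaryota",
                          "Eukaryota\tLife", "Euryarchaeota\tLife"))
  expect_equal(classify_groups(c("Animalia", "Euryarchaeota"), h2)$label, "Life")
  # existing classifications unchanged
  expect_equal(classify_groups(c("Animalia", "Fungi"), h2)$label, "Opisthokonta")
  expect_equal(classify_groups(c("Animalia", "Plantae"), h2)$label, "Eukaryota")
})

test_that("candidates combine only for identical or nested labels", {
  h <- parse_hierarchy(c("Bacteroidetes\tBacteria", "Chlorobi\tBacteria",
                         "Fungi\tOpisthokonta"))
  tr <- parse_newick("(((T-a,T-b)0.9,(Bacteroidetes-x,Bacteroidetes-y)0.8)0.7,(Chlorobi-p,Chlorobi-q)0.6);")
  tc <- find_target_clade(tr, c("T-a", "T-b"))
  ss <- extract_sisters(tr, tc)
  ss <- lapply(ss, function(s) {
    s$label <- classify_groups(unique(s$groups), h)$label
    s
  })
  # Bacteroidetes vs Chlorobi: same parent but distinct labels -> NOT combined
  out <- combine_candidates(tr, tc, ss[[1]], ss[[2]], h)
  expect_length(out, 2L)

  # identical labels -> combined, leaf set is the full complement
  c1 <- ss[[1]]; c2 <- ss[[2]]
  c1$label <- "Euryarchaeota"; c2$label <- "Euryarchaeota"
  out2 <- combine_candidates(tr, tc, c1, c2, h)
  expect_length(out2, 1L)
  expect_equal(out2[[1]]$label, "Euryarchaeota")
  expect_setequal(out2[[1]]$leaves, setdiff(tr$tip.label, tc$leaves))
  # combined support = split separating the target from everything else
  expect_equal(out2[[1]]$support, 0.9)

  # ancestor/descendant labels -> combined as the more general one
  c1$label <- "Opisthokonta"; c2$label <- "Fungi"
  out3 <- combine_candidates(tr, tc, c1, c2, h)
  expect_length(out3, 1L)
  expect_equal(out3[[1]]$label, "Opisthokonta")

  # UNCLASSIFIED never combines
  c1$label <- UNCLASSIFIED; c2$label <- UNCLASSIFIED
  expect_length(combine_candidates(tr, tc, c1, c2, h), 2L)
})

test_that("combination preserves the union of reported leaf sets", {
  for (seed in 1:10) {
    sc <- plant_sister_scenario(n_leaves = sample(8:24, 1), seed = seed)
    tr <- sc$tree
    tc <- find_target_clade(tr, match_target_leaves(tr, "Bacteroidetes-"))
    ss <- extract_sisters(tr, tc)
    ss <- lapply(ss, function(s) {
      s$support <- association_support(tr, tc, s)
      s$label <- classify_groups(unique(s$groups))$label
      s
    })
    if (length(ss) == 2L) {
      out <- combine_candidates(tr, tc, ss[[1]], ss[[2]])
      expect_setequal(unlist(lapply(out, `[[`, "leaves")),
                      unlist(lapply(ss, `[[`, "leaves")))
    }
  }
})

test_that("top-level class lookup rolls labels up to the forest roots", {
  h <- example_h()
  expect_equal(top_class(h, "Animalia"), "Eukaryota")
  expect_equal(top_class(h, "Eukaryota"), "Eukaryota")
  expect_equal(top_class(h, "Euryarchaeota"), "Euryarchaeota")
  expect_equal(top_class(NULL, "X"), "X")
})
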