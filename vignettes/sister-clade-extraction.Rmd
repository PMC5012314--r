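---
title: "Screening gene phylogenies for sister clades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene phylogenies for sister clades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisterclade)
```

## The problem

Automated phylogenetic pipelines produce thousands of gene trees per
genome (a *phylome*). A recurring question is: *who is the nearest
neighbour of my taxon of interest in each of these trees, and how well is
that relationship supported?* Aggregated over a phylome, the answer
quantifies vertical inheritance and flags outliers — a gene tree that
places a bacterium sister to a clade of archaea is a candidate horizontal
gene transfer (HGT), hybridisation, contamination, or long-branch
artefact worth manual attention.

Extracting that answer is not entirely trivial because gene trees usually
have **arbitrary roots**: maximum-likelihood programs emit a rooted newick
string, but nothing biological distinguishes its root. Any method that
reads "the sister of X" off the rooted topology is answering a question
about the arbitrary root, not about the gene's history.

## The model: sisters on the unrooted topology

This package treats every input tree as an unrooted topology that happens
to be written down with a root, and never mutates the input object
("virtual rerooting").

Leaves carry group identifiers in their labels: everything before the
*first* hyphen is the group (`Bacteroidetes-Salinibacter_ruber_x`). The
first hyphen is the delimiter because it is the only parse that keeps
group identifiers hyphen-free while allowing hyphens in the rest of the
name.

Given a search string (a label prefix, or a regular expression), the
pipeline runs in three steps per tree:

1. **Locate the target clade.** The target leaves are monophyletic, in
   the unrooted sense, exactly when they form one side of a bipartition
   (split) of the unrooted topology — equivalently, when some rerooting
   would make them a clade. The certificate is a single tree node whose
   subtree contains either exactly the targets, or exactly the
   non-targets (the latter is the virtually-rerooted case). Single leaves
   are always valid targets. If no split separates the targets the tree
   is reported `NOT_MONOPHYLETIC` and the batch continues; this is a
   per-tree result, not a failure, because phylome screens routinely
   rerun those trees with a narrower search string (e.g. one strain
   instead of a species).

2. **Extract up to two sisters.** Because the root is arbitrary, the
   target's neighbourhood admits two alternative rootings, hence up to
   two mutually exclusive sister hypotheses. In unrooted terms both come
   from the junction vertex across the target's attachment edge: its
   remaining subtrees are the candidates. Written in rooted terms: when
   the target is a child of a degree-2 root, the sisters are the two
   children of the other root child; otherwise the sibling subtree is S1
   and the rest of the phylogeny (the tree as if rerooted at the target's
   parent) is S2. When only one subtree remains (the target's complement
   is a single leaf or a cherry partner), there is a single sister. The
   package deliberately does not decide which sister is biologically
   correct — that requires external information such as a species tree.

3. **Attach the association support.** The support for pairing target T
   with sister S is the annotation on the unrooted edge that separates
   T ∪ S from the remaining leaves: the label of the node whose clade is
   T ∪ S when there is one, otherwise the label of the root of the
   complement subtree. The value is missing when the separating split is
   trivial (remainder a single leaf) or the label is non-numeric. Any
   numeric label is accepted as a support (0–1 local supports and 0–100
   bootstraps alike); non-numeric internal labels are retained in the
   tree object but reported as missing support, since nothing in a newick
   file says what they mean.

### The degree-2 root subtlety

In a rooted binary newick string the two children of the root describe
the *same* unrooted edge, so their labels are two encodings of one
support. PhyML-style output duplicates the value; some tools label only
one child. The package reads whichever is present, prefers the label on
the side uniting target and sister when both exist, and warns when two
numeric labels on one edge disagree — that situation is a malformed input
(two different supports claimed for one edge) and the preference for the
uniting clade follows directly from reading "the support of the node
uniting target and sister". The rerooting helper duplicates a lone
root-edge label onto both children before handing the tree to
`ape::root()`, because `ape` keeps only one of the two labels when the
old root vanishes and which one survives depends on the rerooting path.

### Polytomies

A trifurcating root is the standard unrooted encoding of a binary tree
and is treated as such: the target child of a trifurcating root has two
sister candidates with well-defined supports. True polytomies (degree ≥ 4
at the root, or an unresolved internal junction) yield one candidate per
adjacent subtree; their supports come out missing automatically, because
no single edge certifies any pairing — the remainder of each candidate
union is not one side of a split. We preferred this over rejecting
multifurcating trees so that partially collapsed real trees still
produce auditable rows.

## Hierarchical summarisation

A sister subtree whose leaves span several groups is still informative
when the groups share a higher taxon. A plain-text configuration (one
`child<TAB>parent` pair per line) defines a properly nested forest of
classes above the group identifiers:

```{r}
h <- parse_hierarchy(c("Animalia\tOpisthokonta",
                       "Fungi\tOpisthokonta",
                       "Opisthokonta\tEukaryota",
                       "Plantae\tEukaryota"))
classify_groups(c("Animalia", "Fungi"), h)$label
classify_groups(c("Animalia", "Plantae"), h)$label
classify_groups(c("Animalia", "Euryarchaeota"), h)$label
```

A sister is summarised by the *smallest* class covering all its groups; a
single group is always its own answer; when no class covers the set, the
explicit token `UNCLASSIFIED` is reported rather than dropping the row,
so batch totals stay auditable.

When the two sister candidates carry the same label — or one label is an
ancestor of the other — they are two rootings of the same story and are
combined into a single result labelled with the more general class, whose
leaf set is the full complement of the target and whose support is the
annotation on the target-versus-rest split. We read "belong to the same
hierarchical group" as label identity or nesting, *not* as "share any
ancestor": the latter would merge nearly everything under a root class
and make distinct phylum-level sisters unreportable. Two `UNCLASSIFIED`
candidates are never combined — the token marks the absence of a class,
and merging two unknowns would manufacture a result. This reading is
isolated in `combine_candidates()` so it can be swapped if a project
prefers another.

A report is flagged **exclusive** when every reported candidate rolls up
to one top-level class of the hierarchy. In an HGT screen with a
phylum→domain configuration, "exclusive Archaea" means no rooting of the
tree offers a bacterial or eukaryotic alternative sister — the strongest
topological form of the signal.

## Batch semantics

`run_batch()` maps `process_tree()` over files; every failure mode
(unreadable file, syntax error, labelling-convention violation, no
matching leaf, non-monophyletic target, target spanning all leaves)
becomes a per-tree status and never an exception, so a phylome run always
produces one row per input. Rows follow input order whatever the worker
count, and reruns are byte-identical. The fixed TSV columns are
`tree_id, status, n_target_leaves, s1_label, s1_support, s1_size,
s2_label, s2_support, s2_size, combined, exclusive`; a present-but-missing
support prints `NA`, an absent candidate prints empty fields — so one row
per tree parses losslessly even when a tree has one, two, or a combined
candidate. `summarize_reports()` tallies labels with a support threshold
(default 0.9, the usual local-support screening value) and exclusivity
counts; a tree with two distinct candidates counts towards both labels.

## The synthetic generator

Real phylomes require a database download, so validation rests on a
generator that emulates what matters for this method:

* random binary topologies by iterative random leaf attachment;
* uniformly drawn group identifiers from a configurable alphabet,
  defaulting to a realistic phylum mix (Bacteroidetes target,
  Euryarchaeota sister, bacterial/archaeal background);
* supports drawn uniformly on [0, 1] and rounded to three decimals,
  mimicking PhyML local supports and making serialise→parse round trips
  exact, so planted supports can be asserted to equality;
* planted scenarios `((T,S)support, R)` rerooted on a uniformly random
  edge, so that recovering the plant exercises the virtual-rerooting
  logic rather than the lucky case;
* a scrambling negative control that swaps target leaves with random
  non-target leaves, destroying the certifying split with high
  probability (the truth of each scramble is checked against a
  brute-force bipartition oracle, not assumed).

A single integer seed drives topology, groups, supports and the rerooting
choice, in that documented order, so fixtures regenerate byte-identically.
What the generator does **not** emulate: branch lengths, realistic
support correlation along the tree, duplicated gene copies
(paralogy/xenology mixtures), and non-uniform taxon sampling. Passing
tests therefore demonstrate the correctness of the extraction logic, not
robustness of biological inference on real data — trees with retained
ancestral copies will legitimately come out `NOT_MONOPHYLETIC`, which is
the intended screen-then-inspect behaviour, not a defect.

## Numerical and design choices

* Monophyly certificates and supports are found by counting target
  leaves under each node in one postorder pass (O(n) per query), and
  validated against an independent flood-fill split enumeration and
  against `phangorn`'s bipartitions in the test suite — exhaustively for
  every unrooted topology with ≤ 8 leaves, and on random trees with up
  to 64 leaves.
* Candidate order is deterministic: S1 is the sibling subtree (or the
  first-listed grandchild in newick order when the target is a root
  child), so reruns are reproducible down to bytes.
* Test problem sizes (≤ 64 leaves, hundreds to thousands of trees,
  1,000 planted recovery scenarios, a 2,000-vs-1,000-tree timing ratio
  for the linearity check) were chosen as the smallest sizes at which
  each property is meaningfully exercised across all tree shapes.
* Files holding several trees yield the first with a warning — a batch
  maps files to rows one-to-one by design.

## Known limitations

* NEXUS/PhyloXML input, translation tables, and networks are out of
  scope; one newick tree per file.
* The tool ranks nothing: which of S1/S2 is the true sister, and whether
  an exclusive association is HGT rather than artefact, are downstream
  questions.
* Hierarchies must be properly nested; conflicting taxonomies are
  handled by rerunning with a different configuration file, not merged.
* Support semantics rely on the internal-node-label convention; trees
  annotated with branch-attribute comments (e.g. `[&support=...]`) are
  not understood.
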