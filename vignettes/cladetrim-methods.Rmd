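---
title: "Taxonomy-aware tree dereplication: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomy-aware tree dereplication: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladetrim)
```

# The procedure and its assumptions

cladetrim removes redundant OTUs from a rooted phylogenetic tree: members
of well-supported, taxonomically homogeneous clades beyond a user-chosen
number of representatives. It assumes

* the tree is **rooted as written** — the Newick nesting defines the root,
  and no rerooting is performed or offered. Clades are meaningful only
  relative to that root, so an unrooted or badly rooted input will produce
  formally correct but biologically uninteresting clades;
* **support values are comparable to the threshold as given.** Bootstrap
  percentages (0–100), SH-like values and posterior probabilities (0–1)
  are never rescaled; the user's threshold must live on the file's scale.
  We chose pass-through over guessing a normalization because a wrong
  guess silently changes which clades are eligible;
* **branch lengths are additive distances** (substitutions/site in
  practice, but only relative magnitudes matter); absent lengths count as
  0, which lets cladogram inputs run without crashing — with all depths
  0, representative selection degenerates to "first `retain` leaves in
  tree order", which is documented behaviour, not an error.

The pipeline is: supported internal nodes (root included) →
single-category filter against the lineage table → maximal clades per
category → median-ranked representative selection per clade.

# Parameters that matter

| parameter | meaning | units / scale | default |
|---|---|---|---|
| `threshold` | minimum support for a clade to be examined; 0 = examine every internal node | same scale as the tree's supports | none (required) |
| `rule` category | label that must be shared unanimously | exact, case-sensitive string | — |
| `rule` rank | 1-based position in the lineage at which the category is read | positional index, 1 = most inclusive | — |
| `rule` retain | representatives kept per maximal clade | count ≥ 1 | — |
| `default` | rank + retain applied to any unanimous category with no explicit rule | as above | absent |

Ranks are positional rather than named because lineages need not be
taxonomic at all: sample sites, geographic origins or project tags work
identically for metagenomic dereplication.

Precedence when several rules match one clade: the deepest (largest) rank
wins, then declaration order. Specific-beats-general is the only ordering
that lets a user carve a genus-level exception out of a phylum-level
rule; declaration order resolves the remainder deterministically.

# Selection within a clade

For a maximal clade with basal node $v$ and leaves $\ell$, the depth
$d(\ell)$ is the branch-length sum from $v$ (exclusive of $v$'s own
subtending branch) to $\ell$. The clade statistic is the sample median
$\tilde m$ of the depths — middle value for odd counts, arithmetic mean
of the two central values for even counts. The even-count rule is our
choice of the conventional sample median; the method's description calls
only for "the median" and motivates it as robust against long-branch
outliers, which both conventions satisfy. The `retain` leaves minimizing
$|d(\ell) - \tilde m|$ are kept, ties broken by earlier position in the
tree's leaf order. With those two tie rules the whole pipeline is
deterministic and needs no random seed anywhere.

Clades whose size is **at most** `retain` remove nothing. Sizes strictly
below `retain` are skipped by the stated rule ("fewer members than the
minimum"); sizes exactly equal are processed but have nothing to remove.
Both appear in the reports as zero-removal records — we preferred a
complete audit trail over silence, at the cost of rows that some users
may wish to filter out.

# Edge cases decided here

* **The root counts as a clade.** If the whole tree is one category and
  the root passes (or the threshold is 0), the whole tree is one
  dereplication unit. Degenerate but well defined; refusing it would need
  an arbitrary carve-out.
* **Maximality stops at unsupported parents.** A single-category clade is
  never grown through a parent that fails the support threshold, even if
  the parent's leaf composition is unchanged. The scan is defined from
  supported nodes; the alternative (composition-preserving expansion)
  would make the threshold advisory rather than binding.
* **Cross-category nesting.** With rules at two ranks (say a supergroup
  rule above genus rules), a supported all-supergroup clade can strictly
  contain a supported all-genus clade: both are maximal *within their
  categories* but overlap. The most inclusive clade governs and the
  contained one is not processed separately — consistent with the
  "largest clade" principle, and it keeps processed clades leaf-disjoint
  so each OTU's fate is decided exactly once.
* **Unmapped OTUs are never removed.** An OTU absent from the lineage
  table (or with a lineage too short for the tested rank) disqualifies
  every rule for every clade containing it. Unknown taxa are precious;
  the conservative reading costs only some un-pruned redundancy.
* **Internal labels that fail numeric parsing are node names,** kept and
  re-serialized, never silently dropped.

# Numerical choices

* Branch lengths and supports round-trip through serialization at 15
  significant digits (errors ≪ 1e−9, the documented round-trip
  tolerance).
* The median is computed by an explicit sort-based formula rather than
  `stats::median`. The two agree mathematically, but `mean()` of the two
  central values accumulates in long double; for an even-size clade the
  two central leaves are *exactly* equidistant from the median in real
  arithmetic, so which one wins is decided at machine precision, and the
  explicit formula makes that decision identical across independent
  implementations of the same definition (our brute-force cross-check
  exploits this).
* Depth sums are accumulated stepwise in double precision along the path,
  again so that exact ties are ties for any implementation following the
  same order.

# The synthetic world, and what a green test establishes

`generate_tree()` builds random rooted bifurcating topologies by repeated
uniform coalescence of a leaf pool; each planted clade is attached as one
monophyletic unit whose basal node carries a stated support, and its leaf
set is returned as ground truth. Branch lengths are i.i.d. exponential
with mean 0.1 substitutions/site — a typical single-protein scale, and
only relative depths matter to the median rule; non-planted supports are
uniform on [0, 1); background leaves carry distinct singleton lineages so
no rule can ever unite two of them. Each call is a pure function of its
seed and leaves the caller's RNG untouched.

This emulates the *decision structure* of the problem — nested supported
clades, mixed and homogeneous composition, rank-layered rules, exact
depth ties — not the realism of sequence evolution: no rate
heterogeneity, no correlation between support and branch length, no
paralog birth–death process, and clade sizes far below the
thousand-OTU datasets the method targets. A green suite therefore
establishes that the implementation agrees with an independent
brute-force reimplementation and with the stated invariants on trees up
to 25 leaves, not that any particular biological dataset is reduced to
any particular size; published headline reductions additionally depend on
sequence-database snapshots and upstream search/alignment pipelines that
are out of scope here.

# Known limitations

* **Idempotence and threshold monotonicity hold in the single-rank-rule
  regime only.** With rank-layered rules, the deepest-matching-rank rule
  of a clade can *change* after pruning (e.g. a mixed supergroup clade
  whose retained representatives all belong to one genus), so a second
  pass may legitimately remove more, and raising the threshold can shift
  governance from one inclusive clade to several smaller ones whose
  retain counts sum differently. Both properties are asserted in the test
  suite exactly in the regime where they are theorems; the layered regime
  is instead covered by the brute-force equivalence check.
* Dialects: Newick only (no Nexus/PhyloXML); two support conventions
  (internal label, bracket comment). No rerooting, no support
  recomputation, no branch-length re-estimation.
* Selection knows nothing about the underlying sequences: a
  least-gappy-alignment or abundance-weighted choice of representatives
  is out of scope.
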