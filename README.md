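# cladetrim

Taxonomy-aware dereplication of large phylogenetic trees.

## The problem

High-throughput sequencing makes it easy to build single-gene trees with
hundreds or thousands of OTUs (operational taxonomic units), but most of
that bulk is redundant: orthologs from closely related organisms and
recently expanded lineage-specific paralogs that add computational cost to
rigorous downstream analyses (Bayesian or maximum-likelihood re-analysis)
without adding taxonomic signal. Trimming such datasets by hand is slow,
subjective and hard to reproduce. cladetrim is for phylogeneticists who
want that pruning done objectively, from explicit parameters, with the
original topology and taxonomic breadth preserved.

## The method

Given a rooted tree *T* (Newick, with or without support values and branch
lengths), a reference table mapping each OTU to an ordered lineage
(rank 1 = most inclusive), and a parameter set — a support threshold
*θ* ≥ 0 plus rules (category *c*, rank *r*, retain *k*):

1. **Supported clades.** Collect every internal node *v* (root included)
   with support *s(v)* ≥ *θ*; *θ* = 0 means every internal node. Supports
   are compared on the scale of the file (no 0–1 vs 0–100 rescaling).
2. **Taxonomic homogeneity.** Keep the clades whose full leaf set
   unanimously has category *c* at rank *r* for some rule (an unmapped OTU
   disqualifies every rule; the deepest matching rank wins; an optional
   default rule catches any shared category without an explicit rule).
3. **Maximality.** Discard clades strictly contained in a larger
   single-category clade of the same category. A category scattered across
   the tree in *m* supported clades yields *m* separate dereplication
   units.
4. **Median-ranked representatives.** Within each maximal clade, compute
   each leaf's path length *d(ℓ)* from the clade's basal node, take the
   sample median *m̃*, and keep the *k* leaves minimizing |*d(ℓ)* − *m̃*|
   (ties broken by leaf order). The median damps the pull of unusually
   long-branching OTUs. Clades with ≤ *k* leaves are left untouched.

Everything else — mixed clades, weakly supported clades, unmapped OTUs —
is always retained. Outputs are the retained-OTU list (the functional
result), a trimmed reference cladogram, and a machine-readable removal
table. The whole pipeline is deterministic: identical inputs give
byte-identical outputs.

## Worked example

The package ships a small synthetic 14-OTU tree (mitochondrial-protein
flavoured; all names carry a `_syn` suffix because they correspond to no
real accessions) with a dense animal clade and a green-plant clade:

```r
library(cladetrim)
d <- system.file("extdata", package = "cladetrim")
res <- run_trim(tree_path     = file.path(d, "example_tree.nwk"),
                taxonomy_path = file.path(d, "example_taxonomy.tsv"),
                params_path   = file.path(d, "example_params.tsv"),
                out_dir       = "ex_out")
#> threshold: 0.8
#> leaves in: 14, retained: 8, removed: 6
#> clades dereplicated: 2
#> outputs written to ex_out
```

The parameters collapse well-supported all-Metazoa and all-Viridiplantae
clades to 2 representatives each. `ex_out/retained_otus.txt` then reads:

```
Rattus_norvegicus_syn
Gallus_gallus_syn
Saccharomyces_cerevisiae_syn
Dictyostelium_discoideum_syn
Oryza_sativa_syn
Zea_mays_syn
Plasmodium_falciparum_syn
Cyanidioschyzon_merolae_syn
# --- dereplication summary ---
# clades_dereplicated: 2
# otus_removed: 6
# category	rank	clade_size	retained	removed	support	median
# Metazoa	2	6	2	4	0.98	0.18
# Viridiplantae	2	4	2	2	0.92	0.195
```

The six-member Metazoa clade (support 0.98) keeps the two OTUs whose
basal-node-to-leaf path lengths straddle the clade median 0.18
(*Rattus* at 0.21, *Gallus* at 0.15); the four-member plant clade keeps
*Oryza* and *Zea*. The fungus, slime mold, apicomplexan and red alga are
each the sole member of their category, so they are untouched — taxonomic
breadth survives while OTU density drops from 14 to 8.
`ex_out/reference_tree.nwk` holds the corresponding cladogram and
`ex_out/removal_table.tsv` the same records as TSV.

The same run from the shell:

```sh
Rscript -e 'quit(status = cladetrim::cladetrim_main())' \
  --tree tree.nwk --taxonomy taxonomy.tsv --params params.tsv --out ex_out
```

(or use the installed `exec/cladetrim` script). Exit codes: 0 success,
2 usage error, 3 input validation error.

## File formats

* **Tree**: Newick; supports either as internal-node labels
  (`(A,B)0.97:0.1`, default) or bracket comments (`(A,B)[0.97]:0.1`),
  selected by `--support-style {label|comment}`.
* **Taxonomy**: `<otu_name>\t<rank1>;<rank2>;...`, `#` comments.
* **Parameters**: lines `threshold\t<float>`,
  `rule\t<category>\t<rank>\t<retain>`, `default\t<rank>\t<retain>`.
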