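---
title: "Anchoring draft scaffolds, detecting syntenic gene losses, and mapping losses onto a species tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring draft scaffolds, detecting syntenic gene losses, and mapping losses onto a species tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntanchor)
```

## The problem

A typical draft genome of a non-model species is a set of a few hundred
scaffolds, while a close relative may already have a chromosome-level
assembly. Three questions follow naturally, and this package answers each
with a small, well-specified procedure:

1. **Where does each scaffold belong?** Each scaffold is *anchored* to the
   reference chromosome on which most of its genes find their best BLAST
   hit, and classified by how cleanly it maps.
2. **Which genes did the draft-genome lineage lose?** A reference gene with
   no ortholog in the query is called a *syntenic loss* when its conserved
   neighbours are still adjacent in the query, leaving no room for it.
3. **On which branch of the species tree did each loss happen?** Given a
   gene x taxon presence/pseudogene/absence matrix and a rooted tree,
   Dollo parsimony assigns every loss to a branch.

The motivating use case is a catfish-style comparison: a scaffold-level
assembly (haploid chromosome number n = 30) anchored onto the 29
chromosomes of a related species, with known lineage-specific losses such
as the gadusol (sunscreen) biosynthesis genes *EEVS* and *MT-Ox*, and Hox
cluster losses shared with or distinct from zebrafish.

## Anchoring model

Let a scaffold carry $G$ annotated genes of which $H$ have a best-hit
assignment to some reference chromosome. Writing $v_c$ for the number of
genes assigned to chromosome $c$, the scaffold is anchored to
$\hat c = \arg\max_c v_c$ and classified

* **conserved** if $v_{\hat c} / H > 0.5$ — the majority criterion is
  *strictly* better than 50%, so an exact 50/50 split is not conserved;
* **rearranged** otherwise (its genes are dispersed over several
  chromosomes, indicating inter-chromosomal rearrangement since the common
  ancestor);
* **unplaced** if $H = 0$.

Ties at the top of the vote are broken to the lexicographically smallest
chromosome and flagged `ambiguous`, so the procedure is a deterministic
function of the hit set. The vote denominator is genes *with* assignments
by default (`denominator = "hit_genes"`); `"all_genes"` uses every
annotated gene instead. Both are exposed because the underlying criterion
("more than 50% of gene matches") can be read either way; the default is
the reading under which genes without hits carry no evidence.

The genome-wide summary totals bp per class and reports integer percent
shares of the classified (conserved + rearranged) bp, rounded by the
largest-remainder method so the two shares always sum to exactly 100. With
class totals of 417 Mb and 298 Mb this yields 58% / 42% of a 715 Mb
assembly. Scaffolds shorter than `min_len_bp` (default 1 Mb, the usual
display threshold for chromosome paintings; set 0 to call everything) are
excluded from calls and reported separately.

Best hits themselves are ranked by bitscore, then alignment length, then
lexicographic subject — a total order, so the reduction is invariant to
row order. Multiple HSPs of one gene against one chromosome are represented
by the best single HSP by default; `sum_hsps = TRUE` sums the pair's
bitscores first. Neither the source alignment tool's tie behaviour nor its
HSP handling is standardized, which is why both are explicit options here.

## Building hypothetical chromosomes

Within each chromosome, anchored scaffolds are ordered by the **median**
subject position of their voting genes — the median, not the mean, so a
minority of translocated genes cannot drag a scaffold out of place — and
oriented by the sign of the Spearman rank correlation between gene order
along the scaffold and subject position ($\rho \ge 0 \Rightarrow$ `+`).
Scaffolds with fewer than two informative genes default to `+` with
`low_confidence = TRUE`; zero correlation also defaults to `+` so output
is deterministic. The result is emitted as AGP 2.1 with 100 bp `U` gaps
(gap type `scaffold`), a conventional placeholder with no biological
meaning. Ordering and orientation are an extension beyond plain
anchoring: per-scaffold chromosome assignment needs only the vote, but a
usable pseudochromosome needs an order, so the rules above were chosen to
be robust, parameter-free and deterministic.

## Syntenic loss detection

For every reference gene with no query ortholog, the nearest flanking
genes *with* orthologs are sought within `max_flank_scan` (default 3)
genes on each side. A loss is called when both flank orthologs lie on one
query scaffold with at most `max_intervening` (default 0: strict
adjacency) unrelated query genes between them. The reported interval is
the query gap between the inner edges of the two flank orthologs —
deliberately only *reported*, because ruling out residual sequence
similarity inside the gap (e.g. by TBLASTN) is an alignment task outside
this package's scope. A run of $k$ adjacent lost genes yields $k$ calls
sharing one interval, matching how a jointly lost two-gene cluster such as
*EEVS*/*MT-Ox* is described. Flanks on different scaffolds give
`unresolved_split_flanks` (the same status covers flanks on one scaffold
separated by too many genes — a deliberate economy of states, documented
here because the two situations have different causes but the same
consequence: the interval cannot be interpreted); a missing flank gives
`unresolved_flank_missing`.

Ortholog mapping accepts either gene-level assignments (subjects are
reference gene IDs) or chromosome-level assignments, in which case a
query gene is matched to the reference gene whose span contains its
subject midpoint.

## Dollo census

Gene gain is assumed to happen once, at the root (the post-duplication
ancestor carried the full complement); only losses are inferred. Under
that assumption the minimum-loss placement for a gene is unique: one loss
on each **maximal clade whose leaves all lack the gene**. A gene absent
from every leaf is assigned a single loss on the root branch. Pseudogene
cells are mapped before inference: `as_absent` (default) treats a
pseudogene as lost — appropriate when asking when the functional gene
disappeared — while `as_present` treats it as retained, appropriate when
asking about sequence presence. The default matters for the bundled Hox
fixture: three genes are pseudogenes in zebrafish but deleted in catfish,
and only `as_absent` places their loss on the shared ancestral branch.

The shipped matrix (`inst/extdata/hox_presence_synthetic.tsv`) is a
synthetic reconstruction: the three branch-specific loss lists and the
pseudogene states are transcribed from the published comparison of the
catfish and zebrafish Hox clusters, and the shared intact complement is
filled with plausible cluster members so the per-taxon intact totals (51
catfish, 49 zebrafish — difference 2 = 5 − 3) are consistent with the
published counts. It is a worked example, not a curated dataset. Note the
published description is internally inconsistent about one zebrafish loss
(*C9a* vs *C9b* appear in different places); the fixture follows the
figure-legend list (*C9a*).

## The simulator and what it does (not) show

`simulate_genomes()` is the package's test bed. It builds a reference of
29 chromosomes x 200 evenly spaced genes (2 kb genes, 8 kb spacers) and
derives the second genome by reciprocal 10-gene block translocations,
one fission (n = 29 → n = 30), gene losses, pseudogenizations, and
fragmentation into scaffolds with geometric gene counts (mean 25),
breaking only in intergenic space. The hit table gives every surviving
gene one true hit (bitscore 500 ± 5) and noise at three rates chosen as
plausible for cross-species BLASTN of gene models: 5% of genes with no
hit (diverged or unassembled), 2% spurious extra hits (bitscore 50–300,
never outranking a true hit), 1% equal-bitscore paralog ties. Identical
configurations produce byte-identical outputs, and the ground truth
(per-gene origin, per-scaffold majority origin, true scaffold order,
loss/pseudogene sets, full event log) supports parameter-recovery tests.

What passing these tests shows: the procedures recover exactly what the
generative model planted, at the stated noise levels. What they do not
show: behaviour under nucleotide-level divergence, tandem duplication,
inversions, assembly chimeras or annotation error — none of which the
simulator models. The simulator is a correctness harness, not a realism
claim.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GFF3 and AGP are
  converted at the file boundary. Length is always `end - start`.
* All tie-breaks (vote ties, bitscore ties, ordering ties, zero
  correlation) resolve lexicographically or to `+`, so every output is a
  deterministic function of its input.
* Integer shares use largest-remainder rounding; ties in fractional part
  resolve by name order.
* Degenerate inputs: empty hit tables give empty assignments; scaffolds
  with no hit genes are `unplaced`; an empty call set is an error for the
  summary ("nothing to summarize") rather than a silent zero.
* Test problem sizes: the parameter-recovery suite runs the full
  29 x 200 study-scale genome (~5,800 genes); oracle-equivalence suites
  use 5–10 chromosomes and 30–60 genes per chromosome so brute-force
  recounts stay trivial; the monotone-degradation suite uses
  29 chromosomes x 60 genes over 4 translocation levels x 20 seeds.

## A worked run

```{r demo}
out <- file.path(tempdir(), "demo")
report <- run_demo(out, config = sim_config(seed = 1,
                                            hit_miss_rate = 0,
                                            spurious_hit_rate = 0,
                                            paralog_tie_rate = 0),
                   n_plant_losses = 5)
report$anchoring$accuracy_vs_truth
report$losses[c("planted", "recall", "precision")]
```

With zero noise, every scaffold anchors to its true chromosome and the
five planted losses are recovered at recall = precision = 1 — the
clean-data contract every stage is tested against.

## Limitations

* Anchoring is evidence-counting, not statistics: no significance is
  attached to a vote, and a 6/10 scaffold is "conserved" exactly like a
  10/10 one (the `top_fraction` column preserves the distinction).
* Loss detection cannot distinguish true loss from an assembly gap; the
  reported interval is the tool for downstream checks.
* The Dollo model excludes regain and horizontal acquisition by
  construction.
* Scaffold ordering assumes collinearity within chromosomes; within-
  scaffold rearrangement is reflected only in the orientation confidence.
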