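---
title: "Strain-level classification with assembly-driven database reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-level classification with assembly-driven database reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(strainsift)
```

## The problem

Strain-level read classification against a comprehensive bacterial
reference database faces two coupled obstacles: the database is too
large to map against efficiently, and it contains many near-identical
genomes among which individual long reads cannot discriminate. The
approach implemented here uses the sample's own assembly to shrink the
search space first: contigs aggregate the signal of thousands of reads,
so contig-to-database mappings identify a small candidate set of
references far more reliably than any single read can. Reads are then
classified against that reduced set.

The package operates entirely on mapping files (PAF, the minimap2
pairwise format) plus a taxonomy sidecar; it never touches sequence
data. Assembly, strain-separation estimation and mapping are left to
the dedicated tools for those jobs.

## Stage one: database reduction

Every contig alignment receives the harmonic-mean score
$H = 2\,N\,ml/(N+ml)$ of its exact match count $N$ and its mapping
length $ml = \max(\text{query span}, \text{target span})$. The harmonic
mean is deliberately pessimistic: a long alignment with poor identity,
or a near-perfect but tiny one, both score low. Scores are summed over
all alignments of a contig to a reference into $S(c, r)$, so split
alignments accumulate support.

Contigs mapping to a single reference are *unique*: their target enters
the reduced database directly. The ambiguous remainder is soft-clustered
by EM over the mixture
$P(c) = \sum_r P(c \mid r)\,P(r)$ with fixed conditionals
$P(c \mid r) = S(c,r)/\max_j S(c,r_j)$ and uniform initial priors
$P(r) = 1/g$. The E-step is Bayes' rule per contig; the M-step sums the
posteriors per reference and renormalizes them into the new prior. The
log-likelihood $\sum_c \log \sum_r P(c \mid r) P(r)$ is tracked each
iteration; iteration stops when it changes by less than `tol` (default
1e-6, absolute) or after `max_iter` (default 100) iterations.

Two numerical points deserve note:

* **M-step normalization.** Dividing the posterior column sums by the
  total number of mappings leaves the prior summing to (contigs /
  mappings) rather than 1, which breaks the probabilistic reading of the
  E-step. The default therefore renormalizes the update to total 1 —
  this is the standard mixture-weight maximum-likelihood update, and it
  makes the likelihood provably non-decreasing (a property the test
  suite checks numerically on every instance). The literal
  mapping-count denominator remains available via
  `em_step(..., literal_mstep = TRUE)` for comparison; it preserves the
  argmax structure of each posterior row but not monotonicity.
* **Degenerate inputs.** Contigs with all-zero scores are excluded with
  a warning; a contig mapped to one reference keeps posterior 1
  regardless of iteration count; an instance at a fixed point converges
  in one step.

Each contig is then classified to the species carrying the largest
summed posterior (ties: smaller species taxid, so the result is
deterministic), and the top (estimate + offset) references of that
species are retained per contig, ranked by posterior with ties broken by
summarized score and then reference id. The estimate is the contig's
collapsed-strain count — how many strains the assembler merged into the
contig, as reported by a strain-separation tool; contigs without an
estimate default to 1. The offset (default 2) is a safety margin: it
costs a handful of extra candidates per contig but protects recall when
the estimate is off by one or two. Two budget-free baselines,
`baseline_top_k(scores, 1)` and `baseline_top_k(scores, 3)`, bracket the
selection from below and above.

## Stage two: read classification

Read alignments are scored by the match ratio $S = N/ml \in (0, 1]$;
only the best alignment per (read, reference) pair is kept. A read whose
maximum is attained by exactly one reference is *unique*; ties make it
*non-unique*. The tie tolerance defaults to 0 — exact score equality —
because mapping scores of truly interchangeable placements are exactly
equal; a small positive tolerance is available when mapper rounding
splits genuine ties.

Reads are first pinned to a species by the best within-species score.
Exact cross-species ties (near-identical genomes filed under different
species) are resolved by a uniform draw from the tied species; the draw
uses one seeded generator consumed in sorted read-id order, so the
result is independent of input file order, and such reads are flagged
`species_tie_random`. Within each species, references sharing at least
one tied read are linked and the connected components form clusters;
every non-unique read is reassigned to its cluster's best-supported
member, the argmax of $M_i = U_i + N_i$ (unique + tied mapping counts).
The paper-level intuition is centroid-like: ambiguous reads flow to the
reference that unique evidence already supports. Ties on $M$ break by
larger $U$, then smaller id — a deterministic cascade chosen here
because the total count alone cannot separate two references that share
all their reads.

"Share many mappings" is operationalized as a minimum shared-read
threshold of 1 (`min_shared`), exposed as a parameter since the notion
is inherently qualitative; components are parameter-light and consistent
with per-cluster argmax reassignment.

## Abundances, post-clustering, evaluation

Primary abundance is the per-reference read count; the optional
length-normalized variant divides total assigned read bases by the
reference length (an approximate mean coverage), using the full read
length from PAF column 2 rather than the aligned span. For composition
comparisons the Bray–Curtis dissimilarity
$\mathrm{BC}(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ is computed
on raw read counts over the union of true and detected strains.

Because reference databases contain near-duplicate entries, an optional
post-clustering step builds, per species, a binary matrix of which reads
"strongly support" each reference — defined as attaining the read's
within-species best score, consistent with best-hit semantics elsewhere
— and clusters rows by DBSCAN over precomputed Jaccard distances with
eps = 0.9 and min_samples = 1. With min_samples = 1 DBSCAN reduces
exactly to connected components of the eps-threshold graph; the
implementation is a generic density clustering over a distance matrix,
and the test suite verifies the equivalence against an independent
component search on random support matrices. Each cluster is reported
under its best-supported member. Clustering is deliberately
species-scoped: near-duplicates filed under different species are not
merged, reproducing the known failure mode rather than papering over it.

Evaluation follows simulator semantics: an unclassified read whose
Badread label is `random` or `junk` is a true negative, any other
unclassified read a false negative; a classified read is a true positive
when it lands on the expected strain (or, in cluster mode, in the
expected strain's cluster) and a false positive otherwise. Chimeric
reads are scored against their single recorded source; when
unclassified they count as false negatives, the literal reading of the
label rule.

## What the synthetic generator does and does not emulate

`generate_community()` synthesizes the pipeline's *inputs* at the
mapping level: PAF records whose match counts and spans realize a
controlled score structure. The default community holds a 50-genome
database with 8 present strains (4 species × 2 strains, 200 reads per
strain, 3 contigs per strain); each present species carries 3 additional
absent "decoy" references, and the rest of the database is filler
species. Contig scores for a true strain dominate same-species decoys by
a margin shrinking with the `similarity` parameter (default 0.5, a
moderate within-species similarity); 20% of reads are emitted as exact
best-score ties between sibling strains (`tie_fraction = 0.2`),
emulating reads from conserved regions; 1% each of junk, random, and
chimeric reads follow the Badread simulator's default proportions. Read
lengths are log-normal around 5 kb, typical of nanopore metagenomes.

What this shows: that scoring, EM selection, reassignment, clustering
and evaluation interlock correctly, with ground truth known by
construction. What it does not show: robustness to real alignment
artifacts (split alignments from structural differences, repeat-induced
multi-species mappings, coverage bias, chimera breakpoints), since
scores are synthesized rather than derived from sequences. Passing tests
certify the algorithmic contract, not end-to-end accuracy on real data.

Problem sizes throughout the tests (a 50-reference database, a few
thousand reads, EM oracle instances of up to 6 contigs × 5 references)
were chosen so the full suite exercises every code path in well under a
minute while remaining large enough for the properties of interest —
recall of every true strain, conservation of read counts, equivalence
with brute-force implementations — to be non-trivial.

## Known limitations

* The EM treats the conditional matrix as fixed; it reassigns contigs
  but never re-estimates the score model.
* Reference selection assumes the species call is right; a contig
  assigned to the wrong species cannot recover its true strain.
* Cross-species near-duplicates are resolved by a seeded random draw,
  not by evidence.
* The collapsed-strain estimate is trusted as given; underestimates
  beyond the offset cost recall by design.

## End-to-end run

```{r pipeline}
b   <- generate_community(community_spec(seed = 1))
red <- reduce_database(b$contig_paf, b$taxonomy, b$estimates)
red

cls <- classify_reads(filter_paf_targets(b$read_paf, red$refs),
                      b$taxonomy, seed = 1, read_ids = b$truth$read_id)
sup <- build_support_vectors(attr(cls, "read_scores"), b$taxonomy,
                             attr(cls, "species_of_read"))
clu <- density_cluster(sup, stats = attr(cls, "reference_stats"))

score_reads(cls, b$truth)                  # strain level
score_reads(cls, b$truth, clusters = clu)  # cluster level
```
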