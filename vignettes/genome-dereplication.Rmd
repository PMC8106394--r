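---
title: "Dereplicating prokaryotic genome collections with k-mer set distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dereplicating prokaryotic genome collections with k-mer set distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derepkit)
library(dplyr)
```

## The problem

Public genome repositories hold tens of thousands of near-identical
prokaryotic assemblies: thousands of *Escherichia coli* or *Mycobacterium
tuberculosis* strains next to a single representative of an entire candidate
phylum. Any broad comparative or phylogenomic analysis must first
*dereplicate* such a collection — reduce it to one high-quality
representative per cluster of similar genomes — while preserving as much
deep phylogenetic diversity as possible. derepkit implements an
alignment-free, iterative dereplication pipeline that scales by
divide-and-conquer and selects representatives by explicit, reproducible
quality criteria.

## Genome distances from k-mer dictionaries

Each genome is reduced to the set of its distinct nucleotide k-mers — its
"dictionary" of words. Multiplicities are deliberately ignored: two genomes
are compared by which words they contain, not how often. Windows containing
any non-ACGT character are skipped entirely, so ambiguity codes neither
invent nor expand words.

Two similarities are available on dictionaries $A$ and $B$:

* the **Jaccard index**, $JI(A,B) = |A \cap B| / |A \cup B|$, and
* the **Identical Genome Fraction**,
  $IGF(A,B) = |A \cap B| / \min(|A|, |B|)$,

with the clustering distance defined as $1 - $ similarity in both cases.
The IGF replaces the union by the size of the smaller dictionary, giving a
containment-style similarity that does not punish a genome for being
partial or reduced (MAGs, streamlined endosymbionts). Note that
$IGF \ge JI$ always, with equality exactly when the two sets coincide or do
not intersect at all — under strict containment the IGF saturates at 1
while the JI does not.

**Choice of k.** The default is $k = 12$. The reasoning is a vocabulary
argument: with $k = 11$ only $4^{11} \approx 4.2$ million words exist, and
large bacterial genomes approach that bound, which collapses all pairwise
similarities; $4^{12} \approx 16.8$ million words leaves ample headroom
(the largest observed dictionaries stay well below half of it), while
$k = 13$ mainly buys computing time and species-level over-specificity.
`kmer_vocabulary_size()` returns these counts analytically, and the test
suite verifies them by enumeration at small k.

**Strandedness.** For finished genomes, strand-specific k-mers are kept
(gene orientation is informative). For draft or scaffold-stage assemblies
the `canonical` option replaces each window by the lexicographic minimum of
itself and its reverse complement, making comparison strand-insensitive.
Canonical dictionaries are about half the size — exactly $4^k/2$ classes
for odd $k$, $(4^k + 4^{k/2})/2$ for even $k$ because palindromes are their
own reverse complement — which is worth remembering when distinguishing
very large genomes.

**Exact versus sketched.** The exact engines intersect full dictionaries.
The `sketch_ji` engine instead stores, per genome, the $s$ smallest values
of a seeded 64-bit hash over the dictionary (a bottom sketch) and estimates
the JI from the merged bottom-$s$ of two sketches: among the $s$ smallest
hashes of the union, the fraction present in both sketches is an unbiased
estimate of the JI with standard error $\approx \sqrt{j(1-j)/s}$. The hash
(FNV-1a with a splitmix64 finalizer, seed recorded in the sketch) is
platform-independent, so sketches are reproducible artifacts. Whenever both
dictionaries fit inside the sketch the estimate is exact. The estimated JI
can also be converted to an approximate per-base mutation distance with
`mash_distance()`, $D = -\tfrac{1}{k}\ln\frac{2j}{1+j}$, capped at 1 when
$j = 0$ (the logarithm is undefined there) and 0 when $j = 1$.

## Which genome represents a cluster

Representatives should be the *best* genomes, not arbitrary centroids.
Every genome gets a global quality rank before any clustering happens,
by an equal-weight sum of per-metric ranks:

| metric | direction | source |
|---|---|---|
| `quast.N.per.100.kbp` | lower better | computed (assembly) |
| `quast.largest.contig.ratio` | higher better | computed (assembly) |
| `annot.certainty` | higher better | computed (proteome descriptions) |
| `42.contam.perc` | lower better | ingested (marker-gene contamination) |
| `42.added.ali` | lower better | ingested (marker-gene contamination) |

For each metric a ranking is produced across all genomes (rank 1 = best;
ties get the average of the spanned positions) and the totals are summed
without weights. Exact total ties are broken by accession order — the
choice is arbitrary but must be deterministic, because the clustering
outcome depends on the processing order. Any numeric manifest column can be
used in a custom `ranking_spec()`; the direction of `42.added.ali` is
treated as a contamination indicator (lower better), a documented
assumption that the user can flip. A genome missing a required metric is
excluded from the run with a logged reason — in particular, genomes without
predicted proteomes are discarded whenever annotation metrics are part of
the ranking. Priority lists short-circuit the order: priority genomes move
to the head (preserving their relative ranks), so model organisms survive
dereplication as representatives without disabling it.

The supporting per-genome metrics are the standard assembly statistics
(N50/N75 are the lengths of the contig at which the descending cumulative
length first reaches 50%/75% of the assembly, L50/L75 their 1-based ranks;
">1 kbp" and ">500 bp" totals use strict cutoffs; a cumulative sum landing
exactly on the percentage counts as reached), annotation *certainty*
(fraction of proteins whose description does not contain an uncertainty
word — default vocabulary `probable, putative, hypothetical, unknown,
uncharacterized, predicted, possible`, configurable, matched
case-insensitively on whole words) and *completeness* (fraction of proteins
with a non-blank description), plus an SSU rRNA chimera screen: the
genome's SSU sequences are clustered greedily at a species-delineation
identity (97.5% by default, 99% supported), and a genome whose SSUs fall
into two or more clusters is flagged as likely chimeric. Identity is
computed by global alignment (match +1, mismatch −1, linear gap −2) over
the shorter sequence — the identity definition of greedy incremental
clusterers. A size-range filter (100 kbp – 15 Mbp by default) removes
assemblies too small to be complete or too large to be clean.

## Greedy clustering inside packs

Within a pack, genomes are processed best-rank-first. The first genome
founds cluster 1; each following genome scans clusters in creation order
and joins the first one where it finds a genome at distance strictly below
the threshold, founding a new cluster if none accepts it. Because of the
processing order, every cluster's founder is automatically its best-ranked
member — the representative. Two modes differ in what is compared:

* **loose** — compare against every member (founder first, then join
  order). This is pure single-linkage: a genome joins as soon as *any*
  member is close enough, which compensates for representatives sitting at
  the "outskirts" of their cluster, but lets one intermediate genome bridge
  two groups.
* **strict** — compare against founders only. Fewer comparisons, and the
  bridging pathology is suppressed: in the 3-genome chain
  $d(1,2) = d(2,3) = 0.1$, $d(1,3) = 0.9$ at threshold 0.2, loose mode
  returns one cluster, strict mode two.

The scan order (clusters by creation, members by join order, first hit
wins) is fixed; it is one of several defensible conventions, and pinning it
makes runs bit-reproducible. The join condition is a strict inequality, so
threshold 0 yields all singletons. Distances are computed lazily and
memoized across packs and rounds, and the per-pack distance-call counter
makes the loose/strict cost difference measurable.

## The divide-and-conquer engine

Comparing all genomes at once is quadratic and hopeless at repository
scale. Instead each round: (1) sorts the surviving genomes either by their
lineage string (taxonomic sort — related genomes share packs, so most
merging happens immediately) or randomly (seeded, reshuffled each round);
(2) cuts the list into packs (200 genomes by default); (3) clusters each
pack independently — packs are independent by construction, which is the
parallelization contract: results cannot depend on pack scheduling; and
(4) merges the pack representatives into the next round's input. Membership
is composed transitively, so every input genome maps to its final
representative.

The engine stops when any active criterion fires: a maximum number of
rounds (default 20; taxonomic-sort runs typically converge in 2–5), a
ceiling on the representative count (off by default), or a per-round
*clustering ratio* — the percentage of genomes removed during the round
relative to those entering it — falling below a minimum (default 0.1%). A
round that merges nothing is a fixed point (no later round could merge
anything either) and always stops the engine. Defaults are engine policy:
they guarantee termination while leaving each criterion user-settable.

Two structural properties hold by construction and are asserted in the
tests: representative sets are nested across rounds (hence the count is
non-increasing), and with a single pack covering all genomes and one round
the engine is identical to plain greedy clustering of the ranked list.
Smaller packs can only fragment clusters — genomes separated into different
packs cannot merge that round — so shrinking the pack size never decreases
the final representative count; the cure is larger packs (quadratically
slower) or more rounds.

## Reporting

`diversity_report()` groups the original genomes by final representative
and reports, at a chosen lineage rank (default the second field,
the phylum of an NCBI-style `Bacteria;<phylum>;...` string): the number of
groups, the number of taxa with at least one representative ("diversity"),
the **redundancy index** RI = groups / taxa (lower is better — an RI of 4
means four representatives per represented phylum on average), and purity:
a group is **mixed** when its members span two or more taxa at that rank
(unclassified members are ignored).

## The synthetic benchmark

`generate_family_set()` builds the ground-truthed test collection used
throughout the package: one random root sequence is diverged into
`n_groups` ancestors at a between-group substitution rate `mu_b`, and each
group's members are drawn from their ancestor at a within-group rate
`mu_w`. Defaults are 10 groups × 5 members, 50 kb genomes, `mu_w = 0.01`,
`mu_b = 0.3` — within-group pairs then differ at ~2% of sites (two
independent draws at 1%), a strain-level divergence, while between-group
pairs are essentially unrelated at the k-mer level, a phylum-like gap.
Lineage strings encode the group labels so taxonomic sorting and diversity
reporting are testable end to end; proteomes with exact uncertain/blank
description fractions, SSU sets (optionally chimeric two-species pairs) and
plausible external contamination columns complete the manifest. Optional
chimeras concatenate halves of two ancestors — a deliberate caricature of
the bridge genomes that defeat pure single-linkage.

**Why threshold 0.06 in the recovery tests.** At `k = 7` the vocabulary has
$4^7 = 16384$ words while a 50 kb genome offers ~50,000 windows, so every
genome covers a fraction $c \approx 1 - e^{-50000/16384} \approx 0.95$ of
the whole vocabulary. Two unrelated genomes then share most of their
dictionaries by saturation alone: the between-group JI is approximately
$c/(2-c) \approx 0.91$ (distance ≈ 0.09), while within-group pairs at ~2%
divergence retain JI ≈ 0.96–0.97 (distance ≈ 0.03–0.04). The recovery
threshold 0.06 is the midpoint of that analytically predicted gap. This
also illustrates the production-scale k choice: a too-small vocabulary
compresses all distances toward 0.

What the generator does *not* emulate: indels, rearrangements, horizontal
transfer, GC skew, repeat structure, or assembly artifacts other than
scaffolding Ns. Substitution-only mutation keeps the expected k-mer overlap
analytically tractable. Passing the recovery tests therefore demonstrates
that the machinery — distances, ranking, packing, clustering, iteration,
bookkeeping — behaves exactly as specified on separable data; it does not
certify threshold choices on real repository data, where divergence is
continuous and the loose/strict and JI/IGF trade-offs become real
decisions.

## Problem sizes in the test suite

The tests run the exact engines at small k (3–7), where full enumeration
and brute-force set algebra serve as oracles: 1,000 random dictionary pairs
against set-algebra oracles, 500 random well-separated distance matrices
against a connected-components oracle, 20 seeded replicates of the
10-group benchmark for parameter recovery, and 1,000 sketch trials at
$s = 1000$. These sizes give the property checks real coverage while the
whole suite stays in the minutes range on one CPU.

## A worked example

```{r example, eval = FALSE}
fs <- generate_family_set(seed = 1, with_ssu = FALSE)  # 10 groups x 5 genomes
cfg <- derep_config(k = 7, threshold = 0.06, pack_size = 10,
                    size_filter = FALSE)
res <- run_dereplication(fs$manifest, cfg)
glance(res)
diversity_report(res, fs$manifest)
membership_purity(res, fs$truth)
autoplot(res)
```

## Known limitations

* Equal weights only in the ranking; weighted or learned scores are an
  extension point, not implemented.
* No average/complete linkage, centroid updating or reassignment passes —
  the greedy pass is single-shot by design.
* SSU prediction and marker-gene contamination estimation are upstream
  tools' jobs; their outputs are inputs here (manifest columns and SSU
  FASTA files).
* The exact engines hold each genome's dictionary in memory as a character
  set; at `k = 12` and repository scale the sketch engine is the practical
  choice.
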