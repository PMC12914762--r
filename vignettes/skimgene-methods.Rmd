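---
title: "Recovering target genes from genome-skimming reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering target genes from genome-skimming reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimgene)
```

## The problem

Genome skimming — shallow (roughly 1–10×) whole-genome shotgun sequencing —
is now the cheapest way to collect genomic data for non-model organisms, but
it rarely supports whole-genome assembly. For phylogenomics one usually only
needs a panel of target loci (single-copy nuclear genes, Angiosperms353-style
markers), and those can be recovered directly from raw reads when a set of
reference sequences from related taxa is available. The difficulty is that
available references are often quite divergent from the sample (several
percent per site), and that shallow data mixes true signal with sequencing
errors and library artefacts such as inverted chimeras.

`skimgene` implements a reference-guided recovery pipeline for this setting:

1. **Baiting** — assign raw reads to genes via shared k-mers with the
   references, using a compact two-level k-mer→gene-set multimap.
2. **Fine-grained read selection** — per (read, gene), call the orientation
   of every k-mer match and apply three statistical tests to discard reads
   with inversions or unresolvable structure; remove discordant pairs; then
   re-filter iteratively with an increasing k-mer size under a coverage
   guard.
3. **Adaptive assembly** — pick a per-gene assembly k-mer size from an
   anchor-score profile, then walk a weighted de Bruijn graph seeded and
   oriented by the reference.
4. **Quality control** — trim contigs against the reference with a local
   alignment, and filter paralogs by pairwise divergence in an alignment.

A self-contained simulation harness generates the benchmark this package is
validated on: genes evolved along a ten-taxon tree, references mutated to a
chosen divergence, and paired-end reads with sequencing errors.

## The k-mer index

References are decomposed into overlapping k-mers (2-bit packed, up to
k = 31 in a 64-bit word), and each k-mer maps to the *set* of gene
identifiers containing it. The storage contract is that of a deduplicated
multimap with amortised constant-time insert/membership and output-linear
set retrieval, with **no false positives**: a membership "yes" is always a
real insertion. K-mers shared by more than `capacity_bound = 1024` genes are
blacklisted — such k-mers carry no filtering information — and identical
gene sets are interned so that k-mers sharing a set share one stored
instance. Only forward-strand reference k-mers are stored; queries probe a
k-mer and its reverse complement, which halves memory and keeps strand
information recoverable. K-mer windows containing ambiguous bases are
skipped entirely, since 2-bit encoding has no slot for ambiguity.

The compact quotient-block layout with cuckoo displacement that motivates
this contract is a performance detail, not a semantic one; this
implementation backs the blocks with deduplicated sorted sets, under which
insertion never fails (the failure counter the interface exposes is
honestly zero) and all the contractual properties are testable directly.

## Orientation screening

For a read assigned to gene *g* and a small test k (default 17), every
k-mer window is classified: **F** if the k-mer occurs in the reference and
its reverse complement does not, **R** in the converse case, ignored
otherwise. A genuine read from one strand yields a long block of same
direction calls; inverted chimeras yield alternating blocks.

*Runs test.* With `n1` F-calls, `n2` R-calls and `r` runs, the
Wald–Wolfowitz statistic uses

$$E(R) = \frac{2 n_1 n_2}{n_1+n_2} + 1,\qquad
\sigma^2 = \frac{2 n_1 n_2\,(2 n_1 n_2 - n_1 - n_2)}{(n_1+n_2)^2 (n_1+n_2-1)}$$

and a read is accepted only when \(z = (r - E(R))/\sigma\) falls in the
lower tail at significance \(10^{-5}\) — i.e. when directionality is far
more autocorrelated than random. Reads matching in a single direction
(`n1 = 0` or `n2 = 0`) bypass this test: it is undefined there, and such
reads are exactly the unambiguous majority.

*Longest-run test.* The expected longest run of a fair binary sequence of
length \(n\) is very accurately \(E_n(L) = \log_2 n - 0.6676\) (the
oscillating correction term is below \(10^{-6}\) and is absorbed into the
constant). A direction qualifies when its longest run exceeds
\(E_n(L) + 4\); treating each of the \(E(R)\) expected runs as an
independent geometric sample gives the closed-form lower bound

$$P(L \le E_n(L)+4) \gtrsim 1 - 0.5^{E_n(L)+5}\, (n/2+1),$$

which `longest_run_bound()` evaluates; it already exceeds 0.95 at
\(n = 2\) (0.95040) and increases with \(n\), so the threshold rejects the
random-direction null with at least 95% confidence for every \(n \ge 2\).
Reads with no qualifying direction are removed; one qualifying direction
orients the read.

*k-mer identity test.* Reads with long runs in *both* directions may still
be genuine (e.g. a small transposon inverted relative to the reference).
The reference-match proportions \(p_1, p_2\) of the two regions are
compared with a two-proportion z-score; only a significant asymmetry
(|z| > 1.96) resolves the orientation toward the more reference-similar
region, otherwise the read is unresolvable and removed.

Salvaged mates — reads added to a gene only because their pair matched —
carry no k-mer evidence of their own, so they inherit the opposite
orientation of their accepted mate (FR library geometry) rather than being
pushed through tests that would vacuously remove them. Pairs accepted in
the *same* orientation on a gene, or pairs whose other mate was removed as
ambiguous, are dropped as discordant.

*Iterative re-filtering.* After screening, each gene's read set is
re-filtered at increasing k (default `kf, kf+4, …` capped at 31, so the
schedule is empty when `kf` is already 31). If the coverage estimate
(retained bases over reference length) drops below a floor (default 2×),
the last step is reverted and filtering stops — the returned set is never
empty. On clean simulated data the three tests remove well under 1% of
reads; their value lies in pathological libraries, not typical ones.

## Parameter calculation

The filtering k-mer size comes from the read acquisition rate

$$p(k) = 1 - \bigl(1 - (1-v)^k\bigr)^{l_r - k + 1},$$

the probability that a read of length \(l_r\) shares at least one
mutation-free k-mer with a reference at per-site divergence \(v\) (windows
treated as independent). `compute_kf()` returns the largest
\(k \in [17, \min(31, l_r)]\) with \(p \ge 0.99\), relaxing once to
\(p \ge 0.95\), and errors out otherwise — shorter k-mers than 17 produce
too many spurious hits to be useful. Note \(p(k)\) is an optimistic
estimate at high divergence (real mismatches cluster windows together),
so baiting recall degrades gracefully rather than sharply as divergence
grows past the design point.

Two further thresholds are package policy (the source material names them
but not their formulas), reported with provenance notes by
`recommend_params()`:

* `retention_length = max(lr, 0.2*lg)` — a trimmed overhang may never
  exceed a read length or a fifth of a typical gene;
* `max_difference = min(3v + 0.02, 0.5)` — the expected sample-to-sample
  divergence in an alignment is roughly twice the sample-to-reference
  divergence; the policy adds headroom for alignment noise and caps at 0.5;
* `min_identity = max(1 - 2v, 0.6)` for trimming, same reasoning.

## Adaptive k and the weighted walk

**Anchor score.** An anchor k-mer occurs exactly once in a read and also in
the reference; the first k-mer of each consecutive anchor run is a *unique*
anchor, and runs longer than `run_cap` (default 64) contribute one extra
unique anchor per cap-length segment, so very long exact matches outvote
coincidental overlaps. The score \(s = kN/(l_r - k + 1)\) is anchored bases
normalised by the number of k-mers in the read. `select_k()` averages
\(s\) over a read sample for each odd candidate \(k \in \{17,\dots,31\}\)
and picks the **largest k whose mean score is at least half the maximum** —
sacrificing the shortest anchors buys specificity in repeats and against
paralogs, while keeping at least half of the anchored evidence.

**Graph and walk.** Nodes are canonical k-mers (minimum of code and
reverse-complement code; odd k so no k-mer is its own reverse complement)
weighted by read multiplicity, with reference k-mers marked. Assembly seeds
at the heaviest reference-marked node, orients it to the reference strand,
and extends greedily both ways, always taking the heaviest eligible
successor; ties break toward reference-marked nodes, then to the
alphabetically smallest base, making the walk fully deterministic. A node
is eligible if unused and its weight reaches `min_weight` (default 2) —
**or** if it is reference-marked with any read support at all: one read in
exact agreement with an independently derived reference cannot be a
sequencing error, and this reference-confirmation rescue bridges the
single-coverage k-mer gaps that otherwise fragment contigs at
moderate depth. Since every node comes from reads, contigs report the
sample's alleles, never reference-only bases.

A flat `min_weight = 2` (rather than dropping to 1 at low depth) is a
deliberate accuracy choice: weight-1 unconfirmed nodes are dominated by raw
read errors (a 150 bp Q20 read carries 1.5 errors on average), and
admitting them trades error-free short contigs for longer contaminated
ones. At 1× the output is short but clean, which matches the intended
quality profile.

**Soft boundary.** The finished walk is trimmed to at most
`soft_boundary` bases (default half a read length) beyond its outermost
reference-anchored node. Trimming the finished walk — rather than stopping
extension at a distance from the last anchor — matters: at divergence 0.05
and k = 31 the expected gap between reference-matching k-mers inside a
gene can exceed the boundary, and a stop rule would truncate mid-gene.
Unanchored walks are not emitted.

## Trimming and paralog filtering

`retention_trim()` aligns each contig to its reference with an internal
affine-gap local aligner (match +1, mismatch −2, gap open 5, gap extend 2;
scores verified against `Biostrings::pairwiseAlignment`), keeps the aligned
block, and discards contigs whose unaligned overhang exceeds the retention
length or whose aligned identity falls below the minimum — this removes
soft-boundary spill-over and chimeric flanks before evaluation.
`divergence_filter()` operates on a pre-aligned set (the package does not
run multiple sequence alignment itself): pairwise divergence is mismatches
over shared non-gap columns, and the sequence with the largest mean
divergence is removed iteratively until the maximum pairwise divergence
reaches the threshold, which is exactly the post-condition it guarantees.

## The simulation harness

`simulate_genes()` evolves independent 1000 bp genes under GTR with equal
base frequencies along a committed ten-taxon tree (tips A–I ingroup, J
outgroup, unequal branch lengths; `inst/extdata/ten_taxon_tree.nwk`). The
tree's depths were drawn once and versioned: ingroup tip-to-tip distances
of roughly 0.02–0.05 and an outgroup distance near 0.06 substitutions/site
keep the *realised* reference divergence close to its nominal value while
leaving clear phylogenetic signal in 1000 bp. With the default equal
exchangeabilities the process is Jukes–Cantor-like, giving the closed-form
p-distance `expected_p_distance()` used as the simulation oracle.

References are built per gene by mutating a source sequence at the nominal
divergence, each site independently to a uniformly chosen different base.
The default source is the per-column majority consensus of the ten
standards: it sits near the centre of the tree, so every taxon sees a
reference at about the nominal divergence — matching the idea of a single
divergence "level" per benchmark. A `random_taxon` mode instead mutates
one tip's standard, which adds that tip's tree distance for all other taxa
and is the harder, asymmetric variant.

`simulate_reads()` draws fragments uniformly (normal insert,
350 ± 50 bp by default — typical Illumina paired-end geometry), sequences
both strands, and injects independent per-base substitution errors at 1%
(Q20). The pair count is `round(coverage × genome/(2 × 150))`. What this
generator deliberately does **not** emulate: indel errors, quality-score
gradients along reads, GC-coverage bias, duplicated or organellar
sequence, and real intron/exon structure. Passing benchmarks here
demonstrates the pipeline's statistical machinery and assembly logic under
controlled divergence and depth, not robustness to every artefact of real
libraries.

## Evaluation scheme

Each recovered sequence is compared to its taxon's gold standard:
identity and coverage come from an ends-free alignment (an exact substring
short-circuits to identity 100), and `count` is the number of taxa with a
recovery for that gene. Levels: **L1** identity 100, coverage 50–100%
(closed at 50), count 7–10; **L2** identity 100, coverage < 50%, count
7–10; **L3** identity 100, count ≤ 6; **L4** any substitution or indel.
The overall mismatch rate is total erroneous bases over total recovered
length. `run_benchmark()` packages simulate → recover → classify for one
coverage/divergence setting; `scripts/acceptance.R` runs the full grid
(200 genes, coverages {1, 2, 5, 10}×, divergences {0.05, 0.1}) — problem
sizes chosen so the whole grid completes in minutes on one core while
keeping multinomial noise on the reported proportions near a percentage
point.

## Numerical and degenerate-input choices

* Runs-test tail and thresholds are computed in double precision;
  comparisons are strict as specified (≤ for the lower tail, > for run
  thresholds), and `qnorm` supplies the normal quantile.
* Zero-variance runs statistics (e.g. `n1 = n2 = 1`) and single-direction
  reads bypass to the longest-run test; degenerate identity-test
  denominators (both proportions 0 or 1) remove the read.
* `encode_kmer()` returns doubles and therefore stops at k = 26 (the exact
  integer range of a double); all internal paths are 64-bit and support
  k ≤ 31, exchanging k-mers as strings at the R boundary.
* Empty read sets, empty baiting results, and genes without anchored seeds
  produce empty-but-well-formed results (`recovered = FALSE`), never
  errors; an empty reference or a zero-length reference is an error.
* All randomness flows through R's RNG: a single seed reproduces gene
  simulation, reference mutation, read simulation, and therefore the whole
  pipeline byte-for-byte.

## Known limitations

* Intron-containing genes assembled against exonic (e.g. transcriptome)
  references remain out of reach: reads spanning exon boundaries carry
  k-mers absent from the reference, and the walk stops there.
* The acquisition-rate formula treats k-mer windows as independent, so at
  high divergence (≳ 0.15) the chosen `kf` is optimistic and baiting
  recall falls below the nominal rate.
* The paralog filter requires an externally produced alignment and removes
  whole sequences; it does not detect within-sequence chimerism.
* Coverage estimates in re-filtering use retained bases over reference
  length, which overestimates coverage when reads pile up on a fragment
  of the gene.
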