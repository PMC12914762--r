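# skimgene

Reference-guided recovery of target genes from genome-skimming reads.

Genome skimming — shallow (~1–10×) whole-genome shotgun sequencing — is the
cheapest route to genomic data for non-model organisms, but it cannot
support whole-genome assembly. For phylogenomics you usually need only a
panel of loci (single-copy nuclear genes, Angiosperms353-style markers),
recoverable directly from raw reads given reference sequences from related
taxa. `skimgene` is for researchers doing exactly that, including when the
only available references are several percent divergent from the sample.

The pipeline:

1. **k-mer baiting** — reads are assigned to genes via shared k-mers with
   the references, using a compact two-level k-mer → gene-set multimap
   (forward strand stored; both strands probed; no false positives;
   promiscuous k-mers beyond 1024 genes blacklisted).
2. **Fine-grained read selection** — per k-mer orientation calls (F/R) are
   screened with a Wald–Wolfowitz runs test
   (accept only when `z = (r − E(R))/σ` is in the lower tail at `1e-5`),
   a longest-run test against the threshold `E_n(L) + 4` with
   `E_n(L) = log2(n) − 0.6676`, and a two-proportion k-mer identity test
   (`|z| > 1.96`) for reads with long runs both ways; discordant pairs are
   removed, then reads are re-filtered at increasing k under a coverage
   floor with revert-on-drop.
3. **Adaptive assembly** — the per-gene assembly k maximises k subject to
   the anchor score `s = kN/(lr − k + 1)` staying above half its maximum;
   contigs come from a greedy, fully deterministic walk on a weighted de
   Bruijn graph seeded and oriented by the reference, trimmed to a soft
   boundary beyond the outermost reference-anchored node.
4. **QC** — parameter calculation from the read acquisition rate
   `p = 1 − (1 − (1−v)^k)^(lr−k+1)` (largest `k ∈ [17, 31]` with
   `p ≥ 0.99`, falling back to `0.95`, else an error), local-alignment
   trimming against the reference, and iterative pairwise-divergence
   filtering of paralogs.

A self-contained simulation harness (genes evolved under GTR along a
ten-taxon tree, references mutated to a chosen divergence, paired-end Q20
reads) generates the benchmark and classifies recovered sequences into
quality levels L1–L4 (identity / coverage of the true sequence / per-gene
taxon count / presence of errors).

## Worked example

```r
library(skimgene)

# simulate a small benchmark: 5 genes on the ten-taxon tree,
# references at 5% divergence, 10x paired-end reads for taxon C
set.seed(1)
genes <- simulate_genes(5, length = 1000, seed = 11)
refs  <- build_reference_set(genes, divergence = 0.05, seed = 12)
pr    <- paired_reads(simulate_reads(concat_genome(genes, "C"), coverage = 10, seed = 13))

res <- mine_genes(pr$reads, refs, mate = pr$mate, v = 0.05, d = 10)
res$status[, c("gene", "n_baited", "ka", "longest", "recovered")]
#>       gene n_baited ka longest recovered
#> 1 gene0001       34 31     454      TRUE
#> 2 gene0002       68 31     601      TRUE
#> 3 gene0003       80 31     561      TRUE
#> 4 gene0004       82 31     970      TRUE
#> 5 gene0005       66 27     793      TRUE

q <- classify_quality(data.frame(gene = res$best$gene, taxon = "C",
                                 seq = res$best$seq), genes)
q[, c("gene", "identity", "coverage", "level")]
#>       gene identity coverage level
#> 1 gene0001      100     45.4    L3
#> 2 gene0002      100     60.1    L3
#> 3 gene0003      100     56.1    L3
#> 4 gene0004      100     97.0    L3
#> 5 gene0005      100     79.3    L3
```

All five genes are recovered with `identity = 100` (no substitution or
indel errors); `coverage` is the fraction of the true gene covered, which
grows with depth and read luck per gene. `level` is `L3` here only because
a single taxon was sequenced (`count = 1`); running all ten taxa promotes
complete error-free recoveries to L1/L2. Parameters came from
`recommend_params(v = 0.05, lr = 150, lg = 1000, d = 10)`: filtering k-mer
`kf = 31`, retention length 200 bp, maximum difference 0.17.

A thin command-line wrapper is installed at
`system.file("scripts", "skimgene", package = "skimgene")` with
subcommands `index`, `mine`, `params`, `simulate`, `evaluate`.

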