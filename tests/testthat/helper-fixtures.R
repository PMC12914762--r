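# Shared fixture builders: everything is generated in code at test time.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Error-free reads tiling a sequence on both strands.
tiling_reads <- function(seq, read_len = 150, step = 15) {
  starts <- seq(1, nchar(seq) - read_len + 1, by = step)
  fwd <- substring(seq, starts, starts + read_len - 1)
  c(fwd, revcomp(fwd))
}

# A tiny two-gene benchmark: standards, references, reads for one taxon.
mini_benchmark <- function(n_genes = 2, coverage = 10, divergence = 0.05,
                           taxon = "C", seed = 77, p_err = 0.01) {
  set.seed(seed)
  genes <- simulate_genes(n_genes, length = 1000, seed = seed)
  refs <- build_reference_set(genes, divergence, seed = seed + 1)
  genome <- concat_genome(genes, taxon)
  rs <- simulate_reads(genome, coverage, p_err = p_err, seed = seed + 2)
  pr <- paired_reads(rs)
  list(genes = genes, refs = refs, genome = genome, reads = pr$reads,
       mate = pr$mate, taxon = taxon)
}
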