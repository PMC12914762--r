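#' The ten-taxon benchmark species tree
#'
#' Reads the committed fixture tree: ten taxa `A`--`J` with unequal branch
#' lengths (substitutions/site), `A`--`I` forming the ingroup and `J` the
#' outgroup. Branch lengths were drawn once and versioned with the
#' package, so every simulation shares the same topology and depths.
#'
#' @return an `ape::phylo` tree.
#' @export
default_species_tree <- function() {
  path <- system.file("extdata", "ten_taxon_tree.nwk", package = "skimgene")
  tr <- ape::read.tree(path)
  stopifnot(setequal(tr$tip.label, LETTERS[1:10]), all(tr$edge.length > 0))
  tr
}

#' Simulate single-copy gene alignments along a species tree
#'
#' Evolves `n_genes` independent genes of the given length along the tree
#' under GTR with equal base frequencies (0.25); the exchangeability
#' rates default to all equal, which makes the process symmetric.
#' Deterministic for a fixed seed.
#'
#' @param n_genes number of genes.
#' @param length sites per gene (default 1000).
#' @param tree an `ape::phylo` tree (default [default_species_tree()]).
#' @param rates six GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param base_freq equilibrium base frequencies (default equal).
#' @param seed optional integer seed.
#' @return named list of genes (`gene0001`, ...), each a named character
#'   vector of upper-case sequences per taxon.
#' @export
simulate_genes <- function(n_genes, length = 1000L,
                           tree = default_species_tree(),
                           rates = rep(1, 6), base_freq = rep(0.25, 4),
                           seed = NULL) {
  stopifnot(n_genes >= 1, length >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    aln <- phangorn::simSeq(tree, l = length, Q = rates, bf = base_freq,
                            type = "DNA")
    m <- toupper(as.character(aln))
    out[[i]] <- setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
  }
  names(out) <- sprintf("gene%04d", seq_len(n_genes))
  out
}

#' Closed-form expected p-distance under the symmetric GTR used here
#'
#' With equal base frequencies and equal exchangeabilities the process is
#' Jukes-Cantor-like: the expected proportion of differing sites over a
#' path of length `d` substitutions/site is `3/4 (1 - exp(-4 d / 3))`.
#'
#' @param d path length (substitutions/site).
#' @return expected p-distance.
#' @export
expected_p_distance <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Mutate a reference away from a gold-standard sequence
#'
#' Substitutes each site independently with probability `divergence` to a
#' uniformly chosen different base. Deterministic for a fixed seed.
#'
#' @param seqs character vector of sequences.
#' @param divergence per-site substitution probability (0--1).
#' @param seed optional integer seed.
#' @return character vector of mutated sequences.
#' @export
mutate_reference <- function(seqs, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 1)
  if (!is.null(seed)) set.seed(seed)
  setNames(cpp_mutate(as.character(seqs), divergence), names(seqs))
}

#' Build a divergent reference set from simulated genes
#'
#' For each gene, a source sequence is derived from the gold standards
#' and mutated to the requested divergence. The default source is the
#' per-column majority consensus of the ten standards, which sits near
#' the centre of the tree so that the realised reference divergence is
#' close to `divergence` for every taxon; `source = "random_taxon"`
#' instead picks one tip's standard per gene (uniformly), making the
#' realised divergence `divergence` plus the tree distance to that tip.
#'
#' @param genes output of [simulate_genes()].
#' @param divergence per-site substitution probability.
#' @param source `"consensus"` (default) or `"random_taxon"`.
#' @param seed optional integer seed.
#' @return named character vector (gene -> reference sequence); for
#'   `"random_taxon"`, attribute `source_taxon` records the tips used.
#' @export
build_reference_set <- function(genes, divergence,
                                source = c("consensus", "random_taxon"),
                                seed = NULL) {
  source <- match.arg(source)
  if (!is.null(seed)) set.seed(seed)
  if (source == "random_taxon") {
    taxa <- names(genes[[1L]])
    src <- sample(taxa, length(genes), replace = TRUE)
    refs <- vapply(seq_along(genes), function(i) genes[[i]][[src[i]]],
                   character(1))
    names(refs) <- names(genes)
    out <- mutate_reference(refs, divergence)
    attr(out, "source_taxon") <- setNames(src, names(genes))
    return(out)
  }
  refs <- vapply(genes, majority_consensus, character(1))
  names(refs) <- names(genes)
  mutate_reference(refs, divergence)
}

# Per-column majority base over equal-length ungapped sequences; ties go
# to the alphabetically first base (deterministic).
majority_consensus <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  cons <- apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1L]
  })
  paste0(cons, collapse = "")
}

#' Concatenate one taxon's gene sequences into a genome
#'
#' @param genes output of [simulate_genes()].
#' @param taxon taxon label.
#' @return a single string with attribute `coords`, a data frame of
#'   0-based half-open gene coordinates.
#' @export
concat_genome <- function(genes, taxon) {
  seqs <- vapply(genes, function(g) g[[taxon]], character(1))
  len <- nchar(seqs)
  end <- cumsum(len)
  genome <- paste0(seqs, collapse = "")
  attr(genome, "coords") <- data.frame(gene = names(genes),
                                       start = end - len, end = end,
                                       stringsAsFactors = FALSE)
  genome
}

#' Simulate paired-end genome-skimming reads
#'
#' Uniform fragment positions, normal insert sizes, both strands, and
#' independent per-base substitution errors (`p_err = 0.01` corresponds
#' to Q20). The number of pairs is
#' `round(coverage * nchar(genome) / (2 * read_len))`. Deterministic for
#' a fixed seed.
#'
#' @param genome a single genome string (e.g. [concat_genome()]).
#' @param coverage mean sequencing depth (x).
#' @param read_len read length (default 150).
#' @param insert_mean,insert_sd insert size distribution (default 350,
#'   50).
#' @param p_err per-base substitution error rate (default 0.01).
#' @param seed optional integer seed.
#' @return list with `r1`, `r2` (character vectors), `start` (1-based
#'   fragment starts), `frag_len`, and `minus` (fragment strand).
#' @export
simulate_reads <- function(genome, coverage, read_len = 150L,
                           insert_mean = 350, insert_sd = 50,
                           p_err = 0.01, seed = NULL) {
  stopifnot(coverage > 0)
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- max(1L, as.integer(round(coverage * nchar(genome) /
                                        (2 * read_len))))
  cpp_sim_reads(as.character(genome), n_pairs, as.integer(read_len),
                insert_mean, insert_sd, p_err)
}

#' Interleave a simulated pair list into reads + mate mapping
#'
#' @param rs result of [simulate_reads()].
#' @return list with `reads` (r1 then r2) and `mate` (index of each
#'   read's mate).
#' @export
paired_reads <- function(rs) {
  n <- length(rs$r1)
  list(reads = c(rs$r1, rs$r2),
       mate = c(seq_len(n) + n, seq_len(n)))
}
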