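#' Run the simulation benchmark: simulate reads, recover, classify
#'
#' For each taxon of the simulated gene set, generates paired-end reads
#' from the concatenated gene sequences at the requested coverage, runs
#' the full recovery pipeline against the (divergent) reference set, and
#' classifies every recovered sequence against its gold standard.
#'
#' @param genes gold standards from [simulate_genes()].
#' @param references divergent reference set from [build_reference_set()].
#' @param coverage mean sequencing depth (x).
#' @param v expected reference divergence passed to the parameter
#'   calculator.
#' @param p_err per-base sequencing error rate (default 0.01, Q20).
#' @param read_len read length (default 150).
#' @param taxa taxa to sequence (default all).
#' @param seed optional integer seed for the read simulation.
#' @param ... further arguments to [mine_genes()].
#' @return list with
#'   \item{records}{[classify_quality()] data frame over all taxa}
#'   \item{recovered_genes}{genes with at least one recovered sequence}
#'   \item{n_genes}{number of simulated genes}
#'   \item{screen}{pooled read-screening tallies (`n_reads_total`,
#'     `n_reads_removed`)}
#' @export
run_benchmark <- function(genes, references, coverage, v, p_err = 0.01,
                          read_len = 150L, taxa = NULL, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxa)) taxa <- names(genes[[1L]])
  rows <- list()
  n_reads_total <- 0L
  n_reads_removed <- 0L
  for (tx in taxa) {
    genome <- concat_genome(genes, tx)
    rs <- simulate_reads(genome, coverage, read_len = read_len,
                         p_err = p_err)
    pr <- paired_reads(rs)
    res <- mine_genes(pr$reads, references, mate = pr$mate, v = v,
                      d = coverage, ...)
    n_reads_total <- n_reads_total + res$screen$n_reads_total
    n_reads_removed <- n_reads_removed + res$screen$n_reads_removed
    rows[[tx]] <- data.frame(gene = res$best$gene, taxon = tx,
                             seq = res$best$seq, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  records <- classify_quality(rec, genes)
  list(records = records,
       recovered_genes = sort(unique(records$gene)),
       n_genes = length(genes),
       screen = list(n_reads_total = n_reads_total,
                     n_reads_removed = n_reads_removed))
}
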