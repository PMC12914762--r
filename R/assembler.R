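#' Anchor k-mer statistics of reads against a reference
#'
#' Anchor k-mers occur exactly once in a read and are present in the
#' reference; the first k-mer of each consecutive run of anchors is a
#' unique anchor, and runs longer than `run_cap` contribute one extra
#' unique anchor per cap-length segment. The score
#' `s = k * N / (lr - k + 1)` is the number of bases covered by unique
#' anchors normalised by the number of k-mers in the read, so it does not
#' systematically favour small k on short reads.
#'
#' @param reads character vector of read sequences.
#' @param reference the gene's reference sequence(s).
#' @param k anchor k-mer size.
#' @param run_cap maximum anchors per run before an extra unique anchor is
#'   counted (default 64; `0` means uncapped).
#' @return data frame with `k`, `N` (unique anchors) and `s` per read.
#' @export
anchor_score <- function(reads, reference, k, run_cap = 64L) {
  reads <- as.character(reads)
  N <- cpp_anchor_n(reads, as.character(reference), as.integer(k),
                    as.integer(run_cap))
  lr <- nchar(reads)
  s <- ifelse(lr >= k, k * N / (lr - k + 1), 0)
  data.frame(k = as.integer(k), N = N, s = s)
}

#' Adaptive per-gene k-mer size selection
#'
#' Evaluates the mean anchor score over a read sample for each candidate
#' k and returns the largest k whose mean score is at least half the
#' maximum over candidates. Larger k reduces spurious overlaps and
#' improves assembly through repeats, at the cost of fewer anchors;
#' accepting any k retaining half of the peak anchored bases trades the
#' shortest anchors for specificity.
#'
#' @param reads character vector of the gene's screened reads.
#' @param reference the gene's reference sequence(s).
#' @param k_candidates ascending candidate sizes (default odd 17..31).
#' @param run_cap see [anchor_score()].
#' @param sample_size maximum reads scored (default 10000).
#' @param fallback k to return (with a warning) when every candidate
#'   scores zero, typically the filtering k-mer size.
#' @return list with `ka` (selected k) and `profile` (data frame of
#'   `k`, `s_bar`).
#' @export
select_k <- function(reads, reference, k_candidates = seq(17L, 31L, 2L),
                     run_cap = 64L, sample_size = 10000L, fallback = NULL) {
  stopifnot(length(reads) >= 1L)
  if (is.unsorted(k_candidates, strictly = TRUE)) {
    stop("k_candidates must be ascending")
  }
  if (length(reads) > sample_size) reads <- reads[seq_len(sample_size)]
  s_bar <- vapply(k_candidates, function(k) {
    mean(anchor_score(reads, reference, k, run_cap)$s)
  }, numeric(1))
  profile <- data.frame(k = as.integer(k_candidates), s_bar = s_bar)
  if (all(s_bar == 0)) {
    ka <- if (is.null(fallback)) min(k_candidates) else as.integer(fallback)
    warning("no anchor k-mers at any candidate k; falling back to k=", ka)
    return(list(ka = ka, profile = profile))
  }
  ok <- s_bar >= max(s_bar) / 2
  list(ka = as.integer(max(k_candidates[ok])), profile = profile)
}

#' Weighted de Bruijn graph nodes
#'
#' Builds the canonical-k-mer graph of a read set: node weights are read
#' k-mer multiplicities (both strands collapsed), and nodes also present
#' in the reference are marked as anchors.
#'
#' @param reads character vector of reads.
#' @param reference the gene's reference sequence(s).
#' @param ka assembly k-mer size (odd recommended, so no k-mer is its own
#'   reverse complement).
#' @return data frame with `kmer` (canonical), `weight`, `ref_mark`.
#' @export
build_graph <- function(reads, reference, ka) {
  ka <- as.integer(ka)
  if (ka %% 2L == 0L) warning("even ka: palindromic k-mers collapse strands")
  cpp_graph_nodes(as.character(reads), as.character(reference), ka)
}

#' Assemble one gene on the weighted de Bruijn graph
#'
#' Seeds at the heaviest reference-marked nodes and extends greedily in
#' both directions, always taking the highest-weight successor with ties
#' broken toward reference-marked nodes and then lexicographically;
#' extension stops at dead ends, nodes below `min_weight`, or already-used
#' nodes. Each finished walk is trimmed to at most `soft_boundary` bases
#' beyond its outermost reference-anchored node, and only anchored walks
#' are emitted, longest first. Contigs consist of read k-mers only: the
#' sample's alleles are reported even where they differ from the
#' reference, and reference-only bases never enter a contig.
#'
#' @param reads character vector of the gene's screened reads.
#' @param reference the gene's reference sequence(s).
#' @param ka assembly k-mer size (see [select_k()]).
#' @param min_weight minimum node multiplicity for the walk (default 2;
#'   weight-1 nodes are dominated by raw read errors).
#' @param soft_boundary bases allowed beyond the outermost anchored node;
#'   default half the median read length.
#' @param min_length shortest contig emitted (default `ka`).
#' @param max_contigs cap on emitted contigs per gene (default 64).
#' @param ref_rescue walk through nodes below `min_weight` when they are
#'   reference-marked: a single read in exact agreement with the
#'   reference cannot be a sequencing error, so such nodes bridge
#'   coverage gaps without admitting error bases (default TRUE).
#' @return data frame with `contig`, `length`, `support` (mean node
#'   weight); zero rows when the gene is unrecovered.
#' @export
assemble_gene <- function(reads, reference, ka, min_weight = 2L,
                          soft_boundary = NULL, min_length = ka,
                          max_contigs = 64L, ref_rescue = TRUE) {
  ka <- as.integer(ka)
  if (length(reads) == 0L) {
    return(data.frame(contig = character(), length = integer(),
                      support = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(soft_boundary)) {
    soft_boundary <- ceiling(0.5 * stats::median(nchar(reads)))
  }
  res <- cpp_assemble(as.character(reads), as.character(reference), ka,
                      as.integer(min_weight), as.integer(soft_boundary),
                      as.integer(max_contigs), isTRUE(ref_rescue))
  out <- data.frame(contig = as.character(res$contig),
                    length = nchar(as.character(res$contig)),
                    support = as.numeric(res$support),
                    stringsAsFactors = FALSE)
  out[out$length >= min_length, , drop = FALSE]
}
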