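#' Encode a DNA k-mer as a packed integer code
#'
#' Positional base-4 encoding with `A=0, C=1, G=2, T=3` and the leftmost
#' base most significant, so `"ACGT"` encodes to `0*64 + 1*16 + 2*4 + 3 = 27`.
#' The encoding commutes with reverse complementation:
#' `encode_kmer(revcomp(x))` equals the packed reverse complement of
#' `encode_kmer(x)`.
#'
#' Codes are returned as doubles, which hold the packed value exactly for
#' `k <= 26`; longer k-mers (up to the 31-base limit of the packed
#' representation) are handled internally by the index and the assembler,
#' which exchange k-mers as character strings at the R boundary.
#'
#' @param seq a single k-mer string over `A,C,G,T` (case-insensitive),
#'   at most 26 bases at this interface.
#' @return a numeric code with attribute `k` (the k-mer length).
#' @seealso [decode_kmer()], [revcomp()]
#' @examples
#' encode_kmer("ACGT")  # 27
#' @export
encode_kmer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- nchar(seq)
  if (k > 26L) {
    stop("encode_kmer() returns exact doubles only for k <= 26; ",
         "longer k-mers are supported by the string-based index operations")
  }
  structure(cpp_encode_kmer(seq), k = k)
}

#' Decode a packed k-mer code
#'
#' @param value numeric code as returned by [encode_kmer()].
#' @param k k-mer length in bases.
#' @return the k-mer string.
#' @export
decode_kmer <- function(value, k = attr(value, "k")) {
  stopifnot(is.numeric(value), length(value) == 1L, !is.null(k))
  cpp_decode_kmer(as.numeric(value), as.integer(k))
}

#' Reverse complement of DNA strings
#'
#' @param seqs character vector of DNA sequences; non-ACGT characters
#'   become `N`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seqs) cpp_revcomp(as.character(seqs))

#' Build a k-mer to gene-set multimap from reference sequences
#'
#' Stores every k-substring of every reference on the forward strand,
#' mapped to the (dense, zero-based) identifier of its gene. Strand
#' sensitivity is recovered at query time by probing both a k-mer and its
#' reverse complement. K-mers shared by more than `capacity_bound` genes
#' carry no filtering information and are blacklisted: they are excluded
#' from [index_lookup()] and [index_contains()]. Identical gene sets are
#' interned so k-mers sharing a set share one stored instance.
#'
#' @param references named character vector of reference sequences (one
#'   per gene; names are the gene labels) or a `Biostrings::DNAStringSet`.
#' @param k k-mer size, 1--31.
#' @param capacity_bound maximum genes per k-mer before blacklisting
#'   (default 1024).
#' @return an object of class `kmer_gene_index`.
#' @examples
#' idx <- build_kmer_index(c(geneA = "ACGTACGT"), k = 4)
#' index_lookup(idx, "ACGT")
#' @export
build_kmer_index <- function(references, k, capacity_bound = 1024L) {
  if (methods::is(references, "DNAStringSet")) {
    references <- setNames(as.character(references), names(references))
  }
  stopifnot(is.character(references), length(references) >= 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) stop("k must be between 1 and 31")
  nm <- names(references)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("references must be named by gene")
  }
  if (anyDuplicated(nm)) stop("duplicate gene names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  ptr <- cpp_index_new(k, as.integer(capacity_bound))
  cpp_index_set_genes(ptr, nm)
  for (i in seq_along(references)) {
    cpp_index_insert_seq(ptr, references[[i]], i - 1L)
  }
  cpp_index_finalize(ptr)
  structure(list(ptr = ptr, k = k, genes = nm,
                 capacity_bound = as.integer(capacity_bound)),
            class = "kmer_gene_index")
}

#' Create an empty, mutable k-mer index
#'
#' Mostly useful for incremental construction and stress testing;
#' [build_kmer_index()] is the usual entry point.
#'
#' @inheritParams build_kmer_index
#' @param genes character vector of gene labels (ids are assigned densely
#'   in this order, starting at 0).
#' @export
new_kmer_index <- function(k, genes = character(), capacity_bound = 1024L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) stop("k must be between 1 and 31")
  ptr <- cpp_index_new(k, as.integer(capacity_bound))
  cpp_index_set_genes(ptr, genes)
  structure(list(ptr = ptr, k = k, genes = genes,
                 capacity_bound = as.integer(capacity_bound)),
            class = "kmer_gene_index")
}

#' Insert k-mer/gene pairs into an index
#'
#' Duplicate insertion is a no-op; pairs landing on a blacklisted k-mer
#' are discarded and counted. K-mers containing ambiguous bases are
#' skipped.
#'
#' @param index a `kmer_gene_index`.
#' @param kmers character vector of k-mers (length `index$k`).
#' @param genes integer vector of zero-based gene ids (recycled).
#' @return the index, invisibly.
#' @export
index_insert <- function(index, kmers, genes) {
  stopifnot(inherits(index, "kmer_gene_index"))
  n <- max(length(kmers), length(genes))
  cpp_index_insert(index$ptr, rep_len(as.character(kmers), n),
                   rep_len(as.integer(genes), n))
  invisible(index)
}

#' Test membership of a k-mer/gene pair
#'
#' Returns `TRUE` only for pairs that were inserted and retained; a
#' membership `TRUE` is always a real insertion (no false positives).
#'
#' @inheritParams index_insert
#' @return logical vector.
#' @export
index_contains <- function(index, kmers, genes) {
  stopifnot(inherits(index, "kmer_gene_index"))
  cpp_index_contains(index$ptr, as.character(kmers), as.integer(genes))
}

#' Look up the gene set of a k-mer
#'
#' @param index a `kmer_gene_index`.
#' @param kmer a single k-mer string.
#' @param names return gene labels instead of zero-based ids.
#' @return sorted integer vector of gene ids (empty for unknown or
#'   blacklisted k-mers), or gene labels if `names = TRUE`.
#' @export
index_lookup <- function(index, kmer, names = FALSE) {
  stopifnot(inherits(index, "kmer_gene_index"), length(kmer) == 1L)
  ids <- cpp_index_lookup(index$ptr, as.character(kmer))
  if (names) index$genes[ids + 1L] else ids
}

#' Index statistics
#'
#' @param index a `kmer_gene_index`.
#' @return a list: k, number of k-mers, genes, blacklisted k-mers and
#'   pairs, dropped pairs (insertion failures), stored unique gene-set
#'   regions, and the capacity bound.
#' @export
index_stats <- function(index) {
  stopifnot(inherits(index, "kmer_gene_index"))
  cpp_index_stats(index$ptr)
}

#' Serialize an index to a versioned binary file
#'
#' Writes magic bytes, format version, k, the gene table and both levels
#' of the map with sorted keys, so identical indexes produce byte-identical
#' files. A plain-text TSV sidecar (`<path>.stats.tsv`) records summary
#' counts.
#'
#' @param index a `kmer_gene_index`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
index_save <- function(index, path) {
  stopifnot(inherits(index, "kmer_gene_index"))
  cpp_index_save(index$ptr, path.expand(path))
  st <- index_stats(index)
  sidecar <- data.frame(kmers = st$kmers, genes = st$genes,
                        blacklisted = st$blacklisted, dropped = st$dropped)
  write.table(sidecar, paste0(path, ".stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a serialized index
#'
#' @param path file written by [index_save()].
#' @return a `kmer_gene_index`.
#' @export
index_load <- function(path) {
  ptr <- cpp_index_load(path.expand(path))
  structure(list(ptr = ptr, k = cpp_index_k(ptr),
                 genes = as.character(cpp_index_genes(ptr)),
                 capacity_bound = as.integer(cpp_index_stats(ptr)$capacity_bound)),
            class = "kmer_gene_index")
}

#' @export
print.kmer_gene_index <- function(x, ...) {
  st <- index_stats(x)
  cat(sprintf(
    "kmer_gene_index: k=%d, %s k-mers, %d genes, %s blacklisted, %s dropped\n",
    x$k, format(st$kmers, big.mark = ","), length(x$genes),
    format(st$blacklisted, big.mark = ","), format(st$dropped)))
  invisible(x)
}
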