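#' Read reference sequences from FASTA
#'
#' Accepts a multi-record FASTA (record id = gene name, up to the first
#' whitespace) or a directory of per-gene FASTA files (file stem = gene
#' name; the first record of each file is used).
#'
#' @param path FASTA file or directory.
#' @return named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(fa|fasta|fna)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no FASTA files in directory '", path, "'")
    seqs <- vapply(files, function(f) {
      x <- read_fasta(f)
      unname(x[1L])
    }, character(1))
    names(seqs) <- tools::file_path_sans_ext(basename(files))
    return(seqs)
  }
  read_fasta(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file; empty or unreadable files raise an error
#'   naming the file. Duplicate record ids are rejected.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("reference file '", path, "' does not exist")
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("cannot read FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("reference file '", path, "' contains no sequences")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(toupper(as.character(x)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- seqs[nchar(seqs) > 0]
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read one FASTQ file (optionally gzipped)
#'
#' @param path FASTQ(.gz) file.
#' @return character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("read file '", path, "' does not exist")
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Read paired FASTQ files into reads + mate mapping
#'
#' @param path1,path2 the `_1`/`_2` files; `path2 = NULL` for single-end.
#' @return list with `reads` and `mate` (NA for single-end).
#' @export
read_fastq_paired <- function(path1, path2 = NULL) {
  r1 <- read_fastq(path1)
  if (is.null(path2)) {
    return(list(reads = r1, mate = rep(NA_integer_, length(r1))))
  }
  r2 <- read_fastq(path2)
  if (length(r1) != length(r2)) {
    stop("paired files have different read counts (",
         length(r1), " vs ", length(r2), ")")
  }
  n <- length(r1)
  list(reads = c(r1, r2), mate = c(seq_len(n) + n, seq_len(n)))
}

#' Write reads to FASTQ
#'
#' Constant Q20 qualities are written (the simulator's error model).
#'
#' @param reads character vector (names become ids; unnamed reads get
#'   `read<N>`).
#' @param path output path; `.gz` suffix enables compression.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) strrep("5", n), character(1))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Write a TSV report (UTF-8, LF, header row)
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
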