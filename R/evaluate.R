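#' Classify recovered sequences into quality levels L1-L4
#'
#' Compares each recovered sequence with its gold-standard sequence.
#' Identity and coverage come from an ends-free alignment of the
#' recovered sequence to the standard (identity over aligned columns;
#' coverage = aligned standard positions / standard length); an exact
#' substring short-circuits to identity 100. `count` is the number of
#' taxa with at least one recovered sequence for the gene. Levels:
#' \itemize{
#'   \item L1: identity 100, coverage 50--100 (closed at 50), count 7--10
#'   \item L2: identity 100, coverage < 50, count 7--10
#'   \item L3: identity 100, count 1--6
#'   \item L4: any substitution or indel error
#' }
#' `mismatch_rate` is erroneous bases (substitutions + indel bases) as a
#' percentage of the recovered length.
#'
#' @param recovered data frame with columns `gene`, `taxon`, `seq`
#'   (empty/NA seq rows are ignored).
#' @param standards named list (gene -> named character vector of
#'   gold-standard sequences per taxon), as from [simulate_genes()].
#' @return data frame with `gene`, `taxon`, `identity`, `coverage`,
#'   `count`, `level`, `mismatch_rate`.
#' @export
classify_quality <- function(recovered, standards) {
  stopifnot(all(c("gene", "taxon", "seq") %in% names(recovered)))
  recovered <- recovered[!is.na(recovered$seq) & nchar(recovered$seq) > 0, ,
                         drop = FALSE]
  unknown <- setdiff(unique(recovered$gene), names(standards))
  if (length(unknown)) {
    stop("recovered sequences reference unknown genes: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  n <- nrow(recovered)
  identity <- coverage <- mismatch <- numeric(n)
  for (i in seq_len(n)) {
    std <- standards[[recovered$gene[i]]][[recovered$taxon[i]]]
    rec <- recovered$seq[i]
    if (length(grepRaw(rec, std, fixed = TRUE, all = FALSE)) > 0) {
      identity[i] <- 100
      coverage[i] <- 100 * nchar(rec) / nchar(std)
      mismatch[i] <- 0
    } else {
      stats <- align_errors(rec, std)
      identity[i] <- stats$identity
      coverage[i] <- stats$coverage
      mismatch[i] <- stats$mismatch_rate
    }
  }
  cnt <- tapply(recovered$taxon, recovered$gene,
                function(x) length(unique(x)))
  count <- as.integer(cnt[recovered$gene])
  level <- ifelse(identity < 100, "L4",
           ifelse(count <= 6, "L3",
           ifelse(coverage >= 50, "L1", "L2")))
  data.frame(gene = recovered$gene, taxon = recovered$taxon,
             identity = identity, coverage = coverage, count = count,
             level = factor(level, levels = c("L1", "L2", "L3", "L4")),
             mismatch_rate = mismatch, stringsAsFactors = FALSE)
}

# Ends-free alignment statistics of a recovered sequence vs its standard.
align_errors <- function(rec, std) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(rec),
                                       Biostrings::DNAString(std),
                                       type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  nmis <- Biostrings::nmismatch(aln)
  insd <- Biostrings::indel(aln)
  indel_bases <- sum(BiocGenerics::width(insd@insertion[[1L]])) +
    sum(BiocGenerics::width(insd@deletion[[1L]]))
  nmat <- Biostrings::nmatch(aln)
  cols <- nmat + nmis + indel_bases
  srng <- aln@subject@range
  list(identity = if (cols > 0) 100 * nmat / cols else 0,
       coverage = 100 * (BiocGenerics::end(srng) -
                           BiocGenerics::start(srng) + 1L) / nchar(std),
       mismatch_rate = 100 * (nmis + indel_bases) / nchar(rec))
}

#' Summarize quality records
#'
#' @param records data frame from [classify_quality()] with optional
#'   grouping columns added by the caller (e.g. `coverage_x`,
#'   `divergence`).
#' @param by character vector of grouping columns (default none: one
#'   overall row).
#' @param recovered_lengths optional numeric vector (per record) of
#'   recovered sequence lengths; when given, the overall mismatch rate is
#'   total erroneous bases over total recovered length.
#' @return data frame with the group, number of records, L1--L4
#'   proportions, and the overall `mismatch_rate` (%).
#' @export
summarize_quality <- function(records, by = character(),
                              recovered_lengths = NULL) {
  stopifnot(nrow(records) >= 1L)
  if (is.null(recovered_lengths)) {
    recovered_lengths <- rep(1, nrow(records))
  }
  grp <- if (length(by)) interaction(records[by], drop = TRUE, sep = "|")
         else factor(rep("all", nrow(records)))
  res <- lapply(levels(grp), function(g) {
    idx <- grp == g
    lv <- table(records$level[idx])
    n <- sum(idx)
    err_bases <- sum(records$mismatch_rate[idx] / 100 *
                       recovered_lengths[idx])
    data.frame(group = g, n = n,
               L1 = lv[["L1"]] / n, L2 = lv[["L2"]] / n,
               L3 = lv[["L3"]] / n, L4 = lv[["L4"]] / n,
               mismatch_rate = 100 * err_bases / sum(recovered_lengths[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
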