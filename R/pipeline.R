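#' Recover target genes from reads (full pipeline, in memory)
#'
#' Runs the complete recovery chain for one sample: k-mer baiting against
#' the reference index, pair salvage, the three-test orientation screen,
#' discordant-pair removal, coverage-guarded iterative re-filtering,
#' adaptive k selection, weighted de Bruijn assembly, and reference-based
#' trimming.
#'
#' @param reads character vector of read sequences (upper-case ACGTN).
#' @param references named character vector of per-gene reference
#'   sequences.
#' @param mate optional mate mapping (see [salvage_pairs()]); `NULL` for
#'   single-end data.
#' @param params a [recommend_params()] bundle; built from `v`, `lr`,
#'   `lg`, `d` when `NULL`.
#' @param v,d expected reference divergence and mean depth, used when
#'   `params` is `NULL` (`lr` and `lg` are then taken from the data).
#' @param k_test k-mer size for the statistical screen (default 17).
#' @param min_hits minimum baiting k-mer hits (default 1).
#' @param coverage_floor re-filtering coverage floor (default 2).
#' @param k_step increment of the re-filtering schedule (default 4; the
#'   schedule is `kf, kf+4, ...` capped at 31).
#' @param k_candidates candidate assembly k-mer sizes (default odd
#'   17..31).
#' @param min_weight minimum de Bruijn node weight (default 2).
#' @param soft_boundary see [assemble_gene()].
#' @param trim apply [retention_trim()] to the contigs (default TRUE).
#' @param max_trim_contigs trim at most this many (longest) contigs per
#'   gene (default 3).
#' @param screen_report collect the per-read screening report (gene, read,
#'   direction statistics, z, verdict) in the result (default FALSE).
#' @param keep_reads record the retained read indices per gene in the
#'   result (default FALSE).
#' @param verbose print progress.
#' @return list with
#'   \item{status}{per-gene data frame: reads after each stage, `ka`,
#'     contigs, longest, support, recovered flag}
#'   \item{best}{per-gene data frame of the single best (longest trimmed)
#'     sequence; empty `seq` when unrecovered}
#'   \item{contigs}{all emitted contigs per gene}
#'   \item{screen}{pooled screening tallies (verdict counts)}
#'   \item{params}{the parameter bundle used}
#' @export
mine_genes <- function(reads, references, mate = NULL, params = NULL,
                       v = 0.05, d = 10, k_test = 17L, min_hits = 1L,
                       coverage_floor = 2, k_step = 4L,
                       k_candidates = seq(17L, 31L, 2L), min_weight = 2L,
                       soft_boundary = NULL, trim = TRUE,
                       max_trim_contigs = 3L, screen_report = FALSE,
                       keep_reads = FALSE, verbose = FALSE) {
  stopifnot(is.character(references), length(references) >= 1L)
  reads <- toupper(as.character(reads))
  if (is.null(params)) {
    lr <- if (length(reads)) as.integer(round(mean(nchar(reads)))) else 150L
    params <- recommend_params(v, lr, mean(nchar(references)), d)
  }
  kf <- params$kf
  if (verbose) message("filtering k-mer size kf = ", kf)

  idx <- build_kmer_index(references, k = kf)
  assignment <- bait_reads(reads, idx, min_hits = min_hits)
  if (!is.null(mate)) assignment <- salvage_pairs(assignment, mate)
  if (!"salvaged" %in% names(assignment)) {
    assignment$salvaged <- rep(FALSE, nrow(assignment))
  }

  genes <- names(references)
  status <- data.frame(gene = genes, n_baited = 0L, n_screened = 0L,
                       n_refiltered = 0L, ka = NA_integer_, n_contigs = 0L,
                       longest = 0L, support = NA_real_, recovered = FALSE,
                       stringsAsFactors = FALSE)
  best <- data.frame(gene = genes, seq = "", length = 0L,
                     support = NA_real_, stringsAsFactors = FALSE)
  contig_rows <- list()
  screen_rows <- list()
  gene_read_sets <- list()
  verdict_tally <- integer()
  removed_reads <- rep(NA, length(reads))  # TRUE once removed everywhere

  schedule_full <- seq(kf, 31L, by = k_step)
  k_schedule <- schedule_full[schedule_full > kf]
  by_gene <- split(seq_len(nrow(assignment)), assignment$gene)

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    rows <- assignment[by_gene[[g]], , drop = FALSE]
    if (is.null(by_gene[[g]])) rows <- assignment[0L, , drop = FALSE]
    status$n_baited[gi] <- nrow(rows)
    if (nrow(rows) == 0L) next
    direct <- rows[!rows$salvaged, , drop = FALSE]
    salv <- rows[rows$salvaged, , drop = FALSE]

    sc <- screen_reads(reads[direct$read], references[[g]], k = k_test)
    if (screen_report) {
      screen_rows[[g]] <- cbind(data.frame(gene = g, read = direct$read,
                                           stringsAsFactors = FALSE), sc)
    }
    vt <- table(sc$verdict)
    verdict_tally <- if (length(verdict_tally)) verdict_tally + vt else vt
    accepted <- grepl("^accept", as.character(sc$verdict))
    rr <- removed_reads[direct$read]
    removed_reads[direct$read] <- ifelse(accepted, FALSE,
                                         ifelse(is.na(rr), TRUE, rr))

    # salvaged mates inherit the opposite orientation of an accepted mate
    keep_ids <- direct$read[accepted]
    verd <- setNames(as.character(sc$verdict), direct$read)
    if (nrow(salv) && !is.null(mate)) {
      mate_of <- mate[salv$read]
      mv <- verd[as.character(mate_of)]
      ok <- !is.na(mv) & grepl("^accept", mv)
      keep_ids <- c(keep_ids, salv$read[ok])
    }
    # discordant pairs among directly screened reads
    if (!is.null(mate)) {
      keep_flag <- remove_discordant_pairs(direct$read, sc$verdict, mate)
      drop_ids <- direct$read[grepl("^accept", as.character(sc$verdict)) &
                                !keep_flag]
      if (length(drop_ids)) {
        keep_ids <- setdiff(keep_ids, c(drop_ids, mate[drop_ids]))
      }
    }
    keep_ids <- unique(keep_ids)
    status$n_screened[gi] <- length(keep_ids)
    if (length(keep_ids) == 0L) next
    gene_reads <- reads[keep_ids]

    if (length(k_schedule)) {
      rf <- iterative_refilter(gene_reads, references[[g]], k_schedule,
                               floor = coverage_floor, min_hits = min_hits)
      gene_reads <- gene_reads[rf$keep]
    }
    status$n_refiltered[gi] <- length(gene_reads)
    if (keep_reads) {
      ids <- keep_ids
      if (length(k_schedule)) ids <- ids[rf$keep]
      gene_read_sets[[g]] <- ids
    }

    sel <- tryCatch(
      suppressWarnings(select_k(gene_reads, references[[g]],
                                k_candidates = k_candidates,
                                fallback = min(k_candidates))),
      error = function(e) list(ka = min(k_candidates)))
    ka <- sel$ka
    status$ka[gi] <- ka

    ctg <- assemble_gene(gene_reads, references[[g]], ka,
                         min_weight = min_weight,
                         soft_boundary = soft_boundary)
    if (nrow(ctg) == 0L) next

    if (trim) {
      top <- head(ctg, max_trim_contigs)
      tr <- retention_trim(top$contig, references[[g]],
                           retention_length = params$retention_length,
                           min_identity = params$min_identity)
      ok <- nchar(tr$seq) > 0
      seqs <- tr$seq[ok]
      sups <- top$support[ok]
    } else {
      seqs <- ctg$contig
      sups <- ctg$support
    }
    status$n_contigs[gi] <- nrow(ctg)
    if (length(seqs) == 0L) next
    o <- order(nchar(seqs), decreasing = TRUE)
    seqs <- seqs[o]; sups <- sups[o]
    status$longest[gi] <- nchar(seqs[1L])
    status$support[gi] <- sups[1L]
    status$recovered[gi] <- TRUE
    best$seq[gi] <- seqs[1L]
    best$length[gi] <- nchar(seqs[1L])
    best$support[gi] <- sups[1L]
    contig_rows[[g]] <- data.frame(gene = g, contig = seqs,
                                   length = nchar(seqs), support = sups,
                                   stringsAsFactors = FALSE)
    if (verbose && gi %% 50L == 0L) {
      message("processed ", gi, "/", length(genes), " genes")
    }
  }

  out <- list(status = status, best = best,
              contigs = if (length(contig_rows)) do.call(rbind, contig_rows)
                        else data.frame(gene = character(),
                                        contig = character(),
                                        length = integer(),
                                        support = numeric()),
              screen = list(verdicts = verdict_tally,
                            n_reads_total = length(reads),
                            n_reads_removed = sum(removed_reads,
                                                  na.rm = TRUE)),
              params = params)
  if (screen_report) {
    out$screen_report <- if (length(screen_rows)) {
      sr <- do.call(rbind, screen_rows)
      rownames(sr) <- NULL
      sr
    } else NULL
  }
  if (keep_reads) out$gene_reads <- gene_read_sets
  out
}
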