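#' Read acquisition rate
#'
#' Probability that a read of length `lr` shares at least one error-free
#' k-mer with a reference at per-site divergence `v`:
#' `p(k) = 1 - (1 - (1 - v)^k)^(lr - k + 1)`.
#'
#' @param v expected per-site divergence to the reference (0--1).
#' @param lr read length in bp.
#' @param k k-mer size.
#' @return acquisition probability.
#' @export
acquisition_rate <- function(v, lr, k) {
  1 - (1 - (1 - v)^k)^(lr - k + 1)
}

#' Filtering k-mer size from the read acquisition rate
#'
#' Scans `k` from 17 to `min(31, lr)` and returns the largest k keeping
#' the acquisition rate `p(k)` at or above 0.99; if no k qualifies, the
#' constraint is relaxed once to 0.95; if that also fails, the
#' divergence/read-length combination cannot support k-mer filtering and
#' an error is raised.
#'
#' @inheritParams acquisition_rate
#' @return the filtering k-mer size `kf`.
#' @examples
#' compute_kf(0.05, 150)
#' @export
compute_kf <- function(v, lr) {
  stopifnot(v >= 0, v < 1, lr > 17)
  ks <- 17:min(31L, as.integer(lr))
  p <- acquisition_rate(v, lr, ks)
  for (threshold in c(0.99, 0.95)) {
    ok <- ks[p >= threshold]
    if (length(ok)) return(max(ok))
  }
  stop(sprintf(
    "no k-mer size in [17, %d] reaches acquisition rate 0.95 at v=%g, lr=%d",
    max(ks), v, as.integer(lr)))
}

#' Recommended run parameters from sample descriptors
#'
#' Derives the filtering k-mer size via [compute_kf()] and two quality
#' thresholds from the four sample descriptors. The retention length and
#' maximum difference policies are this package's own calibration (they
#' are reported with provenance notes): the retention length threshold is
#' `max(lr, 0.2 * lg)` so that a trimmed overhang may never exceed a read
#' length or a fifth of a typical gene, and the maximum pairwise
#' difference is `min(3 * v + 0.02, 0.5)`, i.e. the expected
#' sample-to-sample divergence (twice the reference divergence) plus
#' headroom for alignment noise, capped at 0.5.
#'
#' @param v expected per-site divergence to the reference (0--1).
#' @param lr read length (bp).
#' @param lg mean target gene length (bp).
#' @param d mean sequencing depth (x).
#' @return an object of class `param_bundle`: the four descriptors plus
#'   `kf`, `retention_length`, `max_difference`, `min_identity`
#'   (`max(1 - 2v, 0.6)`, used by [retention_trim()]) and `notes`.
#' @export
recommend_params <- function(v, lr, lg, d) {
  stopifnot(v >= 0, lr > 0, lg > 0, d > 0)
  kf <- compute_kf(v, lr)
  structure(list(
    v = v, lr = as.integer(lr), lg = lg, d = d,
    kf = as.integer(kf),
    retention_length = as.integer(ceiling(max(lr, 0.2 * lg))),
    max_difference = min(3 * v + 0.02, 0.5),
    min_identity = max(1 - 2 * v, 0.6),
    notes = c(kf = "largest k in [17,31] with acquisition rate >= 0.99 (0.95 fallback)",
              retention_length = "package policy: max(lr, 0.2*lg)",
              max_difference = "package policy: min(3*v + 0.02, 0.5)",
              min_identity = "package policy: max(1 - 2*v, 0.6)")),
    class = "param_bundle")
}

#' @export
print.param_bundle <- function(x, ...) {
  cat("Run parameters\n")
  cat(sprintf("  divergence v        : %.3f\n", x$v))
  cat(sprintf("  read length lr      : %d bp\n", x$lr))
  cat(sprintf("  mean gene length lg : %g bp\n", x$lg))
  cat(sprintf("  mean depth d        : %gx\n", x$d))
  cat(sprintf("  filtering k-mer kf  : %d\n", x$kf))
  cat(sprintf("  retention length    : %d bp\n", x$retention_length))
  cat(sprintf("  maximum difference  : %.3f\n", x$max_difference))
  cat(sprintf("  min trim identity   : %.3f\n", x$min_identity))
  invisible(x)
}

#' Trim assembled contigs against their reference
#'
#' Locally aligns each contig to its reference (affine gaps; match +1,
#' mismatch -2, gap open 5, gap extend 2) and retains the aligned block,
#' cutting the flanks. A contig is discarded when its unaligned overhang
#' exceeds `retention_length`, when the aligned identity falls below
#' `min_identity`, or when no alignment is found.
#'
#' @param contigs character vector (or data frame from [assemble_gene()]).
#' @param reference the gene's reference sequence (single string).
#' @param retention_length maximum allowed unaligned overhang (bp).
#' @param min_identity minimum aligned identity (0--1).
#' @return data frame with `seq`, `source_contig`, `start`, `end`
#'   (0-based half-open on the contig), `ref_identity`, and `action`
#'   (`trimmed`, `kept`, `discarded_length`, `discarded_identity`,
#'   `discarded_unaligned`); discarded rows have empty `seq`.
#' @export
retention_trim <- function(contigs, reference, retention_length,
                           min_identity = 0.6) {
  if (is.data.frame(contigs)) contigs <- contigs$contig
  contigs <- as.character(contigs)
  n <- length(contigs)
  out <- data.frame(seq = character(n), source_contig = seq_len(n),
                    start = NA_integer_, end = NA_integer_,
                    ref_identity = NA_real_,
                    action = character(n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  subject <- as.character(reference)[1L]
  for (i in seq_len(n)) {
    aln <- cpp_local_align(contigs[i], subject)
    if (aln$score <= 0) {
      out$action[i] <- "discarded_unaligned"
      next
    }
    s <- aln$p_start  # 0-based half-open on the contig
    e <- aln$p_end
    identity <- aln$identity
    overhang <- nchar(contigs[i]) - (e - s)
    if (overhang > retention_length) {
      out$action[i] <- "discarded_length"
    } else if (identity < min_identity) {
      out$action[i] <- "discarded_identity"
    } else {
      out$seq[i] <- substr(contigs[i], s + 1L, e)
      out$start[i] <- s
      out$end[i] <- e
      out$action[i] <- if (e - s == nchar(contigs[i])) "kept" else "trimmed"
    }
    out$ref_identity[i] <- identity
  }
  out
}

#' Pairwise-divergence paralog filter
#'
#' On pre-aligned sequences (equal length, gaps allowed), computes
#' pairwise divergence as mismatches over shared non-gap columns and
#' iteratively removes the sequence with the largest mean divergence to
#' the rest until the maximum pairwise divergence is at most
#' `max_difference`.
#'
#' @param aligned named character vector of aligned sequences.
#' @param max_difference divergence threshold (0--1).
#' @return list with `kept` (named character vector), `removed` (names),
#'   and `max_divergence` of the surviving set.
#' @export
divergence_filter <- function(aligned, max_difference) {
  aligned <- unlist(aligned)
  if (length(aligned) < 2L) {
    return(list(kept = aligned, removed = character(),
                max_divergence = 0))
  }
  if (length(unique(nchar(aligned))) != 1L) {
    stop("sequences must be pre-aligned to equal length")
  }
  if (is.null(names(aligned))) names(aligned) <- paste0("seq", seq_along(aligned))
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  gap <- m == "-" | m == "."
  pair_div <- function(i, j) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) return(0)
    sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- pair_div(i, j)
  }
  alive <- rep(TRUE, n)
  while (sum(alive) >= 2L && max(D[alive, alive]) > max_difference) {
    md <- rowMeans(D[, alive, drop = FALSE])
    md[!alive] <- -Inf
    alive[which.max(md)] <- FALSE
  }
  list(kept = aligned[alive],
       removed = names(aligned)[!alive],
       max_divergence = if (sum(alive) >= 2L) max(D[alive, alive]) else 0)
}
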