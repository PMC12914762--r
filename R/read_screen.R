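#' Assign reads to genes by shared k-mers (baiting)
#'
#' A read is assigned to a gene when at least `min_hits` of its k-mer
#' windows (probed on both strands) map to that gene in the index. Reads
#' may be assigned to several genes.
#'
#' @param reads character vector of read sequences.
#' @param index a [build_kmer_index()] object built at the filtering k-mer
#'   size.
#' @param min_hits minimum matching k-mers for assignment (default 1).
#' @return a data frame with columns `read` (index into `reads`), `gene`
#'   (label), and `hits`.
#' @export
bait_reads <- function(reads, index, min_hits = 1L) {
  stopifnot(inherits(index, "kmer_gene_index"))
  if (length(reads) == 0L) {
    warning("empty read stream: no assignments")
    return(data.frame(read = integer(), gene = character(),
                      hits = integer(), stringsAsFactors = FALSE))
  }
  df <- cpp_bait(index$ptr, as.character(reads), as.integer(min_hits))
  data.frame(read = df$read, gene = index$genes[df$gene + 1L],
             hits = df$hits, stringsAsFactors = FALSE)
}

#' Salvage unassigned mates of assigned reads
#'
#' If one read of a pair was assigned to a gene, its mate is added to that
#' gene's set as well (short or divergent mates often carry usable
#' sequence even when they share no k-mer with the reference).
#'
#' @param assignment data frame from [bait_reads()].
#' @param mate integer vector: `mate[i]` is the index of read `i`'s mate,
#'   or `NA` for single-end reads.
#' @return the assignment with salvaged rows appended; added rows have
#'   `hits = 0` and `salvaged = TRUE`.
#' @export
salvage_pairs <- function(assignment, mate) {
  assignment$salvaged <- rep(FALSE, nrow(assignment))
  m <- mate[assignment$read]
  cand <- !is.na(m)
  if (!any(cand)) return(assignment)
  key_have <- paste(assignment$read, assignment$gene)
  add <- assignment[cand, , drop = FALSE]
  add$read <- m[cand]
  add_key <- paste(add$read, add$gene)
  add <- add[!(add_key %in% key_have) & !duplicated(add_key), , drop = FALSE]
  if (nrow(add) == 0L) return(assignment)
  add$hits <- 0L
  add$salvaged <- TRUE
  out <- rbind(assignment, add)
  out[order(out$read), , drop = FALSE]
}

#' Direction-call sequence of reads against a reference
#'
#' For every k-mer window of a read, tests whether the k-mer or its
#' reverse complement occurs in the reference: a window calls `F` when
#' only the forward k-mer matches, `R` when only the reverse complement
#' matches; windows matching both ways or neither are ignored. Returns
#' per-read run statistics and the region identity proportions `p1`/`p2`
#' (fraction of windows matching the reference inside the span of F,
#' resp. R, calls).
#'
#' @param reads character vector of read sequences.
#' @param reference character vector of reference sequence(s) for one
#'   gene, or a precomputed set from [ref_kmer_set()].
#' @param k k-mer size for the statistical tests; small values keep the
#'   direction calls sensitive (default 17).
#' @param keep_calls include the compressed call string (e.g. `"FFFR"`).
#' @return a data frame with `n1`, `n2`, `r`, `longest_f`, `longest_r`,
#'   `p1`, `p2` and optionally `calls`.
#' @export
direction_sequence <- function(reads, reference, k = 17L, keep_calls = TRUE) {
  set <- if (is_ref_kmer_set(reference)) {
    stopifnot(attr(reference, "k") == k)
    reference
  } else {
    ref_kmer_set(reference, k)
  }
  cpp_direction_stats(as.character(reads), set, as.integer(k),
                      isTRUE(keep_calls))
}

#' Forward-strand k-mer set of a reference
#'
#' @param reference character vector of sequences.
#' @param k k-mer size.
#' @return an opaque `ref_kmer_set` handle.
#' @export
ref_kmer_set <- function(reference, k) {
  set <- cpp_kmer_set(as.character(reference), as.integer(k))
  attr(set, "k") <- as.integer(k)
  set
}

is_ref_kmer_set <- function(x) {
  typeof(x) == "externalptr" && !is.null(attr(x, "k"))
}

#' Wald-Wolfowitz runs test on a direction sequence
#'
#' Tests whether the F/R direction calls of a read are strongly positively
#' autocorrelated, as expected when a read matches the reference in long
#' same-direction stretches. With `n1` forward and `n2` reverse calls and
#' `r` observed runs, `E(R) = 2 n1 n2/(n1+n2) + 1` and
#' `Var(R) = 2 n1 n2 (2 n1 n2 - n1 - n2) / ((n1+n2)^2 (n1+n2-1))`; a read
#' is accepted when `z = (r - E(R))/sigma` falls in the lower tail at
#' significance `alpha`. Reads matching in a single direction only
#' (`n1 = 0` or `n2 = 0`), or with zero variance, bypass the test
#' (`accept = TRUE`, `bypass = TRUE`) and fall through to the longest-run
#' test.
#'
#' @param n1,n2 forward and reverse call counts (vectors).
#' @param r number of runs.
#' @param alpha lower-tail significance level (default `1e-5`).
#' @return data frame with `z`, `accept`, `bypass`.
#' @export
runs_test <- function(n1, n2, r, alpha = 1e-5) {
  n1 <- as.numeric(n1); n2 <- as.numeric(n2); r <- as.numeric(r)
  n <- n1 + n2
  er <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) / (n^2 * (n - 1))
  z <- rep(NA_real_, length(n))
  ok <- n1 >= 1 & n2 >= 1 & is.finite(v) & v > 0
  z[ok] <- (r[ok] - er[ok]) / sqrt(v[ok])
  crit <- qnorm(alpha)
  accept <- ifelse(ok, z <= crit, TRUE)
  data.frame(z = z, accept = accept, bypass = !ok)
}

#' Expected longest run under the random-direction null
#'
#' `E_n(L) = log2(n) - 0.6676`, the leading term of the longest-run
#' estimator for a fair binary sequence of length `n` (the oscillating
#' correction, below 1e-6, is absorbed into the constant).
#'
#' @param n total number of direction calls.
#' @return expected longest run length.
#' @export
expected_longest_run <- function(n) log2(n) - 0.6676

#' Closed-form lower bound on P(L <= E_n(L) + 4)
#'
#' Treats each of the expected `E(R) = n/2 + 1` runs (at `n1 = n2 = n/2`)
#' as an independent geometric sample, giving the bound
#' `1 - 0.5^(E_n(L) + 5) * E(R)`. The bound exceeds 0.95 already at
#' `n = 2` and increases with `n`, so the longest-run threshold
#' `E_n(L) + 4` rejects the random-direction null at (at least) the 95%
#' confidence level for every `n >= 2`.
#'
#' @param n total number of direction calls.
#' @return lower bound on the null probability that the longest run does
#'   not exceed `E_n(L) + 4`.
#' @export
longest_run_bound <- function(n) {
  1 - 0.5^(expected_longest_run(n) + 5) * (n / 2 + 1)
}

#' Longest-run test
#'
#' A direction qualifies when its longest same-direction run exceeds
#' `E_n(L) + 4` with `n = n1 + n2`. One qualifying direction orients the
#' read; both qualifying defers to the k-mer identity test; neither
#' removes the read (no long same-direction k-mer run).
#'
#' @param n1,n2,longest_f,longest_r direction-sequence statistics.
#' @return factor with levels `forward`, `reverse`, `ambiguous`, `removed`.
#' @export
longest_run_test <- function(n1, n2, longest_f, longest_r) {
  n <- as.numeric(n1) + as.numeric(n2)
  thr <- expected_longest_run(n) + 4
  qf <- longest_f > thr
  qr <- longest_r > thr
  out <- rep("removed", length(n))
  out[qf & !qr] <- "forward"
  out[qr & !qf] <- "reverse"
  out[qf & qr] <- "ambiguous"
  out[n < 2] <- "removed"
  factor(out, levels = c("forward", "reverse", "ambiguous", "removed"))
}

#' k-mer identity test for reads with long runs in both directions
#'
#' Compares the reference-match proportions of the forward region (`p1`,
#' over `n1` k-mers) and the reverse region (`p2`, over `n2` k-mers) with
#' a two-proportion z score,
#' `z = (p1 - p2)/sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`. When the two regions
#' are significantly unequal (|z| > 1.96, 95% two-tailed) the read is
#' kept and oriented toward the more reference-similar region; otherwise
#' the ambiguity is unresolvable and the read is removed.
#'
#' @param p1,p2 region identity proportions.
#' @param n1,n2 region k-mer counts.
#' @return data frame with `z`, `keep`, and `direction`
#'   (`forward`/`reverse`, `NA` when removed).
#' @export
identity_test <- function(p1, p2, n1, n2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  den <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- (p1 - p2) / den
  keep <- is.finite(z) & abs(z) > 1.96
  direction <- ifelse(keep, ifelse(p1 > p2, "forward", "reverse"), NA_character_)
  data.frame(z = z, keep = keep, direction = direction,
             stringsAsFactors = FALSE)
}

#' Screen reads for one gene with the three orientation tests
#'
#' Runs the full fine-grained selection cascade for reads assigned to one
#' gene: direction calls, the runs test (mixed-direction reads only), the
#' longest-run test, and the k-mer identity test for reads with long runs
#' in both directions.
#'
#' @param reads character vector of the gene's candidate reads.
#' @param reference the gene's reference sequence(s) or a [ref_kmer_set()].
#' @param k test k-mer size (default 17).
#' @param alpha runs-test lower-tail significance (default `1e-5`).
#' @return data frame with the direction statistics, `z_runs`, and a
#'   `verdict` factor: `accept_forward`, `accept_reverse`, `removed_runs`,
#'   `removed_no_long_run`, `removed_ambiguous`.
#' @export
screen_reads <- function(reads, reference, k = 17L, alpha = 1e-5) {
  ds <- direction_sequence(reads, reference, k = k, keep_calls = FALSE)
  rt <- runs_test(ds$n1, ds$n2, ds$r, alpha = alpha)
  verdict <- rep(NA_character_, nrow(ds))
  verdict[!rt$accept] <- "removed_runs"
  todo <- is.na(verdict)
  lr <- longest_run_test(ds$n1[todo], ds$n2[todo],
                         ds$longest_f[todo], ds$longest_r[todo])
  v <- as.character(lr)
  v[v == "forward"] <- "accept_forward"
  v[v == "reverse"] <- "accept_reverse"
  v[v == "removed"] <- "removed_no_long_run"
  verdict[todo] <- v
  amb <- which(verdict == "ambiguous")
  if (length(amb)) {
    it <- identity_test(ds$p1[amb], ds$p2[amb], ds$n1[amb], ds$n2[amb])
    verdict[amb] <- ifelse(it$keep,
                           paste0("accept_", it$direction),
                           "removed_ambiguous")
  }
  ds$z_runs <- rt$z
  ds$verdict <- factor(verdict,
                       levels = c("accept_forward", "accept_reverse",
                                  "removed_runs", "removed_no_long_run",
                                  "removed_ambiguous"))
  ds
}

#' Remove discordant read pairs
#'
#' Under an FR (standard Illumina) library, the two mates of a proper
#' pair match a gene in opposite orientations. A pair is dropped from a
#' gene when both mates were accepted in the same orientation, or when
#' one mate was accepted and the other removed as ambiguous (conflicting
#' evidence).
#'
#' @param read integer read indices (within one gene's screen).
#' @param verdict verdict factor from [screen_reads()].
#' @param mate mate mapping as in [salvage_pairs()].
#' @return logical `keep` per entry.
#' @export
remove_discordant_pairs <- function(read, verdict, mate) {
  verdict <- as.character(verdict)
  ori <- ifelse(verdict == "accept_forward", 1L,
                ifelse(verdict == "accept_reverse", -1L, 0L))
  names(ori) <- as.character(read)
  amb <- verdict == "removed_ambiguous"
  names(amb) <- as.character(read)
  keep <- ori != 0L
  m <- mate[read]
  has_mate <- !is.na(m) & as.character(m) %in% names(ori)
  mi <- as.character(m[has_mate])
  same_dir <- ori[has_mate] != 0L & ori[mi] != 0L & ori[has_mate] == ori[mi]
  mate_amb <- ori[has_mate] != 0L & amb[mi]
  keep[has_mate][same_dir | mate_amb] <- FALSE
  unname(keep)
}

#' Iterative re-filtering with a coverage guard
#'
#' Re-filters a gene's read set with an increasing k-mer schedule: at each
#' step a read is retained when it shares at least `min_hits` k-mers (on
#' either strand) with the reference. The coverage estimate is retained
#' bases over the reference length; when it drops below `floor`, the last
#' step is reverted and filtering stops, so the returned set is never
#' empty when the input is non-empty.
#'
#' @param reads character vector of the gene's screened reads.
#' @param reference the gene's reference sequence(s).
#' @param k_schedule strictly increasing k-mer sizes, e.g. `c(21, 25, 29)`.
#' @param floor minimum acceptable coverage (default 2).
#' @param min_hits minimum shared k-mers per read (default 1).
#' @return list with `keep` (logical over `reads`), `coverage`, and
#'   `k_used` (the last schedule entry applied, or `NA` if none).
#' @export
iterative_refilter <- function(reads, reference, k_schedule, floor = 2,
                               min_hits = 1L) {
  ref_len <- sum(nchar(reference))
  if (ref_len == 0L) stop("reference length is zero")
  if (is.unsorted(k_schedule, strictly = TRUE)) {
    stop("k_schedule must be strictly increasing")
  }
  keep <- rep(TRUE, length(reads))
  cov <- sum(nchar(reads)) / ref_len
  k_used <- NA_integer_
  for (k in k_schedule) {
    set <- ref_kmer_set(reference, k)
    hits <- cpp_hit_counts(as.character(reads), set, as.integer(k))
    step_keep <- keep & hits >= min_hits
    step_cov <- sum(nchar(reads)[step_keep]) / ref_len
    if (step_cov < floor) break  # revert this step and stop
    keep <- step_keep
    cov <- step_cov
    k_used <- as.integer(k)
  }
  list(keep = keep, coverage = cov, k_used = k_used)
}
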