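test_that("baiting assigns reads by shared k-mers on either strand", {
  set.seed(21)
  refs <- c(geneA = random_dna(600), geneB = random_dna(600))
  idx <- build_kmer_index(refs, k = 17)
  reads <- c(substr(refs[["geneA"]], 101, 250),       # exact substring
             revcomp(substr(refs[["geneB"]], 51, 200)),  # reverse strand
             random_dna(150))                          # unrelated
  a <- bait_reads(reads, idx, min_hits = 1)
  expect_setequal(a$gene[a$read == 1], "geneA")
  expect_setequal(a$gene[a$read == 2], "geneB")
  expect_false(3 %in% a$read)
  expect_warning(bait_reads(character(), idx), "empty")
})

test_that("baiting recalls nearly all reads from their source genes at divergence 0", {
  set.seed(22)
  genes <- simulate_genes(2, length = 1000, seed = 22)
  refs <- vapply(genes, function(g) g[["A"]], character(1))  # divergence 0
  genome <- concat_genome(genes, "A")
  rs <- simulate_reads(genome, 5, p_err = 0, seed = 23)
  coords <- attr(genome, "coords")
  idx <- build_kmer_index(refs, k = 31)
  pr <- paired_reads(rs)
  a <- bait_reads(pr$reads, idx)
  # ground-truth spans: each mate covers one end of its fragment
  left_s <- rs$start
  left_e <- rs$start + 149
  right_e <- rs$start + rs$frag_len - 1
  right_s <- right_e - 149
  r1_s <- ifelse(rs$minus, right_s, left_s)
  r1_e <- ifelse(rs$minus, right_e, left_e)
  r2_s <- ifelse(rs$minus, left_s, right_s)
  r2_e <- ifelse(rs$minus, left_e, right_e)
  rd_s <- c(r1_s, r2_s)
  rd_e <- c(r1_e, r2_e)
  n_due <- 0L
  n_got <- 0L
  for (i in seq_len(nrow(coords))) {
    overlap <- pmin(rd_e, coords$end[i]) - pmax(rd_s, coords$start[i] + 1L) + 1L
    due <- which(overlap >= 31)  # enough overlap to share one 31-mer
    got <- a$read[a$gene == coords$gene[i]]
    n_due <- n_due + length(due)
    n_got <- n_got + sum(due %in% got)
  }
  expect_gte(n_got / n_due, 0.99)
})

test_that("pair salvage adds unassigned mates and leaves unrelated pairs alone", {
  assignment <- data.frame(read = c(1L, 3L, 4L), gene = c("g1", "g2", "g3"),
                           hits = c(5L, 2L, 7L), stringsAsFactors = FALSE)
  mate <- c(2L, 1L, 4L, 3L, 6L, 5L)
  out <- salvage_pairs(assignment, mate)
  expect_true(any(out$read == 2 & out$gene == "g1" & out$salvaged))
  # mates of 3/4 get each other's genes symmetrically
  expect_true(any(out$read == 4 & out$gene == "g2"))
  expect_true(any(out$read == 3 & out$gene == "g3"))
  # pair (5,6) wholly unassigned stays unassigned
  expect_false(any(out$read %in% c(5L, 6L)))
  # already-present pairs are not duplicated
  expect_false(anyDuplicated(paste(out$read, out$gene)) > 0)
})

test_that("direction sequences mirror read orientation exactly", {
  set.seed(24)
  ref <- random_dna(1000)
  rd <- substr(ref, 101, 250)
  ds <- direction_sequence(rd, ref, k = 17)
  expect_equal(ds$n1, 134)
  expect_equal(ds$n2, 0)
  expect_equal(ds$r, 1)
  expect_equal(ds$longest_f, 134)
  ds_rc <- direction_sequence(revcomp(rd), ref, k = 17)
  expect_equal(ds_rc$n1, 0)
  expect_equal(ds_rc$n2, ds$n1)
  expect_equal(ds_rc$longest_r, ds$longest_f)
  # half-forward, half-inverted read: one F block then one R block
  mix <- paste0(substr(ref, 101, 175), revcomp(substr(ref, 301, 375)))
  ds_mix <- direction_sequence(mix, ref, k = 17)
  expect_equal(ds_mix$r, 2)
  expect_gte(ds_mix$n1, 59)  # 75 - 17 + 1 windows per block (junction
  expect_gte(ds_mix$n2, 59)  # windows may add a chance call)
  expect_match(ds_mix$calls, "^F+R+$")
})

test_that("direction calls of a read and its reverse complement swap F and R", {
  set.seed(25)
  ref <- random_dna(800)
  for (i in 1:10) {
    s <- sample(600, 1)
    rd <- as.character(mutate_reference(substr(ref, s, s + 149), 0.03))
    a <- direction_sequence(rd, ref, k = 17)
    b <- direction_sequence(revcomp(rd), ref, k = 17)
    expect_equal(a$n1, b$n2)
    expect_equal(a$n2, b$n1)
    expect_equal(a$longest_f, b$longest_r)
    expect_equal(a$r, b$r)
  }
})

test_that("runs test matches direct evaluation of its printed formulas", {
  # one F block + one R block of 100 each
  rt <- runs_test(100, 100, 2)
  expect_equal(rt$z, (2 - 101) / sqrt(2 * 100 * 100 * (2 * 100 * 100 - 200) /
                                        (200^2 * 199)), tolerance = 1e-12)
  expect_equal(rt$z, -14.036, tolerance = 1e-3)
  expect_true(rt$accept)
  # perfectly alternating: strong rejection on the upper side
  rt2 <- runs_test(10, 10, 20)
  expect_equal(rt2$z, 4.135, tolerance = 1e-3)
  expect_false(rt2$accept)
  # single-direction and zero-variance inputs bypass
  expect_true(runs_test(134, 0, 1)$bypass)
  expect_true(runs_test(1, 1, 2)$bypass)
})

test_that("runs test accepts i.i.d. null sequences at about the nominal lower-tail rate", {
  set.seed(26)
  alpha <- 0.05
  for (n in c(20, 100, 400)) {
    reps <- 4000
    m <- matrix(sample(c(0L, 1L), n * reps, replace = TRUE), nrow = n)
    n1 <- colSums(m)
    n2 <- n - n1
    r <- 1L + colSums(m[-1L, , drop = FALSE] != m[-n, , drop = FALSE])
    rt <- runs_test(n1, n2, r, alpha = alpha)
    rate <- mean(rt$accept & !rt$bypass)
    se <- sqrt(alpha * (1 - alpha) / reps)
    expect_lt(abs(rate - alpha), 4 * se + 0.01)
  }
})

test_that("longest-run threshold follows E_n(L) + 4 and the n = 2 bound holds", {
  expect_equal(expected_longest_run(130) + 4, log2(130) - 0.6676 + 4)
  expect_identical(as.character(longest_run_test(130, 0, 130, 0)), "forward")
  # n = 64, longest run 5 in each direction: threshold ~9.33, neither qualifies
  expect_identical(as.character(longest_run_test(32, 32, 5, 5)), "removed")
  expect_identical(as.character(longest_run_test(0, 130, 0, 130)), "reverse")
  expect_identical(as.character(longest_run_test(60, 60, 20, 25)), "ambiguous")
  expect_identical(as.character(longest_run_test(1, 0, 1, 0)), "removed")
  # closed-form bound at n = 2 exceeds the 95% confidence level
  expect_gt(longest_run_bound(2), 0.95)
  # and increases with n
  ns <- 2^(1:10)
  expect_true(all(diff(longest_run_bound(ns)) > 0))
})

test_that("k-mer identity test keeps only significantly asymmetric reads", {
  expect_false(identity_test(0.9, 0.9, 50, 50)$keep)   # z = 0
  it <- identity_test(1.0, 0.5, 50, 50)
  expect_equal(it$z, 7.071, tolerance = 1e-3)
  expect_true(it$keep)
  expect_identical(it$direction, "forward")
  it2 <- identity_test(0.6, 0.5, 20, 20)
  expect_equal(abs(it2$z), 0.639, tolerance = 1e-3)
  expect_false(it2$keep)
  # unresolvable degenerate proportions are removed
  expect_false(identity_test(1, 0, 30, 30)$keep)
})

test_that("screening verdicts cover the cascade", {
  set.seed(27)
  ref <- random_dna(1000)
  rd <- substr(ref, 101, 250)
  inv <- paste0(substr(ref, 101, 175), revcomp(substr(ref, 301, 375)))
  junk <- random_dna(150)
  sc <- screen_reads(c(rd, revcomp(rd), inv, junk), ref)
  expect_identical(as.character(sc$verdict),
                   c("accept_forward", "accept_reverse",
                     "removed_ambiguous", "removed_no_long_run"))
})

test_that("discordant pairs are dropped by orientation conflicts", {
  mate <- c(2L, 1L, 4L, 3L, 6L, 5L)
  read <- 1:6
  v <- factor(c("accept_forward", "accept_reverse",    # proper pair
                "accept_forward", "accept_forward",    # same-direction pair
                "accept_forward", "removed_ambiguous"),  # ambiguous mate
              levels = levels(screen_reads("ACGTACGTACGTACGTACGT",
                                           "ACGTACGTACGTACGTACGT")$verdict))
  keep <- remove_discordant_pairs(read, v, mate)
  expect_identical(keep, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("iterative re-filtering reverts on a coverage drop and never empties the set", {
  set.seed(28)
  truth <- random_dna(500)
  # 10x error-free reads: the schedule runs to its end with everything kept
  reads10 <- tiling_reads(truth, 150, 15)
  rf <- iterative_refilter(reads10, truth, c(21, 25, 29), floor = 2)
  expect_true(all(rf$keep))
  expect_identical(rf$k_used, 29L)
  # sparse divergent reads + aggressive schedule: revert, non-empty result
  few <- as.character(mutate_reference(
    substring(truth, c(1, 180, 350), c(150, 329, 499)), 0.1))
  rf2 <- iterative_refilter(few, truth, c(21, 27), floor = 2)
  expect_gt(sum(rf2$keep), 0)
  # floor 0 is vacuous: identical to running the full schedule
  rf3 <- iterative_refilter(reads10, truth, c(21, 25, 29), floor = 0)
  expect_identical(rf3$keep, rf$keep)
  expect_error(iterative_refilter(reads10, "", c(21)), "zero")
  expect_error(iterative_refilter(reads10, truth, c(25, 21)), "increasing")
})
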