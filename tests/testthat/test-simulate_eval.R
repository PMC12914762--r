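test_that("the fixture tree has ten tips A-J with unequal positive branch lengths", {
  tr <- default_species_tree()
  expect_setequal(tr$tip.label, LETTERS[1:10])
  expect_true(all(tr$edge.length > 0))
  expect_gt(length(unique(tr$edge.length)), 5)  # unequal lengths
})

test_that("gene simulation is deterministic and follows the tree", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,J:0):0);")
  tr$edge.length <- rep(1e-9, length(tr$edge.length))  # effectively zero
  g <- simulate_genes(1, length = 200, tree = tr, seed = 5)
  expect_length(unique(unname(g[[1]])), 1)  # no evolution: identical tips
  g1 <- simulate_genes(3, length = 100, seed = 6)
  g2 <- simulate_genes(3, length = 100, seed = 6)
  expect_identical(g1, g2)
  expect_true(all(nchar(unlist(g1)) == 100))
  expect_true(all(strsplit(g1[[1]][["A"]], "")[[1]] %in% c("A", "C", "G", "T")))
})

test_that("observed p-distances match the closed-form expectation", {
  # two leaves at total path length 0.1, long sequences
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  g <- simulate_genes(1, length = 10000, tree = tr, seed = 7)
  p_obs <- mean(strsplit(g[[1]][["A"]], "")[[1]] !=
                  strsplit(g[[1]][["B"]], "")[[1]])
  p_exp <- expected_p_distance(0.1)
  sd3 <- 3 * sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), sd3)
})

test_that("reference mutation hits the requested divergence", {
  set.seed(8)
  s <- random_dna(1000)
  expect_identical(as.character(mutate_reference(s, 0)), s)
  m1 <- as.character(mutate_reference(s, 1))
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))
  m <- as.character(mutate_reference(s, 0.05))
  nd <- sum(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  expect_lt(abs(nd - 50), 3 * sqrt(1000 * 0.05 * 0.95))
  expect_identical(mutate_reference(s, 0.05, seed = 9),
                   mutate_reference(s, 0.05, seed = 9))
})

test_that("read simulation matches its contract", {
  set.seed(10)
  genome <- random_dna(5000)
  rs <- simulate_reads(genome, 10, p_err = 0, seed = 11)
  expect_length(rs$r1, round(10 * 5000 / 300))
  expect_true(all(nchar(rs$r1) == 150))
  # error-free reads are exact substrings of the genome or its reverse
  # complement
  both <- paste0(genome, "NN", revcomp(genome))
  ok <- vapply(c(rs$r1[1:50], rs$r2[1:50]), function(r)
    length(grepRaw(r, both, fixed = TRUE)) > 0, logical(1))
  expect_true(all(ok))
  # total bases approximate the requested coverage within 2%
  bases <- sum(nchar(rs$r1)) + sum(nchar(rs$r2))
  expect_lt(abs(bases - 10 * 5000) / (10 * 5000), 0.02)
  # determinism
  rs2 <- simulate_reads(genome, 10, p_err = 0, seed = 11)
  expect_identical(rs, rs2)
  # error rate within 3 SD of the binomial expectation
  rs_e <- simulate_reads(genome, 30, p_err = 0.01, seed = 12)
  n <- length(rs_e$r1)
  errs <- 0L; tot <- 0L
  for (i in seq_len(n)) {
    s <- rs_e$start[i]
    frag <- substr(genome, s, s + rs_e$frag_len[i] - 1)
    left <- substr(frag, 1, 150)
    right <- revcomp(substr(frag, rs_e$frag_len[i] - 149, rs_e$frag_len[i]))
    a <- if (rs_e$minus[i]) right else left
    b <- if (rs_e$minus[i]) left else right
    errs <- errs + sum(strsplit(rs_e$r1[i], "")[[1]] != strsplit(a, "")[[1]]) +
      sum(strsplit(rs_e$r2[i], "")[[1]] != strsplit(b, "")[[1]])
    tot <- tot + 300L
  }
  expect_lt(abs(errs / tot - 0.01), 3 * sqrt(0.01 * 0.99 / tot))
  # a genome shorter than the insert errors out
  expect_error(simulate_reads(random_dna(100), 5), "shorter")
})

test_that("quality classification implements the four-level scheme", {
  set.seed(13)
  std <- lapply(1:2, function(i) {
    setNames(vapply(1:10, function(j) random_dna(1000), character(1)),
             LETTERS[1:10])
  })
  names(std) <- c("g1", "g2")
  # full-length exact recovery in all 10 taxa: L1 across the board
  rec <- data.frame(gene = "g1", taxon = LETTERS[1:10],
                    seq = unname(std[["g1"]]), stringsAsFactors = FALSE)
  q <- classify_quality(rec, std)
  expect_true(all(q$level == "L1"))
  expect_true(all(q$identity == 100 & q$coverage == 100 & q$count == 10))
  # 300 bp fragments in 8 taxa: coverage 30 < 50 -> L2
  rec2 <- data.frame(gene = "g1", taxon = LETTERS[1:8],
                     seq = substr(unname(std[["g1"]][1:8]), 201, 500),
                     stringsAsFactors = FALSE)
  q2 <- classify_quality(rec2, std)
  expect_true(all(q2$level == "L2"))
  expect_true(all(q2$coverage == 30))
  # exact recovery in 3 taxa only: count <= 6 -> L3
  rec3 <- rec[1:3, ]
  expect_true(all(classify_quality(rec3, std)$level == "L3"))
  # one substitution: identity < 100 -> L4 with a positive mismatch rate
  s <- std[["g2"]][["A"]]
  bad <- paste0(substr(s, 1, 499), ifelse(substr(s, 500, 500) == "A", "G", "A"),
                substr(s, 501, 1000))
  rec4 <- data.frame(gene = rep("g2", 7), taxon = LETTERS[1:7],
                     seq = c(bad, unname(std[["g2"]][2:7])),
                     stringsAsFactors = FALSE)
  q4 <- classify_quality(rec4, std)
  expect_identical(as.character(q4$level[1]), "L4")
  expect_gt(q4$mismatch_rate[1], 0)
  expect_true(all(q4$level[-1] == "L1"))
  # coverage exactly 50 closes into L1
  rec5 <- data.frame(gene = "g1", taxon = LETTERS[1:7],
                     seq = substr(unname(std[["g1"]][1:7]), 1, 500),
                     stringsAsFactors = FALSE)
  expect_true(all(classify_quality(rec5, std)$level == "L1"))
  # unknown gene ids are an error
  expect_error(classify_quality(data.frame(gene = "nope", taxon = "A",
                                           seq = "ACGT"), std), "unknown")
})

test_that("summaries pool levels and length-weight the mismatch rate", {
  rec <- data.frame(gene = "g", taxon = LETTERS[1:10],
                    identity = c(rep(100, 8), 98, 98),
                    coverage = rep(100, 10), count = 10,
                    level = factor(c(rep("L1", 8), "L4", "L4"),
                                   levels = c("L1", "L2", "L3", "L4")),
                    mismatch_rate = c(rep(0, 8), 2, 2))
  s <- summarize_quality(rec, recovered_lengths = rep(1000, 10))
  expect_equal(s$L1, 0.8)
  expect_equal(s$L4, 0.2)
  expect_equal(s$mismatch_rate, 0.4)  # 2 of 10 sequences at 2%
  s2 <- summarize_quality(rec[1:8, ], recovered_lengths = rep(1000, 8))
  expect_equal(s2$L1, 1.0)
  expect_equal(s2$mismatch_rate, 0)
})
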