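test_that("anchor score equals normalised anchored bases", {
  set.seed(31)
  ref <- random_dna(1000)
  # read identical to a reference region: one run, N = 1 at uncapped runs
  rd <- substr(ref, 201, 350)
  a1 <- anchor_score(rd, ref, k = 31, run_cap = 0)
  expect_equal(a1$N, 1)
  expect_equal(a1$s, 31 / 120)
  # no shared k-mers: N = 0, s = 0
  a0 <- anchor_score(random_dna(150), ref, k = 31, run_cap = 0)
  expect_equal(a0$N, 0)
  expect_equal(a0$s, 0)
  # two disjoint anchor runs at k = 21: N = 2, s = 42/130
  rd2 <- paste0(substr(ref, 101, 140),    # 40 bp -> 20 anchors
                random_dna(70),           # spacer breaks the run
                substr(ref, 501, 540))    # 40 bp -> 20 anchors
  a2 <- anchor_score(rd2, ref, k = 21, run_cap = 0)
  expect_equal(a2$N, 2)
  expect_equal(a2$s, 42 / 130)
  # run cap: a 150 bp exact read has 120 anchors at k=31 -> ceil(120/64) = 2
  a3 <- anchor_score(rd, ref, k = 31, run_cap = 64)
  expect_equal(a3$N, 2)
})

test_that("adaptive k selection applies the half-max rule", {
  set.seed(32)
  ref <- random_dna(1000)
  reads <- tiling_reads(ref, 150, 25)
  # identical reads: score profile rises with k, ka is the largest candidate
  sel <- select_k(reads, ref)
  expect_identical(sel$ka, max(sel$profile$k[
    sel$profile$s_bar >= max(sel$profile$s_bar) / 2]))
  expect_identical(select_k(reads, ref, k_candidates = 21L)$ka, 21L)
  # all-zero profile falls back with a warning
  expect_warning(sel0 <- select_k(random_dna(150), ref, fallback = 19),
                 "falling back")
  expect_identical(sel0$ka, 19L)
})

test_that("k selection is monotone under reference divergence", {
  set.seed(33)
  truth <- random_dna(1000)
  reads <- tiling_reads(truth, 150, 20)
  ka0 <- select_k(reads, truth)$ka
  ka1 <- select_k(reads, as.character(mutate_reference(truth, 0.1, seed = 34)))$ka
  expect_lte(ka1, ka0)
})

test_that("graph nodes carry read multiplicities and reference marks", {
  reads <- rep("ACGTACGGTTACGGAT", 10)
  g <- build_graph(reads, "ACGTACGGTTACGGAT", 7)
  expect_true(all(g$weight == 10))
  expect_true(all(g$ref_mark))
  expect_equal(nrow(g), 10)  # 16 - 7 + 1 windows, all distinct canonically
  # two reads overlapping by ka-1 form one unbranched chain
  set.seed(35)
  s <- random_dna(60)
  g2 <- build_graph(c(substr(s, 1, 40), substr(s, 21, 60)), s, 21)
  expect_equal(nrow(g2), 40 - 21 + 1 + 20)
  # a single SNP between two reads opens a bubble of ka nodes
  a <- random_dna(61)
  b <- paste0(substr(a, 1, 30), ifelse(substr(a, 31, 31) == "A", "C", "A"),
              substr(a, 32, 61))
  g3 <- build_graph(c(a, b), a, 21)
  ga <- build_graph(a, a, 21)
  expect_equal(nrow(g3) - nrow(ga), 21)
})

test_that("perfect-coverage reads reconstruct the sample sequence", {
  set.seed(36)
  truth <- random_dna(500)
  ref <- as.character(mutate_reference(truth, 0.05, seed = 37))
  reads <- tiling_reads(truth, 150, 15)  # ~10x error-free
  ctg <- assemble_gene(reads, ref, 31)
  expect_equal(nrow(ctg) >= 1, TRUE)
  expect_true(grepl(ctg$contig[1], truth, fixed = TRUE))
  expect_gte(ctg$length[1], 450)
})

test_that("contigs report the sample allele, never the reference base", {
  set.seed(38)
  truth <- random_dna(300)
  # reference carries G where every read carries A
  pos <- 150
  sample_base <- "A"
  ref_base <- "G"
  truth <- paste0(substr(truth, 1, pos - 1), sample_base,
                  substr(truth, pos + 1, 300))
  ref <- paste0(substr(truth, 1, pos - 1), ref_base,
                substr(truth, pos + 1, 300))
  reads <- tiling_reads(truth, 100, 10)
  ctg <- assemble_gene(reads, ref, 25)
  expect_true(grepl(ctg$contig[1], truth, fixed = TRUE))
  expect_false(grepl(ref, ctg$contig[1], fixed = TRUE))
})

test_that("the weighted walk prefers the strongly supported branch of a bubble", {
  set.seed(39)
  truth <- random_dna(200)
  alt <- paste0(substr(truth, 1, 99), ifelse(substr(truth, 100, 100) == "A", "C", "A"),
                substr(truth, 101, 200))
  reads <- c(rep(substring(truth, seq(1, 141, 20), seq(60, 200, 20)), 9),
             substring(alt, seq(1, 141, 20), seq(60, 200, 20)))
  ctg <- assemble_gene(reads, truth, 21, min_weight = 1)
  expect_true(grepl(substr(truth, 80, 120), ctg$contig[1], fixed = TRUE))
})

test_that("assembly is deterministic and respects edge cases", {
  set.seed(40)
  truth <- random_dna(400)
  ref <- as.character(mutate_reference(truth, 0.05, seed = 41))
  reads <- sample(tiling_reads(truth, 120, 30))
  c1 <- assemble_gene(reads, ref, 25)
  c2 <- assemble_gene(reads, ref, 25)
  expect_identical(c1, c2)
  # contigs come out longest first
  expect_false(is.unsorted(rev(c1$length)))
  # empty read set: unrecovered
  expect_equal(nrow(assemble_gene(character(), ref, 25)), 0)
  # reads with no reference anchor yield no contig
  expect_equal(nrow(assemble_gene(tiling_reads(random_dna(300), 100, 20),
                                  ref, 25)), 0)
})

test_that("soft boundary trims extension beyond the anchored span", {
  set.seed(42)
  core <- random_dna(300)
  flank <- random_dna(200)
  truth <- paste0(core, flank)  # sample has a long tail the reference lacks
  reads <- tiling_reads(truth, 100, 10)
  ctg <- assemble_gene(reads, core, 25, soft_boundary = 30)
  # walk reaches into the flank but is trimmed to ~30 bases past the anchors
  expect_lte(ctg$length[1], 300 + 30 + 24 + 5)
  expect_gte(ctg$length[1], 250)
})
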