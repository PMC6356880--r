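test_that("score filtering keeps the boundary and drops below it", {
  cands <- data.frame(id = c("a", "b", "c"), score = c(2.0, 1.99, 7.3))
  kept <- score_filter(cands)
  expect_identical(kept$id, c("a", "c"))
  expect_equal(nrow(score_filter(cands[0, ])), 0L)
})

test_that("hairpin folding solves the canonical stem and refuses nothing pairable", {
  f <- fold_hairpin("GGGAAACCC")
  expect_equal(f$max_pairs, 3L)
  expect_equal(f$pairing[1:3], c(9L, 8L, 7L))
  expect_equal(fold_hairpin("AAAAAA")$max_pairs, 0L)
})

test_that("hairpin folding equals exhaustive enumeration up to 14 nt", {
  set.seed(51)
  seqs <- c("GGGAAACCC", "GCGCAAAGCGC", "AAAAAA",
            vapply(5:14, random_rna, character(1)),
            vapply(1:25, function(i) random_rna(sample(6:14, 1)),
                   character(1)))
  for (s in seqs) {
    f <- fold_hairpin(s)
    expect_equal(f$max_pairs, oracle_max_pairs(s), info = s)
    # valid structure: symmetric, non-crossing, pairable, min loop
    p <- f$pairing
    for (i in which(p > 0)) {
      expect_equal(p[p[i]], i)
      if (p[i] > i) expect_gte(p[i] - i - 1, 3)
    }
    pairs <- which(p > seq_along(p))
    if (length(pairs) > 1) {
      for (i in pairs) for (j in pairs) {
        if (i < j) expect_false(i < j & j < p[i] & p[i] < p[j])
      }
    }
    expect_equal(sum(p > 0) %/% 2, f$max_pairs)
  }
})

# a candidate engineered to satisfy all five annotation criteria
make_candidate <- function() {
  cfg <- simulation_config(seed = 61L, n_genes = 2L)
  mo <- generate_mirnaome(cfg)
  p <- mo$precursors[1, ]
  m5 <- mo$matures$sequence[mo$matures$id == p$mature5p]
  m3 <- mo$matures$sequence[mo$matures$id == p$mature3p]
  off3 <- as.integer(regexpr(m3, p$sequence, fixed = TRUE))
  ev <- data.frame(
    sequence = c(rep(m5, 3), rep(m3, 2)),
    count = c(6L, 5L, 4L, 3L, 2L),
    sample = c("s1", "s2", "s3", "s1", "s2"),
    offset = c(1L, 1L, 1L, off3, off3),
    mismatches = 0L, stringsAsFactors = FALSE)
  list(precursor = p, matures = mo$matures, read_evidence = ev)
}

test_that("a designed candidate passes all five criteria", {
  cand <- make_candidate()
  rep <- validate_criteria(cand)
  expect_true(rep$c1); expect_true(rep$c2); expect_true(rep$c3)
  expect_true(rep$c4); expect_true(rep$c5)
  expect_true(rep$overall)
  expect_gte(rep$evidence$n_perfect_reads, 10)
})

test_that("criteria fail on thin evidence and stay monotone under more reads", {
  cand <- make_candidate()
  thin <- cand
  thin$read_evidence$count <- c(3L, 2L, 2L, 1L, 1L)  # 9 perfect reads
  rep <- validate_criteria(thin)
  expect_false(rep$c2)
  expect_false(rep$overall)

  one_sample <- cand
  one_sample$read_evidence$sample <- "s1"
  expect_false(validate_criteria(one_sample)$c1)

  # adding perfect reads at the modal start never flips pass -> fail
  more <- cand
  more$read_evidence <- rbind(more$read_evidence,
                              data.frame(sequence = more$read_evidence$sequence[1],
                                         count = 50L, sample = "s4",
                                         offset = 1L, mismatches = 0L))
  rep2 <- validate_criteria(more)
  expect_true(rep2$overall)

  expect_error(validate_criteria(list(precursor = cand$precursor,
                                      matures = cand$matures,
                                      read_evidence = NULL)),
               "unevaluable")
})

test_that("a poorly paired mature fails the 60% pairing criterion", {
  # 5p arm mostly unpairable: an 8-base G/C stem followed by a C run whose
  # possible G partners are limited, keeping the 5p paired fraction under 60%
  m5 <- paste0("GCGCGCGC", strrep("C", 14))          # 22 nt
  loop <- "UUUAAAUUU"
  m3 <- paste0(strrep("A", 10), revcomp_rna(substr(m5, 1, 8)), "AA")
  pre <- paste0(m5, loop, m3)
  prec <- data.frame(id = "pw", sequence = pre, flank5 = strrep("C", 30),
                     flank3 = strrep("C", 30), mature5p = "pw-5p",
                     mature3p = "pw-3p", stringsAsFactors = FALSE)
  matures <- data.frame(id = c("pw-3p", "pw-5p"), sequence = c(m3, m5),
                        arm = c("3p", "5p"), parent = "pw",
                        stringsAsFactors = FALSE)
  ev <- data.frame(sequence = c(m5, m3), count = c(10L, 10L),
                   sample = c("s1", "s2"),
                   offset = c(1L, as.integer(regexpr(m3, pre, fixed = TRUE))),
                   mismatches = 0L)
  rep <- validate_criteria(list(precursor = prec, matures = matures,
                                read_evidence = ev))
  expect_false(rep$c5)
  expect_false(rep$overall)
})

test_that("curated precursor tables pass mature-substring containment", {
  tbl <- read.delim(mirforge_example("novel_salmon_mirnas.tsv"))
  ok <- check_mature_containment(tbl)
  expect_true(all(ok))
  corrupt <- tbl
  substr(corrupt$mature5p[3], 5, 5) <-
    setdiff(c("A", "C", "G", "U"), substr(corrupt$mature5p[3], 5, 5))[1]
  ok2 <- check_mature_containment(corrupt)
  expect_false(ok2[[3]])
  expect_equal(sum(ok2), 16L)
})

test_that("repeat flagging counts both strands with a strict >15 rule", {
  set.seed(71)
  pre <- random_rna(60)
  planted16 <- paste0(vapply(1:16, function(i)
    paste0(random_rna(20), pre, random_rna(20)), character(1)),
    collapse = "")
  r16 <- flag_repeats(pre, c(chr1 = planted16))
  expect_equal(r16$n_loci, 16L)
  expect_true(r16$repeat_flag)
  planted15 <- paste0(vapply(1:14, function(i)
    paste0(random_rna(20), pre, random_rna(20)), character(1)),
    collapse = "")
  genome15 <- c(chr1 = planted15,
                chr2 = paste0(random_rna(30), revcomp_rna(pre),
                              random_rna(30)))
  r15 <- flag_repeats(pre, genome15)
  expect_equal(r15$n_loci, 15L)
  expect_false(r15$repeat_flag)
  r1 <- flag_repeats(pre, c(chr1 = paste0(random_rna(10), pre)))
  expect_false(r1$repeat_flag)
})

test_that("cluster annotation respects the 10-kb gap, strand, and input order", {
  base <- loci_frame(id = c("g1", "g2"), contig = "c1",
                     start = c(1000L, 1000L + 70L + 8400L),
                     end = c(1070L, 1070L + 70L + 8400L), strand = "+")
  cl <- annotate_clusters(base)
  expect_identical(cl$cluster_id, rep("cluster_g1", 2))

  exact <- base; exact$start[2] <- exact$end[1] + 10000L
  exact$end[2] <- exact$start[2] + 70L
  expect_identical(annotate_clusters(exact)$cluster_id,
                   rep("cluster_g1", 2))
  over <- base; over$start[2] <- over$end[1] + 10001L
  over$end[2] <- over$start[2] + 70L
  expect_true(all(is.na(annotate_clusters(over)$cluster_id)))

  anti <- base; anti$strand <- c("+", "-"); anti$start[2] <- anti$end[1] + 100L
  anti$end[2] <- anti$start[2] + 70L
  expect_true(all(is.na(annotate_clusters(anti)$cluster_id)))

  # order invariance and transitive chaining
  chain <- loci_frame(id = c("a", "b", "c"), contig = "c2",
                      start = c(0L, 5000L, 10000L),
                      end = c(100L, 5100L, 10100L), strand = "-")
  shuffled <- chain[c(3, 1, 2), ]
  out <- annotate_clusters(shuffled)
  expect_identical(out$cluster_id[out$id == "c"], "cluster_a")
  expect_identical(unique(out$cluster_id), "cluster_a")
})
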