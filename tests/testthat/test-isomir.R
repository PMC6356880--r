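# a miniature miRNAome with hand-controlled sequences for classification tests
tiny_mirnaome <- function() {
  m5 <- "UGAGGUAGUAGGUUGUAUAGUU"          # 22 nt, let-7-like
  loop <- "GGGAAAGGGAAAGGGUU"
  m3 <- paste0(revcomp_rna(substr(m5, 1, 20)), "CC")
  pre <- paste0(m5, loop, m3)
  precursors <- data.frame(id = "pre-t1", sequence = pre,
                           flank5 = strrep("G", 30),
                           # downstream context starts with G
                           flank3 = paste0("G", strrep("A", 29)),
                           mature5p = "t1-5p", mature3p = "t1-3p",
                           stringsAsFactors = FALSE)
  matures <- data.frame(id = c("t1-3p", "t1-5p"),
                        sequence = c(m3, m5), arm = c("3p", "5p"),
                        parent = "pre-t1", stringsAsFactors = FALSE)
  list(precursors = precursors, matures = matures)
}

test_that("seed-anchored classification assigns the expected categories", {
  mo <- tiny_mirnaome()
  m5 <- mo$matures$sequence[mo$matures$id == "t1-5p"]
  expect_identical(classify_read(m5, mo$matures)$category, "canonical")

  plusU <- paste0(m5, "U")
  cl <- classify_read(plusU, mo$matures)
  expect_identical(cl$category, "isomir_3p_len")
  expect_identical(cl$ext3, "U")

  internal <- m5
  substr(internal, 10, 10) <- "C"   # position 10 of 22
  expect_identical(classify_read(internal, mo$matures)$category,
                   "mismatch_internal")

  sub3 <- m5
  substr(sub3, 22, 22) <- "A"
  expect_identical(classify_read(sub3, mo$matures)$category, "isomir_3p_sub")

  sub5 <- m5
  substr(sub5, 1, 1) <- "A"
  expect_identical(classify_read(sub5, mo$matures)$category, "isomir_5p")

  ext5 <- paste0("C", m5)
  cl5 <- classify_read(ext5, mo$matures)
  expect_identical(cl5$category, "isomir_5p")
  expect_identical(cl5$ext5, "C")

  # a seed-disrupting substitution cannot anchor to this canonical
  seedmut <- m5
  substr(seedmut, 5, 5) <- "C"
  expect_null(classify_read(seedmut, mo$matures))
})

test_that("templated checks use precursor plus flank context", {
  mo <- tiny_mirnaome()
  prec <- mo$precursors
  # 3' extension of the 3p arm: next genomic base is flank3[1] == "G"
  expect_true(check_templated(list(parent = "t1-3p", edits = "",
                                   ext3 = "G", ext5 = ""),
                              prec, mo$matures))
  expect_false(check_templated(list(parent = "t1-3p", edits = "",
                                    ext3 = "U", ext5 = ""),
                               prec, mo$matures))
  # 5' extension of the 5p arm: upstream context is all-G flank
  expect_true(check_templated(list(parent = "t1-5p", edits = "",
                                   ext3 = "", ext5 = "G"),
                              prec, mo$matures))
  expect_false(check_templated(list(parent = "t1-5p", edits = "",
                                    ext3 = "", ext5 = "C"),
                               prec, mo$matures))
  # substitutions are never templated
  expect_false(check_templated(list(parent = "t1-5p", edits = "22:U>A",
                                    ext3 = "", ext5 = ""),
                               prec, mo$matures))
  # missing flanks are an error
  noflank <- prec; noflank$flank3 <- ""
  expect_error(check_templated(list(parent = "t1-5p", edits = "", ext3 = "U",
                                    ext5 = ""), noflank, mo$matures),
               "flanks")
})

test_that("isomiR calling drops templated and short variants and thresholds ESVs", {
  mo <- tiny_mirnaome()
  m5 <- mo$matures$sequence[mo$matures$id == "t1-5p"]
  ext_t <- paste0(m5, substr(mo$precursors$sequence, 23, 23)) # templated
  ext_n <- paste0(m5, "A")                                    # non-templated
  short <- substr(m5, 1, 20)                                  # degradation-like
  esv <- m5; substr(esv, 22, 22) <- "G"                       # low-count 3' sub
  col <- data.frame(
    sequence = c(m5, ext_t, ext_n, short, esv),
    count = c(1000L, 900L, 800L, 700L, 10L))
  prof <- structure(list(r5 = 0.02, r_int = 0.0004, r3 = 0.21, window = 2L),
                    class = "esv_profile")
  calls <- call_isomirs(col, mo, prof)
  expect_false(ext_t %in% calls$sequence)     # templated: absent entirely
  expect_false(short %in% calls$sequence)     # shorter than canonical
  nt <- calls[calls$sequence == ext_n, ]
  expect_identical(nt$category, "isomir_3p_len")
  expect_equal(nt$threshold, as.integer(ceiling(2 * 0.21 * 1000)))
  expect_true(nt$passed_filter)               # 800 >= 420
  low <- calls[calls$sequence == esv, ]
  expect_false(low$passed_filter)             # 10 < 420: filtered as ESV
  expect_true(all(!calls$templated))
})

test_that("polymorphism calling applies the strict 40% fraction rule", {
  mo <- tiny_mirnaome()
  m5 <- mo$matures$sequence[mo$matures$id == "t1-5p"]
  v <- m5; substr(v, 10, 10) <- "C"
  prof <- structure(list(r5 = 0.02, r_int = 0.0004, r3 = 0.21, window = 2L),
                    class = "esv_profile")
  # 450 / (450 + 600) = 0.4286 > 0.40: called
  calls <- call_isomirs(data.frame(sequence = c(m5, v),
                                   count = c(600L, 450L)), mo, prof)
  poly <- call_polymorphisms(calls)
  expect_equal(nrow(poly), 1L)
  expect_equal(poly$position, 10L)
  expect_equal(poly$fraction, 450 / 1050, tolerance = 1e-12)
  expect_false(poly$in_seed)
  # 400 / (400 + 600) = 0.40 exactly: not called (strict inequality)
  calls2 <- call_isomirs(data.frame(sequence = c(m5, v),
                                    count = c(600L, 400L)), mo, prof)
  expect_equal(nrow(call_polymorphisms(calls2)), 0L)
})

test_that("allelic pair comparison reports Hamming distance and seed overlap", {
  p <- compare_allelic_pair("ACAAGCTTGTGTCTATAGGTATG",
                            "ACAAGCTCGTGTCTATAGGTATG")
  expect_equal(p$hamming, 1L)
  expect_equal(p$position, 8L)
  expect_true(p$in_seed)
  p2 <- compare_allelic_pair("AAAA", "AAAA")
  expect_equal(p2$hamming, 0L)
})

test_that("class summaries report 3'-end percentages and abundance flags", {
  expect_equal(pct_3p_end_variants(32, 8, 1), 98)
  mo <- tiny_mirnaome()
  m5 <- mo$matures$sequence[mo$matures$id == "t1-5p"]
  v <- paste0(m5, "A")
  prof <- structure(list(r5 = 0.02, r_int = 0.0004, r3 = 0.21, window = 2L),
                    class = "esv_profile")
  calls <- call_isomirs(data.frame(sequence = c(m5, v),
                                   count = c(100L, 300L)), mo, prof)
  s <- summarize_classes(calls)
  expect_equal(unname(s$class_counts["isomir_3p_len"]), 1L)
  expect_equal(s$pct_3p_end, 100)
  expect_true(s$parent_summary$variant_exceeds_canonical)
  empty <- summarize_classes(calls[calls$category == "none", ])
  expect_true(is.na(empty$pct_3p_end))
  expect_null(empty$parent_summary)
})
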