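cfg_small <- function(seed = 5L, ...) {
  simulation_config(seed = seed, n_genes = 6L, library_size = 20000L, ...)
}

test_that("generated precursors contain their matures and are deterministic", {
  cfg <- cfg_small()
  mo <- generate_mirnaome(cfg)
  expect_equal(nrow(mo$precursors), 6L)
  expect_true(all(nchar(mo$precursors$sequence) >= 55 &
                    nchar(mo$precursors$sequence) <= 70))
  for (i in seq_len(nrow(mo$precursors))) {
    p <- mo$precursors[i, ]
    m5 <- mo$matures$sequence[mo$matures$id == p$mature5p]
    m3 <- mo$matures$sequence[mo$matures$id == p$mature3p]
    expect_true(startsWith(p$sequence, m5))
    expect_true(endsWith(p$sequence, m3))
    expect_true(nchar(p$flank5) == 30 && nchar(p$flank3) == 30)
  }
  # byte-identical FASTA under the same seed
  mo2 <- generate_mirnaome(cfg_small())
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(setNames(mo$precursors$sequence, mo$precursors$id), f1)
  write_fasta(setNames(mo2$precursors$sequence, mo2$precursors$id), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("configured gene pairs are placed as same-strand clusters", {
  cfg <- cfg_small()
  mo <- generate_mirnaome(cfg)
  cl <- mo$truth$clustered
  expect_equal(nrow(cl), 1L)
  a <- mo$loci[mo$loci$id == cl$gene_a, ]
  b <- mo$loci[mo$loci$id == cl$gene_b, ]
  expect_identical(a$contig, b$contig)
  expect_identical(a$strand, b$strand)
  expect_equal(b$start - a$end, 8000L)
})

test_that("control references have the expected lengths and composition", {
  ctl <- generate_control_references(99L)
  expect_equal(unname(nchar(ctl)), c(1750L, 540L))
  gc <- vapply(strsplit(ctl, ""), function(b) mean(b %in% c("G", "C")),
               numeric(1))
  expect_true(all(gc > 0.35 & gc < 0.65))
  expect_identical(generate_control_references(99L), ctl)
})

test_that("manifest label counts are conserved and match the library", {
  cfg <- cfg_small()
  mo <- generate_mirnaome(cfg)
  ctl <- generate_control_references(5L)
  lib <- simulate_library(cfg, mo, ctl)
  expect_equal(nrow(lib$manifest), cfg$library_size)
  expect_equal(sum(table(lib$manifest$label)), cfg$library_size)
  expect_equal(nrow(lib$reads), cfg$library_size)
  expect_true(all(nchar(lib$reads$sequence) == cfg$cycles))
})

test_that("a no-noise, no-variant library contains only expected sequences", {
  cfg <- simulation_config(seed = 2L, n_genes = 4L, library_size = 5000L,
                           esv_rates = c(r5 = 0, r_int = 0, r3 = 0),
                           control_fraction = 0,
                           fragment_rates = c(degradation = 0,
                                              precursor_fragment = 0),
                           isomir_spec = data.frame(),
                           polymorphism_spec = data.frame(),
                           cluster_spec = data.frame())
  mo <- generate_mirnaome(cfg)
  ctl <- generate_control_references(2L)
  lib <- simulate_library(cfg, mo, ctl)
  canon <- mo$matures$sequence[match(mo$precursors$mature5p, mo$matures$id)]
  expect_true(all(lib$manifest$insert %in% canon))
  expect_true(all(lib$manifest$label == "canonical"))
})

test_that("injected substitutions hit read ends at the configured rates", {
  ctl <- generate_control_references(17L)
  n <- 1e5
  cr <- simulate_control_reads(ctl, n, seed = 17L)
  # fraction of reads with >=1 substitution among the last two bases
  ref <- ctl[cr$reference]
  truth <- substring(ref, cr$offset + 1L, cr$offset + nchar(cr$sequence))
  lastmm <- vapply(seq_len(n), function(i) {
    L <- nchar(truth[i])
    substr(truth[i], L - 1L, L) != substr(cr$sequence[i], L - 1L, L)
  }, logical(1))
  p_expect <- 1 - (1 - 0.21)^2
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(mean(lastmm) - p_expect), 3 * se)
  # per-position histogram at the 5' end and internally
  firstmm <- substr(truth, 1, 1) != substr(cr$sequence, 1, 1)
  se5 <- sqrt(0.02 * 0.98 / n)
  expect_lt(abs(mean(firstmm) - 0.02), 3 * se5)
  midmm <- substr(truth, 10, 10) != substr(cr$sequence, 10, 10)
  se_int <- sqrt(0.0004 * 0.9996 / n)
  expect_lt(abs(mean(midmm) - 0.0004), 3 * se_int)
})

test_that("simulated qPCR tables are deterministic and recover planted folds", {
  cfg <- cfg_small(seed = 21L)
  q0 <- simulate_qpcr(cfg, noise_sd = 0)
  expect_true(all(cfg$tissue_profiles$brain["mir-sim-1-5p"] == 2048))
  r <- ddct(q0, "mir-sim-1-5p", "brain")
  expect_equal(r$ddct, -11)        # log2(2048) planted enrichment
  expect_equal(r$fold_rounded, 2048)
  q1 <- simulate_qpcr(cfg)
  q2 <- simulate_qpcr(cfg_small(seed = 21L))
  expect_identical(q1$cq, q2$cq)
  expect_true(all(q1$reference_ids %in% rownames(q1$cq)))
})
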