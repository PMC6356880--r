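#' Simulation configuration for synthetic small-RNA libraries
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' describe a library with the read structure the analysis assumes: canonical
#' mature miRNAs (18-25 nt), planted isomiRs and allelic variants, reads from
#' two abundant control RNAs, degradation and precursor fragments, 3' adapter
#' read-through on a fixed 36-cycle single-end run, and position-class
#' substitution errors biased towards the read ends (3'-terminal 0.21,
#' 5'-terminal 0.02, internal 0.0004 per base call).
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param n_genes number of synthetic miRNA genes.
#' @param n_samples number of samples reads are attributed to.
#' @param library_size total number of reads to emit.
#' @param esv_rates named numeric `(r5, r_int, r3)`: per-base substitution
#'   probabilities for 5'-terminal, internal and 3'-terminal read positions.
#' @param window terminal window width in bases defining the 5'/3' position
#'   classes (also used downstream by the error model and classifier).
#' @param control_fraction fraction of reads drawn from the control RNAs.
#' @param fragment_rates named numeric `(degradation, precursor_fragment)`:
#'   fractions of 3'-truncated mature reads and random precursor substrings.
#' @param adapter 3' adapter sequence (DNA spelling accepted).
#' @param cycles sequencing cycle count; reads shorter than this carry
#'   adapter read-through.
#' @param phred_char constant Phred+33 quality symbol emitted for all bases.
#' @param isomir_spec data.frame (`gene`, `category`, `rel_abundance`) of
#'   planned isomiR variants; `category` is one of `isomir_3p_len` (3' U
#'   addition), `isomir_3p_sub` (3'-terminal substitution), `isomir_5p`
#'   (first-base substitution). Abundances are relative to the parent
#'   canonical (weight 1).
#' @param polymorphism_spec data.frame (`gene`, `position`, `rel_abundance`)
#'   of planned allelic variants; `position` is 1-based on the mature and must
#'   be internal and outside the seed.
#' @param cluster_spec data.frame (`gene_a`, `gene_b`, `gap`) of gene pairs
#'   placed on one contig, same strand, separated by `gap` bases.
#' @param tissue_profiles named list mapping tissue to a named numeric vector
#'   of per-miRNA relative abundances (used by [simulate_qpcr()]).
#' @param qpcr_noise_sd Gaussian noise sd on simulated Cq values.
#' @param qpcr_baseline Cq of a unit-abundance transcript.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 20L,
                              n_samples = 3L,
                              library_size = 1e5L,
                              esv_rates = c(r5 = 0.02, r_int = 0.0004, r3 = 0.21),
                              window = 2L,
                              control_fraction = 0.2,
                              fragment_rates = c(degradation = 0.05,
                                                 precursor_fragment = 0.05),
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              cycles = 36L,
                              phred_char = "I",
                              isomir_spec = NULL,
                              polymorphism_spec = NULL,
                              cluster_spec = NULL,
                              tissue_profiles = NULL,
                              qpcr_noise_sd = 0.15,
                              qpcr_baseline = 35) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  stopifnot(n_genes >= 1L, library_size > 0L, n_samples >= 1L)
  stopifnot(all(esv_rates >= 0), all(esv_rates <= 1))
  stopifnot(control_fraction >= 0, control_fraction <= 1,
            all(fragment_rates >= 0), sum(fragment_rates) + control_fraction < 1)
  if (is.null(isomir_spec)) {
    isomir_spec <- data.frame(
      gene = c(1L, 2L, 3L),
      category = c("isomir_3p_len", "isomir_3p_sub", "isomir_5p"),
      rel_abundance = c(2.5, 2.5, 0.25),
      stringsAsFactors = FALSE
    )
    isomir_spec <- isomir_spec[isomir_spec$gene <= n_genes, , drop = FALSE]
  }
  if (is.null(polymorphism_spec)) {
    polymorphism_spec <- data.frame(gene = 4L, position = 10L,
                                    rel_abundance = 1.0)
    polymorphism_spec <-
      polymorphism_spec[polymorphism_spec$gene <= n_genes, , drop = FALSE]
  }
  if (is.null(cluster_spec)) {
    cluster_spec <- data.frame(gene_a = 5L, gene_b = 6L, gap = 8000L)
    cluster_spec <- cluster_spec[cluster_spec$gene_b <= n_genes, ,
                                 drop = FALSE]
  }
  if (nrow(isomir_spec) &&
      (max(isomir_spec$gene) > n_genes ||
       !all(isomir_spec$category %in%
            c("isomir_3p_len", "isomir_3p_sub", "isomir_5p")))) {
    stop("invalid isomir_spec")
  }
  if (nrow(polymorphism_spec)) {
    stopifnot(all(polymorphism_spec$gene <= n_genes),
              all(polymorphism_spec$rel_abundance > 0))
  }
  if (is.null(tissue_profiles)) {
    tissue_profiles <- list(
      brain  = c("mir-sim-1-5p" = 2048, "mir-sim-2-5p" = 1, "mir-sim-3-5p" = 1,
                 "mir-sim-4-5p" = 100),
      liver  = c("mir-sim-1-5p" = 1, "mir-sim-2-5p" = 4096, "mir-sim-3-5p" = 1,
                 "mir-sim-4-5p" = 100),
      heart  = c("mir-sim-1-5p" = 1, "mir-sim-2-5p" = 1, "mir-sim-3-5p" = 512,
                 "mir-sim-4-5p" = 100),
      muscle = c("mir-sim-1-5p" = 1, "mir-sim-2-5p" = 1, "mir-sim-3-5p" = 1,
                 "mir-sim-4-5p" = 100)
    )
  }
  structure(list(seed = seed, n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 library_size = as.integer(library_size),
                 esv_rates = esv_rates, window = as.integer(window),
                 control_fraction = control_fraction,
                 fragment_rates = fragment_rates,
                 adapter = as_rna(adapter), cycles = as.integer(cycles),
                 phred_char = phred_char, isomir_spec = isomir_spec,
                 polymorphism_spec = polymorphism_spec,
                 cluster_spec = cluster_spec,
                 tissue_profiles = tissue_profiles,
                 qpcr_noise_sd = qpcr_noise_sd,
                 qpcr_baseline = qpcr_baseline),
            class = "sim_config")
}

#' Generate a synthetic miRNA gene complement
#'
#' Designs `n_genes` hairpin precursors (55-70 nt) whose 5p arm is a prefix
#' region and whose 3p arm is a suffix region, both exact substrings, with the
#' 3p arm largely reverse-complementary to the 5p arm so the precursor folds
#' into the expected duplex. Each precursor is placed on a synthetic contig
#' with 30-nt flanking context recorded; gene pairs named in
#' `config$cluster_spec` are placed on a shared contig, same strand, at the
#' configured gap, so cluster annotation can be tested against ground truth.
#'
#' Seed heptamers (mature bases 2-8) are made unique across genes, and the
#' genomic base immediately downstream of each mature is forced to `A` so a
#' planted 3' `U` addition is always non-templated.
#'
#' @param config a [simulation_config()].
#' @return list of class `mirnaome` with elements `precursors` (data.frame:
#'   `id`, `sequence`, `flank5`, `flank3`, `mature5p`, `mature3p`), `matures`
#'   (data.frame: `id`, `sequence`, `arm`, `parent`), `loci` (a
#'   [loci_frame()]), and `truth` (list with `clustered` id pairs).
#' @export
generate_mirnaome <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  pre <- vector("list", n)
  seeds_used <- character(0)
  for (i in seq_len(n)) {
    repeat {
      l5 <- sample(20:24, 1L)
      m5 <- .random_seq(l5)
      sd7 <- substr(m5, 2, 8)
      if (!sd7 %in% seeds_used) break
    }
    seeds_used <- c(seeds_used, sd7)
    # loop starts with A: the base after the 5p mature is never U, so a
    # planted 3' U addition on the 5p arm is always non-templated
    loop <- paste0("A", .random_seq(sample(14:19, 1L)))
    m3 <- paste0(revcomp_rna(substr(m5, 1, l5 - 2L)), "CC")
    hairpin <- paste0(m5, loop, m3)
    flank5 <- .random_seq(30L)
    # downstream base A: a planted 3' U addition can never be templated
    flank3 <- paste0("A", .random_seq(29L))
    pre[[i]] <- data.frame(
      id = sprintf("pre-mir-sim-%d", i), sequence = hairpin,
      flank5 = flank5, flank3 = flank3,
      mature5p = sprintf("mir-sim-%d-5p", i),
      mature3p = sprintf("mir-sim-%d-3p", i),
      m5 = m5, m3 = m3, stringsAsFactors = FALSE
    )
  }
  pre <- do.call(rbind, pre)
  matures <- rbind(
    data.frame(id = pre$mature5p, sequence = pre$m5, arm = "5p",
               parent = pre$id, stringsAsFactors = FALSE),
    data.frame(id = pre$mature3p, sequence = pre$m3, arm = "3p",
               parent = pre$id, stringsAsFactors = FALSE)
  )
  matures <- matures[order(matures$id), , drop = FALSE]
  rownames(matures) <- NULL
  pre$m5 <- NULL; pre$m3 <- NULL

  contig <- sprintf("contig_%d", seq_len(n))
  start <- rep(5000L, n)
  strand <- rep("+", n)
  plen <- nchar(pre$sequence)
  clustered <- NULL
  cs <- config$cluster_spec
  if (!is.null(cs) && nrow(cs)) {
    for (k in seq_len(nrow(cs))) {
      a <- cs$gene_a[k]; b <- cs$gene_b[k]
      contig[b] <- contig[a]
      start[b] <- start[a] + plen[a] + as.integer(cs$gap[k])
      strand[b] <- strand[a]
      clustered <- rbind(clustered,
                         data.frame(gene_a = pre$id[a], gene_b = pre$id[b]))
    }
  }
  loci <- loci_frame(id = pre$id, contig = contig, start = start,
                     end = start + plen, strand = strand)
  structure(list(precursors = pre, matures = matures, loci = loci,
                 truth = list(clustered = clustered)),
            class = "mirnaome")
}

#' Generate the two abundant control RNA references
#'
#' Emulates the use of a ribosomal RNA (1750 nt) and a short ribosomal protein
#' mRNA (540 nt) as in-library error controls: abundant, ubiquitous transcripts
#' whose reads are not expected to be RNA-edited, so any mismatch against them
#' measures the sequencing pipeline rather than biology.
#'
#' @param seed integer seed.
#' @return named character vector of two RNA sequences of lengths 1750 and 540.
#' @export
generate_control_references <- function(seed) {
  set.seed(as.integer(seed) + 2L)
  c(control_rRNA_like = .random_seq(1750L),
    control_mRNA_like = .random_seq(540L))
}

# Apply position-class substitution errors to reads.
# Each base is substituted independently: the first `window` read positions at
# rate r5, the last `window` at rate r3, all others at r_int. Returns the
# mutated sequences plus per-read mutation counts.
.apply_esv <- function(seqs, esv_rates, window) {
  lens <- nchar(seqs)
  n <- length(seqs)
  if (!n) return(list(sequence = seqs, n_mut = integer(0)))
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  idx <- rep.int(seq_len(n), lens)
  pos <- sequence(lens)
  len_of <- lens[idx]
  rate <- ifelse(pos <= window, esv_rates[["r5"]],
                 ifelse(pos > len_of - window, esv_rates[["r3"]],
                        esv_rates[["r_int"]]))
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    alt <- matrix(c("C", "G", "U",  # A ->
                    "A", "G", "U",  # C ->
                    "A", "C", "U",  # G ->
                    "A", "C", "G"), # U ->
                  nrow = 4L, byrow = TRUE,
                  dimnames = list(.RNA_BASES, NULL))
    cur <- match(chars[hit], .RNA_BASES)
    pick <- sample.int(3L, sum(hit), replace = TRUE)
    chars[hit] <- alt[cbind(cur, pick)]
  }
  n_mut <- tabulate(idx[hit], nbins = n)
  ends <- cumsum(lens)
  out <- substring(paste(chars, collapse = ""), ends - lens + 1L, ends)
  list(sequence = out, n_mut = n_mut)
}

#' Simulate reads from the control references only
#'
#' Draws inserts uniformly from the two control RNAs (start uniform over the
#' reference chosen proportionally to its length, insert length uniform on
#' `len_range`) and applies the position-class substitution error model. This
#' is the read population the ESV estimator is calibrated on.
#'
#' @param controls named character vector from [generate_control_references()].
#' @param n number of reads.
#' @param esv_rates,window as in [simulation_config()].
#' @param len_range integer length-2 insert size range.
#' @param seed integer seed.
#' @return data.frame with columns `sequence` (RNA), `reference`, `offset`
#'   (0-based start on the reference), `n_mut` (injected substitutions).
#' @export
simulate_control_reads <- function(controls, n,
                                   esv_rates = c(r5 = 0.02, r_int = 0.0004,
                                                 r3 = 0.21),
                                   window = 2L, len_range = c(18L, 25L),
                                   seed = 1L) {
  set.seed(as.integer(seed) + 3L)
  reflen <- nchar(controls)
  which_ref <- sample.int(length(controls), n, replace = TRUE,
                          prob = reflen / sum(reflen))
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  maxstart <- reflen[which_ref] - len
  off <- floor(runif(n) * (maxstart + 1))
  insert <- substring(controls[which_ref], off + 1L, off + len)
  mut <- .apply_esv(insert, esv_rates, window)
  data.frame(sequence = mut$sequence,
             reference = names(controls)[which_ref],
             offset = as.integer(off), n_mut = mut$n_mut,
             stringsAsFactors = FALSE)
}

#' Simulate a complete small-RNA sequencing library
#'
#' Draws reads from canonical matures, the planned isomiR and allelic
#' variants, the control references, 3'-truncated degradation products and
#' random precursor substrings, in the configured proportions; substitutes
#' each base independently at its position-class error rate; appends the 3'
#' adapter up to the cycle count; and records every read's provenance in a
#' ground-truth manifest.
#'
#' Planted variant sequences are deterministic given the miRNAome: 3' length
#' isomiRs append a non-templated `U`; 3' isomiRs substitute the last base
#' (to `U`, or `A` when the canonical already ends in `U`); 5' isomiRs
#' substitute the first base; allelic variants substitute the configured
#' internal position (to `C`, or `U` when the reference base is `C`).
#'
#' @param config a [simulation_config()].
#' @param mirnaome a [generate_mirnaome()] result.
#' @param controls a [generate_control_references()] result.
#' @return list of class `sim_library` with elements `reads` (data.frame:
#'   `id`, `sequence` with adapter read-through, `quality`), `manifest`
#'   (data.frame: `id`, `label`, `source`, `parent`, `sample`, `insert`,
#'   `planted`; `label` is the source label, replaced by `"esv"` for reads
#'   that acquired at least one substitution error), and `planted`
#'   (data.frame of the planted variant identities with expected category).
#' @export
simulate_library <- function(config, mirnaome, controls) {
  set.seed(config$seed + 4L)
  mat <- mirnaome$matures
  pre <- mirnaome$precursors
  canon <- setNames(mat$sequence, mat$id)

  # source pool: canonical 5p per gene plus planned variants
  gene_mature <- pre$mature5p
  pool <- data.frame(label = "canonical", parent = gene_mature,
                     sequence = unname(canon[gene_mature]),
                     weight = 1, stringsAsFactors = FALSE)
  isp <- config$isomir_spec
  if (nrow(isp)) {
    for (k in seq_len(nrow(isp))) {
      parent <- gene_mature[isp$gene[k]]
      cs <- canon[[parent]]
      L <- nchar(cs)
      v <- switch(isp$category[k],
        isomir_3p_len = paste0(cs, "U"),
        isomir_3p_sub = paste0(substr(cs, 1, L - 1),
                               if (substr(cs, L, L) == "U") "A" else "U"),
        isomir_5p = paste0(if (substr(cs, 1, 1) == "U") "A" else "U",
                           substr(cs, 2, L)))
      pool <- rbind(pool, data.frame(label = isp$category[k], parent = parent,
                                     sequence = v,
                                     weight = isp$rel_abundance[k]))
    }
  }
  psp <- config$polymorphism_spec
  if (nrow(psp)) {
    for (k in seq_len(nrow(psp))) {
      parent <- gene_mature[psp$gene[k]]
      cs <- canon[[parent]]
      p <- psp$position[k]
      stopifnot(p > config$window, p <= nchar(cs) - config$window,
                p < 2 || p > 8)
      ref <- substr(cs, p, p)
      v <- cs
      substr(v, p, p) <- if (ref == "C") "U" else "C"
      pool <- rbind(pool, data.frame(label = "polymorphism", parent = parent,
                                     sequence = v,
                                     weight = psp$rel_abundance[k]))
    }
  }

  N <- config$library_size
  frac_other <- config$control_fraction + sum(config$fragment_rates)
  probs <- c(pool$weight / sum(pool$weight) * (1 - frac_other),
             config$control_fraction,
             config$fragment_rates[["degradation"]],
             config$fragment_rates[["precursor_fragment"]])
  draw <- as.integer(rmultinom(1L, N, probs))
  npool <- nrow(pool)
  n_ctl <- draw[npool + 1L]
  n_deg <- draw[npool + 2L]
  n_frag <- draw[npool + 3L]

  src_label <- c(rep(pool$label, draw[seq_len(npool)]),
                 rep("control", n_ctl), rep("degradation", n_deg),
                 rep("precursor_fragment", n_frag))
  src_parent <- c(rep(pool$parent, draw[seq_len(npool)]),
                  rep(NA_character_, n_ctl + n_deg + n_frag))
  insert <- c(rep(pool$sequence, draw[seq_len(npool)]), character(n_ctl),
              character(n_deg), character(n_frag))

  if (n_ctl) {
    reflen <- nchar(controls)
    wr <- sample.int(length(controls), n_ctl, replace = TRUE,
                     prob = reflen / sum(reflen))
    ln <- sample(18:25, n_ctl, replace = TRUE)
    off <- floor(runif(n_ctl) * (reflen[wr] - ln + 1))
    insert[src_label == "control"] <- substring(controls[wr], off + 1L,
                                                off + ln)
  }
  if (n_deg) {
    g <- sample.int(config$n_genes, n_deg, replace = TRUE)
    cs <- canon[gene_mature[g]]
    L <- nchar(cs)
    trunc <- pmin(sample(1:4, n_deg, replace = TRUE), pmax(L - 18L, 1L))
    insert[src_label == "degradation"] <- substr(cs, 1, L - trunc)
    src_parent[src_label == "degradation"] <- gene_mature[g]
  }
  if (n_frag) {
    g <- sample.int(config$n_genes, n_frag, replace = TRUE)
    ps <- pre$sequence[g]
    L <- nchar(ps)
    ln <- pmin(sample(18:25, n_frag, replace = TRUE), L)
    off <- floor(runif(n_frag) * (L - ln + 1))
    insert[src_label == "precursor_fragment"] <- substring(ps, off + 1L,
                                                           off + ln)
    src_parent[src_label == "precursor_fragment"] <- pre$id[g]
  }

  ord <- sample.int(N, N)  # shuffle so read order carries no signal
  src_label <- src_label[ord]; src_parent <- src_parent[ord]
  insert <- insert[ord]
  planted_seq <- insert

  mut <- .apply_esv(insert, config$esv_rates, config$window)
  insert <- mut$sequence
  label <- ifelse(mut$n_mut > 0L, "esv", src_label)

  ids <- sprintf("read_%06d", seq_len(N))
  with_adapter <- substr(paste0(insert, config$adapter,
                                strrep("A", config$cycles)),
                         1, config$cycles)
  reads <- data.frame(id = ids, sequence = with_adapter,
                      quality = strrep(config$phred_char, config$cycles),
                      stringsAsFactors = FALSE)
  manifest <- data.frame(id = ids, label = label, source = src_label,
                         parent = src_parent,
                         sample = sprintf("sample_%d",
                                          sample.int(config$n_samples, N,
                                                     replace = TRUE)),
                         insert = insert, planted = planted_seq,
                         stringsAsFactors = FALSE)
  planted <- pool[pool$label != "canonical", c("label", "parent", "sequence")]
  rownames(planted) <- NULL
  structure(list(reads = reads, manifest = manifest, planted = planted,
                 config = config),
            class = "sim_library")
}

#' Simulate an RT-qPCR quantification-cycle table
#'
#' Cq values follow `baseline - log2(abundance) + noise`; the two reference
#' miRNAs (`mir-25-3p-like`, `mir-107-3p-like`) have constant abundance across
#' tissues up to noise, so reference-normalized contrasts recover the planted
#' log2 enrichments.
#'
#' @param config a [simulation_config()]; `tissue_profiles` must be set.
#' @param noise_sd overrides `config$qpcr_noise_sd` when not `NULL`.
#' @return list of class `qpcr_table` with elements `cq` (matrix, miRNA x
#'   sample), `tissue` (named character vector: sample -> tissue) and
#'   `reference_ids`.
#' @export
simulate_qpcr <- function(config, noise_sd = NULL) {
  set.seed(config$seed + 5L)
  if (is.null(noise_sd)) noise_sd <- config$qpcr_noise_sd
  profiles <- config$tissue_profiles
  stopifnot(length(profiles) >= 2L)
  mirnas <- names(profiles[[1]])
  refs <- c("mir-25-3p-like", "mir-107-3p-like")
  all_ids <- c(mirnas, refs)
  tissues <- names(profiles)
  samples <- paste(rep(tissues, each = config$n_samples),
                   rep(seq_len(config$n_samples), length(tissues)), sep = "_")
  tissue_of <- setNames(rep(tissues, each = config$n_samples), samples)
  cq <- matrix(NA_real_, length(all_ids), length(samples),
               dimnames = list(all_ids, samples))
  for (s in samples) {
    ab <- c(profiles[[tissue_of[[s]]]][mirnas], setNames(rep(1000, 2), refs))
    cq[, s] <- config$qpcr_baseline - log2(ab) +
      rnorm(length(ab), sd = noise_sd)
  }
  structure(list(cq = cq, tissue = tissue_of, reference_ids = refs),
            class = "qpcr_table")
}
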