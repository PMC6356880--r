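#' Filter candidate precursors by discovery score
#'
#' Keeps candidates whose discovery log-odds score is greater than or equal
#' to the cutoff (boundary inclusive).
#'
#' @param candidates data.frame with a numeric `score` column.
#' @param min_score score cutoff.
#' @return the passing rows.
#' @export
score_filter <- function(candidates, min_score = 2) {
  candidates[is.finite(candidates$score) & candidates$score >= min_score, ,
             drop = FALSE]
}

#' Fold a sequence into its maximum base-pairing hairpin structure
#'
#' Maximum-cardinality nested pairing over AU, GC and GU pairs with a minimum
#' hairpin loop, computed by dynamic programming (Nussinov-style). The
#' traceback is deterministic: pairing the outer bases is preferred over
#' leaving either end unpaired, which is preferred over bifurcation at the
#' smallest split point. This is a pairing-count folder, not a thermodynamic
#' one: the hairpin criteria it feeds are pairing fractions, not energies.
#'
#' @param sequence the sequence to fold (RNA or DNA spelling).
#' @param min_loop minimum number of unpaired bases closing a hairpin loop.
#' @return object of class `hairpin_structure`: list with `pairing` (integer
#'   vector, 1-based partner position or 0 when unpaired), `max_pairs`, and
#'   `sequence`.
#' @export
fold_hairpin <- function(sequence, min_loop = 3L) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  stopifnot(n >= min_loop + 2L)
  dp <- .nussinov_dp_cpp(sequence, as.integer(min_loop))
  bases <- strsplit(sequence, "")[[1]]
  pairable <- function(i, j) {
    a <- bases[i]; b <- bases[j]
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "U") || (a == "U" && b == "G")
  }
  pairing <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i >= j) next
    val <- dp[i, j]
    if (val == 0L) next
    inner <- if (i + 1L <= j - 1L) dp[i + 1L, j - 1L] else 0L
    if (pairable(i, j) && j - i - 1L >= min_loop && val == inner + 1L) {
      pairing[i] <- j; pairing[j] <- i
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
    } else if (val == dp[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else if (val == dp[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    } else {
      for (k in (i + 1L):(j - 1L)) {
        if (val == dp[i, k] + dp[k + 1L, j]) {
          stack[[length(stack) + 1L]] <- c(i, k)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  structure(list(pairing = pairing, max_pairs = dp[1L, n],
                 sequence = sequence),
            class = "hairpin_structure")
}

#' Validate a novel miRNA candidate against hairpin and read-evidence criteria
#'
#' The five criteria mirror the community standard for annotating a novel
#' miRNA gene from small-RNA read evidence:
#' \enumerate{
#'   \item detected in at least two independent samples;
#'   \item at least 10 perfectly matching (0-mismatch) mature/star reads
#'     mapped to the precursor arms;
#'   \item the two mature arms pair with each other in the folded hairpin,
#'     each with a 0-4 nt 3' overhang;
#'   \item consistent 5' processing: the modal 5' start among the dominant
#'     arm's perfect reads accounts for at least `homogeneity` of them
#'     (count-weighted);
#'   \item more than 60\% of each mature's bases are paired in the hairpin.
#' }
#'
#' @param candidate list with `precursor` (one-row data.frame with
#'   `sequence`, `mature5p`, `mature3p`), `matures` (data.frame `id`,
#'   `sequence`), and `read_evidence` (data.frame `sequence`, `count`,
#'   `sample`, `offset` (1-based start on the precursor), `mismatches`).
#' @param min_reads criterion-2 read count.
#' @param homogeneity criterion-4 modal 5'-start fraction.
#' @param min_paired_frac criterion-5 pairing fraction (strict).
#' @param overhang_range allowed 3' overhang lengths (criterion 3).
#' @param min_loop passed to [fold_hairpin()].
#' @return list of class `criteria_report`: logical `c1`..`c5`, `overall`
#'   (their conjunction), and an `evidence` list of the measured quantities.
#' @export
validate_criteria <- function(candidate, min_reads = 10L, homogeneity = 0.9,
                              min_paired_frac = 0.6,
                              overhang_range = c(0L, 4L), min_loop = 3L) {
  ev <- candidate$read_evidence
  if (is.null(ev) || !nrow(ev)) {
    stop("read evidence required: criteria 1, 2 and 4 are unevaluable")
  }
  prec <- candidate$precursor
  pseq <- as_rna(prec$sequence)
  m5 <- as_rna(candidate$matures$sequence[candidate$matures$id ==
                                            prec$mature5p])
  m3 <- as_rna(candidate$matures$sequence[candidate$matures$id ==
                                            prec$mature3p])
  at5 <- as.integer(regexpr(m5, pseq, fixed = TRUE))
  at3 <- as.integer(regexpr(m3, pseq, fixed = TRUE))
  if (at5 < 1L || at3 < 1L) stop("mature arms must be precursor substrings")
  span5 <- at5:(at5 + nchar(m5) - 1L)
  span3 <- at3:(at3 + nchar(m3) - 1L)

  # criterion 1: independent samples
  c1 <- length(unique(ev$sample)) >= 2L

  # criterion 2: perfect mature/star reads
  rd_end <- ev$offset + nchar(ev$sequence) - 1L
  on_arm <- (ev$offset <= max(span5) & rd_end >= min(span5)) |
    (ev$offset <= max(span3) & rd_end >= min(span3))
  perfect <- ev$mismatches == 0L & on_arm
  n_perfect <- sum(ev$count[perfect])
  c2 <- n_perfect >= min_reads

  # criteria 3 and 5: fold the hairpin
  fold <- fold_hairpin(pseq, min_loop = min_loop)
  p <- fold$pairing
  arm_report <- function(span, other) {
    paired_at <- span[p[span] > 0L]
    list(frac = length(paired_at) / length(span),
         inter = sum(p[span] %in% other),
         overhang = if (length(paired_at)) max(span) - max(paired_at)
         else NA_integer_)
  }
  a5 <- arm_report(span5, span3)
  a3 <- arm_report(span3, span5)
  c3 <- a5$inter > 0L && a3$inter > 0L &&
    !is.na(a5$overhang) && !is.na(a3$overhang) &&
    a5$overhang >= overhang_range[1] && a5$overhang <= overhang_range[2] &&
    a3$overhang >= overhang_range[1] && a3$overhang <= overhang_range[2]
  c5 <- a5$frac > min_paired_frac && a3$frac > min_paired_frac

  # criterion 4: 5' homogeneity of the dominant arm
  arm_of <- ifelse(abs(ev$offset - at5) <= abs(ev$offset - at3), "5p", "3p")
  perfect5 <- perfect & arm_of == "5p"
  perfect3 <- perfect & arm_of == "3p"
  dom <- if (sum(ev$count[perfect5]) >= sum(ev$count[perfect3])) perfect5
  else perfect3
  if (any(dom)) {
    starts <- tapply(ev$count[dom], ev$offset[dom], sum)
    modal_frac <- max(starts) / sum(starts)
  } else {
    modal_frac <- 0
  }
  c4 <- modal_frac >= homogeneity

  overall <- c1 && c2 && c3 && c4 && c5
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
                 overall = overall,
                 evidence = list(n_samples = length(unique(ev$sample)),
                                 n_perfect_reads = n_perfect,
                                 overhang_5p = a5$overhang,
                                 overhang_3p = a3$overhang,
                                 paired_frac_5p = a5$frac,
                                 paired_frac_3p = a3$frac,
                                 modal_start_frac = modal_frac)),
            class = "criteria_report")
}

#' Check that printed matures are exact substrings of their precursor
#'
#' Consistency check for curated precursor tables: both the 5p and the 3p
#' mature sequence must occur verbatim within the precursor sequence.
#'
#' @param tbl data.frame with columns `id`, `mature5p`, `mature3p`,
#'   `precursor` (sequences, any spelling).
#' @return logical vector, one element per row, named by `id`.
#' @export
check_mature_containment <- function(tbl) {
  p <- as_rna(tbl$precursor)
  m5 <- as_rna(tbl$mature5p)
  m3 <- as_rna(tbl$mature3p)
  ok <- vapply(seq_len(nrow(tbl)), function(i) {
    grepl(m5[i], p[i], fixed = TRUE) && grepl(m3[i], p[i], fixed = TRUE)
  }, logical(1))
  setNames(ok, tbl$id)
}

#' Count genomic occurrences of a precursor and flag interspersed repeats
#'
#' Counts exact occurrences of the precursor on both strands of the genome
#' contigs; candidates hitting more than `max_loci` loci are flagged as
#' likely interspersed repeats rather than miRNA genes.
#'
#' @param precursor precursor sequence.
#' @param genome named character vector of contig sequences.
#' @param max_loci flag threshold (strictly more than this flags).
#' @return list with `n_loci` and `repeat_flag`.
#' @export
flag_repeats <- function(precursor, genome, max_loci = 15L) {
  pre <- Biostrings::DNAString(as_dna(as_rna(precursor)))
  rc <- Biostrings::reverseComplement(pre)
  n <- 0L
  for (contig in genome) {
    subj <- Biostrings::DNAString(as_dna(as_rna(contig)))
    n <- n + Biostrings::countPattern(pre, subj) +
      Biostrings::countPattern(rc, subj)
  }
  list(n_loci = n, repeat_flag = n > max_loci)
}

#' Annotate clustered miRNA genes
#'
#' Single-linkage chaining of loci on the same contig and strand whose
#' inter-gene gap (end of one to start of the next, after sorting by start)
#' is at most `max_gap` bases. Chained groups of two or more genes form a
#' cluster named after its leftmost member; all other loci are unclustered.
#'
#' @param loci a [loci_frame()] data.frame.
#' @param max_gap maximum inter-gene gap in bases (boundary inclusive).
#' @return `loci` with a `cluster_id` column (`NA` for unclustered loci),
#'   rows in the original input order.
#' @export
annotate_clusters <- function(loci, max_gap = 10000L) {
  loci$cluster_id <- NA_character_
  ord <- order(loci$contig, loci$strand, loci$start, loci$id)
  key <- paste(loci$contig, loci$strand)
  for (grp in split(ord, key[ord])) {
    if (length(grp) < 2L) next
    s <- loci$start[grp]; e <- loci$end[grp]
    gap_ok <- s[-1] - e[-length(e)] <= max_gap
    chain_id <- cumsum(c(TRUE, !gap_ok))
    for (ch in split(grp, chain_id)) {
      if (length(ch) < 2L) next
      loci$cluster_id[ch] <- paste0("cluster_", loci$id[ch[1]])
    }
  }
  loci
}
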