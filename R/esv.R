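#' Best ungapped placement of reads on a reference
#'
#' Exhaustively scans every offset of each read along the reference and
#' returns the placement minimizing the mismatch count, with ties broken by
#' the smallest offset. Reads whose best placement still exceeds
#' `max_mismatches` are reported as unaligned. Short-read error profiling
#' needs no indel handling: indel-containing reads simply fail to align and
#' are ignored.
#'
#' @param reads character vector of read sequences (RNA or DNA spelling).
#' @param reference a single reference sequence.
#' @param max_mismatches maximum mismatches tolerated.
#' @return data.frame with one row per read: `offset` (0-based; `NA` when
#'   unaligned), `mismatches` (count), and `positions` (list column of
#'   1-based read positions of the mismatches).
#' @export
align_ungapped <- function(reads, reference, max_mismatches = 3L) {
  reads <- as_rna(reads)
  reference <- as_rna(reference)
  res <- .align_ungapped_cpp(reads, reference, as.integer(max_mismatches))
  off <- res$offset
  off[off < 0L] <- NA_integer_
  out <- data.frame(offset = off, mismatches = res$mismatches)
  out$positions <- res$positions
  out
}

#' Estimate the position-class ESV profile from control-aligned reads
#'
#' Aligns collapsed reads to the control references (each read is assigned to
#' the first reference, in input order, among those giving its minimal
#' mismatch count) and estimates, for each position class, the erroneous
#' sequence variant (ESV) ratio as the count-weighted fraction of base calls
#' in that class that mismatch the reference. Position classes are the first
#' `window` read positions (5'-terminal), the last `window` (3'-terminal),
#' and everything between (internal). This per-base-call convention makes the
#' internal ratio directly comparable to the Phred-implied per-bp error
#' probability (see [phred_error_prob()]).
#'
#' @param collapsed a [collapse_reads()] data.frame (`sequence`, `count`).
#' @param controls named character vector of control reference sequences.
#' @param window terminal window width in bases.
#' @param max_mismatches alignment mismatch tolerance.
#' @return object of class `esv_profile`: list with `r5`, `r_int`, `r3`
#'   (class ratios), `n_aligned` and `n_perfect` (count-weighted read
#'   totals), `window`, and `class_calls` (mismatching / total base calls
#'   per class).
#' @export
estimate_esv_profile <- function(collapsed, controls, window = 2L,
                                 max_mismatches = 3L) {
  stopifnot(nrow(collapsed) > 0L, length(controls) >= 1L)
  window <- as.integer(window)
  stopifnot(window >= 1L)
  hits <- vector("list", length(controls))
  for (j in seq_along(controls)) {
    hits[[j]] <- align_ungapped(collapsed$sequence, controls[[j]],
                                max_mismatches)
  }
  mm <- vapply(hits, function(h) {
    m <- h$mismatches
    m[is.na(m)] <- .Machine$integer.max
    m
  }, integer(nrow(collapsed)))
  mm <- matrix(mm, nrow = nrow(collapsed))
  best_ref <- apply(mm, 1L, which.min)  # first reference wins ties
  best_mm <- mm[cbind(seq_len(nrow(collapsed)), best_ref)]
  aligned <- best_mm != .Machine$integer.max
  if (!any(aligned)) stop("no reads aligned to the control references")

  lens <- nchar(collapsed$sequence)
  counts <- collapsed$count
  mm_calls <- c(r5 = 0, r_int = 0, r3 = 0)
  tot_calls <- c(
    r5 = sum(counts[aligned] * pmin(window, lens[aligned])),
    r_int = sum(counts[aligned] * pmax(lens[aligned] - 2L * window, 0L)),
    r3 = sum(counts[aligned] * pmin(window, lens[aligned]))
  )
  for (i in which(aligned & best_mm > 0L)) {
    pos <- hits[[best_ref[i]]]$positions[[i]]
    cls <- ifelse(pos <= window, "r5",
                  ifelse(pos > lens[i] - window, "r3", "r_int"))
    for (cl in cls) mm_calls[[cl]] <- mm_calls[[cl]] + counts[i]
  }
  ratios <- ifelse(tot_calls > 0, mm_calls / tot_calls, 0)
  structure(list(r5 = unname(ratios["r5"]), r_int = unname(ratios["r_int"]),
                 r3 = unname(ratios["r3"]),
                 n_aligned = sum(counts[aligned]),
                 n_perfect = sum(counts[aligned & best_mm == 0L]),
                 window = window,
                 class_calls = list(mismatch = mm_calls, total = tot_calls)),
            class = "esv_profile")
}

#' @export
print.esv_profile <- function(x, ...) {
  cat("ESV profile (terminal window:", x$window, "nt)\n")
  cat(sprintf("  5'-terminal : %.5f\n", x$r5))
  cat(sprintf("  internal    : %.5f\n", x$r_int))
  cat(sprintf("  3'-terminal : %.5f\n", x$r3))
  cat(sprintf("  aligned reads: %d (perfect: %d)\n", x$n_aligned,
              x$n_perfect))
  invisible(x)
}

#' Convert a Phred quality score to an error probability
#'
#' @param q Phred score(s), `>= 0`.
#' @return `10^(-q/10)`.
#' @examples
#' phred_error_prob(32)  # ~0.00063
#' @export
phred_error_prob <- function(q) {
  stopifnot(all(q >= 0))
  10^(-q / 10)
}

#' Filtering parameters for the ESV count threshold
#'
#' @param alpha safety multiplier on the expected ESV count (guards against
#'   noise in the estimated class ratios).
#' @param min_count absolute minimum count a variant must reach.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(alpha = 2, min_count = 10L) {
  stopifnot(alpha > 0, min_count >= 1L)
  structure(list(alpha = alpha, min_count = as.integer(min_count)),
            class = "filter_params")
}

#' Minimum count for a variant to be accepted as a true isomiR
#'
#' The count of reads identical to the canonical miRNA sets the scale: a
#' variant whose count could plausibly be produced by the class-specific ESV
#' rate acting on the canonical pool is rejected. The threshold is
#' `max(min_count, ceiling(alpha * r_class * canonical_count))`.
#'
#' @param profile an [estimate_esv_profile()] result.
#' @param canonical_count count of reads identical to the parent canonical.
#' @param variant_class one of `"5p"`, `"internal"`, `"3p"`.
#' @param params a [filter_params()].
#' @return integer minimum count.
#' @export
esv_threshold <- function(profile, canonical_count, variant_class,
                          params = filter_params()) {
  stopifnot(canonical_count >= 0)
  r <- switch(variant_class,
              "5p" = profile$r5,
              "internal" = profile$r_int,
              "3p" = profile$r3,
              stop("unknown variant class: ", variant_class))
  max(params$min_count, as.integer(ceiling(params$alpha * r *
                                           canonical_count)))
}
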