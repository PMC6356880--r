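# Seed-anchored classification of reads against canonical mature miRNAs.
#
# The anchor is an exact occurrence of a canonical's seed (bases 2-8) in the
# read; the implied offset fixes an ungapped alignment of read to canonical.
# Reads whose only edits fall inside the seed will not anchor to that
# canonical -- the same behavior as seed-extension isomiR aligners.

# alignment of one read against one canonical at 0-based shift s
# (read position of canonical base 1, minus 1; s = -1 means the canonical's
# first base lies upstream of the read start)
.align_at_anchor <- function(read, canon, s, window) {
  lr <- nchar(read); lc <- nchar(canon)
  c_idx <- seq_len(lc)
  r_idx <- s + c_idx
  inside <- r_idx >= 1L & r_idx <= lr
  rb <- strsplit(read, "")[[1]]
  cb <- strsplit(canon, "")[[1]]
  sub_at <- c_idx[inside][rb[r_idx[inside]] != cb[inside]]
  ext5 <- if (s > 0L) substr(read, 1L, s) else ""
  trunc5 <- sum(r_idx < 1L)
  ext3 <- if (s + lc < lr) substr(read, s + lc + 1L, lr) else ""
  trunc3 <- sum(r_idx > lr)
  n_edits <- length(sub_at) + nchar(ext5) + trunc5 + nchar(ext3) + trunc3

  category <- if (s != 0L || 1L %in% sub_at) {
    "isomir_5p"
  } else if (length(setdiff(sub_at, c(1L, seq(lc - window + 1L, lc))))) {
    "mismatch_internal"
  } else if (lr != lc) {
    "isomir_3p_len"
  } else if (length(sub_at)) {
    "isomir_3p_sub"
  } else {
    "canonical"
  }
  list(category = category, n_edits = n_edits, sub_at = sub_at,
       ext5 = ext5, trunc5 = trunc5, ext3 = ext3, trunc3 = trunc3)
}

#' Classify a read against a set of canonical mature miRNAs
#'
#' Finds every canonical whose seed (bases 2-8) occurs exactly in the read,
#' aligns the read at each implied offset, and keeps the assignment with the
#' fewest edits (substitutions plus end-length differences), breaking ties by
#' canonical id order. Categories: `canonical` (identical), `isomir_3p_sub`
#' (same 5' start, substitutions confined to the last `window` bases),
#' `isomir_3p_len` (same 5' start, 3' extension or shortening), `isomir_5p`
#' (different 5' start or first-base substitution), `mismatch_internal`
#' (internal substitutions).
#'
#' @param read a single read sequence.
#' @param matures data.frame with columns `id`, `sequence` (canonicals).
#' @param window 3'-terminal window width (same convention as the ESV model).
#' @return list with `parent`, `category`, `n_edits`, `sub_at` (1-based
#'   canonical positions of substitutions), `ext5`/`ext3` (end extensions),
#'   `trunc5`/`trunc3` (end truncations), or `NULL` when no seed anchors.
#' @export
classify_read <- function(read, matures, window = 2L) {
  read <- as_rna(read)
  best <- NULL
  for (i in seq_len(nrow(matures))) {
    canon <- matures$sequence[i]
    seed <- substr(canon, 2L, 8L)
    anchors <- .find_all_fixed(seed, read)[[1]]
    for (a in anchors) {
      al <- .align_at_anchor(read, canon, a - 2L, window)
      if (is.null(best) || al$n_edits < best$n_edits) {
        best <- c(list(parent = matures$id[i]), al)
      }
    }
  }
  best
}

# text encoding of substitution edits, "pos:ref>alt" joined by ";"
.fmt_edits <- function(read, canon, shift, sub_at) {
  if (!length(sub_at)) return("")
  paste(sprintf("%d:%s>%s", sub_at,
                substring(canon, sub_at, sub_at),
                substring(read, shift + sub_at, shift + sub_at)),
        collapse = ";")
}

# vectorized candidate generation: for each canonical, all reads containing
# its seed, with anchor positions; returns a data.frame of (read index,
# mature index, shift)
.anchor_candidates <- function(reads, matures) {
  out <- vector("list", nrow(matures))
  for (i in seq_len(nrow(matures))) {
    seed <- substr(matures$sequence[i], 2L, 8L)
    hits <- .find_all_fixed(seed, reads)
    nh <- lengths(hits)
    if (!sum(nh)) next
    out[[i]] <- data.frame(read = rep.int(seq_along(reads), nh),
                           mature = i, shift = unlist(hits) - 2L)
  }
  do.call(rbind, out)
}

#' Call isomiRs from collapsed reads
#'
#' Classifies every collapsed read against the canonical matures, then applies
#' the filtering rules that separate biological variants from pipeline
#' artifacts: reads shorter than their parent canonical are dropped
#' (indistinguishable from degradation products), templated 5' and 3' length
#' variants are dropped (indistinguishable from precursor fragments), and
#' every remaining variant is tested against the class-specific ESV count
#' threshold derived from its parent canonical's read count
#' (3' substitution and 3' length variants against the 3'-terminal rate, 5'
#' variants against the 5'-terminal rate, internal mismatches against the
#' internal rate).
#'
#' @param collapsed a [collapse_reads()] data.frame.
#' @param mirnaome a [generate_mirnaome()]-shaped object (`matures`,
#'   `precursors` with flanks).
#' @param profile an [estimate_esv_profile()] result.
#' @param params a [filter_params()].
#' @param window 3'-terminal window width.
#' @return data.frame of calls: `sequence`, `count`, `parent`, `category`,
#'   `n_edits`, `edits` (text encoding `pos:ref>alt`), `extension`,
#'   `templated`, `canonical_count`, `threshold`, `passed_filter`. Canonical
#'   reads are included with `threshold` 0 and `passed_filter` `TRUE`.
#' @export
call_isomirs <- function(collapsed, mirnaome, profile,
                         params = filter_params(), window = 2L) {
  matures <- mirnaome$matures
  cand <- .anchor_candidates(collapsed$sequence, matures)
  empty <- data.frame(sequence = character(0), count = integer(0),
                      parent = character(0), category = character(0),
                      n_edits = integer(0), edits = character(0),
                      extension = character(0), templated = logical(0),
                      canonical_count = integer(0), threshold = integer(0),
                      passed_filter = logical(0))
  if (is.null(cand) || !nrow(cand)) return(empty)

  rows <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$read[k]; j <- cand$mature[k]
    al <- .align_at_anchor(collapsed$sequence[i], matures$sequence[j],
                           cand$shift[k], window)
    rows[[k]] <- data.frame(
      read = i, parent = matures$id[j], category = al$category,
      n_edits = al$n_edits,
      edits = .fmt_edits(collapsed$sequence[i], matures$sequence[j],
                         cand$shift[k], al$sub_at),
      extension = al$ext3, ext5 = al$ext5,
      shorter = nchar(collapsed$sequence[i]) <
        nchar(matures$sequence[j]),
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, rows)
  # best assignment per read: fewest edits, ties by canonical id order
  calls <- calls[order(calls$read, calls$n_edits, calls$parent), ,
                 drop = FALSE]
  calls <- calls[!duplicated(calls$read), , drop = FALSE]

  # degradation-indistinguishable: read shorter than its canonical
  calls <- calls[!calls$shorter, , drop = FALSE]
  if (!nrow(calls)) return(empty)

  # templated checks for length/5' variants; substitutions never templated
  pre_of <- setNames(matures$parent, matures$id)
  calls$templated <- FALSE
  need <- calls$category %in% c("isomir_3p_len", "isomir_5p")
  for (k in which(need)) {
    prec <- mirnaome$precursors[
      mirnaome$precursors$id == pre_of[[calls$parent[k]]], , drop = FALSE]
    calls$templated[k] <- check_templated(
      list(parent = calls$parent[k], category = calls$category[k],
           edits = if (calls$n_edits[k] > 0L && nzchar(calls$edits[k]))
             calls$edits[k] else "",
           ext3 = calls$extension[k], ext5 = calls$ext5[k]),
      prec, matures)
  }
  calls <- calls[!(need & calls$templated), , drop = FALSE]
  if (!nrow(calls)) return(empty)

  calls$sequence <- collapsed$sequence[calls$read]
  calls$count <- collapsed$count[calls$read]
  canon_count <- tapply(
    calls$count[calls$category == "canonical"],
    calls$parent[calls$category == "canonical"], sum)
  cc <- canon_count[calls$parent]
  cc[is.na(cc)] <- 0L
  calls$canonical_count <- as.integer(cc)

  class_of <- c(canonical = NA, isomir_3p_sub = "3p", isomir_3p_len = "3p",
                isomir_5p = "5p", mismatch_internal = "internal")
  calls$threshold <- 0L
  calls$passed_filter <- TRUE
  for (k in which(calls$category != "canonical")) {
    thr <- esv_threshold(profile, calls$canonical_count[k],
                         class_of[[calls$category[k]]], params)
    calls$threshold[k] <- thr
    calls$passed_filter[k] <- calls$count[k] >= thr
  }
  calls$edits[calls$category == "canonical"] <- ""
  out <- calls[, c("sequence", "count", "parent", "category", "n_edits",
                   "edits", "extension", "templated", "canonical_count",
                   "threshold", "passed_filter")]
  rownames(out) <- NULL
  out
}

#' Is a variant call templated by the genomic context?
#'
#' A 3' extension is templated when it matches the genomic bases immediately
#' downstream of the mature within the precursor/flank; a 5' extension when
#' it matches the upstream context. Substitutions are never templated (an
#' edit is, by definition, a departure from the template). Templated length
#' variants cannot be distinguished from precursor degradation fragments and
#' are excluded upstream.
#'
#' @param call list with `parent`, `category`, `edits`, `ext3`, `ext5`.
#' @param precursor one-row data.frame from a `mirnaome$precursors` table
#'   (with `sequence`, `flank5`, `flank3`).
#' @param matures the `mirnaome$matures` table.
#' @return logical.
#' @export
check_templated <- function(call, precursor, matures) {
  if (!nrow(precursor) || !nzchar(precursor$flank5) ||
      !nzchar(precursor$flank3)) {
    stop("precursor flanks are required for templated checks")
  }
  if (nzchar(call$edits %||% "")) return(FALSE)  # substitutions present
  mseq <- matures$sequence[matures$id == call$parent]
  at <- regexpr(mseq, precursor$sequence, fixed = TRUE)
  if (at < 0L) stop("mature ", call$parent, " not found in its precursor")
  upstream <- paste0(precursor$flank5,
                     substr(precursor$sequence, 1L, at - 1L))
  downstream <- paste0(substr(precursor$sequence, at + nchar(mseq),
                              nchar(precursor$sequence)),
                       precursor$flank3)
  ok3 <- TRUE; ok5 <- TRUE
  if (nzchar(call$ext3 %||% "")) {
    ok3 <- substr(downstream, 1L, nchar(call$ext3)) == call$ext3
  }
  if (nzchar(call$ext5 %||% "")) {
    k <- nchar(call$ext5)
    ok5 <- substr(upstream, nchar(upstream) - k + 1L, nchar(upstream)) ==
      call$ext5
  }
  ok3 && ok5
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call allelic variants (polymorphic mature miRNAs)
#'
#' Internal single-substitution variants that pass the internal-class ESV
#' threshold and whose read fraction among the two alleles,
#' `variant / (variant + canonical)`, is strictly greater than
#' `min_fraction` are reported as polymorphisms rather than artifacts or
#' low-level editing.
#'
#' @param calls a [call_isomirs()] data.frame.
#' @param min_fraction minimum (strict) variant allele read fraction.
#' @return data.frame: `parent`, `position` (1-based on the mature), `ref`,
#'   `alt`, `variant_count`, `canonical_count`, `fraction`, `in_seed`
#'   (position within seed bases 2-8).
#' @export
call_polymorphisms <- function(calls, min_fraction = 0.40) {
  cand <- calls[calls$category == "mismatch_internal" &
                  calls$n_edits == 1L & calls$passed_filter, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(parent = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      variant_count = integer(0),
                      canonical_count = integer(0), fraction = numeric(0),
                      in_seed = logical(0)))
  }
  ed <- regmatches(cand$edits,
                   regexec("^(\\d+):([ACGU])>([ACGU])$", cand$edits))
  pos <- vapply(ed, function(e) as.integer(e[2]), integer(1))
  refb <- vapply(ed, function(e) e[3], character(1))
  altb <- vapply(ed, function(e) e[4], character(1))
  frac <- cand$count / (cand$count + cand$canonical_count)
  keep <- frac > min_fraction
  out <- data.frame(parent = cand$parent[keep], position = pos[keep],
                    ref = refb[keep], alt = altb[keep],
                    variant_count = cand$count[keep],
                    canonical_count = cand$canonical_count[keep],
                    fraction = frac[keep],
                    in_seed = pos[keep] >= 2L & pos[keep] <= 8L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare an allelic variant to its reference mature sequence
#'
#' Utility for curated reference/variant pairs: verifies the pair differs by
#' exactly one substitution and reports its position and whether it falls in
#' the seed (bases 2-8).
#'
#' @param reference,variant equal-length mature sequences.
#' @return list with `hamming`, `position` (1-based; `NA` unless
#'   `hamming == 1`), `ref`, `alt`, `in_seed`.
#' @export
compare_allelic_pair <- function(reference, variant) {
  reference <- as_rna(reference); variant <- as_rna(variant)
  stopifnot(nchar(reference) == nchar(variant))
  rb <- strsplit(reference, "")[[1]]
  vb <- strsplit(variant, "")[[1]]
  diff <- which(rb != vb)
  pos <- if (length(diff) == 1L) diff else NA_integer_
  list(hamming = length(diff), position = pos,
       ref = if (!is.na(pos)) rb[pos] else NA_character_,
       alt = if (!is.na(pos)) vb[pos] else NA_character_,
       in_seed = !is.na(pos) && pos >= 2L && pos <= 8L)
}

#' Summarize isomiR classes
#'
#' @param calls a [call_isomirs()] data.frame.
#' @return list with `class_counts` (passed variant calls per category),
#'   `pct_3p_end` (percentage of passed variants that are 3'-end variants,
#'   rounded to the nearest integer), and `parent_summary` (per parent:
#'   canonical count, summed passed variant count, their ratio, and a flag
#'   for variants more abundant than their canonical).
#' @export
summarize_classes <- function(calls) {
  variants <- calls[calls$category != "canonical" & calls$passed_filter, ,
                    drop = FALSE]
  cats <- c("isomir_3p_sub", "isomir_3p_len", "isomir_5p",
            "mismatch_internal")
  class_counts <- vapply(cats, function(cl) sum(variants$category == cl),
                         integer(1))
  n_var <- nrow(variants)
  pct_3p_end <- if (n_var) {
    round(100 * sum(variants$category %in%
                      c("isomir_3p_sub", "isomir_3p_len")) / n_var)
  } else {
    NA_real_
  }
  parent_summary <- NULL
  if (n_var) {
    vc <- tapply(variants$count, variants$parent, sum)
    cc <- tapply(calls$canonical_count, calls$parent, max)[names(vc)]
    more <- tapply(variants$count > variants$canonical_count,
                   variants$parent, any)
    parent_summary <- data.frame(
      parent = names(vc), canonical_count = as.integer(cc),
      variant_count = as.integer(vc),
      variant_to_canonical = ifelse(cc > 0, vc / cc, Inf),
      variant_exceeds_canonical = as.logical(more),
      stringsAsFactors = FALSE)
    rownames(parent_summary) <- NULL
  }
  list(class_counts = class_counts, pct_3p_end = pct_3p_end,
       parent_summary = parent_summary)
}

#' Percentage of 3'-end variants from class counts
#'
#' Class-summary arithmetic on externally tabulated counts of 3'
#' substitution, 3' length and 5' variants.
#'
#' @param n_3p_sub,n_3p_len,n_5p variant counts per class.
#' @return integer percentage of all variants that are 3'-end variants.
#' @export
pct_3p_end_variants <- function(n_3p_sub, n_3p_len, n_5p) {
  round(100 * (n_3p_sub + n_3p_len) / (n_3p_sub + n_3p_len + n_5p))
}
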