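#' Trim the 3' adapter from reads
#'
#' Removes everything from the leftmost qualifying adapter occurrence onward:
#' either a full internal match of the adapter, or a 3'-terminal match of an
#' adapter prefix of at least `min_overlap` bases (the read-through case where
#' the insert plus a partial adapter fills the cycle count). Reads without a
#' qualifying match are returned unchanged; reads where nothing remains become
#' `NA`.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (DNA or RNA spelling).
#' @param min_overlap minimum exact 3'-terminal overlap with the adapter
#'   prefix.
#' @return character vector of trimmed reads (`NA` where nothing remains).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  stopifnot(nzchar(adapter))
  reads <- as_rna(reads)
  adapter <- as_rna(adapter)
  la <- nchar(adapter)
  n <- length(reads)
  lens <- nchar(reads)
  cut <- rep.int(NA_integer_, n)  # 1-based position where the adapter starts

  # full internal occurrence (leftmost)
  full <- regexpr(adapter, reads, fixed = TRUE)
  has_full <- full > 0L
  cut[has_full] <- full[has_full]

  # 3'-terminal overlap with an adapter prefix, length min_overlap .. la-1;
  # the leftmost (smallest) qualifying cut wins
  hi <- min(la - 1L, if (n) max(lens) else 0L)
  if (hi >= min_overlap) {
    for (k in hi:min_overlap) {
      pref <- substr(adapter, 1L, k)
      at <- lens - k + 1L
      match_k <- at >= 1L & substr(reads, at, lens) == pref
      upd <- match_k & (is.na(cut) | at < cut)
      cut[upd] <- at[upd]
    }
  }

  out <- reads
  trimmed <- !is.na(cut)
  out[trimmed] <- substr(reads[trimmed], 1L, cut[trimmed] - 1L)
  out[trimmed & cut == 1L] <- NA_character_
  out
}

#' Filter reads to the expected mature miRNA size range
#'
#' @param reads character vector of read sequences.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 25 nt, the
#'   expected size range of mature miRNAs).
#' @return the reads whose length is within `[min_len, max_len]`.
#' @export
size_filter <- function(reads, min_len = 18L, max_len = 25L) {
  reads <- reads[!is.na(reads)]
  reads[nchar(reads) >= min_len & nchar(reads) <= max_len]
}

#' Collapse reads into unique sequences with counts
#'
#' @param reads character vector of read sequences.
#' @param samples optional character vector parallel to `reads` attributing
#'   each read to a sample.
#' @return data.frame with columns `sequence`, `count` and (when `samples`
#'   is given) `samples` (comma-joined sorted unique sample ids), sorted by
#'   descending count with ties broken lexicographically by sequence.
#' @export
collapse_reads <- function(reads, samples = NULL) {
  reads <- as_rna(reads)
  if (!length(reads)) {
    return(data.frame(sequence = character(0), count = integer(0)))
  }
  tab <- table(reads)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    stopifnot(length(samples) == length(reads))
    sm <- lapply(split(samples, reads), function(s)
      paste(sort(unique(s)), collapse = ","))
    out$samples <- unlist(sm)[out$sequence]
  }
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full read preprocessing chain
#'
#' Adapter trimming, size filtering and collapsing, in that order.
#'
#' @param reads character vector of raw read sequences.
#' @param adapter adapter sequence.
#' @param min_len,max_len size-filter bounds.
#' @param min_overlap adapter trimming minimum overlap.
#' @param samples optional per-read sample ids.
#' @return a [collapse_reads()] data.frame.
#' @export
preprocess_reads <- function(reads, adapter, min_len = 18L, max_len = 25L,
                             min_overlap = 5L, samples = NULL) {
  trimmed <- trim_adapter(reads, adapter, min_overlap)
  keep <- !is.na(trimmed) & nchar(trimmed) >= min_len &
    nchar(trimmed) <= max_len
  collapse_reads(trimmed[keep],
                 samples = if (!is.null(samples)) samples[keep])
}
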