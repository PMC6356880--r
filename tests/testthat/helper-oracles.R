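# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# exhaustive all-offset scan for the best ungapped placement
oracle_align <- function(read, reference, max_mismatches = 3L) {
  rb <- strsplit(read, "")[[1]]
  fb <- strsplit(reference, "")[[1]]
  n <- length(rb)
  if (n > length(fb)) return(NULL)
  best <- NULL
  for (off in 0:(length(fb) - n)) {
    mm <- which(rb != fb[off + seq_len(n)])
    if (is.null(best) || length(mm) < length(best$pos)) {
      best <- list(offset = off, pos = mm)
    }
  }
  if (length(best$pos) > max_mismatches) return(NULL)
  best
}

# exhaustive enumeration of all nested AU/GC/GU structures (no memoization);
# returns the maximum number of pairs
oracle_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  ok <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 1L):j) {
      if (k - i - 1L >= min_loop && ok(b[i], b[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(b))
}

# brute-force scan of every 7-mer window for reverse-complementarity to the
# seed (Watson-Crick only)
oracle_seed_sites <- function(mature, utr) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seed <- strsplit(substr(mature, 2, 8), "")[[1]]
  ub <- strsplit(utr, "")[[1]]
  hits <- integer(0)
  if (length(ub) < 7) return(hits)
  for (s in 1:(length(ub) - 6L)) {
    win <- ub[s:(s + 6L)]
    if (all(win == rev(unname(comp[seed])))) hits <- c(hits, s)
  }
  hits
}

# leftmost qualifying adapter cut, by trying every cut position directly
oracle_trim <- function(read, adapter, min_overlap = 5L) {
  n <- nchar(read); la <- nchar(adapter)
  for (i in seq_len(n)) {
    frag <- substr(read, i, n)
    lf <- nchar(frag)
    full <- lf >= la && substr(frag, 1, la) == adapter
    suff <- lf < la && lf >= min_overlap && frag == substr(adapter, 1, lf)
    if (full || suff) {
      if (i == 1L) return(NA_character_)
      return(substr(read, 1, i - 1L))
    }
  }
  read
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
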