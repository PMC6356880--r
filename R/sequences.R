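#' Normalize nucleotide sequences to the internal RNA alphabet
#'
#' Uppercases sequences and converts `T` to `U` so that DNA- and RNA-space
#' inputs (mature miRNAs are conventionally printed in RNA, genomes in DNA)
#' compare as equal. Validates that only `A`, `C`, `G`, `U`/`T`, `N` occur.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over the alphabet `A`, `C`, `G`, `U`, `N`.
#' @examples
#' as_rna(c("acgt", "ACGU"))
#' @export
as_rna <- function(x) {
  nm <- names(x)
  x <- chartr("T", "U", toupper(as.character(x)))
  names(x) <- nm
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("invalid nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  x
}

#' Convert internal RNA sequences to DNA spelling
#'
#' @param x character vector of RNA sequences.
#' @return character vector with `U` replaced by `T`.
#' @export
as_dna <- function(x) {
  nm <- names(x)
  x <- chartr("Uu", "Tt", as.character(x))
  names(x) <- nm
  x
}

#' Reverse complement of RNA sequences
#'
#' Watson-Crick reverse complement in RNA space (`A<->U`, `G<->C`).
#'
#' @param x character vector of RNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp_rna("GAGGUAG")
#' @export
revcomp_rna <- function(x) {
  vapply(as_rna(x), function(s) {
    paste(rev(.COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all (overlapping) start positions of fixed `pattern` in each element of `x`;
# returns a list of 1-based integer vectors
.find_all_fixed <- function(pattern, x) {
  pat <- paste0("(?=", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", pattern), ")")
  hits <- gregexpr(pat, x, perl = TRUE)
  lapply(hits, function(h) {
    h <- as.integer(h)
    h[h > 0L]
  })
}

# random sequence helper used by the generators
.random_seq <- function(n, bases = .RNA_BASES, prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}
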