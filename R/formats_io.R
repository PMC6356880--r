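#' Read a FASTA file into a named vector of RNA sequences
#'
#' Sequences are uppercased and `T` is normalized to `U` (the package works in
#' RNA space internally). Record ids are the first whitespace-delimited token
#' of each header; the remainder is kept as the `description` attribute.
#'
#' @param path path to a FASTA file.
#' @return named character vector of RNA sequences, with a `description`
#'   character vector attribute parallel to the records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  if (length(seqs) && any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(names(set)[!nzchar(seqs)], collapse = ", "))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- as_rna(seqs)
  names(out) <- ids
  attr(out, "description") <- desc
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs named character vector of sequences (RNA or DNA spelling).
#' @param path output path.
#' @param dna write in DNA spelling (`U` as `T`)? Default keeps RNA.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, dna = FALSE) {
  stopifnot(!is.null(names(seqs)))
  s <- as_rna(seqs)
  if (dna) s <- as_dna(s)
  set <- Biostrings::BStringSet(setNames(s, names(seqs)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Reads are normalized to the internal RNA alphabet. Read/quality length
#' equality is checked per record.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `sequence` (RNA), `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    list(ids = names(set), seqs = as.character(set),
         qual = as.character(S4Vectors::mcols(set)$qualities))
  }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  qual <- parsed$qual
  seqs <- parsed$seqs
  if (any(nchar(seqs, type = "bytes") != nchar(qual, type = "bytes"))) {
    stop("read/quality length mismatch at record(s): ",
         paste(utils::head(which(nchar(seqs) != nchar(qual)), 5L),
               collapse = ", "))
  }
  data.frame(id = sub("\\s.*$", "", parsed$ids),
             sequence = as_rna(seqs),
             quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' Sequences are written in DNA spelling, as produced by sequencers.
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("read/quality length mismatch")
  }
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$id)
  lines[seq(2, length(lines), 4)] <- as_dna(reads$sequence)
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$quality
  writeLines(lines, path)
  invisible(path)
}

#' Construct a table of genomic loci
#'
#' Loci use 0-based half-open coordinates internally (unambiguous interval
#' arithmetic for the 10-kb cluster rule); GFF3 output is 1-based inclusive.
#'
#' @param id character vector of feature ids.
#' @param contig character vector of contig names.
#' @param start,end integer vectors, 0-based half-open (`end > start`).
#' @param strand character vector of `"+"`/`"-"`.
#' @return data.frame of class `mir_loci`.
#' @export
loci_frame <- function(id, contig, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("start must be non-negative")
  if (any(end <= start)) stop("end must be greater than start")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(id = as.character(id), contig = as.character(contig),
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("mir_loci", "data.frame")
  out
}

#' Write loci to a GFF3 file
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention. Extra columns of `loci` beyond the five locus
#' fields (e.g. `cluster_id`) are emitted as GFF3 attributes.
#'
#' @param loci a [loci_frame()] data.frame, optionally with attribute columns.
#' @param path output path.
#' @param type GFF3 feature type (column 3).
#' @param source GFF3 source (column 2).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path, type = "miRNA_primary_transcript",
                       source = "mirforge") {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- loci$id
  extra <- setdiff(names(loci), c("id", "contig", "start", "end", "strand"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- loci[[col]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into a loci table
#'
#' Coordinates are converted back to the internal 0-based half-open
#' convention; GFF3 attributes become extra columns.
#'
#' @param path path to a GFF3 file.
#' @return a [loci_frame()] data.frame with any attribute columns appended.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- as.character(seq_along(gr))
  out <- loci_frame(
    id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  for (col in setdiff(names(mc), c("source", "type", "score", "phase", "ID"))) {
    out[[col]] <- mc[[col]]
  }
  out
}
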