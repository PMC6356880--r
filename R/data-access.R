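#' Bundled example datasets
#'
#' Three curated tables from the Atlantic salmon miRNAome ship with the
#' package as worked validation material:
#' \describe{
#'   \item{`novel_salmon_mirnas.tsv`}{17 novel miRNA precursors with their
#'     mature 5p/3p products; every mature is an exact substring of its
#'     precursor.}
#'   \item{`polymorphic_salmon_mirnas.tsv`}{5 reference/variant pairs of
#'     polymorphic mature miRNAs, each differing by a single substitution.}
#'   \item{`qpcr_tissue_enrichment.tsv`}{20 RT-qPCR tissue-enrichment
#'     measurements (delta-delta-Ct and the implied fold enrichment).}
#' }
#'
#' @param file file name within the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return path to the file, or a character vector of file names.
#' @examples
#' mirforge_example()
#' novel <- read.delim(mirforge_example("novel_salmon_mirnas.tsv"))
#' @export
mirforge_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "mirforge", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled file named ", file)
  path
}
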